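#' File readers and writers
#'
#' Plain-text interchange for the pipeline: pedigree and genotype TSV,
#' marker-map TSV, phenotype CSV, truth CSV. All files carry a header row,
#' use `NA` for missing values and round-trip through the matching reader.
#'
#' @param x object to write.
#' @param path file path.
#' @name io
NULL

#' @rdname io
#' @export
write_pedigree <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname io
#' @export
read_pedigree <- function(path) {
  p <- utils::read.delim(path)
  p$id <- as.integer(p$id); p$sire <- as.integer(p$sire)
  p$dam <- as.integer(p$dam); p$generation <- as.integer(p$generation)
  p
}

#' @rdname io
#' @export
write_genotypes <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname io
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  G <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(G) <- "integer"
  rownames(G) <- df$id
  G
}

#' @rdname io
#' @export
write_marker_map <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname io
#' @export
read_marker_map <- function(path) utils::read.delim(path)

#' @rdname io
#' @export
write_phenotypes <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
}

#' @rdname io
#' @export
read_phenotypes <- function(path) utils::read.csv(path, check.names = FALSE)

#' @rdname io
#' @param truth truth list as produced by [sim_phenotypes()].
#' @param dir directory receiving `truth_tbv.csv` and `truth_qtl.csv`.
#' @export
write_truth <- function(truth, dir) {
  tbv <- data.frame(id = rownames(truth$tbv), truth$tbv, check.names = FALSE)
  utils::write.csv(tbv, file.path(dir, "truth_tbv.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(truth$qtl, file.path(dir, "truth_qtl.csv"),
                   row.names = FALSE, quote = FALSE)
}

#' @rdname io
#' @export
read_truth <- function(dir) {
  tbv_df <- utils::read.csv(file.path(dir, "truth_tbv.csv"), check.names = FALSE)
  tbv <- as.matrix(tbv_df[, -1, drop = FALSE])
  rownames(tbv) <- tbv_df$id
  list(tbv = tbv,
       qtl = utils::read.csv(file.path(dir, "truth_qtl.csv")))
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Values that parse as numbers become numeric.
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    key <- trimws(p[1])
    val <- trimws(paste(p[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
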