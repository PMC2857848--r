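#' The twelve low-density panel scenarios
#'
#' Catalogue of reduced-density GEBV scenarios: markers chosen for even
#' genome spacing (`EVEN`) or largest absolute estimated effect (`SIG`), at
#' 19, 38 or 76 genotyped SNPs, optionally completed to the full panel with
#' genotype probabilities (`_GP`).
#'
#' @param panel_size full panel size (default 453).
#' @return data.frame: `scenario`, `selection` (`even`/`sig`),
#'   `n_genotyped`, `use_gp`, `n_prob_filled`, `n_total`.
#' @export
scenario_table <- function(panel_size = 453L) {
  sel <- rep(c("even", "sig"), each = 3)
  mg <- rep(c(19L, 38L, 76L), 2)
  base <- data.frame(
    scenario = paste0(toupper(sel), "_", mg),
    selection = sel, n_genotyped = mg, use_gp = FALSE)
  gp <- base
  gp$scenario <- sub("_", "_GP_", gp$scenario)
  gp$use_gp <- TRUE
  out <- rbind(base, gp)
  out$n_prob_filled <- ifelse(out$use_gp, panel_size - out$n_genotyped, 0L)
  out$n_total <- out$n_genotyped + out$n_prob_filled
  out
}

#' Look up one scenario specification by name
#'
#' @param name e.g. `"EVEN_GP_19"`.
#' @inheritParams scenario_table
#' @return single-row data.frame from [scenario_table()].
#' @export
scenario_spec <- function(name, panel_size = 453L) {
  tab <- scenario_table(panel_size)
  row <- tab[tab$scenario == name, ]
  if (nrow(row) != 1) stop("unknown scenario: ", name)
  row
}

#' Select markers evenly spaced along the genome
#'
#' Default `"quantile"` rule: places `m` targets at the quantile centers
#' `(i - 0.5)/m` of the cumulative map length and takes the nearest marker
#' to each (ties to the lower index); a marker hit twice is replaced by the
#' next unused marker. The `"stride"` alternative ignores map distances and
#' picks indices at the same quantile centers of the marker index range.
#'
#' @param map marker map (`chrom`, `pos` in Morgan).
#' @param m number of markers to select (<= panel size).
#' @param rule `"quantile"` (map-aware, default) or `"stride"`.
#' @return sorted integer marker indices.
#' @export
select_even <- function(map, m, rule = c("quantile", "stride")) {
  rule <- match.arg(rule)
  n <- nrow(map)
  if (m < 1 || m > n) stop("m must lie in 1..panel size")
  if (rule == "stride")
    return(as.integer(ceiling(n * (seq_len(m) - 0.5) / m)))
  chroms <- unique(map$chrom)
  lens <- vapply(chroms, function(c) max(map$pos[map$chrom == c]), numeric(1))
  offs <- c(0, cumsum(lens))[seq_along(chroms)]
  cum <- map$pos + offs[match(map$chrom, chroms)]
  L <- sum(lens)
  targets <- L * (seq_len(m) - 0.5) / m
  chosen <- integer(0)
  for (t in targets) {
    d <- abs(cum - t)
    cand <- order(d, seq_len(n))   # ties to the lower index
    pick <- cand[!(cand %in% chosen)][1]
    chosen <- c(chosen, pick)
  }
  sort(chosen)
}

#' Select the markers with the largest absolute effects
#'
#' @param beta_means per-marker posterior-mean effects from a completed
#'   training run.
#' @param m number of markers (<= panel size).
#' @return sorted integer marker indices of the `m` largest `|beta|`; ties
#'   broken by the lower index.
#' @export
select_largest_effects <- function(beta_means, m) {
  n <- length(beta_means)
  if (m < 1 || m > n) stop("m must lie in 1..panel size")
  ord <- order(-abs(beta_means), seq_len(n))
  sort(ord[seq_len(m)])
}

#' Build the low-density design matrix for a scenario
#'
#' Selected markers contribute their observed integer codes. With genotype
#' probabilities on (`use_gp`), every remaining marker contributes the
#' expected code `P1 + 2 P2` and the design spans the full panel; off, the
#' design holds only the selected columns and must be paired with the
#' matching subset of effects.
#'
#' @param genotypes observed genotype matrix for the individuals to
#'   predict (full panel columns).
#' @param selected integer indices of the genotyped subset.
#' @param probs genotype-probability table from [genotype_prob_table()]
#'   covering (at least) the non-selected markers; required when `use_gp`.
#' @param use_gp logical.
#' @return numeric design matrix; columns follow the full panel order when
#'   `use_gp`, else the selected markers.
#' @export
build_design <- function(genotypes, selected, probs = NULL, use_gp = FALSE) {
  m_full <- ncol(genotypes)
  if (!use_gp) {
    X <- genotypes[, selected, drop = FALSE]
    storage.mode(X) <- "double"
    return(X)
  }
  if (is.null(probs)) stop("use_gp requires a genotype-probability table")
  other <- setdiff(seq_len(m_full), selected)
  need <- colnames(genotypes)[other]
  if (!all(need %in% colnames(probs$P1)))
    stop("probability table is missing markers required by the scenario")
  X <- matrix(0, nrow(genotypes), m_full,
              dimnames = dimnames(genotypes))
  X[, selected] <- genotypes[, selected]
  X[, other] <- expected_genotype_code(
    probs$P1[rownames(genotypes), need, drop = FALSE],
    probs$P2[rownames(genotypes), need, drop = FALSE])
  X
}

#' Genomic breeding values from a design and effect vector
#'
#' `GEBV_i = sum_j X[i, j] beta_j`; no intercept (correlations and
#' regressions downstream are location-invariant).
#'
#' @param X design matrix (observed and/or expected genotype codes).
#' @param beta effect vector matching the columns of `X`.
#' @return named numeric vector of GEBV.
#' @export
compute_gebv <- function(X, beta) {
  if (ncol(X) != length(beta))
    stop("design has ", ncol(X), " columns but ", length(beta), " effects")
  drop(X %*% beta)
}

#' GEBV for one low-density scenario
#'
#' Subsets the full-panel posterior-mean effects (never retrained) for the
#' scenario's marker set and evaluates the design from [build_design()].
#'
#' @param scenario scenario name or single-row spec.
#' @param genotypes prediction-set genotype matrix (full panel).
#' @param map marker map.
#' @param beta_means full-panel posterior-mean effects.
#' @param probs probability table (needed for `_GP` scenarios).
#' @return list: `gebv`, `selected` indices, `scenario`.
#' @export
scenario_gebv <- function(scenario, genotypes, map, beta_means,
                          probs = NULL) {
  spec <- if (is.character(scenario))
    scenario_spec(scenario, ncol(genotypes)) else scenario
  selected <- if (spec$selection == "even")
    select_even(map, spec$n_genotyped)
  else select_largest_effects(beta_means, spec$n_genotyped)
  X <- build_design(genotypes, selected, probs, spec$use_gp)
  beta <- if (spec$use_gp) beta_means else beta_means[selected]
  list(gebv = compute_gebv(X, beta), selected = selected,
       scenario = spec$scenario)
}
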