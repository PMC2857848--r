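#' Simulate a two-generation full/half-sib pedigree
#'
#' Builds a pedigree with unrelated founder sires and dams followed by one
#' offspring generation. Every sire is mated to every dam and the offspring
#' are allocated to the sire-by-dam full-sib families as evenly as possible,
#' so the default (5 sires, 20 dams, 2000 offspring) yields 100 full-sib
#' families of 20, connected into paternal and maternal half-sib groups.
#'
#' @param n_sires,n_dams,n_offspring positive counts of founder sires,
#'   founder dams and offspring.
#' @param seed integer seed; the allocation itself is deterministic, the seed
#'   only fixes the (round-robin) order in which leftover offspring are
#'   assigned when families cannot be exactly even.
#' @return a `data.frame` with columns `id`, `sire`, `dam`, `generation`
#'   (0 for founders, 1 for offspring); `0` encodes an unknown parent.
#'   Parents always precede offspring.
#' @export
sim_pedigree <- function(n_sires, n_dams, n_offspring, seed = 1L) {
  stopifnot(n_sires >= 1, n_dams >= 1, n_offspring >= 1)
  n_f <- n_sires + n_dams
  sire_ids <- seq_len(n_sires)
  dam_ids <- n_sires + seq_len(n_dams)
  # full factorial mating; distribute offspring over families as evenly as
  # possible, remainders to the earliest families
  fam <- expand.grid(sire = sire_ids, dam = dam_ids)
  n_fam <- nrow(fam)
  base <- n_offspring %/% n_fam
  extra <- n_offspring %% n_fam
  sizes <- rep(base, n_fam) + as.integer(seq_len(n_fam) <= extra)
  off_sire <- rep(fam$sire, sizes)
  off_dam <- rep(fam$dam, sizes)
  data.frame(
    id = c(sire_ids, dam_ids, n_f + seq_len(n_offspring)),
    sire = c(rep(0L, n_f), off_sire),
    dam = c(rep(0L, n_f), off_dam),
    generation = c(rep(0L, n_f), rep(1L, n_offspring))
  )
}

#' Default marker map emulating a five-chromosome, one-Morgan genome
#'
#' @param n_markers total marker count (default 453), spread over the
#'   chromosomes as evenly as possible and approximately equally spaced
#'   within each.
#' @param n_chrom number of chromosomes (default 5).
#' @param chrom_length chromosome length in Morgan (default 1).
#' @return `data.frame` with `marker` (name), `chrom`, `pos` (Morgan).
#' @export
sim_marker_map <- function(n_markers = 453L, n_chrom = 5L, chrom_length = 1) {
  stopifnot(n_markers >= 1, n_chrom >= 1, chrom_length > 0)
  per <- rep(n_markers %/% n_chrom, n_chrom) +
    as.integer(seq_len(n_chrom) <= n_markers %% n_chrom)
  chrom <- rep(seq_len(n_chrom), per)
  pos <- unlist(lapply(per, function(k) chrom_length * (seq_len(k) - 0.5) / k),
                use.names = FALSE)
  data.frame(
    marker = sprintf("M%03d", seq_len(n_markers)),
    chrom = chrom,
    pos = pos
  )
}

#' Sample one gamete from a phased parent
#'
#' Picks a starting haplotype per chromosome and switches between the two
#' parental haplotypes at each marker interval with the Haldane
#' recombination fraction `r = (1 - exp(-2d)) / 2` (d in Morgan); no
#' interference, chromosomes independent.
#'
#' @param h1,h2 parental haplotypes (0/1 vectors over the map's markers).
#' @param map marker map (`chrom`, `pos`).
#' @return 0/1 gamete vector.
#' @export
sim_gamete <- function(h1, h2, map) {
  m <- length(h1)
  d <- diff(map$pos)
  newchrom <- diff(map$chrom) != 0
  r <- (1 - exp(-2 * d)) / 2
  r[newchrom] <- 0.5
  switch_at <- c(stats::runif(1) < 0.5, stats::runif(m - 1) < r)
  src <- cumsum(switch_at) %% 2L
  ifelse(src == 0L, h1, h2)
}

#' Gene-drop SNP genotypes through a pedigree
#'
#' Founders receive Hardy-Weinberg genotypes at the supplied allele
#' frequencies (independent markers, linkage equilibrium); non-founder
#' gametes are formed with recombination between adjacent markers under
#' Haldane's map function (no interference), chromosomes segregating
#' independently.
#'
#' @param pedigree pedigree `data.frame` (parents before offspring).
#' @param map marker map as from [sim_marker_map()].
#' @param founder_freqs per-marker frequency of the counted allele, each in
#'   (0, 1); recycled if scalar.
#' @param seed integer seed.
#' @return integer matrix (individuals x markers, dimnames set) of allele
#'   counts 0/1/2 with no missing entries.
#' @export
sim_genotypes <- function(pedigree, map, founder_freqs = 0.5, seed = 1L) {
  m <- nrow(map)
  founder_freqs <- rep_len(founder_freqs, m)
  if (any(founder_freqs <= 0 | founder_freqs >= 1))
    stop("founder allele frequencies must lie strictly inside (0, 1)")
  n <- nrow(pedigree)
  check_pedigree_sorted(pedigree)
  set.seed(seed)
  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)
  idx <- match(seq_len(max(pedigree$id)), pedigree$id)
  for (i in seq_len(n)) {
    s <- pedigree$sire[i]; d <- pedigree$dam[i]
    if (s == 0L && d == 0L) {
      H1[i, ] <- as.integer(stats::runif(m) < founder_freqs)
      H2[i, ] <- as.integer(stats::runif(m) < founder_freqs)
    } else {
      si <- idx[s]; di <- idx[d]
      H1[i, ] <- sim_gamete(H1[si, ], H2[si, ], map)
      H2[i, ] <- sim_gamete(H1[di, ], H2[di, ], map)
    }
  }
  G <- H1 + H2
  dimnames(G) <- list(pedigree$id, map$marker)
  G
}

#' Gompertz growth law
#'
#' `A * exp(-b * exp(-k * t))`: asymptote `A`, displacement `b`, rate `k`.
#' @param t age(s).
#' @param A,b,k curve parameters.
#' @export
gompertz <- function(t, A, b, k) A * exp(-b * exp(-k * t))

#' Logistic growth law `A / (1 + b * exp(-k * t))`
#' @inheritParams gompertz
#' @export
logistic_growth <- function(t, A, b, k) A / (1 + b * exp(-k * t))

#' Simulate growth phenotypes and true breeding values
#'
#' A set of QTL is drawn from the mapped markers with additive effects from a
#' reflected gamma distribution (few large effects, random sign). Genetic
#' effects act on the Gompertz asymptote, so time points are genetically
#' correlated under a single QTL architecture. Effects are stored on the
#' scale of the last observed time point: the true breeding value at time t
#' is `TBV_T * g(t) / g(T)` where `g(t) = exp(-b exp(-kt))`, and the
#' phenotype at time t is the individual curve plus Gaussian noise scaled so
#' heritability equals `h2` at the last time point (and, by construction, at
#' every time point).
#'
#' Phenotypes are produced for a designated half of the offspring only
#' (alternate offspring within each full-sib family), mirroring a design in
#' which the phenotyped half trains the model and their unphenotyped sibs
#' form the prediction set. True breeding values are recorded for everyone.
#'
#' @param genotypes matrix from [sim_genotypes()].
#' @param pedigree the matching pedigree.
#' @param n_qtl number of QTL (`<= ncol(genotypes)`); 0 gives a pure-noise
#'   trait.
#' @param h2 narrow-sense heritability at the last time point, in (0, 1].
#' @param timepoints ages at which phenotypes are recorded.
#' @param growth_base baseline Gompertz parameters `c(A, b, k)`.
#' @param effect_shape,effect_scale gamma parameters for |QTL effect| before
#'   standardization.
#' @param genetic_sd target standard deviation of the true breeding value at
#'   the last time point, in trait units (effects are rescaled to hit it).
#' @param base_resid_sd residual standard deviation (last time point) used
#'   when `n_qtl = 0`, where `h2` cannot define one.
#' @param seed integer seed.
#' @return list with `phenotypes` (data.frame: `id` then one column per time
#'   point, phenotyped individuals only), `truth` (list: `qtl` data.frame of
#'   marker/index/effect on the last-time-point scale, `tbv` matrix of true
#'   breeding values for all individuals at all time points plus `t600`,
#'   `h2`, `seed`), and `phenotyped_ids`.
#' @export
sim_phenotypes <- function(genotypes, pedigree, n_qtl = 10L, h2 = 0.5,
                           timepoints = c(0, 132, 265, 397, 530),
                           growth_base = c(A = 100, b = 3, k = 0.01),
                           effect_shape = 0.4, effect_scale = 1,
                           genetic_sd = 10, base_resid_sd = 1,
                           seed = 1L) {
  m <- ncol(genotypes)
  if (n_qtl > m) stop("n_qtl exceeds the number of markers")
  if (h2 <= 0 || h2 > 1) stop("h2 must lie in (0, 1]")
  set.seed(seed)
  A0 <- growth_base[["A"]]; b0 <- growth_base[["b"]]; k0 <- growth_base[["k"]]
  tt <- sort(timepoints)
  Tlast <- tt[length(tt)]
  g <- exp(-b0 * exp(-k0 * c(tt, 600)))
  gT <- exp(-b0 * exp(-k0 * Tlast))

  if (n_qtl > 0) {
    qtl_idx <- sort(sample.int(m, n_qtl))
    eff <- stats::rgamma(n_qtl, shape = effect_shape, scale = effect_scale) *
      sample(c(-1, 1), n_qtl, replace = TRUE)
    tbv_T <- drop(genotypes[, qtl_idx, drop = FALSE] %*% eff)
    sd_raw <- stats::sd(tbv_T)
    if (sd_raw > 0) {
      eff <- eff * genetic_sd / sd_raw
      tbv_T <- drop(genotypes[, qtl_idx, drop = FALSE] %*% eff)
    }
  } else {
    qtl_idx <- integer(0)
    eff <- numeric(0)
    tbv_T <- rep(0, nrow(genotypes))
  }

  # TBV at each time point scales with the curve ordinate
  tbv <- outer(tbv_T / gT, g)
  colnames(tbv) <- c(paste0("t", tt), "t600")
  rownames(tbv) <- rownames(genotypes)

  gvar <- stats::var(tbv_T)
  sigmaT <- if (gvar > 0) sqrt(gvar * (1 - h2) / h2) else base_resid_sd
  sds <- sigmaT * g[seq_along(tt)] / gT

  off <- pedigree$id[pedigree$generation > 0]
  # alternate offspring within each family into the phenotyped half
  fam <- interaction(pedigree$sire, pedigree$dam, drop = TRUE)[pedigree$generation > 0]
  within_rank <- stats::ave(seq_along(off), fam, FUN = seq_along)
  phen_ids <- off[within_rank %% 2L == 1L]

  rows <- match(phen_ids, rownames(genotypes))
  curve <- outer(A0 + tbv_T[rows] / gT, g[seq_along(tt)]) # A_i * g(t)
  noise <- matrix(stats::rnorm(length(rows) * length(tt)), length(rows)) %*%
    diag(sds, length(tt))
  ph <- curve + noise
  phenotypes <- data.frame(id = phen_ids, ph)
  names(phenotypes) <- c("id", paste0("t", tt))

  list(
    phenotypes = phenotypes,
    truth = list(
      qtl = data.frame(marker = colnames(genotypes)[qtl_idx],
                       index = qtl_idx, effect = eff),
      tbv = tbv, h2 = h2, seed = seed
    ),
    phenotyped_ids = phen_ids
  )
}

#' Simulate a full QTL-MAS-XIII-like population
#'
#' Convenience wrapper chaining [sim_pedigree()], [sim_marker_map()],
#' [sim_genotypes()] and [sim_phenotypes()] with the default design: 5
#' sires, 20 dams, 2000 offspring (1000 phenotyped), 453 SNPs on 5 x 1
#' Morgan chromosomes, growth phenotypes at t0...t530.
#'
#' @param n_sires,n_dams,n_offspring pedigree design.
#' @param n_markers marker count.
#' @param maf_range founder allele frequencies are drawn uniformly from this
#'   range.
#' @param seed master seed; sub-stages derive their own seeds from it.
#' @param ... passed to [sim_phenotypes()].
#' @return list with `pedigree`, `map`, `genotypes`, `phenotypes`, `truth`,
#'   `phenotyped_ids`.
#' @export
sim_population <- function(n_sires = 5L, n_dams = 20L, n_offspring = 2000L,
                           n_markers = 453L, maf_range = c(0.2, 0.8),
                           seed = 1L, ...) {
  ped <- sim_pedigree(n_sires, n_dams, n_offspring, seed = seed)
  map <- sim_marker_map(n_markers)
  set.seed(seed)
  freqs <- stats::runif(n_markers, maf_range[1], maf_range[2])
  G <- sim_genotypes(ped, map, freqs, seed = seed + 1L)
  sim <- sim_phenotypes(G, ped, seed = seed + 2L, ...)
  c(list(pedigree = ped, map = map, genotypes = G, founder_freqs = freqs), sim)
}

check_pedigree_sorted <- function(pedigree) {
  pos <- match(pedigree$sire, pedigree$id)
  pos2 <- match(pedigree$dam, pedigree$id)
  here <- seq_len(nrow(pedigree))
  known_s <- pedigree$sire != 0L
  known_d <- pedigree$dam != 0L
  if (anyNA(pos[known_s]) || anyNA(pos2[known_d]))
    stop("pedigree refers to parents absent from the id column")
  if (any(pos[known_s] >= here[known_s]) || any(pos2[known_d] >= here[known_d]))
    stop("pedigree must list parents before their offspring")
  if (anyDuplicated(pedigree$id)) stop("pedigree ids must be unique")
  invisible(TRUE)
}
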