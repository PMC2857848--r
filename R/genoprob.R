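# Mendelian transmission machinery for a biallelic locus.
# gamete_prob[g + 1, a + 1] = P(parent with genotype code g transmits a
# copies of the counted allele), a in {0, 1}.
gamete_prob <- rbind(c(1, 0), c(0.5, 0.5), c(0, 1))

# trans_array[gs + 1, gd + 1, go + 1] = P(offspring go | sire gs, dam gd)
trans_array <- local({
  Tarr <- array(0, c(3, 3, 3))
  for (gs in 0:2) for (gd in 0:2) for (as in 0:1) for (ad in 0:1)
    Tarr[gs + 1, gd + 1, as + ad + 1] <-
      Tarr[gs + 1, gd + 1, as + ad + 1] +
      gamete_prob[gs + 1, as + 1] * gamete_prob[gd + 1, ad + 1]
  Tarr
})
# flattened (sire fastest within dam): row idx = 3*gd + gs + 1
trans_mat9 <- matrix(trans_array, 9, 3)

hw_prior <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)

#' Single-locus genotype probabilities by iterative peeling
#'
#' Propagates genotype probabilities through the pedigree by repeated
#' up-and-down passes, combining for each individual the anterior
#' information (parents, sibs and their ancestors) with posterior
#' information (own offspring and mates), in the manner of single-locus
#' segregation analysis. Founder priors are Hardy-Weinberg at
#' `allele_freq`. Observed individuals are fixed at a point mass. For
#' loop-free pedigrees the fixed point equals the exact marginal
#' probabilities; with inbreeding loops the result is approximate.
#'
#' Individuals must have either both parents in the pedigree or none.
#'
#' @param pedigree pedigree data.frame (parents before offspring).
#' @param observed integer vector of genotype codes 0/1/2 with `NA` for
#'   ungenotyped individuals, aligned with the pedigree rows.
#' @param allele_freq founder frequency of the counted allele, in (0, 1).
#' @param tol convergence tolerance on the largest probability change.
#' @param max_rounds cap on peeling rounds.
#' @return numeric matrix n x 3 (columns `P0`, `P1`, `P2`), rows named by
#'   id; every row sums to 1.
#' @export
single_locus_probs <- function(pedigree, observed, allele_freq,
                               tol = 1e-8, max_rounds = 50L) {
  if (allele_freq <= 0 || allele_freq >= 1)
    stop("allele_freq must lie strictly inside (0, 1)")
  check_pedigree_sorted(pedigree)
  n <- nrow(pedigree)
  if (length(observed) != n) stop("observed must align with the pedigree")
  one_parent <- xor(pedigree$sire == 0L, pedigree$dam == 0L)
  if (any(one_parent))
    stop("individuals must have both parents known or both unknown")
  idx <- match(seq_len(max(pedigree$id, 1L)), pedigree$id)

  # penetrance: point mass if observed
  pen <- matrix(1, n, 3)
  obs_rows <- which(!is.na(observed))
  for (i in obs_rows) {
    pen[i, ] <- 0
    pen[i, observed[i] + 1L] <- 1
  }

  # direct trio consistency check where all three are observed
  nonf <- which(pedigree$sire != 0L)
  for (i in intersect(nonf, obs_rows)) {
    si <- idx[pedigree$sire[i]]; di <- idx[pedigree$dam[i]]
    if (!is.na(observed[si]) && !is.na(observed[di]) &&
        trans_array[observed[si] + 1L, observed[di] + 1L,
                    observed[i] + 1L] == 0)
      stop(sprintf(
        "Mendelian inconsistency: offspring %d (code %d) with sire %d (code %d) and dam %d (code %d)",
        pedigree$id[i], observed[i], pedigree$sire[i], observed[si],
        pedigree$dam[i], observed[di]))
  }

  # nuclear families
  offrows <- which(pedigree$sire != 0L)
  famkey <- paste(pedigree$sire[offrows], pedigree$dam[offrows])
  fams <- split(offrows, famkey)
  fams <- fams[order(vapply(fams, min, integer(1)))]  # eldest families first
  fam_s <- vapply(fams, function(o) idx[pedigree$sire[o[1]]], integer(1))
  fam_d <- vapply(fams, function(o) idx[pedigree$dam[o[1]]], integer(1))
  nfam <- length(fams)
  # mates/family links per individual: list of family indices
  fam_of_parent <- vector("list", n)
  for (f in seq_len(nfam)) {
    fam_of_parent[[fam_s[f]]] <- c(fam_of_parent[[fam_s[f]]], f)
    fam_of_parent[[fam_d[f]]] <- c(fam_of_parent[[fam_d[f]]], f)
  }
  fam_of_child <- integer(n)
  for (f in seq_len(nfam)) fam_of_child[fams[[f]]] <- f

  prior <- hw_prior(allele_freq)
  ant <- matrix(prior, n, 3, byrow = TRUE)
  # posterior terms, one per (parent side of a) family: post_s[[f]] is the
  # message to the sire from family f, post_d[[f]] to the dam
  post_s <- rep(list(rep(1, 3)), nfam)
  post_d <- rep(list(rep(1, 3)), nfam)

  # parent belief excluding one family's own posterior message
  u_excl <- function(i, f_excl) {
    u <- ant[i, ] * pen[i, ]
    for (f in fam_of_parent[[i]]) {
      if (f == f_excl) next
      u <- u * (if (fam_s[f] == i) post_s[[f]] else post_d[[f]])
    }
    u
  }
  # child factor: penetrance times posterior messages from the child's own
  # families
  child_q <- function(o) {
    q <- pen[o, ]
    for (f in fam_of_parent[[o]])
      q <- q * (if (fam_s[f] == o) post_s[[f]] else post_d[[f]])
    q
  }

  marg <- function() {
    P <- ant * pen
    for (f in seq_len(nfam)) {
      P[fam_s[f], ] <- P[fam_s[f], ] * post_s[[f]]
      P[fam_d[f], ] <- P[fam_d[f], ] * post_d[[f]]
    }
    s <- rowSums(P)
    if (any(s <= 0)) {
      i <- which(s <= 0)[1]
      stop(sprintf(
        "Mendelian inconsistency around individual %d (sire %d, dam %d)",
        pedigree$id[i], pedigree$sire[i], pedigree$dam[i]))
    }
    P / s
  }

  P_old <- marg()
  for (round in seq_len(max_rounds)) {
    # downward pass: anteriors in pedigree order
    for (f in seq_len(nfam)) {
      s <- fam_s[f]; d <- fam_d[f]; off <- fams[[f]]
      Us <- u_excl(s, f); Ud <- u_excl(d, f)
      Q <- vapply(off, child_q, numeric(3))         # 3 x n_off
      W <- trans_mat9 %*% Q                         # 9 x n_off
      K <- rep(Ud, each = 3) * rep(Us, 3)           # row idx = 3*gd + gs + 1
      prodW <- apply(W, 1, prod)
      for (oi in seq_along(off)) {
        wi <- W[, oi]
        loo <- ifelse(wi > 0, prodW / wi,
                      apply(W[, -oi, drop = FALSE], 1, prod))
        a <- drop(crossprod(trans_mat9, K * loo))
        s_a <- sum(a)
        if (s_a > 0) ant[off[oi], ] <- a / s_a
      }
    }
    # upward pass: posterior messages, youngest families first
    for (f in rev(seq_len(nfam))) {
      s <- fam_s[f]; d <- fam_d[f]; off <- fams[[f]]
      Us <- u_excl(s, f); Ud <- u_excl(d, f)
      Q <- vapply(off, child_q, numeric(3))
      W <- trans_mat9 %*% Q
      prodW <- apply(W, 1, prod)
      M <- matrix(prodW, 3, 3)                      # M[gs, gd]
      ps <- drop(M %*% Ud)
      pd <- drop(crossprod(M, Us))
      if (max(ps) > 0) post_s[[f]] <- ps / max(ps)
      if (max(pd) > 0) post_d[[f]] <- pd / max(pd)
    }
    P_new <- marg()
    delta <- max(abs(P_new - P_old))
    P_old <- P_new
    if (delta < tol) break
  }
  dimnames(P_old) <- list(pedigree$id, c("P0", "P1", "P2"))
  P_old
}

#' Genotype probabilities for many markers
#'
#' Runs [single_locus_probs()] marker by marker. Markers whose allele
#' frequency is not supplied use [estimate_allele_freq()] on the observed
#' column.
#'
#' @param pedigree pedigree data.frame.
#' @param genotypes matrix with `NA` entries for ungenotyped
#'   individual/marker pairs, rows aligned with the pedigree.
#' @param markers marker (column) names to process; default all.
#' @param freqs optional named per-marker founder allele frequencies.
#' @return list with matrices `P0`, `P1`, `P2` (individuals x markers).
#' @export
genotype_prob_table <- function(pedigree, genotypes, markers = NULL,
                                freqs = NULL) {
  if (is.null(markers)) markers <- colnames(genotypes)
  founder <- pedigree$sire == 0L & pedigree$dam == 0L
  n <- nrow(genotypes)
  P0 <- P1 <- P2 <- matrix(NA_real_, n, length(markers),
                           dimnames = list(rownames(genotypes), markers))
  for (j in seq_along(markers)) {
    g <- genotypes[, markers[j]]
    p <- if (!is.null(freqs) && markers[j] %in% names(freqs))
      freqs[[markers[j]]] else estimate_allele_freq(g, founder)
    pr <- single_locus_probs(pedigree, g, p)
    P0[, j] <- pr[, 1]; P1[, j] <- pr[, 2]; P2[, j] <- pr[, 3]
  }
  list(P0 = P0, P1 = P1, P2 = P2)
}

#' Estimate the counted-allele frequency from observed genotypes
#'
#' Allele count over twice the number of genotyped individuals, using
#' genotyped founders when at least 10 are available and all genotyped
#' individuals otherwise; clamped to [0.01, 0.99] so it can serve as a
#' peeling prior.
#'
#' @param observed genotype codes with `NA` allowed.
#' @param founder logical vector marking founders (optional).
#' @return frequency in [0.01, 0.99].
#' @export
estimate_allele_freq <- function(observed, founder = NULL) {
  if (!is.null(founder) && sum(founder & !is.na(observed)) >= 10)
    observed <- observed[founder]
  observed <- observed[!is.na(observed)]
  if (length(observed) == 0) stop("no observed genotypes")
  min(max(sum(observed) / (2 * length(observed)), 0.01), 0.99)
}

#' Expected genotype dosage from genotype probabilities
#'
#' The design-matrix element used for an ungenotyped individual:
#' `P(1) + 2 P(2)`, the expected allele count given heterozygote and
#' homozygote probabilities. A point mass reproduces the integer code.
#'
#' @param P1,P2 probabilities of the heterozygous and (code 2) homozygous
#'   genotypes; vectors allowed.
#' @return expected code(s) in [0, 2].
#' @export
expected_genotype_code <- function(P1, P2) {
  if (any(P1 < 0 | P2 < 0 | P1 + P2 > 1 + 1e-9))
    stop("invalid genotype probabilities")
  P1 + 2 * P2
}
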