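#' Numerator relationship matrix (tabular method)
#'
#' Wright's additive relationship matrix built by the tabular recursion:
#' for i with parents s, d (listed before i),
#' `a_ij = 0.5 (a_js + a_jd)` for j < i and `a_ii = 1 + 0.5 a_sd`.
#' The diagonal is `1 + F_i` with `F_i` the inbreeding coefficient.
#'
#' @param pedigree pedigree data.frame (id/sire/dam, parents before
#'   offspring, 0 = unknown).
#' @return symmetric numeric matrix, rows/cols ordered and named as the
#'   pedigree ids.
#' @export
relationship_matrix <- function(pedigree) {
  check_pedigree_sorted(pedigree)
  n <- nrow(pedigree)
  idx <- match(seq_len(max(pedigree$id, 1L)), pedigree$id)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- pedigree$sire[i]; d <- pedigree$dam[i]
    si <- if (s > 0L) idx[s] else 0L
    di <- if (d > 0L) idx[d] else 0L
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row_s <- if (si > 0L) A[si, j] else 0
      row_d <- if (di > 0L) A[di, j] else 0
      A[i, j] <- 0.5 * (row_s + row_d)
      A[j, i] <- A[i, j]
    }
    A[i, i] <- 1 + if (si > 0L && di > 0L) 0.5 * A[si, di] else 0
  }
  dimnames(A) <- list(pedigree$id, pedigree$id)
  A
}

#' Inverse of the numerator relationship matrix (Henderson's rules)
#'
#' Built directly from the pedigree with inbreeding taken from the tabular
#' diagonal. The Mendelian-sampling variance for individual i is
#' `0.5 - 0.25 (F_s + F_d)` (both parents known), `0.75 - 0.25 F_p` (one
#' known) or 1 (founder).
#'
#' @inheritParams relationship_matrix
#' @return the inverse relationship matrix as a dense numeric matrix.
#' @export
relationship_inverse <- function(pedigree) {
  A <- relationship_matrix(pedigree)
  Fcoef <- diag(A) - 1
  n <- nrow(pedigree)
  idx <- match(seq_len(max(pedigree$id, 1L)), pedigree$id)
  Ainv <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- pedigree$sire[i]; d <- pedigree$dam[i]
    si <- if (s > 0L) idx[s] else 0L
    di <- if (d > 0L) idx[d] else 0L
    dm <- if (si > 0L && di > 0L) 0.5 - 0.25 * (Fcoef[si] + Fcoef[di])
          else if (si > 0L) 0.75 - 0.25 * Fcoef[si]
          else if (di > 0L) 0.75 - 0.25 * Fcoef[di]
          else 1
    w <- 1 / dm
    Ainv[i, i] <- Ainv[i, i] + w
    for (p in c(si, di)) {
      if (p > 0L) {
        Ainv[i, p] <- Ainv[i, p] - 0.5 * w
        Ainv[p, i] <- Ainv[p, i] - 0.5 * w
      }
    }
    pp <- c(si, di)[c(si, di) > 0L]
    for (p1 in pp) for (p2 in pp)
      Ainv[p1, p2] <- Ainv[p1, p2] + 0.25 * w
  }
  dimnames(Ainv) <- dimnames(A)
  Ainv
}

#' Pedigree BLUP from a single-trait animal model
#'
#' Solves Henderson's mixed-model equations for
#' `y = 1 mu + Z u + e`, `u ~ N(0, A sigma2_a)`, `e ~ N(0, I sigma2_e)`,
#' with the overall mean as the only fixed effect and variance ratio
#' `alpha = sigma2_e / sigma2_a = (1 - h2) / h2`. Individuals without
#' records receive EBV through their relationships.
#'
#' @param phenotypes data.frame with columns `id` and the trait (selected by
#'   `trait`); only listed ids are treated as recorded. `NA` records are
#'   dropped.
#' @param pedigree pedigree data.frame covering all ids.
#' @param h2 heritability in (0, 1).
#' @param trait trait column name (default: the second column).
#' @return list of class `ebv_result`: `ebv` (named vector over all pedigree
#'   ids), `mean` (fixed-effect estimate), `h2`, `trait`.
#' @export
animal_model_blup <- function(phenotypes, pedigree, h2 = 0.5, trait = NULL) {
  if (h2 <= 0 || h2 >= 1) stop("h2 must lie strictly inside (0, 1)")
  if (is.null(trait)) trait <- names(phenotypes)[2]
  y <- phenotypes[[trait]]
  keep <- !is.na(y)
  y <- y[keep]
  ids <- phenotypes$id[keep]
  if (length(y) == 0) stop("no phenotyped individuals")
  n <- nrow(pedigree)
  rec <- match(ids, pedigree$id)
  if (anyNA(rec)) stop("phenotyped ids missing from the pedigree")

  alpha <- (1 - h2) / h2
  Ainv <- relationship_inverse(pedigree)
  nrec <- length(y)
  # MME: [ n      t(z)   ] [mu]   [ sum y ]
  #      [ z  ZtZ + alpha*Ainv ] [u ] = [ Zty  ]
  z <- tabulate(rec, nbins = n)
  C <- matrix(0, n + 1, n + 1)
  C[1, 1] <- nrec
  C[1, -1] <- z
  C[-1, 1] <- z
  ZtZ <- diag(z, n)
  C[-1, -1] <- ZtZ + alpha * Ainv
  rhs <- c(sum(y), unname(tapply(y, factor(rec, levels = seq_len(n)), sum,
                                 default = 0)))
  rhs[is.na(rhs)] <- 0
  sol <- tryCatch(solve(C, rhs), error = function(e)
    stop("mixed-model equations are singular: ", conditionMessage(e)))
  ebv <- sol[-1]
  names(ebv) <- pedigree$id
  structure(list(ebv = ebv, mean = sol[1], h2 = h2, trait = trait),
            class = "ebv_result")
}

#' Grid-search REML for the animal-model heritability
#'
#' One-dimensional profile over a grid of h2 values maximizing the
#' restricted log-likelihood of `y = 1 mu + Zu + e` with
#' `V = sigma2 (h2 Z A Z' + (1 - h2) I)` and the overall scale `sigma2`
#' profiled out analytically. Intended for modest record counts (the
#' direct-V likelihood is O(n^3) per grid point).
#'
#' @inheritParams animal_model_blup
#' @param grid candidate h2 values.
#' @return list: `h2` (maximizer), `grid`, `loglik`.
#' @export
reml_h2_grid <- function(phenotypes, pedigree, grid = seq(0.1, 0.9, by = 0.1),
                         trait = NULL) {
  if (is.null(trait)) trait <- names(phenotypes)[2]
  y <- phenotypes[[trait]]
  keep <- !is.na(y)
  y <- y[keep]
  rec <- match(phenotypes$id[keep], pedigree$id)
  A <- relationship_matrix(pedigree)
  Arec <- A[rec, rec]
  nrec <- length(y)
  X <- matrix(1, nrec, 1)
  ll <- vapply(grid, function(h2) {
    V0 <- h2 * Arec + (1 - h2) * diag(nrec)
    ch <- tryCatch(chol(V0), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    Vinv <- chol2inv(ch)
    XtVX <- crossprod(X, Vinv %*% X)
    P <- Vinv - Vinv %*% X %*% solve(XtVX, t(X) %*% Vinv)
    yPy <- drop(crossprod(y, P %*% y))
    -0.5 * ((nrec - 1) * log(yPy) + 2 * sum(log(diag(ch))) +
              log(XtVX[1, 1]))
  }, numeric(1))
  list(h2 = grid[which.max(ll)], grid = grid, loglik = ll)
}
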