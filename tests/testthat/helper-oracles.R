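# Independent oracles used across tests. These deliberately avoid the code
# paths they check: brute-force enumeration, direct linear algebra, closed
# forms.

# Exhaustive single-locus genotype-probability oracle: enumerate every
# genotype configuration of the unobserved individuals, weight by founder
# Hardy-Weinberg priors and Mendelian transmission, and marginalize.
enum_genotype_probs <- function(pedigree, observed, p) {
  n <- nrow(pedigree)
  hw <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  gam <- rbind(c(1, 0), c(0.5, 0.5), c(0, 1))
  trans <- function(go, gs, gd) {
    pr <- 0
    for (as in 0:1) for (ad in 0:1)
      if (as + ad == go) pr <- pr + gam[gs + 1, as + 1] * gam[gd + 1, ad + 1]
    pr
  }
  free <- which(is.na(observed))
  k <- length(free)
  probs <- matrix(0, n, 3)
  grid <- as.matrix(expand.grid(rep(list(0:2), k)))
  idx <- match(seq_len(max(pedigree$id)), pedigree$id)
  for (r in seq_len(max(nrow(grid), 1))) {
    g <- observed
    if (k > 0) g[free] <- grid[r, ]
    w <- 1
    for (i in seq_len(n)) {
      s <- pedigree$sire[i]; d <- pedigree$dam[i]
      w <- w * if (s == 0 && d == 0) hw[g[i] + 1]
      else trans(g[i], g[idx[s]], g[idx[d]])
      if (w == 0) break
    }
    if (w > 0) for (i in seq_len(n)) probs[i, g[i] + 1] <- probs[i, g[i] + 1] + w
  }
  probs / rowSums(probs)
}

# Direct GLS/BLUP oracle for the animal model: V = Z A Z' s2a + I s2e,
# bhat = (X'V^-1 X)^-1 X'V^-1 y, uhat = s2a A Z' V^-1 (y - X bhat).
gls_blup <- function(y, rec, A, h2) {
  vp <- 1  # scale-free: only the ratio matters, use s2a = h2, s2e = 1 - h2
  s2a <- h2 * vp; s2e <- (1 - h2) * vp
  nr <- length(y)
  Z <- matrix(0, nr, nrow(A)); Z[cbind(seq_len(nr), rec)] <- 1
  V <- Z %*% A %*% t(Z) * s2a + diag(nr) * s2e
  Vi <- solve(V)
  X <- matrix(1, nr, 1)
  bhat <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- s2a * A %*% t(Z) %*% Vi %*% (y - X %*% bhat)
  list(mean = drop(bhat), ebv = drop(u))
}

# Random sorted pedigree for property tests: founders then offspring whose
# parents are drawn from earlier individuals.
random_pedigree <- function(n_founder, n_desc, seed) {
  set.seed(seed)
  id <- seq_len(n_founder + n_desc)
  sire <- dam <- integer(n_founder + n_desc)
  gen <- c(rep(0L, n_founder), rep(1L, n_desc))
  for (i in (n_founder + 1):(n_founder + n_desc)) {
    pair <- sample(seq_len(i - 1), 2)
    sire[i] <- pair[1]; dam[i] <- pair[2]
  }
  data.frame(id = id, sire = sire, dam = dam, generation = gen)
}

# Monte-Carlo standard error of a chain mean, using the package ESS only as
# a denominator (the estimator under test has its own direct checks).
mcse <- function(x) stats::sd(x) / sqrt(ess(x))

# Simulate a small training fixture with known effects
marker_fixture <- function(n, m, seed, beta_sd = 0.3, sigma = 1) {
  set.seed(seed)
  X <- matrix(stats::rbinom(n * m, 2, 0.5), n, m)
  beta <- stats::rnorm(m, 0, beta_sd)
  y <- 2 + drop(X %*% beta) + stats::rnorm(n, 0, sigma)
  list(X = X, beta = beta, y = y)
}
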