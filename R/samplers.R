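#' Configuration for a marker-effect Gibbs chain
#'
#' The three methods share the two-level hierarchy
#' `y = mu + X beta + e`, `e ~ N(0, sigma2e I)`, `beta_j ~ N(0, v_j)` and
#' differ in the prior on the per-marker variance `v_j`:
#' \describe{
#'   \item{bayes_a}{`v_j ~ scaled-Inv-chi2(v, s2)` with both hyperparameters
#'     fixed.}
#'   \item{student_t}{as Bayes-A but `v` and `s2` are estimated: uniform
#'     prior on `1/v` over (0, 1] (so `v >= 1`) and uniform prior on `s`
#'     over (0, A].}
#'   \item{lasso}{`v_j = tau2_j ~ Exp(lambda2 / 2)` giving a Laplace
#'     marginal on `beta_j`; `lambda2 ~ Gamma(a, b)`. The per-marker
#'     variance is not scaled by `sigma2e`, so posterior unimodality is not
#'     guaranteed.}
#' }
#' `mu` has a flat prior and `sigma2e` the scale-invariant `1/sigma2e`
#' prior unless proper surrogates are supplied via `prior_mu` /
#' `prior_sigma_e` (used e.g. by simulation-based sampler validation).
#'
#' @param method one of `"bayes_a"`, `"student_t"`, `"lasso"`.
#' @param n_iter,burn_in,thin chain length, burn-in, thinning interval
#'   (defaults 15000 / 5500 / 30).
#' @param seed integer seed for the whole chain.
#' @param v,s2 Bayes-A degrees of freedom (default 4.012) and scale; `s2 =
#'   NULL` resolves at run time so the prior mean of the per-marker variance
#'   equals `h2_guess * var(y) / (2 sum p_j (1 - p_j))`.
#' @param h2_guess heritability guess used in the Bayes-A scale heuristic.
#' @param A upper bound of the uniform prior on `s` (Student-t); `NULL`
#'   resolves to `1000 * sd(y)`.
#' @param v_step random-walk sd of the Metropolis step on `1/v`.
#' @param a,b Gamma prior on `lambda2` (defaults 0.05 and 1.0, essentially
#'   uniform over a wide range).
#' @param fix_sigma2e,fix_snp_var freeze the residual variance / the
#'   per-marker variance layer at given values (scalar `fix_snp_var` is
#'   recycled); used for closed-form validation, `NULL` to sample.
#' @param fix_lambda2 freeze the Lasso `lambda2` at a value (the `tau2`
#'   layer still updates), `NULL` to sample.
#' @param prior_mu `c(mean, variance)` for a proper normal prior on `mu`,
#'   or `NULL` for the flat prior.
#' @param prior_sigma_e `c(nu0, s02)` for a proper scaled-Inv-chi2 prior on
#'   `sigma2e`, or `NULL` for `1/sigma2e`.
#' @param random_order permute the marker update order each sweep (default
#'   `FALSE`: fixed ascending map order).
#' @param store_beta keep thinned samples of the whole effect vector.
#' @return list of class `chain_config`.
#' @export
chain_config <- function(method = c("bayes_a", "student_t", "lasso"),
                         n_iter = 15000L, burn_in = 5500L, thin = 30L,
                         seed = 1L, v = 4.012, s2 = NULL, h2_guess = 0.5,
                         A = NULL, v_step = 0.05, a = 0.05, b = 1.0,
                         fix_sigma2e = NULL, fix_snp_var = NULL,
                         fix_lambda2 = NULL,
                         prior_mu = NULL, prior_sigma_e = NULL,
                         random_order = FALSE, store_beta = TRUE) {
  method <- match.arg(method)
  stopifnot(burn_in < n_iter, thin >= 1, a > 0, b > 0, v > 0,
            is.null(s2) || s2 > 0)
  structure(list(method = method, n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), v = v, s2 = s2,
                 h2_guess = h2_guess, A = A, v_step = v_step, a = a, b = b,
                 fix_sigma2e = fix_sigma2e, fix_snp_var = fix_snp_var,
                 fix_lambda2 = fix_lambda2,
                 prior_mu = prior_mu, prior_sigma_e = prior_sigma_e,
                 random_order = random_order, store_beta = store_beta),
            class = "chain_config")
}

# fill data-dependent defaults (Bayes-A scale, Student-t A)
resolve_config <- function(config, y, X) {
  if (is.null(config$s2)) {
    p <- colMeans(X) / 2
    het <- 2 * sum(p * (1 - p))
    if (het <= 0) het <- ncol(X) / 2
    vb <- config$h2_guess * stats::var(y) / het
    # prior mean of scaled-Inv-chi2(v, s2) is v s2 / (v - 2)
    config$s2 <- if (config$v > 2) vb * (config$v - 2) / config$v else vb
  }
  if (is.null(config$A)) config$A <- 1000 * stats::sd(y)
  config
}

#' Scaled inverse chi-square draws and density
#'
#' `rscinvchisq(n, df, scale)` draws `df * scale / chisq_df`;
#' `dscinvchisq(x, df, scale)` is the matching density.
#' @param n number of draws.
#' @param x evaluation points.
#' @param df degrees of freedom (> 0).
#' @param scale scale parameter (> 0).
#' @export
rscinvchisq <- function(n, df, scale) df * scale / stats::rchisq(n, df)

#' @rdname rscinvchisq
#' @export
dscinvchisq <- function(x, df, scale) {
  exp((df / 2) * log(df * scale / 2) - lgamma(df / 2) -
        (1 + df / 2) * log(x) - df * scale / (2 * x))
}

#' Inverse-Gaussian draws (Michael-Schucany-Haas)
#'
#' @param n number of draws.
#' @param mean,shape distribution mean and shape, both > 0 (recycled).
#' @export
rinvgauss <- function(n, mean, shape) {
  mean <- rep_len(mean, n); shape <- rep_len(shape, n)
  y <- stats::rnorm(n)^2
  x <- mean + mean^2 * y / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * y + (mean * y)^2)
  x <- pmax(x, 1e-300)
  u <- stats::runif(n)
  ifelse(u <= mean / (mean + x), x, mean^2 / x)
}

#' Initialize the Gibbs sampler state
#'
#' Neutral starting values: `mu = mean(y)`, `beta = 0`,
#' `sigma2e = var(y)/2`, per-marker variances `0.01 var(y) / m`, `v = 4`,
#' `s2` at the prior scale, `lambda2 = a / b`.
#'
#' @param y phenotype vector.
#' @param X genotype matrix (no missing values).
#' @param config resolved [chain_config()].
#' @return list of class `sampler_state` holding `mu`, `beta`, residuals
#'   `e`, `sigma2e`, `snp_var`, `v`, `s2`, `lambda2`, and Metropolis
#'   acceptance counters.
#' @export
init_state <- function(y, X, config) {
  m <- ncol(X)
  vy <- stats::var(y)
  if (!is.finite(vy) || vy == 0) vy <- 1
  mu <- mean(y)
  sv <- rep(0.01 * vy / m, m)
  if (!is.null(config$fix_snp_var)) sv <- rep_len(config$fix_snp_var, m)
  s2e <- if (!is.null(config$fix_sigma2e)) config$fix_sigma2e else vy / 2
  structure(list(
    mu = mu, beta = rep(0, m), e = y - mu, sigma2e = s2e, snp_var = sv,
    v = if (config$method == "bayes_a") config$v else 4,
    s2 = if (is.null(config$s2)) 0.01 * vy / m else config$s2,
    lambda2 = config$a / config$b,
    v_acc = 0L, v_try = 0L), class = "sampler_state")
}

# step 1: overall mean
draw_mu <- function(state, config) {
  n <- length(state$e)
  if (is.null(config$prior_mu)) {
    mu_new <- state$mu + mean(state$e) +
      stats::rnorm(1, 0, sqrt(state$sigma2e / n))
  } else {
    m0 <- config$prior_mu[1]; v0 <- config$prior_mu[2]
    sum_t <- sum(state$e) + n * state$mu   # sum of y - X beta
    pv <- 1 / (n / state$sigma2e + 1 / v0)
    pm <- pv * (sum_t / state$sigma2e + m0 / v0)
    mu_new <- stats::rnorm(1, pm, sqrt(pv))
  }
  state$e <- state$e - (mu_new - state$mu)
  state$mu <- mu_new
  state
}

#' Gauss-Seidel sweep over marker effects with residual update
#'
#' For each marker in turn, removes its contribution from the residual,
#' draws the effect from its univariate normal full conditional
#' `N(C_j^-1 r_j, C_j^-1)` with `C_j = x_j'x_j / sigma2e + 1 / v_j` and
#' `r_j = x_j'e / sigma2e`, and restores the contribution. Never forms an
#' m x m system; a zero-variance column reduces to a prior draw.
#'
#' @param state `sampler_state`.
#' @param X numeric genotype matrix.
#' @param config `chain_config`.
#' @param xtx optional precomputed column sums of squares.
#' @return updated state (residual identity `e = y - mu - X beta`
#'   preserved).
#' @export
draw_beta_gauss_seidel <- function(state, X, config, xtx = NULL) {
  if (!is.double(X)) storage.mode(X) <- "double"
  if (is.null(xtx)) xtx <- colSums(X^2)
  m <- ncol(X)
  ord <- if (isTRUE(config$random_order)) sample.int(m) else seq_len(m)
  beta <- state$beta + 0  # force fresh copies; the C++ sweep works in place
  e <- state$e + 0
  beta_sweep_cpp(X, e, beta, xtx, state$sigma2e, state$snp_var,
                 as.integer(ord))
  state$beta <- beta
  state$e <- e
  state
}

#' Draw the residual variance
#'
#' `sigma2e ~ scaled-Inv-chi2(n, e'e/n)` under the `1/sigma2e` prior, or
#' `scaled-Inv-chi2(nu0 + n, (nu0 s02 + e'e)/(nu0 + n))` under a proper
#' prior. A zero residual sum of squares is floored at 1e-12.
#'
#' @inheritParams draw_beta_gauss_seidel
#' @return updated state.
#' @export
draw_sigma_e <- function(state, config) {
  if (!is.null(config$fix_sigma2e)) return(state)
  n <- length(state$e)
  sse <- max(sum(state$e^2), 1e-12)
  if (is.null(config$prior_sigma_e)) {
    state$sigma2e <- sse / stats::rchisq(1, n)
  } else {
    nu0 <- config$prior_sigma_e[1]; s02 <- config$prior_sigma_e[2]
    state$sigma2e <- (nu0 * s02 + sse) / stats::rchisq(1, n + nu0)
  }
  state
}

#' Draw per-marker variances from their scaled-Inv-chi2 conditionals
#'
#' Bayes-A / Student-t layer:
#' `v_j ~ scaled-Inv-chi2(v + 1, (v s2 + beta_j^2) / (v + 1))`.
#'
#' @inheritParams draw_beta_gauss_seidel
#' @return updated state.
#' @export
draw_snp_variances <- function(state, config) {
  if (!is.null(config$fix_snp_var)) return(state)
  m <- length(state$beta)
  vdf <- if (config$method == "bayes_a") config$v else state$v
  s2 <- if (config$method == "bayes_a") config$s2 else state$s2
  state$snp_var <- (vdf * s2 + state$beta^2) / stats::rchisq(m, vdf + 1)
  state
}

# log full-conditional kernel of v given the per-marker variances and s2
loglik_v <- function(v, s2, snp_var) {
  m <- length(snp_var)
  m * ((v / 2) * log(v * s2 / 2) - lgamma(v / 2)) -
    (1 + v / 2) * sum(log(snp_var)) - (v * s2 / 2) * sum(1 / snp_var)
}

#' Metropolis update of the Student-t degrees of freedom
#'
#' Random walk on `u = 1/v` (uniform prior over (0, 1], so `v >= 1`) with
#' reflection at the boundaries; a rejected proposal keeps the current `v`.
#' Acceptance counts accumulate in the state.
#'
#' @inheritParams draw_beta_gauss_seidel
#' @return updated state.
#' @export
draw_v_metropolis <- function(state, config) {
  u <- 1 / state$v
  up <- u + stats::rnorm(1, 0, config$v_step)
  for (i in 1:100) {
    if (up > 0 && up <= 1) break
    if (up < 0) up <- -up else if (up > 1) up <- 2 - up
    if (up == 0) up <- 1e-12
  }
  llc <- loglik_v(state$v, state$s2, state$snp_var)
  llp <- loglik_v(1 / up, state$s2, state$snp_var)
  state$v_try <- state$v_try + 1L
  if (log(stats::runif(1)) <= llp - llc) {
    state$v <- 1 / up
    state$v_acc <- state$v_acc + 1L
  }
  state
}

#' Student-t hyperparameter updates
#'
#' `s2` is drawn from its Gamma-form full conditional
#' `Gamma(m v / 2 + 1/2, (v / 2) sum(1 / v_j))` (the 1/2 in the shape comes
#' from the uniform-on-`s` prior), truncated at `A^2` by inverse-CDF
#' sampling; `v` is updated by [draw_v_metropolis()].
#'
#' @inheritParams draw_beta_gauss_seidel
#' @return updated state.
#' @export
draw_student_t_hyper <- function(state, config) {
  m <- length(state$snp_var)
  shape <- m * state$v / 2 + 0.5
  rate <- (state$v / 2) * sum(1 / state$snp_var)
  cap <- stats::pgamma(config$A^2, shape, rate = rate)
  if (cap <= 0) {
    state$s2 <- config$A^2
  } else {
    state$s2 <- stats::qgamma(stats::runif(1, 0, cap), shape, rate = rate)
    if (state$s2 <= 0) state$s2 <- 1e-300
  }
  draw_v_metropolis(state, config)
}

#' Bayesian Lasso variance layer
#'
#' `1/tau2_j ~ Inverse-Gaussian(sqrt(lambda2 / beta_j^2), lambda2)` with
#' `|beta_j|` floored at 1e-8, then
#' `lambda2 ~ Gamma(a + m, b + sum(tau2_j) / 2)`.
#'
#' @inheritParams draw_beta_gauss_seidel
#' @return updated state.
#' @export
draw_lasso_layer <- function(state, config) {
  if (!is.null(config$fix_snp_var)) return(state)
  m <- length(state$beta)
  if (!is.null(config$fix_lambda2)) state$lambda2 <- config$fix_lambda2
  babs <- pmax(abs(state$beta), 1e-8)
  itau <- rinvgauss(m, sqrt(state$lambda2) / babs, state$lambda2)
  state$snp_var <- 1 / itau
  if (is.null(config$fix_lambda2))
    state$lambda2 <- stats::rgamma(1, shape = config$a + m,
                                   rate = config$b + sum(state$snp_var) / 2)
  state
}

#' One full Gibbs scan (steps 1-5)
#'
#' Updates, in order: the mean, all marker effects (Gauss-Seidel with
#' residual update), the residual variance, and the method-specific
#' per-marker variance layer with its hyperparameters.
#'
#' @inheritParams draw_beta_gauss_seidel
#' @return updated state.
#' @export
gibbs_scan <- function(state, X, config, xtx = NULL) {
  state <- draw_mu(state, config)
  state <- draw_beta_gauss_seidel(state, X, config, xtx)
  state <- draw_sigma_e(state, config)
  if (config$method == "lasso") {
    state <- draw_lasso_layer(state, config)
  } else {
    state <- draw_snp_variances(state, config)
    if (config$method == "student_t" && is.null(config$fix_snp_var))
      state <- draw_student_t_hyper(state, config)
  }
  state
}

#' Run a marker-effect Gibbs chain
#'
#' Single chain; every `thin`-th post-burn-in state is stored and posterior
#' means are averages of the stored samples.
#'
#' @param y phenotype vector (finite).
#' @param X genotype matrix, individuals x markers, codes 0/1/2, no
#'   missing entries.
#' @param config a [chain_config()].
#' @return object of class `posterior_summary`: `beta_mean` (named by
#'   marker), `mu_mean`, `sigma2e_mean`, method-parameter means (`v_mean`,
#'   `s2_mean`, `lambda_mean` as applicable), `samples` (data.frame of
#'   thinned scalar draws), `beta_samples` (matrix, if requested), `ess`
#'   (effective sample sizes of monitored variances), `accept_rate_v`,
#'   `config`, and a `provenance` string recording the training dimensions.
#' @export
run_chain <- function(y, X, config) {
  if (!all(is.finite(y))) stop("phenotypes must be finite")
  X <- as.matrix(X)
  if (ncol(X) == 0) stop("no markers")
  if (nrow(X) != length(y)) stop("dimension mismatch between y and X")
  if (anyNA(X)) stop("genotype matrix must be complete")
  storage.mode(X) <- "double"
  config <- resolve_config(config, y, X)
  set.seed(config$seed)
  state <- init_state(y, X, config)
  xtx <- colSums(X^2)
  m <- ncol(X)

  keep <- seq(config$burn_in + config$thin, config$n_iter, by = config$thin)
  n_keep <- length(keep)
  S <- data.frame(iter = keep, mu = numeric(n_keep),
                  sigma2e = numeric(n_keep), v = numeric(n_keep),
                  s2 = numeric(n_keep), lambda2 = numeric(n_keep),
                  mean_snp_var = numeric(n_keep))
  B <- if (isTRUE(config$store_beta)) matrix(0, n_keep, m) else NULL
  beta_sum <- rep(0, m)
  k <- 0L
  for (it in seq_len(config$n_iter)) {
    state <- gibbs_scan(state, X, config, xtx)
    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0) {
      k <- k + 1L
      S$mu[k] <- state$mu; S$sigma2e[k] <- state$sigma2e
      S$v[k] <- state$v; S$s2[k] <- state$s2
      S$lambda2[k] <- state$lambda2
      S$mean_snp_var[k] <- mean(state$snp_var)
      beta_sum <- beta_sum + state$beta
      if (!is.null(B)) B[k, ] <- state$beta
    }
  }
  if (k == 0) stop("no post-burn-in samples stored; check n_iter/burn_in/thin")
  beta_mean <- beta_sum / k
  names(beta_mean) <- colnames(X)
  ess_list <- list(sigma2e = ess(S$sigma2e),
                   mean_snp_var = ess(S$mean_snp_var))
  if (config$method == "student_t") {
    ess_list$s2 <- ess(S$s2); ess_list$v <- ess(S$v)
  }
  if (config$method == "lasso") ess_list$lambda2 <- ess(S$lambda2)
  structure(list(
    beta_mean = beta_mean, mu_mean = mean(S$mu),
    sigma2e_mean = mean(S$sigma2e),
    v_mean = if (config$method == "student_t") mean(S$v) else config$v,
    s2_mean = if (config$method == "student_t") mean(S$s2) else config$s2,
    lambda_mean = if (config$method == "lasso") mean(sqrt(S$lambda2)) else NULL,
    samples = S, beta_samples = B, ess = ess_list,
    accept_rate_v = if (state$v_try > 0) state$v_acc / state$v_try else NA_real_,
    config = config,
    provenance = sprintf("trained:%s n=%d m=%d seed=%d", config$method,
                         length(y), m, config$seed)),
    class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("%s chain: %d markers, mu=%.4g sigma2e=%.4g\n",
              x$config$method, length(x$beta_mean), x$mu_mean,
              x$sigma2e_mean))
  if (x$config$method == "student_t")
    cat(sprintf("  v=%.3g s2=%.4g (v-Metropolis acceptance %.2f)\n",
                x$v_mean, x$s2_mean, x$accept_rate_v))
  if (x$config$method == "lasso")
    cat(sprintf("  lambda=%.4g\n", x$lambda_mean))
  invisible(x)
}

#' Effective sample size (initial positive sequence estimator)
#'
#' Geyer's initial-positive-sequence truncation of the autocorrelation sum:
#' pair sums of autocorrelations are accumulated while positive and the
#' integrated autocorrelation time is `-1 + 2 sum Gamma_k`. A constant
#' chain returns `length(x)` with attribute `constant = TRUE`.
#'
#' @param x numeric vector of (at least 10) stored draws.
#' @return scalar ESS.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 10) stop("need at least 10 samples for an ESS estimate")
  if (stats::var(x) == 0) return(structure(as.numeric(n), constant = TRUE))
  lag_max <- min(n - 1, 2000L)
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[, 1, 1]
  tau <- 0
  k <- 0
  while (2 * k + 1 <= lag_max) {
    g <- ac[2 * k + 1] + ac[2 * k + 2]
    if (!is.finite(g) || g <= 0) break
    tau <- tau + g
    k <- k + 1
  }
  iact <- max(2 * tau - 1, 1 / n)
  min(n / iact, n)
}

#' Draw a parameter state from the (proper) prior
#'
#' Used by simulation-based validation of the samplers: requires proper
#' surrogates for the mean and residual-variance priors. Per-marker
#' variances, hyperparameters and effects are drawn from the method's own
#' hierarchy.
#'
#' @param config `chain_config` with `prior_mu`, `prior_sigma_e` and (for
#'   Bayes-A) a numeric `s2` set.
#' @param m number of markers.
#' @return `sampler_state` (residuals unset until data are attached).
#' @export
sample_prior_state <- function(config, m) {
  if (is.null(config$prior_mu) || is.null(config$prior_sigma_e))
    stop("prior draws require proper priors on mu and sigma2e")
  mu <- stats::rnorm(1, config$prior_mu[1], sqrt(config$prior_mu[2]))
  sigma2e <- rscinvchisq(1, config$prior_sigma_e[1], config$prior_sigma_e[2])
  v <- config$v; s2 <- config$s2; lambda2 <- config$a / config$b
  if (config$method == "student_t") {
    v <- 1 / stats::runif(1)
    s2 <- stats::runif(1, 0, config$A)^2
    snp_var <- rscinvchisq(m, v, s2)
  } else if (config$method == "bayes_a") {
    if (is.null(s2)) stop("bayes_a prior draws need a numeric s2")
    snp_var <- rscinvchisq(m, v, s2)
  } else {
    lambda2 <- stats::rgamma(1, config$a, rate = config$b)
    snp_var <- stats::rexp(m, rate = lambda2 / 2)
  }
  beta <- stats::rnorm(m, 0, sqrt(snp_var))
  structure(list(mu = mu, beta = beta, e = NULL, sigma2e = sigma2e,
                 snp_var = snp_var, v = v, s2 = s2, lambda2 = lambda2,
                 v_acc = 0L, v_try = 0L), class = "sampler_state")
}

#' Simulate phenotypes from a sampler state
#'
#' `y ~ N(mu + X beta, sigma2e I)`; also refreshes the state's residual
#' vector to match the new data.
#'
#' @param state `sampler_state`.
#' @param X genotype matrix.
#' @return list with `y` and the updated `state`.
#' @export
sample_y <- function(state, X) {
  n <- nrow(X)
  y <- state$mu + drop(X %*% state$beta) +
    stats::rnorm(n, 0, sqrt(state$sigma2e))
  state$e <- y - state$mu - drop(X %*% state$beta)
  list(y = y, state = state)
}
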