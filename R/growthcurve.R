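#' Fit a growth curve to repeated measures on one individual
#'
#' Nonlinear least squares (Levenberg-Marquardt) for the three-parameter
#' Gompertz curve `A * exp(-b * exp(-k * t))` or its logistic comparator
#' `A / (1 + b * exp(-k * t))`, with a deterministic multi-start grid:
#' `A in {max(y), 1.5 max(y)}`, `k in {0.005, 0.01, 0.02}`, and `b` solved
#' from the first observation. The best (lowest-RSS) converged start wins;
#' a fit that fails every start is returned flagged, never thrown.
#'
#' AIC and BIC are computed under Gaussian residuals as
#' `n log(RSS/n) + 2k` and `n log(RSS/n) + k log(n)` with `k` = number of
#' curve parameters + 1 for the residual variance.
#'
#' @param times,values numeric vectors of equal length (>= 4 distinct times).
#' @param model `"gompertz"` or `"logistic"`.
#' @return object of class `growth_fit`: list with `model`, `pars`
#'   (named A, b, k), `rss`, `n`, `aic`, `bic`, `converged`, `message`.
#' @export
fit_growth <- function(times, values, model = c("gompertz", "logistic")) {
  model <- match.arg(model)
  stopifnot(length(times) == length(values))
  if (length(unique(times)) < 4)
    stop("need at least 4 distinct time points")
  if (!all(is.finite(values))) stop("values must be finite")
  n <- length(values)
  fun <- if (model == "gompertz") gompertz else logistic_growth

  # degenerate flat series: asymptote = the constant, no curvature to fit
  if (stats::sd(values) < 1e-12) {
    pars <- c(A = mean(values), b = 0, k = 0.01)
    return(new_growth_fit(model, pars, rss = 0, n = n, converged = TRUE))
  }

  resid_fn <- function(p) values - fun(times, p[1], p[2], p[3])
  ymax <- max(values)
  y0 <- values[which.min(times)]
  starts <- list()
  for (Astart in c(ymax, 1.5 * ymax)) {
    for (kstart in c(0.005, 0.01, 0.02)) {
      b0 <- if (model == "gompertz") {
        if (y0 > 0 && y0 < Astart) log(Astart / y0) else 3
      } else {
        if (y0 > 0 && y0 < Astart) Astart / y0 - 1 else 3
      }
      starts[[length(starts) + 1]] <- c(A = Astart, b = b0, k = kstart)
    }
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (!is.finite(rss)) next
    if (is.null(best) || rss < best$rss)
      best <- list(pars = fit$par, rss = rss)
  }
  if (is.null(best)) {
    pars <- starts[[1]]
    return(new_growth_fit(model, pars, rss = sum(resid_fn(pars)^2), n = n,
                          converged = FALSE,
                          message = "no start converged"))
  }
  # the optimizer only descends, so RSS <= RSS at every start's initial point
  pars <- best$pars
  names(pars) <- c("A", "b", "k")
  new_growth_fit(model, pars, rss = best$rss, n = n, converged = TRUE)
}

new_growth_fit <- function(model, pars, rss, n, converged, message = "") {
  rss_eff <- max(rss, 1e-300)
  k <- length(pars) + 1
  structure(list(model = model, pars = pars, rss = rss, n = n,
                 aic = n * log(rss_eff / n) + 2 * k,
                 bic = n * log(rss_eff / n) + k * log(n),
                 converged = converged, message = message),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("%s fit: A=%.4g b=%.4g k=%.4g  RSS=%.4g AIC=%.2f BIC=%.2f%s\n",
              x$model, x$pars["A"], x$pars["b"], x$pars["k"], x$rss,
              x$aic, x$bic, if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

#' Predict the growth curve at an age
#'
#' @param fit a `growth_fit`.
#' @param t age(s), finite and >= 0.
#' @return predicted value(s).
#' @export
predict_growth <- function(fit, t) {
  p <- fit$pars
  fun <- if (fit$model == "gompertz") gompertz else logistic_growth
  fun(t, p[["A"]], p[["b"]], p[["k"]])
}

#' Select the best growth model by AIC
#'
#' Minimum AIC wins; ties broken by BIC, then by fewer parameters, then by
#' position in the candidate list.
#' @param fits list of `growth_fit`s on the same data.
#' @return the winning `growth_fit`.
#' @export
select_growth_model <- function(fits) {
  if (length(fits) == 0) stop("no candidate fits")
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  npar <- vapply(fits, function(f) length(f$pars), numeric(1))
  ord <- order(aic, bic, npar, seq_along(fits))
  fits[[ord[1]]]
}

#' Fit growth curves for every individual in a phenotype table
#'
#' Applies [fit_growth()] per row for each candidate model, selects by AIC,
#' and predicts the phenotype at `t_pred` (default 600, beyond the observed
#' range).
#'
#' @param phenotypes data.frame: `id` then time columns named `t<age>`.
#' @param models candidate model names.
#' @param t_pred age at which to extrapolate.
#' @return data.frame: id, model, A, b, k, rss, aic, bic, converged, and a
#'   `t<t_pred>` prediction column.
#' @export
fit_growth_table <- function(phenotypes, models = c("gompertz", "logistic"),
                             t_pred = 600) {
  tcols <- grep("^t[0-9]+$", names(phenotypes), value = TRUE)
  times <- as.numeric(sub("^t", "", tcols))
  out <- vector("list", nrow(phenotypes))
  for (i in seq_len(nrow(phenotypes))) {
    y <- as.numeric(phenotypes[i, tcols])
    fits <- lapply(models, function(mod) fit_growth(times, y, mod))
    f <- select_growth_model(fits)
    out[[i]] <- data.frame(
      id = phenotypes$id[i], model = f$model,
      A = f$pars[["A"]], b = f$pars[["b"]], k = f$pars[["k"]],
      rss = f$rss, aic = f$aic, bic = f$bic, converged = f$converged,
      pred = predict_growth(f, t_pred))
  }
  res <- do.call(rbind, out)
  names(res)[names(res) == "pred"] <- paste0("t", t_pred)
  res
}
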