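#' GEBV accuracy as a Pearson correlation
#'
#' @param gebv,reference equal-length finite vectors (n >= 3); the
#'   reference is typically EBV or, in simulation, TBV.
#' @return Pearson correlation.
#' @export
accuracy <- function(gebv, reference) {
  if (length(gebv) != length(reference) || length(gebv) < 3)
    stop("need equal-length vectors of at least 3 values")
  if (!all(is.finite(gebv)) || !all(is.finite(reference)))
    stop("inputs must be finite")
  if (stats::sd(gebv) == 0 || stats::sd(reference) == 0)
    stop("zero variance in accuracy input")
  stats::cor(gebv, reference)
}

#' Bias as the regression of the reference on the GEBV
#'
#' `b = cov(reference, gebv) / var(gebv)`; b = 1 means unbiased dispersion.
#'
#' @inheritParams accuracy
#' @return regression coefficient.
#' @export
bias_regression <- function(reference, gebv) {
  if (length(gebv) != length(reference) || length(gebv) < 3)
    stop("need equal-length vectors of at least 3 values")
  if (stats::var(gebv) == 0) stop("zero GEBV variance")
  stats::cov(reference, gebv) / stats::var(gebv)
}

#' Cross-validated genomic prediction accuracy
#'
#' Splits the phenotyped individuals into `n_reps` disjoint test sets
#' (train fraction `train_frac`), retrains the chain on each training split
#' with the same configuration, and reports the correlation between the
#' predicted GEBV and the observed phenotypes of the held-out individuals.
#'
#' @param y phenotypes of the phenotyped set.
#' @param X their genotype matrix.
#' @param config [chain_config()] reused for every replicate (its seed is
#'   offset per replicate).
#' @param n_reps number of replicates (default 10).
#' @param train_frac training fraction (default 0.9); must satisfy
#'   `n_reps * (1 - train_frac) <= 1` so test sets can be disjoint.
#' @param seed seed for the split permutation.
#' @return data.frame: `rep`, `n_train`, `n_test`, `accuracy`.
#' @export
cross_validate <- function(y, X, config, n_reps = 10L, train_frac = 0.9,
                           seed = 1L) {
  n <- length(y)
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must lie strictly inside (0, 1)")
  test_frac <- 1 - train_frac
  if (n_reps * test_frac > 1 + 1e-9)
    stop("cannot build ", n_reps, " disjoint test sets of fraction ",
         test_frac)
  n_test <- floor(n * test_frac + 1e-9)
  if (n_test < 3) stop("test sets too small")
  set.seed(seed)
  perm <- sample.int(n)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    test <- perm[((r - 1) * n_test + 1):(r * n_test)]
    train <- setdiff(seq_len(n), test)
    cfg <- config
    cfg$seed <- config$seed + r
    fit <- run_chain(y[train], X[train, , drop = FALSE], cfg)
    gebv <- compute_gebv(X[test, , drop = FALSE], fit$beta_mean)
    out[[r]] <- data.frame(rep = r, n_train = length(train),
                           n_test = n_test,
                           accuracy = accuracy(gebv, y[test]))
  }
  do.call(rbind, out)
}

#' Evaluate GEBV for all scenarios against reference breeding values
#'
#' Computes, per method and scenario (the full panel plus the 12
#' low-density scenarios), the correlation with the reference (EBV and,
#' when supplied, TBV), the regression of the reference on the GEBV, and
#' the change in correlation relative to the full panel.
#'
#' @param fits named list of `posterior_summary` objects (one per method).
#' @param genotypes prediction-set genotype matrix.
#' @param map marker map.
#' @param ebv reference EBV for the prediction set (named or aligned).
#' @param tbv optional true breeding values, same alignment.
#' @param probs genotype-probability table for the `_GP` scenarios; when
#'   `NULL` those scenarios are skipped.
#' @return tidy data.frame: `method`, `scenario`, `metric`, `value`, `n`.
#' @export
evaluation_report <- function(fits, genotypes, map, ebv, tbv = NULL,
                              probs = NULL) {
  scen <- scenario_table(ncol(genotypes))
  if (is.null(probs)) scen <- scen[!scen$use_gp, ]
  rows <- list()
  add <- function(method, scenario, metric, value, n) {
    rows[[length(rows) + 1]] <<- data.frame(
      method = method, scenario = scenario, metric = metric,
      value = value, n = n)
  }
  for (method in names(fits)) {
    beta <- fits[[method]]$beta_mean
    full <- compute_gebv(`storage.mode<-`(genotypes, "double"), beta)
    acc_full <- accuracy(full, ebv)
    add(method, "ALL", "cor_ebv", acc_full, length(full))
    add(method, "ALL", "b_ebv", bias_regression(ebv, full), length(full))
    if (!is.null(tbv)) {
      acc_full_tbv <- accuracy(full, tbv)
      add(method, "ALL", "cor_tbv", acc_full_tbv, length(full))
    }
    for (i in seq_len(nrow(scen))) {
      sg <- scenario_gebv(scen[i, ], genotypes, map, beta, probs)
      a <- accuracy(sg$gebv, ebv)
      add(method, scen$scenario[i], "cor_ebv", a, length(sg$gebv))
      add(method, scen$scenario[i], "delta_cor_ebv", a - acc_full,
          length(sg$gebv))
      add(method, scen$scenario[i], "b_ebv", bias_regression(ebv, sg$gebv),
          length(sg$gebv))
      if (!is.null(tbv)) {
        at <- accuracy(sg$gebv, tbv)
        add(method, scen$scenario[i], "cor_tbv", at, length(sg$gebv))
        add(method, scen$scenario[i], "delta_cor_tbv", at - acc_full_tbv,
            length(sg$gebv))
      }
    }
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Chains simulate -> growth-curve fits -> pedigree EBV -> Bayesian
#' training (three methods) -> genotype probabilities -> low-density
#' scenarios -> evaluation, writing every artifact under `outdir` along
#' with a JSON summary and a log of seeds and settings. Stages can be
#' restricted; later stages require the artifacts of earlier ones in
#' memory, so prefixes of the stage list are the useful subsets.
#'
#' @param config list (or path to a `key = value` file readable by
#'   [read_config()]) with optional entries: `seed`, `outdir`, `stages`
#'   (comma-separated subset of simulate, growth, ebv, train, genoprob,
#'   scenarios, evaluate), `n_offspring`, `n_markers`, `n_qtl`, `h2`,
#'   `n_iter`, `burn_in`, `thin`, `methods` (comma-separated), `trait`.
#' @return invisible list with the in-memory artifacts.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_config(config)
  g <- function(key, default) if (!is.null(config[[key]])) config[[key]] else default
  seed <- as.integer(g("seed", 1))
  outdir <- g("outdir", "results")
  stages <- strsplit(g("stages",
                       "simulate,growth,ebv,train,genoprob,scenarios,evaluate"),
                     ",")[[1]]
  methods <- strsplit(g("methods", "bayes_a,student_t,lasso"), ",")[[1]]
  trait <- g("trait", "t530")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "pipeline_log.txt")
  logline <- function(...) cat(format(Sys.time(), "%H:%M:%S "),
                               sprintf(...), "\n", sep = "",
                               file = logfile, append = TRUE)
  logline("pipeline start: seed=%d stages=%s", seed,
          paste(stages, collapse = ","))
  logline("config: %s", paste(names(config), unlist(lapply(config, paste,
                                                           collapse = ",")),
                              sep = "=", collapse = " "))
  art <- list()

  if ("simulate" %in% stages) {
    art$pop <- sim_population(
      n_offspring = as.integer(g("n_offspring", 2000)),
      n_markers = as.integer(g("n_markers", 453)),
      n_qtl = as.integer(g("n_qtl", 10)), h2 = g("h2", 0.5), seed = seed)
    write_pedigree(art$pop$pedigree, file.path(outdir, "pedigree.tsv"))
    write_genotypes(art$pop$genotypes, file.path(outdir, "genotypes.tsv"))
    write_marker_map(art$pop$map, file.path(outdir, "map.tsv"))
    write_phenotypes(art$pop$phenotypes, file.path(outdir, "phenotypes.csv"))
    write_truth(art$pop$truth, outdir)
    logline("simulate: %d individuals, %d markers",
            nrow(art$pop$pedigree), ncol(art$pop$genotypes))
  }
  pop <- art$pop
  if (is.null(pop)) return(invisible(art))
  pred_ids <- setdiff(pop$pedigree$id[pop$pedigree$generation > 0],
                      pop$phenotyped_ids)
  Gpred <- pop$genotypes[as.character(pred_ids), , drop = FALSE]

  if ("growth" %in% stages) {
    art$growth <- fit_growth_table(pop$phenotypes)
    utils::write.csv(art$growth, file.path(outdir, "growth_fits.csv"),
                     row.names = FALSE)
    logline("growth: %d fits, %d converged", nrow(art$growth),
            sum(art$growth$converged))
  }
  if ("ebv" %in% stages) {
    ph <- pop$phenotypes
    if (trait == "t600" && !is.null(art$growth))
      ph <- data.frame(id = art$growth$id, t600 = art$growth$t600)
    art$ebv <- animal_model_blup(ph, pop$pedigree, h2 = g("h2", 0.5),
                                 trait = if (trait %in% names(ph)) trait else NULL)
    utils::write.csv(
      data.frame(id = names(art$ebv$ebv), ebv = art$ebv$ebv),
      file.path(outdir, "ebv.csv"), row.names = FALSE)
    logline("ebv: mean=%.4g", art$ebv$mean)
  }
  if ("train" %in% stages) {
    ytab <- pop$phenotypes
    if (trait == "t600" && !is.null(art$growth))
      ytab <- data.frame(id = art$growth$id, t600 = art$growth$t600)
    y <- ytab[[if (trait %in% names(ytab)) trait else names(ytab)[2]]]
    Gtrain <- pop$genotypes[as.character(ytab$id), , drop = FALSE]
    art$fits <- list()
    for (mth in methods) {
      cfg <- chain_config(mth, n_iter = as.integer(g("n_iter", 15000)),
                          burn_in = as.integer(g("burn_in", 5500)),
                          thin = as.integer(g("thin", 30)), seed = seed)
      fit <- run_chain(y, Gtrain, cfg)
      art$fits[[mth]] <- fit
      utils::write.table(
        data.frame(marker = names(fit$beta_mean), beta_mean = fit$beta_mean),
        file.path(outdir, paste0("effects_", mth, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      logline("train %s: sigma2e=%.4g ess(sigma2e)=%.0f", mth,
              fit$sigma2e_mean, fit$ess$sigma2e)
    }
  }
  if ("genoprob" %in% stages) {
    # prediction set ungenotyped except panel markers is scenario-specific;
    # here probabilities are computed with prediction-set genotypes masked,
    # founders and training sibs observed
    Gmask <- pop$genotypes
    Gmask[as.character(pred_ids), ] <- NA_integer_
    art$probs <- genotype_prob_table(pop$pedigree, Gmask,
                                     freqs = stats::setNames(
                                       pop$founder_freqs, pop$map$marker))
    logline("genoprob: %d markers", ncol(art$probs$P1))
  }
  if ("scenarios" %in% stages && !is.null(art$fits)) {
    scen <- scenario_table(ncol(pop$genotypes))
    rows <- list()
    for (mth in names(art$fits)) {
      for (i in seq_len(nrow(scen))) {
        if (scen$use_gp[i] && is.null(art$probs)) next
        sg <- scenario_gebv(scen[i, ], Gpred, pop$map,
                            art$fits[[mth]]$beta_mean, art$probs)
        rows[[length(rows) + 1]] <- data.frame(
          id = names(sg$gebv), scenario = sg$scenario, method = mth,
          gebv = sg$gebv)
      }
    }
    art$scenario_gebv <- do.call(rbind, rows)
    utils::write.csv(art$scenario_gebv, file.path(outdir, "gebv.csv"),
                     row.names = FALSE)
    logline("scenarios: %d rows", nrow(art$scenario_gebv))
  }
  if ("evaluate" %in% stages && !is.null(art$fits) && !is.null(art$ebv)) {
    ebv_pred <- art$ebv$ebv[as.character(pred_ids)]
    tbv_pred <- pop$truth$tbv[as.character(pred_ids), trait]
    art$report <- evaluation_report(art$fits, Gpred, pop$map, ebv_pred,
                                    tbv_pred, art$probs)
    utils::write.csv(art$report, file.path(outdir, "report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      split(art$report, art$report$method),
      file.path(outdir, "report.json"), dataframe = "rows",
      auto_unbox = TRUE, digits = NA)
    logline("evaluate: %d metric rows", nrow(art$report))
  }
  logline("pipeline done")
  invisible(art)
}
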