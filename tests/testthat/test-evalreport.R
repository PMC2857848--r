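test_that("accuracy is a guarded Pearson correlation", {
  x <- c(1, 3, 2, 5, 4, 7, 6, 9, 8, 10)
  expect_equal(accuracy(x, x), 1)
  expect_equal(accuracy(x, -x), -1)
  set.seed(1)
  y <- rnorm(10)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(accuracy(x, y), hand)
  expect_error(accuracy(x, rep(1, 10)), "variance")
  expect_error(accuracy(x[1:2], y[1:2]))
})

test_that("bias regression is cov/var with closed-form special cases", {
  set.seed(2)
  g <- rnorm(20)
  expect_equal(bias_regression(2 * g, g), 2)
  expect_equal(bias_regression(g + 5, g), 1)
  r <- rnorm(20)
  expect_equal(bias_regression(r, g), unname(coef(lm(r ~ g))[2]))
  expect_error(bias_regression(r, rep(0, 20)))
})

test_that("cross-validation validates its split geometry", {
  fx <- marker_fixture(60, 15, seed = 3)
  cfg <- chain_config("bayes_a", n_iter = 300, burn_in = 100, thin = 4)
  expect_error(cross_validate(fx$y, fx$X, cfg, n_reps = 1, train_frac = 1.0))
  expect_error(cross_validate(fx$y, fx$X, cfg, n_reps = 10, train_frac = 0.5))
  cv1 <- cross_validate(fx$y, fx$X, cfg, n_reps = 3, train_frac = 0.8,
                        seed = 5)
  cv2 <- cross_validate(fx$y, fx$X, cfg, n_reps = 3, train_frac = 0.8,
                        seed = 5)
  expect_identical(cv1, cv2)
  expect_equal(cv1$n_test, rep(12, 3))
})

test_that("null-signal data cross-validates to zero accuracy", {
  set.seed(4)
  X <- matrix(rbinom(80 * 20, 2, 0.5), 80, 20)
  y <- rnorm(80)  # h2 = 0
  cfg <- chain_config("bayes_a", n_iter = 600, burn_in = 200, thin = 4)
  cv <- cross_validate(y, X, cfg, n_reps = 5, train_frac = 0.8, seed = 6)
  se <- sd(cv$accuracy) / sqrt(nrow(cv))
  expect_lt(abs(mean(cv$accuracy)), 3 * se + 0.05)
})

test_that("evaluation report deltas recompute exactly", {
  pop <- sim_population(n_offspring = 200, n_markers = 100, n_qtl = 4,
                        seed = 8)
  train <- as.character(pop$phenotyped_ids)
  pred <- as.character(setdiff(pop$pedigree$id[pop$pedigree$generation > 0],
                               pop$phenotyped_ids))
  fit <- run_chain(pop$phenotypes$t530, pop$genotypes[train, ],
                   chain_config("bayes_a", n_iter = 500, burn_in = 150,
                                thin = 5, seed = 1))
  ebv <- animal_model_blup(pop$phenotypes[, c("id", "t530")], pop$pedigree)
  G <- pop$genotypes[pred, ]
  probs <- list(P0 = (G == 0) * 1, P1 = (G == 1) * 1, P2 = (G == 2) * 1)
  rep_df <- evaluation_report(list(bayes_a = fit), G, pop$map,
                              ebv$ebv[pred],
                              pop$truth$tbv[pred, "t530"], probs)
  full <- rep_df$value[rep_df$scenario == "ALL" & rep_df$metric == "cor_ebv"]
  for (sc in unique(rep_df$scenario[rep_df$scenario != "ALL"])) {
    a <- rep_df$value[rep_df$scenario == sc & rep_df$metric == "cor_ebv"]
    d <- rep_df$value[rep_df$scenario == sc &
                        rep_df$metric == "delta_cor_ebv"]
    expect_equal(d, a - full)
  }
  expect_true(all(abs(rep_df$value[grepl("^cor", rep_df$metric)]) <= 1))
})

test_that("pipeline stages write their artifacts and rerun identically", {
  d1 <- withr::local_tempdir()
  cfg <- list(seed = 5, outdir = d1, n_offspring = 200, n_markers = 100,
              n_qtl = 4, h2 = 0.5, n_iter = 400, burn_in = 150, thin = 5,
              methods = "bayes_a,lasso")
  # simulate only: data files exist, no model outputs
  art0 <- run_pipeline(c(cfg, list(stages = "simulate")))
  expect_true(file.exists(file.path(d1, "genotypes.tsv")))
  expect_false(file.exists(file.path(d1, "report.csv")))
  # full run
  art <- run_pipeline(cfg)
  expect_true(file.exists(file.path(d1, "report.csv")))
  rep1 <- read.csv(file.path(d1, "report.csv"))
  expect_setequal(unique(rep1$method), c("bayes_a", "lasso"))
  expect_equal(length(unique(rep1$scenario)), 13)  # ALL + 12
  d2 <- withr::local_tempdir()
  cfg$outdir <- d2
  run_pipeline(cfg)
  rep2 <- read.csv(file.path(d2, "report.csv"))
  expect_equal(rep1, rep2)
})

test_that("genotype probabilities with sparse panels confound GEBV with family EBV", {
  # with few observed markers and probability-filled remainders, prediction
  # GEBV collapse towards family means, tracking the pedigree EBV better
  # than the true breeding values
  pop <- sim_population(n_offspring = 400, n_markers = 150, n_qtl = 8,
                        h2 = 0.5, seed = 21)
  train <- as.character(pop$phenotyped_ids)
  pred <- as.character(setdiff(pop$pedigree$id[pop$pedigree$generation > 0],
                               pop$phenotyped_ids))
  fit <- run_chain(pop$phenotypes$t530, pop$genotypes[train, ],
                   chain_config("bayes_a", n_iter = 1500, burn_in = 500,
                                thin = 5, seed = 2))
  ebv <- animal_model_blup(pop$phenotypes[, c("id", "t530")],
                          pop$pedigree)$ebv[pred]
  tbv <- pop$truth$tbv[pred, "t530"]
  Gmask <- pop$genotypes
  Gmask[pred, ] <- NA_integer_
  probs <- genotype_prob_table(pop$pedigree, Gmask,
                               freqs = setNames(pop$founder_freqs,
                                                pop$map$marker))
  sg <- scenario_gebv("EVEN_GP_19", pop$genotypes[pred, ], pop$map,
                      fit$beta_mean, probs)
  expect_gt(accuracy(sg$gebv, ebv), accuracy(sg$gebv, tbv))
})
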