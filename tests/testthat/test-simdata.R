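test_that("pedigree structure matches the mating design", {
  ped <- sim_pedigree(5, 20, 2000, seed = 1)
  expect_equal(nrow(ped), 2025)
  off <- ped[ped$generation > 0, ]
  expect_true(all(off$sire %in% 1:5))
  expect_true(all(off$dam %in% 6:25))
  fams <- table(paste(off$sire, off$dam))
  expect_length(fams, 100)
  expect_true(all(fams == 20))

  tiny <- sim_pedigree(1, 1, 1)
  expect_equal(nrow(tiny), 3)
  expect_equal(tiny$sire[3], 1L)
  expect_equal(tiny$dam[3], 2L)

  p228 <- sim_pedigree(2, 2, 8)
  off <- p228[p228$generation > 0, ]
  expect_true(all(off$sire %in% 1:2))
  expect_false(any(off$id %in% c(p228$sire, p228$dam)))

  expect_error(sim_pedigree(0, 2, 5))
})

test_that("gene drop is Mendelian-consistent and deterministic", {
  ped <- sim_pedigree(3, 6, 40, seed = 2)
  map <- sim_marker_map(30)
  G <- sim_genotypes(ped, map, 0.4, seed = 7)
  expect_false(anyNA(G))
  # every offspring genotype reachable from parental gametes
  gam_ok <- function(go, gs, gd) {
    smin <- as.integer(gs == 2); smax <- as.integer(gs >= 1)
    dmin <- as.integer(gd == 2); dmax <- as.integer(gd >= 1)
    go >= smin + dmin && go <= smax + dmax
  }
  off <- which(ped$generation > 0)
  for (i in off) {
    s <- match(ped$sire[i], ped$id); d <- match(ped$dam[i], ped$id)
    expect_true(all(mapply(gam_ok, G[i, ], G[s, ], G[d, ])))
  }
  expect_identical(G, sim_genotypes(ped, map, 0.4, seed = 7))
  expect_error(sim_genotypes(ped, map, 1.2, seed = 1))
})

test_that("founder allele frequencies follow binomial sampling", {
  ped <- sim_pedigree(250, 250, 1, seed = 1)
  map <- sim_marker_map(10, n_chrom = 1)
  G <- sim_genotypes(ped, map, 0.5, seed = 11)
  founders <- which(ped$generation == 0)  # 500 founders, 1000 alleles/marker
  freq <- colMeans(G[founders, ]) / 2
  se <- sqrt(0.25 / (2 * length(founders)))
  expect_true(all(abs(freq - 0.5) < 3 * se))
})

test_that("recombinant fraction follows Haldane's map function", {
  map2 <- data.frame(marker = c("a", "b"), chrom = c(1L, 1L),
                     pos = c(0.10, 0.11))
  set.seed(5)
  gam <- replicate(10000, sim_gamete(c(0L, 0L), c(1L, 1L), map2))
  rf <- mean(gam[1, ] != gam[2, ])
  r_exp <- (1 - exp(-0.02)) / 2
  se <- sqrt(r_exp * (1 - r_exp) / 10000)
  expect_lt(abs(rf - r_exp), 3 * se)
})

test_that("true breeding values reconstruct exactly from stored QTL", {
  pop <- sim_population(n_offspring = 120, n_markers = 50, n_qtl = 6,
                        seed = 4)
  q <- pop$truth$qtl
  tbv_last <- unname(drop(pop$genotypes[, q$index, drop = FALSE] %*% q$effect))
  expect_equal(unname(pop$truth$tbv[, "t530"]), tbv_last)
  # every other time point is an exact deterministic rescaling
  g <- exp(-3 * exp(-0.01 * c(0, 132, 265, 397, 530, 600)))
  expect_equal(unname(pop$truth$tbv[, "t600"]),
               tbv_last * g[6] / g[5])
})

test_that("degenerate architectures behave as specified", {
  pop0 <- sim_population(n_offspring = 60, n_markers = 20, n_qtl = 0,
                         seed = 2)
  expect_true(all(pop0$truth$tbv == 0))

  pop1 <- sim_population(n_offspring = 400, n_markers = 50, n_qtl = 5,
                         h2 = 1, seed = 3)
  ph <- pop1$phenotypes
  tbv <- pop1$truth$tbv[as.character(ph$id), "t530"]
  expect_gt(cor(tbv, ph$t530), 0.99)
  expect_error(sim_population(n_offspring = 50, n_markers = 20, n_qtl = 30))
  expect_error(sim_population(n_offspring = 50, n_markers = 20, h2 = 1.5))
})

test_that("phenotype regressed on TBV is unbiased at the last time point", {
  pop <- sim_population(n_offspring = 2000, n_markers = 100, n_qtl = 10,
                        h2 = 0.5, seed = 6)
  ph <- pop$phenotypes
  tbv <- pop$truth$tbv[as.character(ph$id), "t530"]
  fit <- summary(lm(ph$t530 ~ tbv))$coefficients
  expect_lt(abs(fit["tbv", "Estimate"] - 1), 3 * fit["tbv", "Std. Error"])
})

test_that("phenotyped half alternates within families and spans them all", {
  pop <- sim_population(n_offspring = 200, n_markers = 20, seed = 8)
  ped <- pop$pedigree
  off <- ped[ped$generation > 0, ]
  fam <- paste(off$sire, off$dam)
  phen <- off$id %in% pop$phenotyped_ids
  expect_equal(length(pop$phenotyped_ids), 100)
  per_fam <- tapply(phen, fam, sum)
  expect_true(all(per_fam >= 1))
})

test_that("tabular files round-trip through the readers", {
  d <- withr::local_tempdir()
  pop <- sim_population(n_offspring = 30, n_markers = 12, n_qtl = 3,
                        seed = 9)
  write_pedigree(pop$pedigree, file.path(d, "ped.tsv"))
  expect_equal(read_pedigree(file.path(d, "ped.tsv")), pop$pedigree)
  write_genotypes(pop$genotypes, file.path(d, "g.tsv"))
  expect_equal(read_genotypes(file.path(d, "g.tsv")), pop$genotypes)
  write_marker_map(pop$map, file.path(d, "map.tsv"))
  expect_equal(read_marker_map(file.path(d, "map.tsv")), pop$map)
  write_phenotypes(pop$phenotypes, file.path(d, "ph.csv"))
  ph <- read_phenotypes(file.path(d, "ph.csv"))
  expect_equal(ph$id, pop$phenotypes$id)
  expect_equal(ph$t530, pop$phenotypes$t530, tolerance = 1e-12)
  write_truth(pop$truth, d)
  tr <- read_truth(d)
  expect_equal(unname(tr$tbv), unname(pop$truth$tbv), tolerance = 1e-12)
  expect_equal(tr$qtl$index, pop$truth$qtl$index)
})
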