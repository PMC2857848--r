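#!/usr/bin/env Rscript
# Stage 1: simulate a QTL-MAS-XIII-like population.
#
# 5 sires x 20 dams (full factorial -> 100 full-sib families), 2000
# offspring of which 1000 are phenotyped; 453 SNPs approximately equally
# spaced on five 1-Morgan chromosomes; growth phenotypes at t0, t132,
# t265, t397, t530 driven by 10 QTL acting on the Gompertz asymptote at
# h2 = 0.5. True breeding values are recorded for every individual.

library(gebvtools)

seed <- 2026L
outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

pop <- sim_population(n_offspring = 2000L, n_markers = 453L, n_qtl = 10L,
                      h2 = 0.5, seed = seed)

write_pedigree(pop$pedigree, file.path(outdir, "pedigree.tsv"))
write_genotypes(pop$genotypes, file.path(outdir, "genotypes.tsv"))
write_marker_map(pop$map, file.path(outdir, "map.tsv"))
write_phenotypes(pop$phenotypes, file.path(outdir, "phenotypes.csv"))
write_truth(pop$truth, outdir)
writeLines(as.character(pop$phenotyped_ids),
           file.path(outdir, "phenotyped_ids.txt"))

cat(sprintf(
  "simulated %d individuals (%d phenotyped), %d markers, %d QTL\n",
  nrow(pop$pedigree), length(pop$phenotyped_ids), ncol(pop$genotypes),
  nrow(pop$truth$qtl)))
cat(sprintf("realized h2 at t530: %.3f\n",
            var(pop$truth$tbv[rownames(pop$truth$tbv) %in%
                                pop$phenotyped_ids, "t530"]) /
              var(pop$phenotypes$t530)))
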