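#!/usr/bin/env Rscript
# Stage 5: single-locus genotype probabilities for the prediction set.
#
# Emulates the low-density situation: prediction-set offspring are treated
# as ungenotyped while founders and the (genotyped) training sibs remain
# observed; iterative peeling then gives each prediction individual its
# genotype-class probabilities per marker. Expected genotype dosages
# P(het) + 2 P(hom) fill the probability columns of the _GP scenarios.

library(gebvtools)

datadir <- "results/data"
pedigree <- read_pedigree(file.path(datadir, "pedigree.tsv"))
genotypes <- read_genotypes(file.path(datadir, "genotypes.tsv"))
phenotyped <- readLines(file.path(datadir, "phenotyped_ids.txt"))
pred <- as.character(setdiff(pedigree$id[pedigree$generation > 0],
                             as.integer(phenotyped)))

Gmask <- genotypes
Gmask[pred, ] <- NA_integer_
probs <- genotype_prob_table(pedigree, Gmask)

for (nm in c("P0", "P1", "P2")) {
  df <- data.frame(id = rownames(probs[[nm]]), probs[[nm]],
                   check.names = FALSE)
  write.table(df, sprintf("results/genoprob_%s.tsv", nm), sep = "\t",
              quote = FALSE, row.names = FALSE)
}
ec <- expected_genotype_code(probs$P1[pred, ], probs$P2[pred, ])
cat(sprintf("peeled %d markers for %d prediction individuals\n",
            ncol(probs$P1), length(pred)))
cat(sprintf("mean |expected dosage - true genotype| on masked entries: %.3f\n",
            mean(abs(ec - genotypes[pred, ]))))
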