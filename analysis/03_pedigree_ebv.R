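#!/usr/bin/env Rscript
# Stage 3: traditional pedigree EBV.
#
# Single-trait animal model (mean + additive animal effect with covariance
# proportional to the numerator relationship matrix) for the last observed
# time point t530 and the extrapolated t600. Unphenotyped prediction-set
# offspring receive EBV through their relatives; these are the reference
# against which GEBV accuracy is measured downstream.

library(gebvtools)

datadir <- "results/data"
pedigree <- read_pedigree(file.path(datadir, "pedigree.tsv"))
phenotypes <- read_phenotypes(file.path(datadir, "phenotypes.csv"))
growth <- read.csv("results/growth_fits.csv")

h2 <- 0.5
out <- list()
for (trait in c("t530", "t600")) {
  ph <- if (trait == "t530") phenotypes[, c("id", "t530")]
        else data.frame(id = growth$id, t600 = growth$t600)
  fit <- animal_model_blup(ph, pedigree, h2 = h2)
  out[[trait]] <- data.frame(id = names(fit$ebv), trait = trait,
                             ebv = unname(fit$ebv))
  cat(sprintf("%s: fixed mean %.3f, sd(EBV) = %.3f\n",
              trait, fit$mean, sd(fit$ebv)))
}
write.csv(do.call(rbind, out), "results/ebv.csv", row.names = FALSE)
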