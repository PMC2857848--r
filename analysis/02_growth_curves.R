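#!/usr/bin/env Rscript
# Stage 2: per-individual growth curves.
#
# Fits Gompertz and logistic curves to the five observed time points of
# every phenotyped individual, selects the better model by AIC, and
# extrapolates each winner to t600 (beyond the observed range).

library(gebvtools)

datadir <- "results/data"
phenotypes <- read_phenotypes(file.path(datadir, "phenotypes.csv"))

fits <- fit_growth_table(phenotypes, t_pred = 600)
write.csv(fits, "results/growth_fits.csv", row.names = FALSE)

cat(sprintf("fitted %d individuals; %d converged\n",
            nrow(fits), sum(fits$converged)))
cat(sprintf("model selected by AIC: %s\n",
            paste(sprintf("%s %.1f%%", names(table(fits$model)),
                          100 * table(fits$model) / nrow(fits)),
                  collapse = ", ")))
cat(sprintf("median t600 prediction: %.2f (median asymptote %.2f)\n",
            median(fits$t600), median(fits$A)))
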