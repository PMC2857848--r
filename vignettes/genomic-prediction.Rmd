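---
title: "Bayesian shrinkage methods for genomic breeding values: models, design and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian shrinkage methods for genomic breeding values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Genomic selection predicts the additive genetic merit of young animals from
dense SNP genotypes. Marker effects are estimated once in a *training*
population with phenotypes and high-density genotypes; *prediction*
candidates — here the unphenotyped half of a full/half-sib livestock
population — then receive a genomic estimated breeding value

GEBV_i = sum_j X[i, j] * beta_j,

where `X` codes each genotype as the number of copies (0, 1, 2) of an
arbitrary reference allele and `beta` holds posterior-mean marker effects.
Because genotyping every candidate at full density is expensive, the
package also implements low-density prediction: panels of 19, 38 or 76
SNPs chosen either for even genome coverage or for largest estimated
effect, optionally completed back to full density with single-locus
genotype probabilities computed from the pedigree.

## The three marker-effect models

All three methods share the two-level hierarchy

y = mu + X beta + e,  e ~ N(0, sigma2e I),  beta_j ~ N(0, v_j),

with a flat prior on `mu` and the scale-invariant `1/sigma2e` prior on the
residual variance. They differ only in the prior on the per-marker
variance `v_j`, which is what produces different shrinkage:

* **Bayes-A** — `v_j ~ scaled-Inv-chi2(v, s2)` with both hyperparameters
  fixed. Default `v = 4.012`; the scale resolves at run time so the prior
  mean per-marker variance equals `h2_guess * var(y) / (2 sum p_j(1-p_j))`
  (`h2_guess = 0.5`), the usual way of spreading a heritability guess over
  the panel. Both are `chain_config()` arguments; note that the shrinkage
  behaviour — in particular how conservative Bayes-A is relative to the
  adaptive methods — depends strongly on the fixed scale, and the classical
  small fixed value `s2 = 0.002` makes it the most conservative of the
  three.
* **Student-t** — the Bayes-A generalization in which `v` and `s2` are
  estimated: uniform prior on `1/v` over (0, 1] (so `v >= 1`) and uniform
  prior on `s` over (0, A], `A = 1000 sd(y)` by default. `s2` has a
  Gamma-form full conditional (truncated at `A^2`, sampled by inverse
  CDF); `v` moves by a Gaussian random walk on `1/v` (step 0.05,
  reflecting at the interval boundaries) accepted by a Metropolis rule.
* **Bayesian Lasso** — `v_j = tau2_j ~ Exp(lambda2 / 2)`, giving the
  Laplace (double-exponential) marginal on effects;
  `lambda2 ~ Gamma(a, b)` with `a = 0.05`, `b = 1.0`, essentially uniform
  over a wide range. The per-marker variance is deliberately *not* scaled
  by `sigma2e`; posterior unimodality is therefore not guaranteed, which
  is documented behaviour, not an issue to be fixed. `1/tau2_j` is drawn
  from an inverse-Gaussian full conditional via the
  Michael–Schucany–Haas transformation, with `|beta_j|` floored at 1e-8
  to avoid overflow in its mean.

One Gibbs scan updates, in order: `mu`; every `beta_j` by Gauss–Seidel
with residual update (the residual vector is corrected marker by marker,
so no m-by-m system is ever formed — the update order is fixed ascending
map order for reproducibility, with a permutation flag available);
`sigma2e` from its scaled-Inv-chi2 conditional; then the per-marker
variance layer and its hyperparameters. Default chain settings are 15000
iterations, 5500 burn-in, storing every 30th state; inferences use the
average of stored post-burn-in samples, and effective sample sizes of the
monitored variances use the initial-positive-sequence (Geyer) estimator.
Initialization is neutral: `mu = mean(y)`, `beta = 0`,
`sigma2e = var(y)/2`, per-marker variances at `0.01 var(y)/m`.

```{r}
library(gebvtools)
pop <- sim_population(seed = 1)            # 2025 individuals, 453 SNPs
fit <- run_chain(pop$phenotypes$t530,
                 pop$genotypes[as.character(pop$phenotyped_ids), ],
                 chain_config("lasso", seed = 1))
```

## Growth curves and the t600 trait

Phenotypes are yield-like measures at t0, t132, t265, t397 and t530. A
sixth trait is the extrapolation of each individual's growth curve to
t600. `fit_growth()` fits the three-parameter Gompertz curve
`A exp(-b exp(-k t))` (and a logistic comparator `A / (1 + b exp(-k t))`)
by Levenberg–Marquardt least squares from a deterministic start grid
(`A in {max(y), 1.5 max(y)}`, `k in {0.005, 0.01, 0.02}`, `b` solved from
the first observation; convergence tolerance 1e-10 on the relative RSS,
500 iterations per start). Model choice is by AIC with BIC, then
parameter count, then candidate order as tie-breaks; under Gaussian
residuals `AIC = n log(RSS/n) + 2k` with `k` counting the curve
parameters plus one for the residual variance. A series that defeats
every start is returned flagged rather than thrown; a constant series
short-circuits to `A = mean(y)`, `RSS = 0`.

## Pedigree EBV

The reference breeding values come from a single-trait animal model
solved through Henderson's mixed-model equations with the numerator
relationship matrix built by the tabular method and its inverse by
Henderson's rules (inbreeding taken from the tabular diagonal). The only
fixed effect is the overall mean — the simulated design has no other
covariates — and the variance ratio is `(1 - h2)/h2` with `h2` accepted
from configuration (default 0.5). A one-dimensional grid REML
(`reml_h2_grid()`, overall scale profiled out analytically) is available
when an estimate is preferred; it is deliberately minimal and the
reported EBV always state which `h2` they used. Dense solves are used
throughout, which is comfortable to n of a few thousand.

## Genotype probabilities and low-density panels

For prediction candidates genotyped only at a small panel, the remaining
markers enter the design as expected dosages `P(het) + 2 P(hom)`.
Probabilities come from single-locus iterative peeling: repeated up-down
passes combine, for every individual, anterior information (parents, full
sibs and their ancestry) with posterior information (own offspring and
mates), founders carrying Hardy–Weinberg priors at the marker's allele
frequency (observed-data estimate by default, clamped to [0.01, 0.99]).
Convergence is declared when the largest probability change drops below
1e-8 (cap 50 rounds); on loop-free pedigrees the fixed point equals the
exact marginal, which is how the implementation is tested — by exhaustive
enumeration over all genotype configurations on small pedigrees. For
inbred (loopy) pedigrees iterative peeling is approximate; that is a
known limitation shared with the method itself. Individuals must have
both parents in the pedigree or none.

The even-coverage panels are defined by a quantile rule the package owns:
targets at `(i - 0.5)/m` of the cumulative genome map length, nearest
marker per target, ties to the lower index, duplicates stepping to the
next unused marker. Largest-effect panels take the `m` largest `|beta|`
per method and trait (ties to the lower index). Scenario GEBV always use
effects from the full-density training run — never retrained on a subset.

## The synthetic population

`sim_population()` emulates the structure the analysis assumes: 5 sires
and 20 dams mated full-factorially into 100 full-sib families (20
offspring each at the default 2000), 453 SNPs approximately equally
spaced on five 1-Morgan chromosomes, founder allele frequencies uniform
on [0.2, 0.8], gene drop with Haldane recombination and no interference,
founders in linkage equilibrium. Ten QTL (reflected-gamma effect sizes:
few large effects) act on the Gompertz asymptote, so all time points are
genetically correlated through a single architecture; effects are stored
on the last-time-point scale and rescaled so the realized genetic
standard deviation is 10 trait units; residual noise is scaled per time
point to hold the target heritability (default 0.5) at every time point.
Phenotypes go to alternating offspring within each family, so training
and prediction sets both span all families.

What this generator does *not* emulate matters for interpreting green
tests: there is no historical linkage disequilibrium (founders are in
equilibrium, so marker-QTL association within the sample comes from
family cosegregation), no selection, mutation, dominance or epistasis,
and the QTL architecture is one-dimensional across time points. Passing
accuracy properties therefore demonstrate internal correctness of the
machinery under the stated structure, not field performance on real
livestock data.

## Validation strategy and problem sizes

The test suite checks every sampler conditional against an independent
route: conjugate closed forms with frozen variance layers (n = 50, m = 1),
ridge/SNP-BLUP equivalence with the variance layer frozen equal
(n = 100, m = 50, correlation > 0.999 required), grid-normalized density
and probability-integral-transform comparisons for the scaled-Inv-chi2,
inverse-Gaussian, Gamma and Metropolis draws (1e5 draws each, max CDF gap
0.02), the Laplace stationary marginal of the Lasso hierarchy (excess
kurtosis 3), and joint-distribution calibration by successive-conditional
simulation at n = 8, m = 3 with proper surrogate priors for the mean and
residual variance. Peeling is checked against exhaustive enumeration on
loop-free pedigrees of up to nine members with six unobserved; the animal
model against direct GLS on pedigrees up to n = 50; growth fitting
against noiseless recovery and simulation. An end-to-end reduced-scale
study (400 training / 400 prediction offspring, 453 markers, 10 QTL,
h2 = 0.5, chains of 5000 iterations, five seeds) verifies the workflow's
qualitative behaviour: full-panel accuracy against true breeding values
above 0.6 for all methods, largest-effect panels beating even-spaced
panels at 19 SNPs, and point-mass probabilities reproducing full-panel
GEBV exactly. These sizes keep the default suite to a few minutes while
leaving every property measurable; the `analysis/` scripts run the same
pipeline at the full 2000-offspring scale.

Three behaviours found during validation are worth knowing about. First,
the qualitative shrinkage ordering (Lasso most sensitive to small QTL,
Bayes-A least) holds when Bayes-A uses its classical small fixed scale;
with the data-driven default scale Bayes-A can become the *least*
conservative method, so the ordering is a property of the configuration,
not of the method name. Second, with sparse even panels completed by
genotype probabilities, prediction GEBV collapse toward family means and
correlate better with pedigree EBV than with true breeding values — an
artifact of full-sib structure that the evaluation report makes visible
by always reporting both references. Third, AIC discrimination between
the Gompertz and logistic curves from only five time points is sharp at
low residual noise (about 1% of the asymptote) but degrades toward a
coin flip at the noise level implied by a 0.5-heritability trait, so the
selected-model column of the growth table should be read per individual
with that in mind.
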