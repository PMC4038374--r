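---
title: "Allometric scaling and trait diversification: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allometric scaling and trait diversification: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allomorph)
```

`allomorph` studies how the masses of avian hindlimb segments scale
with body size and how those masses have diversified along the
neognath phylogeny.  This vignette is the package's own account of the
statistical machinery: the models, their assumptions, the parameters
that matter, and the choices made where the design was genuinely open.
It states no empirical result that the test suite and the acceptance
script do not themselves compute.

## The allometric model

On species means, a power law `y = a * x^b` is fit on the log10 scale:
`log10(y) = log10(a) + b * log10(x)`.  Base-10 logarithms are a fixed
convention, not an option: intercepts are reported on the log10 scale
in the bundled units (grams, centimetres), and they are only meaningful
with that base.  Isometry (geometric similarity) predicts `b = 1`
against body mass and `b = 3` against hindlimb length; these are the
default null slopes throughout and can be overridden per test.

### Why the standardized major axis

Both variables in every pairing — a segment mass and a body-size
measure — carry biological variation and measurement error, so
ordinary regression of y on x attenuates the slope (`b_OLS = r *
b_SMA`).  The standardized major axis treats the two symmetrically:
`b = sign(r) * SD(log y) / SD(log x)`.  Two consequences shape the
test suite:

* swapping x and y maps the slope to its reciprocal, and rescaling a
  raw trait only shifts the intercept — both are asserted as
  invariants;
* the slope estimate never falls below the OLS slope in magnitude, so
  comparisons with PGLS/OLS fits must happen in a common geometry (see
  below).

The slope confidence interval is the exact construction
`b * (sqrt(B + 1) ± sqrt(B))` with
`B = F(1 - alpha; 1, n - 2) * (1 - r^2) / (n - 2)`.  The isometry
F-test forms residual scores `u = y - b0 * x` and axis scores
`v = y + b0 * x`; under the null they are uncorrelated and
`F = r_uv^2 (n - 2) / (1 - r_uv^2)` has an F(1, n − 2) reference.  The
CI-exclusion rule and the F-test are two readings of the same evidence
and are asserted to agree on the bundled data.

**Intercept intervals.** Published SMA tables print intercept CIs
without a formula.  The package uses
`Var(a) = s2_resid / n + mean(x)^2 * Var(b)`, with `Var(b)` implied by
the slope interval half-width on the t scale.  This is an
approximation to the interval produced by standard SMA software,
accurate to a few units in the second decimal at these sample sizes;
it is deliberately not presented as exact.

### Common slopes and elevations

Whether the five segments share a scaling exponent is tested with a
likelihood-ratio statistic under the bivariate-normal SMA formulation:
at a shared slope `b`, each group contributes
`-(n_i - 2.5) * log(1 - r_uv,i(b)^2)`; the pooled profile is minimized
numerically (bounded search over the span of the group slopes,
tolerance 1e-10) and referred to chi-square with k − 1 degrees of
freedom.  The `n_i - 2.5` weight is the Warton–Weber small-sample
correction; with plain `n_i` weights the test measured a 6.6% type-I
rate at n = 30 per group in calibration simulations, against 4.8% with
the correction.  Exactly collinear groups put an infinite wall in the
profile at every slope but their own, so `1 - r^2` is clamped at 1e-12
and the group slopes themselves are included as candidate minimizers.

Elevations (intercepts at the common slope, `mean(y_i) - b_c *
mean(x_i)`) are compared with a Wald statistic.  Elevation variances
combine residual variation about the common-slope axis with the shared
slope's own uncertainty — obtained from the numerical curvature of the
pooled profile — which also induces covariance between elevations of
different groups.  Pairwise comparisons are 1-df Wald tests, and
deliberately unadjusted for multiplicity: the analysis philosophy
pairs effect-size intervals with raw significance values rather than
applying Bonferroni-style corrections, which trade type-I inflation
for substantial power loss at these sample sizes.

## Phylogenetic models

Tip values are modelled as jointly normal, `y ~ MVN(root * 1, sigma2 *
C_theta)`, where `C` is the matrix of shared root-to-ancestor path
lengths (My) and `C_theta` its transform:

* **λ** multiplies off-diagonal entries; diagonal untouched.  λ = 0 is
  a star phylogeny (no signal), λ = 1 Brownian motion.  The search
  range is [0, 1]; super-unity λ is not supported, matching the
  convention of capping confidence limits at 1.
* **δ** raises every entry (node depths) elementwise to a power,
  search range (0, 3].  δ > 1 concentrates change toward the tips.
  The transform is applied **without** total-depth rescaling: a depth
  rescale multiplies C by a constant, which the profiled rate σ²
  absorbs exactly, so likelihood orderings — and hence every fitted
  parameter and every test in this package — are unchanged.  Only the
  reported σ² would differ, and it is documented as being on the
  transformed scale.

The rate and root state have closed-form profile estimates
(`root = (1'C⁻¹1)⁻¹ 1'C⁻¹y`, `sigma2 = r'C⁻¹r / n`, i.e. ML rather
than REML, so likelihoods are comparable across models and with the
PGLS log-likelihood evaluated at its ML rate).  The transform
parameter is then a bounded 1-D maximization, run over both
subintervals on either side of the Brownian reference value 1 plus the
interval bounds and 1 itself; near-ties within 1e-8 log-likelihood
resolve toward the value closest to 1, so "indistinguishable from
Brownian motion" is reported as such rather than as an arbitrary
boundary.  Cholesky factorization guards positive-definiteness; a
single jitter of 1e-10 times the mean diagonal is attempted before
failing.

### Parametric bootstrap and model comparison

Confidence intervals for λ and δ come from a full parametric bootstrap
(simulate at the fitted parameter/rate/root, refit, take 2.5/97.5
percentiles).  The λ-vs-δ comparison is a parametric Monte Carlo
procedure: the observed statistic is `logL(delta-hat) -
logL(lambda-hat)`; traits are re-simulated under each fitted model in
turn (default 1000 iterations at study scale), both models are refit
to every replicate, and a model is rejected when the central 95% band
of its null ratios excludes the observed one.  Replicate i draws from
the substream seeded by `seed + i`, so results are bitwise
reproducible and independent of execution order; runs abort if more
than 1% of refits fail.

The two models overlap substantially in what they can express — both
λ < 1 and δ > 1 thin the relative shared covariance — so the
comparison has only moderate power even at 128 tips, and at the
study's own scale (38 species, root depth 110 My, major divergences
80–110 My old) both λ and δ intervals characteristically span much of
their range.  The test suite reproduces this wide-interval phenomenon
deliberately, generating data at λ = 0.9, representative of the strong
but imperfect signal the single-trait fits estimate (λ between 0.76
and 1.0 across traits and residuals).

### PGLS and co-diversification

Bivariate GLS under the Brownian covariance gives
phylogeny-corrected scaling exponents; coefficient intervals use the
t(n − 2) reference with the n − 2 rate denominator.  Residuals are
taken on the raw (unwhitened) scale, indexed by species, and fed to
the same λ/δ/pmc machinery to ask whether segment masses have
*co-diversified* with size, beyond each trait's own history.  The
regression residuals analysed this way come from **phylogenetic** GLS
(Brownian covariance), not ordinary least squares: the
co-diversification question is posed in a comparative-methods setting,
and the non-phylogenetic variant is a degenerate case (`C = I`) that
remains callable.

A caution encoded in the tests rather than prose: the attenuation
identity `b_OLS = r * b_SMA` generalizes to PGLS only in whitened
coordinates (with the whitened intercept column projected out, the GLS
slope equals the whitened correlation times the whitened SD ratio).
On the raw scale a PGLS slope under a covariance unrelated to the data
can slightly exceed the SMA slope, so no raw-scale inequality is
asserted.

## Coefficient-of-variation comparison

Segment proportions divide thigh, shank, tarsometatarsal, and digit
mass by their four-component sum (the pes is the tars + digits
composite, not a fifth component; shares sum to 1 by construction).
For positive data, Var(log v) ≈ CV², so equal CVs correspond to
homogeneous log-scale variances, tested Levene-style: one-way ANOVA of
absolute deviations of log values from group means.  This is an
interpretation of the classical log-ANOVA approach to CV comparison;
the original two-way layout is under-specified, so the package makes
the blocking explicit and optional.  With a block factor (species,
when every segment is measured on the same individuals), an additive
group + block fit is removed first so body-size variation does not
masquerade as dispersion.  Pairwise comparisons are always unblocked:
for exactly two groups the additive fit forces the two groups'
absolute residuals to coincide, leaving a statistic that is
identically zero.  Calibration at study-like sizes (four lognormal
groups of 35, equal CV, 1000 replicates) measured a 5.8% rejection
rate at nominal 5%.

The bundled analysis computes proportions over all species with
complete segment data (36 of 38) rather than a specific subsample;
with shares, the relevant contrast — distal segments far more variable
than proximal ones — is robust to that choice.

## The synthetic-data generator

Because no time-calibrated tree is bundled, the generator defines the
study conditions for everything phylogenetic:

* **Trees**: Yule (pure birth) with n = 38 tips by default, rescaled
  to root depth 110 My — the scale of the deepest divergences among
  the sampled lineages.  Tests that need statistical power use 128
  tips and say so.
* **Traits**: one MVN draw at `sigma2 * C_theta`; degenerate
  `sigma2 = 0` returns the root state everywhere.
* **Tables**: log10 body mass drawn *log-uniformly* over 1.26–3.84
  (18–6975 g, the bundled table's span).  Log-uniform rather than
  lognormal because the study deliberately sampled functional and size
  extremes rather than a clade at random.  Hindlimb length follows the
  cube-root of body mass with 0.03 log10 residual SD; segments follow
  configurable allometries (defaults near the fitted exponents and
  intercepts) with iid or phylogenetically correlated residuals;
  missing values are punched in at a configurable rate up to 0.3.

What the generator does *not* emulate: non-ultrametric trees, fossil
tips, measurement-error models, clade-structured allometries, or
correlated missingness (in the real table, missingness clusters in
two species dissected without separating the pes).  Passing tests
therefore demonstrate correctness of the machinery under the stated
generative model, not robustness to every feature of real
morphometric data.

## Problem sizes and numerical conventions

Monte Carlo components of the test suite run at reduced but stated
sizes, chosen so the whole suite completes in minutes while leaving
each check statistically meaningful: pmc calibration at 200 inner
simulations and 100 outer replicates on 38-tip trees; power and
nesting checks at 100 inner simulations with 15–20 fixed-seed outer
replicates; λ recovery at 100 replicates per true value on 128-tip
trees; CV and common-slope calibrations at 1000 replicates.
Study-scale analyses default to 1000 simulations.

Numerical conventions, in one place: optimizer x-tolerance 1e-8
(transform parameters) and 1e-10 (common slope); likelihood near-ties
resolve toward Brownian motion; CI boundary exclusion is strict (a
null slope exactly on a limit is not excluded); missing values are
never imputed; species means with two source specimens are single
records; all seeds are mandatory wherever randomness exists.

## Known limitations

* The bundled table stores the published, *rounded* species means.
  Statistics recomputed from it can differ from values computed on
  unrounded source measurements in the second decimal place —
  the test suite documents exactly where.
* The λ/δ comparison is pairwise only; no AIC-style multi-model
  ranking, and no OU/kappa/early-burst/variable-rate models, which
  demand more taxa than this design contemplates.
* SMA machinery covers the standardized major axis only (no major
  axis, no robust variants), matching the analysis it reproduces.
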