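---
title: "Methods: multi-environment GBLUP from pooled allele frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-environment GBLUP from pooled allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models implemented in `mxegp`,
the assumptions behind them, the choices we made where several defensible
options existed, and what the synthetic-data generator does and does not
emulate.

## Data model

The genotype of an accession is a vector of pool-based reference-allele
frequencies: DNA from a large pool of individuals (nominally 200
seedlings) is sequenced together, and the per-marker frequency estimates
take values in [0, 1].  This sidesteps individual genotype calls — natural
for outbreeding forage crops — at the cost of losing within-accession
genotype configurations.  All downstream models treat the frequency
vector as the accession's "genotype".

Marker quality control retains a marker when all three rules hold:

1. at least `min_informative = 10` accessions have a non-missing
   frequency inside `bounds = [0.05, 0.95]`;
2. its mean frequency over non-missing accessions is inside the same
   band;
3. at most `max_missing_frac = 5%` of its entries are missing.

The survivor set is the intersection of the three rules, so application
order is irrelevant (asserted in tests).  We read "between 0.05 and 0.95"
as the *inclusive* interval: boundary values are vanishingly rare in real
frequency data, and inclusion is the conservative reading.  Both the
bounds and their inclusivity are configurable.  Remaining missing values
are imputed by the marker mean, and markers are then centred and divided
by their standard deviation.  We use the sample (n−1) standard deviation;
the convention is not dictated by the method, the alternative differs by
a factor `sqrt((n-1)/n)` absorbed into the variance components, and the
statistics are stored with the matrix so held-out accessions are always
projected with *training* means and sds.  The genomic relationship matrix
is `G = XX'/p`.

## Field-trial adjustment

Plot-level data are adjusted per environment with a linear mixed model:
accession effects (and complete-block effects, where the design has them
as part of the mean structure) fixed, incomplete-block terms (rows,
columns) random, fitted by REML.  Three designs are supported: `rcbd`
(complete blocks, block random), `alpha` (incomplete blocks within fixed
complete replicates) and `p_rep` (partially replicated; rows and columns
act as incomplete blocks and there is no complete-block term).  BLUEs are
the estimated accession means `mu + g_i` from the fixed-accession fit;
BLUPs come from a second fit with the accession random.  We fit with
`lme4::lmer`: the models are routine one- or two-random-term LMMs and a
bespoke REML optimiser would add risk without adding capability.  The
fixed design matrix is rank-checked before fitting so confounded terms
produce an explicit error rather than a silently dropped coefficient.
Single-replicate data with no blocking information are passed through as
raw means and flagged `unadjusted`.

Heritability is available two ways: the OLS slope of BLUP on BLUE (the
shrinkage factor of the random-accession fit; clamped to [0, 1] with the
raw value retained), and the broad-sense ratio
`sigma2_g / (sigma2_g + sigma2_e / n_r)` for balanced trials with `n_r`
replicates.  BLUEs entering genomic prediction are scaled and normalised
*within* each environment — z-scores by default, rank-based normal scores
as an option — because "unscaled" environments would otherwise contribute
unequally to the stacked likelihood.

## Genomic-prediction models

Three GBLUP strategies over the standardised markers:

* **SingleEnv**: `y_j = 1 mu_j + X beta_j + eps_j` per environment.
* **AcrossEnv**: one shared effect vector `b0` with per-environment
  intercepts; the genetic value of an accession is identical in every
  environment (equivalently, the stacked `u ~ N(0, G0 sigma2_u)` with
  `G0` the block-repeated relationship matrix).
* **MxE**: `beta_jk = b_0k + b_jk` — a shared component with variance
  `sigma2_b0` plus an environment-specific deviation with variance
  `sigma2_bj`, inducing `u0 ~ N(0, G sigma2_u0)` shared across
  environments and block-diagonal specific values `u1`.

We sample in marker-effect space rather than building the stacked
`n_env * n_acc` covariance: because the marker matrix is identical across
environments the two parameterisations are the same model
(`sigma2_u = p * sigma2_beta` on the standardised scale, since
`diag(XX'/p) ~ 1`), and the marker-space form makes unbalanced
accession-by-environment incidence trivial — a missing cell is simply an
absent row of the stacked response.  Prediction for any cell, observed or
not, is `mu_j + x'(b0 + b_j)`.

The Gibbs sampler (Rcpp) updates, per iteration: flat-prior intercepts;
each marker effect from its scalar normal full conditional with an
in-place residual update; each block variance from its
scaled-inverse-chi-square full conditional.  A common residual variance
is shared by all environments, matching the single residual term of the
interaction model; a per-environment-residual variant was considered and
deliberately not implemented (the flag exists and errors informatively)
because the joint analyses this package targets standardise each
environment to unit variance first, which removes most residual
heterogeneity.  All randomness flows through R's RNG, so a seed makes
chains bit-reproducible; the sampler's cost per iteration is
`O(p * n_obs)` per effect block.

**Defaults and priors.**  25,000 iterations with 2,500 burn-in (thinning
5) are the reference settings; short exploratory chains are fine for
point predictions but variance components deserve the full run.  Variance
priors are scaled-inverse-chi-square with `prior_df = 5`; scales are set
so the prior mode allocates `prior_R2 = 0.5` of the sample phenotypic
variance to the genetic blocks (split equally among them) and the rest to
the residual — the convention of the reference Bayesian ridge software in
this field.  The phenotypic variance is floored at 1e-8 so degenerate
(constant) responses yield a proper, tightly-concentrated-at-zero
posterior instead of a division by zero.  Fits with fewer than 10
observations are refused outright.

**Model-fit summary.**  Per environment,
`R2_j = (sigma2_u0 + sigma2_uj) / (sigma2_e + sigma2_u0 + sigma2_uj)`.
We report the posterior mean of the *per-draw* ratio (with its posterior
sd), not the ratio of posterior means: a per-draw quantity has a
well-defined spread, which is what a reported sd implies.  The
deterministic `variance_r2()` on point estimates is kept for worked
examples; the two differ by a Jensen gap that shrinks with chain length.

**A note on identifiability.**  With two environments, the split of
genetic signal into shared and specific components is informed only by
the between-environment covariance, and the prior keeps the specific
variances away from zero.  On data simulated with *no* interaction the
posterior specific-to-main ratio settles near 0.3 at n = 300 rather than
collapsing to zero, while genuinely interacting data of the same size
produce ratios near 0.5–0.6; tests assert the contrast, not an
unattainable zero.  GEBVs are far less sensitive than the decomposition:
the interaction fit on non-interacting data agrees with the shared-effect
fit at r > 0.99.

**Oracle.**  `gblup_oracle()` computes the exact multi-kernel BLUP at
fixed variance components by dense algebra: GLS intercepts, then
`u_m = sigma2_m Cov(u_m, y) V^{-1} (y - W mu)` with
`V = sum_m sigma2_m K_m + I sigma2_e`.  It is the package's independent
reference: at fixed variances the Gibbs posterior means must (and in the
acceptance tests do) match it to correlation > 0.999.  It errors on a
singular `V` rather than regularising silently.

## Cross-validation

* **CV1** draws `floor(0.3 n)` accessions per partition and masks them in
  every environment: prediction for entirely unphenotyped material.
* **CV2** draws disjoint subsets, one per environment, each masked in
  exactly one environment, so every test accession remains observed
  elsewhere and information is borrowed through the shared component.
  For more than two environments we keep the minimal construction —
  equal-size disjoint subsets, one per environment — rather than
  resampling independently per environment, which could not guarantee
  non-overlap.  Test-set size uses `floor(fraction * n)`; the remainder
  stays in training.
* **Leave-group-out** holds out one region or breeders'-material group
  everywhere, plus random-removal controls of a fixed size (default 10
  controls) to separate the effect of set size from the effect of
  structure.

Predictive ability is the arithmetic mean over partitions of the
per-environment Pearson correlation between predictions and held-out
values (no Fisher-z transform — the mean of 50 partition correlations is
the conventional summary here); partitions whose test set has fewer than
3 usable observations, or zero variance, record a missing correlation and
are excluded from the mean with the count reported.  Bias is the OLS
slope of observed on predicted, pooled over environments within a
partition.  Marker-number sweeps resample marker subsets (each subset
keeps its own standardisation and marker count, so its relationship
matrix is rebuilt implicitly); training-fraction sweeps rebuild CV1
partitions at each fraction.  Cross-population validation fits on the
full training panel, projects held-out genotypes with training means/sds,
and correlates the *main* genetic value with phenotypes from the new
environments — the shared component is the only part of the model that
transfers to an environment the model has never seen.

## The synthetic-data generator

The generator emulates the shape of a pool-GBS multi-environment panel:
392 accessions by 20,156 markers in five regional groups by default, with
ancestral frequencies uniform on [0.1, 0.9], group frequencies from the
Balding–Nichols beta distribution at `fst = 0.1`, and accession-level
frequencies as binomial proportions from `2 * 200` pool draws (pool
sampling and sequencing noise folded into one binomial layer — only the
variance scale matters downstream).  Phenotypes follow the interaction
model generatively: `b0 ~ N(0, sigma2_u0 / p)`, `bj ~ N(0, sigma2_uj / p)`,
`y_j = mu_j + X(b0 + bj) + e`, with the default components
(0.4 / 0.2 / 0.4) on the standardised scale.  Group-confounded phenotypes
add a per-group mean shift so genetic value and group membership are
correlated — the mechanism by which population structure inflates
random-CV predictive ability.  Plot-level layouts (RCBD, alpha, p-rep)
add block/row/column effects and residual noise at configured sds.

Two properties of the generator deserve emphasis.  First, genotype and
phenotype layers draw from deliberately separated RNG streams: reusing
one seed for both layers would otherwise couple the "noise" to the
markers and let a model interpolate it (we found and fixed exactly this
failure mode during development; a fixture test guards it).  Second,
group structure concentrates a large share of marker variance on the
group-contrast eigenvectors of `G`, so the *realised* genetic variance of
a single effect draw fluctuates widely around its nominal value — at
fst = 0.01 with 200 accessions the leading eigenvalue already carries a
third of the trace.  Tests that assert recovery of nominal variance
fractions therefore use unstructured panels, and structured panels are
used only for directional claims (e.g. leave-group-out PA below
random-control PA), which are robust to this fluctuation.  Real panels
share this property; fitted components describe the fitted panel, not a
platonic parameter.

What the generator does **not** emulate: linkage disequilibrium along
chromosomes (markers are exchangeable), read-depth variation between
loci, allele-frequency estimation error structure beyond binomial,
pedigree relationships within groups, and spatial field trends beyond
row/column blocks.  Passing tests on synthetic data therefore demonstrate
the statistical machinery, not robustness to every artefact of real
pool-GBS data.

## Problem sizes used in the checks

The automated scientific checks run at desk scale, chosen once as
representative rather than maximal: sampler-vs-oracle equivalence at 150
accessions and 400 markers (10,000 iterations); variance-fraction
recovery at 300 accessions, 1,000 markers, two environments, 5,000
iterations over 10 seeds; model- and scheme-ordering comparisons at 200
accessions, 250 markers, 20 partitions over 5 seeds; structure hold-outs
at 160 accessions in four groups; bias calibration over 20 replicates of
a 200-accession single-environment panel.  The reference quantities in
`scripts/acceptance.R` are closed-form ratios and run instantly.

## Known limitations

* Marker priors are ridge-only (one variance per block); heavier-tailed
  marker priors and Gaussian-kernel relationship matrices are out of
  scope.
* The interaction covariance is the shared-plus-specific decomposition;
  factor-analytic structures with heterogeneous loadings are not
  implemented.
* Between-environment genetic covariance is forced non-negative by
  construction (it is `sigma2_u0`), so negatively correlated environments
  are fitted poorly by design.
* Field models ignore spatial correlation beyond row/column blocks
  (no AR1-type trends) and are single-trait.
* The per-environment-residual variant of the joint models is not
  sampled; environments are standardised to unit variance first, which
  the common-residual model matches well.
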