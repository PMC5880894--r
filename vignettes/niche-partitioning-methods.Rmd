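---
title: "Methods: strain-level niche partitioning from amplicon time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain-level niche partitioning from amplicon time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `nichepart`, the defaults and why
they were chosen, what the synthetic-data generator does and does not
emulate, and the numerical conventions. It states no empirical result that
the test suite does not itself compute.

## Scientific setting

Two bloom-forming cyanobacterial genera are followed over a multi-year,
open-water-season sampling series (~135 samples after depth filtering) with
16S amplicon sequencing and matched environmental measurements (particulate
and dissolved N and P, temperature, precipitation, toxin concentration).
Within each genus, exact sequence variants ("strains") are resolved at
single-nucleotide resolution. The central question is how niche similarity
between strains — measured either as co-occurrence or as correlated fitted
responses to the environment — changes with their pairwise genetic
distance.

## Entropy decomposition of reads

`med_decompose` implements a simplified minimum entropy decomposition.
Positional Shannon entropy is computed over the five-symbol alphabet
`A,C,G,T,-` (the gap is a full symbol, so indel columns can drive splits);
while the maximum positional entropy exceeds a threshold, the node is split
by the symbol at the arg-max position, ties resolved toward the lowest
index. A child survives only if its most abundant unique sequence carries
at least `M` reads.

Choices the upstream literature leaves open, fixed here:

* **Entropy threshold 0.0965 nats.** The analysis this package follows
  published only the `-M 500` noise filter; 0.0965 is the decomposition
  tool's own published default and is exposed as a parameter.
* **Discarded children are dropped, not reassigned.** A conservative
  reading of the reported ~7% noise-filtered reads; read conservation
  (retained + noise = input) is asserted in the tests on every run.
* **One split position per recursion step**, the simplest procedure
  consistent with single-nucleotide resolution.

## Conditionally rare taxa

A taxon is conditionally rare when its per-sample relative abundance series
is strongly bimodal (`b >= 0.90`) and it is at least once non-negligible
(maximum relative abundance >= 0.005). Both thresholds are the referenced
detection script's published defaults. Skewness and kurtosis use the
bias-corrected sample estimators. Two consequences worth knowing:

* `b` is undefined for constant series and requires `n >= 4`; such taxa are
  reported not-CRT with a reason rather than erroring the run.
* At small `n` the bias corrections pull `b` well below its population
  value: a 10-sample series with one burst has `b ≈ 0.77`, below the 0.9
  threshold, while the same dynamics over 135 samples exceed it. The
  detector is therefore calibrated for series of roughly a hundred samples,
  which is the design point here.

Genus enrichment uses a two-sided Fisher exact test by full hypergeometric
enumeration, with the background defined as the community *excluding* the
focal genus; degenerate margins return p = 1 by convention.

## Compositional transforms

Counts are compositions; all downstream models operate on centered
log-ratios. Zeros are replaced multiplicatively (zeros become `delta`,
nonzero parts shrink by `1 - Z * delta`), with `delta` defaulting to half
the smallest nonzero relative abundance observed in the matrix — standard
practice where the source analysis cites the procedure without a value.
Two grains are used: genus totals against the whole community (plus an
`other` pool), and strains against their genus total. Samples where the
focal genus is entirely absent are dropped from intra-genus analyses
rather than imputed, because the intra-genus composition is undefined
there; the drop is logged.

## SparCC-style co-occurrence

The log-ratio variation matrix `t_ij = var log(f_i/f_j)` is converted to
basis correlations under the sparsity assumption; with no exclusions the
solution is the closed form `omega_i^2 = (t_i - W)/(D - 2)`. Strongly
correlated pairs violate the assumption, so the single largest `|rho|`
above 0.1 is excluded (its contribution zeroed and the linear system
adjusted) and the solve repeated, up to 10 rounds — the method's published
defaults. The "20 iterations" of the source analysis refer to Dirichlet
fraction resampling (`counts + 1` prior), of which the point estimate is
the elementwise median; that convention is kept. Significance uses a
permutation bootstrap: each taxon's counts are permuted independently
across samples, breaking association while preserving marginals, and the
two-sided pseudo-p is `(1 + #exceedances)/(B + 1)`, never zero. Whether
the original analysis permuted or resampled with replacement is not
stated; permutation is the cleaner null for "no association". Non-positive
basis variances (possible for small D) mark that taxon's correlations
missing, and such null draws are simply excluded from the bootstrap count.

## The latent variable model

On clr abundances the model is
`y_ij = beta0_j + x_i' beta_j + z_i' lambda_j + eps_ij`, with standardized
covariates and their squares as `x` (quadratic columns are squares of the
standardized columns, not re-standardized — the literal `Y ~ X + X^2`
reading), `z_i ~ N(0, I_d)` with `d = 2` by default, and Gaussian errors.

The source analysis fit this family by Bayesian MCMC. Here estimation is
maximum likelihood, for determinism and desk-scale speed, and it separates
exactly into two blocks: because every taxon shares the same design, the
ML regression coefficients are per-taxon ordinary least squares regardless
of the residual covariance; the loadings and uniquenesses are then an EM
factor analysis of the residual covariance, which is monotone in the
marginal likelihood. Loadings are identified by rotation to lower
triangular with positive diagonal. With `d = 0` the model is exactly
per-taxon OLS, which the tests assert to 1e-8. Non-convergence within the
iteration cap (possible for very small taxon sets near Heywood boundaries)
returns a flagged fit with a warning rather than an error.

Niche similarity between taxa j and k is the Pearson correlation across
samples of the fitted environmental responses `X beta_j` and `X beta_k`
(intercepts excluded; the full linear predictor including quadratic
columns). Significance is assessed by a nonparametric bootstrap over
samples (refit per resample, percentile interval excluding zero at 95%),
standing in for the original credible intervals in the same
error-control role. Constant fitted responses have undefined correlation
and are reported missing.

Univariate companion fits (`univariate_best_fit`) compare degree-1 and
degree-2 polynomials per taxon-covariate pair with
`AIC = n log(RSS/n) + 2k`, `k` counting coefficients plus the variance; a
perfect fit (RSS = 0) reports degree 1 by convention.

## Distance decay

Genetic distance is the p-distance: the proportion of differing sites
among sites where neither sequence has a gap. Decay regressions take
unordered pairs as the unit — co-occurrence vs distance at degree 1,
per-dimension co-response vs distance with AIC-selected degree up to 2,
and per-partner `|r_AP - r_BP|` vs `d_AB`. Only pairs whose similarity
statistic is significant enter by default (`only_significant`), mirroring
the source analysis; no correction is applied for the non-independence of
pairs sharing a taxon, also mirroring the source — a known caveat, noted
in output metadata rather than fixed.

## The synthetic world

`generate_study` emulates the study's shape: 135 samples spanning eight
open-water seasons at two alternating sites, two focal genera of 25 and 6
strains with maximum within-genus p-distances near 0.05 and 0.01, 60
background taxa, seven environmental variables with AR(1) + seasonal
structure, and read depths log-normal with median 5,000 (scaled down from
the study's ~4x10^4 for test speed).

Niche coefficients for focal strains are Gaussian-process draws over the
realized p-distance matrix: covariance `sd^2 * K(d)` per design column,
with `K` either exponential (`exp(-d/ell)`, `ell = 0.02` so similarity
falls to ~0.1 across the observed distance range) or a damped cosine
(`(1-w) exp(-d/ell) + w cos(2 pi d/period) exp(-d/ell2)`, period 0.03)
whose implied similarity declines to a dip near d = 0.015 and rebounds
near d = 0.03 — the non-monotone pattern of interest for particulate
nutrients. A kernel that is not positive semidefinite on a realized tree
metric is projected by eigenvalue clipping (logged) or, with
`jitter = FALSE`, rejected.

Generator scales were fixed once, before the acceptance tests were
written: GP scale 0.5 per linear and 0.25 per quadratic column (clr-scale
responses of order one, matching the magnitude of visually reported strain
responses), cell-level logistic-normal noise 0.15 (most overdispersion is
carried by the two latent factors, loading scale 0.3), and focal
intercepts N(0.5, 0.8) so the focal genera hold a bloom-like double-digit
share of reads.

Planted conditionally rare taxa are background taxa pinned at a baseline
relative abundance of 2e-4 that burst in ~5% of samples. Burst heights are
pinned on the **composition scale** at `burst x baseline` (100x by
default), not applied as a factor on the latent scale: a latent-scale
factor makes burst heights inherit the community normalizer's variance
(log-sd ~0.5 under bloom dynamics), which smears the high mode and drops
the bimodality coefficient below threshold for a large fraction of planted
taxa. Ecologically, the pinned version states that bloom events reach a
characteristic share of the community, which is the observable the
detector keys on.

What the generator does **not** emulate — and hence what a green test does
not establish: sequencing error profiles and chimeras (reads are
error-free, so decomposition recovery is exact by construction), within-
variant microdiversity, temporal autocorrelation of taxon abundances
beyond what the environment induces, spatial structure between sites, and
non-neutral covariation between depth and composition.

## Pipeline orchestration

`run_pipeline` executes simulate/ingest, entropy decomposition, clr, CRT,
co-occurrence, LVM, and decay in order from one JSON-configurable object,
writing per-stage outputs and checksums to a manifest; a stage failure
aborts naming the stage, with earlier outputs retained. On simulated
bundles the decomposition stage runs on the per-taxon representative
sequences weighted by total taxon reads — there is no raw per-read
provenance in a simulated study — so its node inventory is recorded as a
demonstration while downstream stages use the ingested count table.

## Numerical conventions and edge cases

* Depth filtering is strict on "less than": a sample with exactly the
  minimum reads is retained.
* Missing environmental values: listwise deletion per analysis, logged;
  the source does not state its handling.
* Stage seeds derive deterministically from the run seed and the stage
  name, so adding a stage never perturbs another's stream; all seeds stay
  below 2^31.
* Correlations are clipped to [-1, 1] with a log entry if a solver
  exceeds them; clr column sums are asserted to zero within 1e-9.
* AIC uses the same `n log(RSS/n) + 2k` form in the univariate
  environmental fits and the decay regressions, for comparability.

## Known limitations

The LVM significance bootstrap refits the model per resample and is the
slow path (`B = 100` default); pair non-independence in decay regressions
is uncorrected; the entropy decomposition omits the upstream tool's
maximum-variation refinement; and the bimodality detector's thresholds are
tuned to ~100-sample series, as noted above.
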