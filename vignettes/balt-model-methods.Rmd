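---
title: "Modelling developmental expression transitions with the BALT sigmoid"
author: "baltatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling developmental expression transitions with the BALT sigmoid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baltatlas)
```

## The problem

During the first trimester of human development the adrenal gland, testis
and ovary execute sharply timed transcriptional programs: testis
determination driven by a transient pulse of *SRY*, a slow SOX9-like
upregulation of Sertoli-associated genes, and an abrupt onset of testicular
steroidogenesis around eight weeks post conception. Bulk expression atlases
of staged samples (Carnegie stages CS17--CS23, fetal stages F1--F3, mapped
to midpoint ages in days post conception, dpc) capture these programs as
per-gene time courses on the log2 scale. `baltatlas` provides the analysis
stack for such atlases: a phenomenological transition model, moderated
differential expression, batch/QC utilities, candidate-gene screens, and a
ground-truth simulator that mirrors the study design (53 samples: 17
adrenal, 20 testis, 10 ovary, 6 single-organ controls, 42--73 dpc).

## The BALT model

Per-gene expression over time is described by a four-parameter sigmoid

$$X(t) = B + \frac{A}{1 + e^{f(T)\,(L - t)}},$$

with **B**asis (starting log2 level), signed **A**mplitude (negative for
down-regulation), **L**ocalisation (inflexion time in dpc) and
**T**ransition (duration in days). The rate sub-function is calibrated as

$$f(T) = \frac{2\ln 9}{T},$$

which makes `T` exactly the time the curve takes to travel from 10% to 90%
of its amplitude — the most interpretable calibration under which the
transition parameter "can be expressed in days". The calibration is a
package design choice; alternative calibrations can be plugged in by
rescaling `T`. Identities that follow (and are tested): `X(L) = B + A/2`,
asymptotes `B` and `B + A`, and a 10--90% rise time equal to `T` exactly.

### Fitting

`balt_fit()` minimises the residual sum of squares with bounded
Levenberg--Marquardt (via `minpack.lm::nls.lm`), using multi-start
initialisation over the 0.1--0.9 quantiles of the observed times for `L`
(basis from the earliest tertile of the data, amplitude from the latest,
`T` from a quarter of the span). Bounds keep the optimiser honest on weakly
informative data: `L` inside the observed range plus half a span either
side, `T` in `[0.1, 3·span]` days, `B` and `A` within the data range
±2 log2 units. RSS ties are broken toward smaller `|A|`, then earlier `L`
(parsimony). The parameter covariance is `σ̂²(JᵀJ)⁻¹` from the
Levenberg--Marquardt Jacobian. On ≤30-point inputs the fit matches an
independent grid-search oracle (L × T grid with B, A solved linearly) to
within 1e-6 in RSS, and noiseless curves are recovered to 1e-4.

### Model selection and classification

`select_model()` compares the full sigmoid against a constant (basis-only)
model by Gaussian BIC (1 vs 4 mean parameters, plus a variance each); ties
go to the constant model. Under a flat truth with noise sd 0.25 the constant
model wins in ≥95% of replicates; under a strong sigmoid truth the sigmoid
wins as often.

`classify_profile()` maps fits onto the dynamic classes the atlas exhibits:
`flat`, `switch_up`/`switch_down`, and `curvilinear_incomplete` (the
SOX9-like shape). A switch call requires the 10--90% transition interval
`L ± T/2` to lie inside the observation window *with a buffer of 10% of the
window span at each edge* (`margin_frac = 0.1`). The buffer exists because
incomplete sigmoids are weakly identified: under noise their fitted
transitions drift to completions just inside the window, and without the
margin genuinely curvilinear genes are called switches. Transitions
completing at or beyond the buffered edge are therefore assigned to the
incomplete class. The amplitude gate (`min_amplitude = 0.58` log2,
≈1.5-fold) suppresses noise-driven calls.

`onset_window()` summarises fitted `L` over switch-classified genes — the
estimator of the steroidogenesis-onset window (54--57 dpc in the testis) —
and `match_reference()` collects genes whose fitted dynamics match a
reference gene (same class, same direction, `|A|` above the gate, `L`/`T`
within tolerances). For curvilinear references only `L` is compared, with
the tolerance doubled, because `T` is poorly identified when the transition
does not complete.

### MCMC uncertainty

`balt_mcmc()` runs random-walk Metropolis on `(B, A, L, log T, log σ²)`
with Gaussian proposals scaled by `2.4²/5` times the (delta-method
transformed) Levenberg--Marquardt covariance, flat priors truncated at the
fit bounds, defaulting to 4 chains × 5000 iterations with 1000 burn-in.
Results are deterministic given the seed. Across 50 noisy replicates
(sd 0.25) the central 95% interval for `L` covers the truth in ≥90% of
replicates; the tests use shortened chains (2 × 1500--3000) to keep the
suite fast, which is sufficient for the interval checks at this data size.

## Differential expression

Contrasts are two-group comparisons of log2 means (`fit_group_means()`),
with empirical-Bayes variance moderation (`moderate_variances()`):
per-gene variances are shrunk toward a prior `s₀²` with prior degrees of
freedom `d₀`, both estimated by method of moments on the log sample
variances (digamma/trigamma matching), and the moderated t is referred to
`df + d₀` degrees of freedom. The two limiting cases are exact: `d₀ = 0`
reproduces the ordinary pooled-variance t, `d₀ = ∞` the pure-prior t. When
the observed log variances are *less* dispersed than chi-square sampling
noise, `d₀ = ∞` is the correct limit and is used (rather than falling back
to the ordinary t, which is reserved for genuine estimation failure). The
estimates agree with an independent empirical-Bayes implementation to
within 1% on simulated data. p-values are two-sided; `adjust_bh()` applies
Benjamini--Hochberg step-up FDR; `select_de()` applies the study's
thresholds (adjusted p ≤ 0.05 with log2FC ≥ 1 or ≥ 2).

Fold-change utilities follow the printed conventions: absolute fold change
is `2^log2FC` for up contrasts (e.g. log2FC 6.85 ↔ 115.4), and qPCR fold
changes use the comparative Ct method, `2^(−ΔΔCt)`.

## Preprocessing and QC

* `quantile_normalize()` forces all sample distributions onto the mean of
  the sorted columns (ties averaged) — the normalisation stand-in when the
  input is not already RMA-normalised.
* `adjust_batch()` removes per-gene batch location/scale effects. The
  `meanvar` mode equalises per-batch gene means/variances exactly (pure
  additive offsets are removed to machine precision). The `eb` mode first
  standardises each gene by its pooled within-batch sd, then shrinks
  per-batch location and log-scale estimates across genes toward their
  batch-wise means with inverse-variance weights before subtraction — a
  ComBat-style correction without covariates. The standardisation step is
  essential: on the raw scale the weights are dominated by biological
  rather than sampling variance and high-signal genes are under-corrected.
  Full ComBat parity (parametric priors, covariates) is not attempted; the
  property downstream stages need is batch-mean equalisation.
* `detect_outliers()` flags samples whose median within-tissue Pearson
  correlation falls below Q1 − k·IQR (default k = 3, an "extreme outlier"
  fence); tissues with fewer than 4 samples are skipped with a warning.
* `pca_embed()` and `cluster_samples()` (Ward `ward.D2` on Euclidean
  distances over the 500 most-variable genes, samples pre-sorted by id so
  the tree is input-order invariant) provide the sample-structure views.

## The synthetic atlas generator

The generator is first-class, tested code: every downstream stage is
validated against planted truth without any download. `build_design()`
reproduces the study composition (53 samples; the testis allocation places
9 samples before CS23, 3 at CS23 and 8 after, so the early/late split
matches the study's N = 9/8 groups), with the stage-midpoint map
CS17 = 42 … CS23 = 56.5 … F3 = 73 dpc (configurable from file; the values
span the published 42--74 dpc range and are package defaults, not
measurements). Profile classes:

* **flat** background genes (baselines spread over 4--10 log2);
* **tissue_offset** identity signatures — 20 genes per tissue with offsets
  3--5 log2. Tissue identity must dominate within-tissue developmental
  change in whole-matrix distances, as it does in real transcriptomes where
  it is carried by hundreds of genes; with only a handful of markers the
  pre-steroidogenic testis becomes artificially indistinguishable from
  control tissue.
* **sigmoid** transitions: 8 steroidogenic genes (onset `L` 54.8--56.2 dpc,
  `T` 3--5 days, amplitudes 4--7 log2, i.e. 16--128-fold, the range the
  published adrenal tables show) and 3 SOX9-like curvilinear genes (slow
  incomplete sigmoids rising ≈2-fold within the window). Steroidogenic
  genes transition in the testis and sit at the finished level `B + A`
  throughout the window in the adrenal (`plateau_tissues`): adrenal
  steroidogenesis onset precedes 42 dpc, and a mid-window adrenal
  transition would leave within-group variance so large that no amplitude
  could make the adrenal-vs-control screen significant — a structural
  property of the moderated t, not a tuning matter.
* **pulse**: one Y-chromosomal SRY-like gene, a Gaussian bump (centre
  45 dpc, width 5 days, height 1.5 log2) that has decayed by ~57 dpc; the
  simplest shape matching the transient profile.

Noise is additive Gaussian on the log2 scale (sd 0.25, the array
log-intensity convention); batch effects are additive per-batch per-gene
offsets drawn Normal(0, 0.3) over two seeded balanced batches. Identical
seeds reproduce matrices bit for bit.

What the generator does **not** emulate: probe-level intensities, RMA
summarisation, correlated gene modules, heterogeneity among the six control
organs, karyotype-specific dosage, or count-based noise. Passing tests
therefore demonstrate correctness of the algorithms under the planted
model, not performance guarantees on arrays.

## The screens

Gene symbols are upper-cased before any set operation. `venn_counts()`
(2- or 3-set partitions, verified against brute-force enumeration),
`split_early_late()` (early = strictly before the boundary stage, late =
strictly after; boundary-stage samples sit on neither side and are returned
separately, matching the "samples either side of this time point" design),
`steroidogenesis_candidates()` (adrenal-up log2FC ≥ 2 ∩ late-testis-up
log2FC ≥ 1, sorted by adrenal fold change), `exclusive_set()`,
`chrY_screen()` (significant up-regulated genes restricted to chromosome Y;
annotation-driven, no biotype inference), `secreted_screen()` (pure
annotation filter on the signal-peptide flag; the manual literature review
step of the original workflow is out of scope) and
`categorize_candidates()` (uncategorised candidates labelled "Novel").
Pathway enrichment is deliberately not implemented — candidate lists are
exported as plain text for external tools.

## Numerical choices and edge cases

* Sigmoid exponents are clamped at ±700 before exponentiation.
* BIC uses an RSS floor of 1e-12, so perfect fits do not produce −∞ and
  the constant model wins exact ties.
* Quantile normalisation averages ties; `adjust_bh` is stable under ties.
* Zero-variance batches are shifted without rescaling.
* All RNG consumers (`build_design`, `simulate_atlas`, `balt_mcmc`) take
  explicit seeds and restore the caller's RNG state.

## Problem sizes

The test suite and worked examples run the pipeline at reduced scale
(40--80 background genes, 50-replicate recovery loops, shortened MCMC
chains), chosen so the full suite completes in a few minutes on a single
CPU while keeping every statistical check meaningfully powered. The
defaults (`n_flat = 274`, giving a 346-gene panel; 4 × 5000 MCMC) are the
intended analysis scale.

## Known limitations

* Two-group contrasts only: no covariates, no multi-factor designs, no
  limma-trend/robust variants.
* The model family is {constant, full sigmoid}; transient pulses are
  simulated (SRY-like truth) but not fitted — the pulse is handled
  descriptively, as in the original analysis.
* `T` is weakly identified for transitions that do not complete inside the
  window; interpret curvilinear `T` (and the doubled `L` tolerance in
  reference matching) accordingly.
* The `eb` batch mode is a deliberately reduced ComBat: no covariates, so
  strong confounding of batch with tissue composition would be partially
  absorbed as batch effect.
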