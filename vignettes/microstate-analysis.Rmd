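---
title: "Microstate analysis with microstatr: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate analysis with microstatr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstatr)
```

## The analysis in one paragraph

Resting-state EEG alternates between brief (~60-120 ms) epochs during
which the scalp potential topography stays quasi-stable - microstates.
The canonical analysis reduces a multichannel recording to the
topographies at the peaks of the global field power (GFP), clusters them
into a small number of template maps ignoring polarity, labels every
sample of the continuous recording by the best-correlated template
(competitive backfitting), cleans the label sequence with temporal
smoothing, and summarizes each class by three temporal parameters: mean
segment duration (ms), time coverage (%), and occurrence (segments per
second). Group comparisons of those parameters, and a random-effects
meta-analysis of standardized group differences across studies,
complete the chain. `microstatr` implements every stage, plus a
surrogate-data generator that plants known microstate dynamics so the
whole chain can be validated end to end.

## GFP and peak extraction

GFP at a time point is the population (1/N) standard deviation of the
potential across electrodes; for average-referenced data this is the
Euclidean norm of the sample divided by sqrt(N). It is invariant to a
common offset across electrodes and scales linearly with the data.
`gfp_peaks()` returns strict local maxima; a flat plateau flanked by
smaller values contributes its first index, and endpoints are never
peaks. These two conventions are fixed purely for determinism - peak
sets from real EEG are insensitive to either choice. No minimum
inter-peak distance is imposed.

`preprocess_recording()` provides the minimal conditioning the rest of
the chain expects: channel demeaning, a zero-phase linear-phase FIR
band-pass (default 1-40 Hz) applied by FFT convolution with group-delay
compensation, integer-factor decimation behind an anti-alias low-pass,
and common-average re-referencing (idempotent). Artifact handling (ICA,
bad-channel interpolation) is deliberately out of scope; the function is
a conditioning step, not a cleaning pipeline.

## Polarity-invariant modified k-means

Microstate topographies are treated as equivalent up to sign, so
ordinary k-means is unsuitable. `microstate_kmeans()`:

* assigns each map to the template maximizing the *squared* spatial
  correlation (Pearson correlation across electrodes of
  average-referenced maps), ties to the lowest class index;
* updates each template as the dominant spatial pattern of its assigned
  maps - the leading eigenvector of the cluster's cross-product matrix,
  which is polarity-invariant by construction - renormalized to unit
  GFP. The sign-aligned normalized mean is the familiar cheaper variant;
  the eigenvector form is used because it solves the squared-correlation
  update exactly;
* scores fits by global explained variance,
  GEV = sum_t (GFP_t c_t)^2 / sum_t GFP_t^2, with c_t the correlation
  between map t and its assigned template;
* keeps the best of `n_restarts` (default 20) random initializations,
  each seeded deterministically from the master seed, iterating to a
  relative GEV change below `tol` (default 1e-6) or `max_iter` (100).
  Empty clusters are re-seeded from the worst-represented map. The GEV
  is monitored and never allowed to decrease within a restart.

Input peak maps are normalized to unit GFP before clustering (so each
peak counts equally) while GEV always weights by the original GFP; the
normalization is configurable because conventions differ between
implementations.

The two-level scheme mirrors common group analyses: k templates per
subject, then a second clustering over the pooled per-subject templates
(unit GFP, so every participant contributes equally, with each subject's
templates ordered by their per-class GEV contribution - the subject's
"most dominant" maps). `align_templates()` matches template sets by the
permutation maximizing total |correlation| (exhaustive over
permutations, k <= 8) and re-signs maps to correlate positively with the
reference. `canonical_templates()` ships four *synthetic* stand-ins for
the canonical class configurations (two diagonal gradients, one
anterior-posterior, one fronto-central extreme, on an idealized circular
montage) used only to attach A-D labels; they are not measured grand
averages, and manual relabeling is always possible.

## Backfitting, smoothing, temporal parameters

`competitive_fit()` labels every sample with the class of highest
absolute spatial correlation; ties go to the lowest index, and
zero-variance samples (possible in synthetic or heavily processed data)
inherit their predecessor's label and are counted in a diagnostics
attribute.

`smooth_labels()` implements a windowed Besag-type penalty: each sample
is relabeled to maximize `corr^2(t, class) + lambda * N_b(t, class)`
where `N_b` counts same-class labels among the 2b neighbours (b =
`window_half_size`, truncated at the edges) under the current labeling.
Sweeps are synchronous and deterministic; a two-cycle (possible with
synchronous updates) is detected and resolved by keeping the current
iterate. Defaults b = 5 and lambda = 10 at 128 Hz follow common
practice for this analysis family. The fit term is the plain squared
correlation rather than a GFP-weighted variant, matching the
correlation-based backfitting; with lambda = 10 the neighbourhood term
dominates, so smoothing behaves like an iterated local majority vote
that removes label noise during low-GFP periods. After convergence,
single-sample segments are (optionally, default on) merged into the
neighbouring segment whose template correlates better at that sample,
one segment at a time - each merge strictly reduces the run count, so
termination is guaranteed.

`microstate_parameters()` treats maximal constant-label runs as
segments, *including* truncated first and last runs. The three
parameters satisfy, exactly and by construction,
`occurrence x mean_duration / 1000 = coverage / 100` per class, and the
coverages sum to 100%. Classes absent from a sequence score 0 on all
three.

## The surrogate generator

`simulate_microstate_eeg()` plants a semi-Markov label sequence: classes
switch by a transition matrix with zero diagonal (default uniform
off-diagonal - no published transition probabilities exist to emulate),
and each visit lasts `1 + Geometric(1/m)` samples, mean m from the
class's requested mean duration. The truncated geometric is the
simplest law with a controllable mean and a one-sample floor; it is a
modelling convenience, not a claim about cortical dynamics. The signal
is the active class's template scaled by an amplitude profile -
sinusoidal by default (1 + 0.3 sin, period ~100 ms) so that GFP peaks
exist; a constant profile has none and is available for tests. Spatially
white Gaussian noise, projected onto the average-reference subspace, is
scaled so that the ratio of time-averaged signal GFP to noise GFP equals
the requested SNR; a GFP-based SNR is the natural choice in a pipeline
whose every stage is GFP-based. Default conditions mirror the study
design this package grew out of: 64 electrodes, 128 Hz, 5-minute
recordings, mean durations in the 60-120 ms range.

What the surrogate does *not* emulate: biophysical forward models,
spatially correlated or 1/f-shaped noise, artifacts, non-stationarity.
Passing parameter recovery on this surrogate therefore demonstrates
correctness of the estimation chain, not robustness to everything real
EEG contains.

### The parameter-recovery experiment

The headline validation (also run by `scripts/acceptance.R`) simulates a
10-subject cohort at SNR 4 with planted durations 70/80/90/100 ms, runs
GFP-peak extraction, two-level clustering, alignment and backfitting,
and compares recovered per-class mean durations against the planted
values. The backfit there runs with smoothing *off*: the planted
truncated-geometric law itself produces one-sample segments, so the
default smoothing (lambda = 10, single-frame rejection) would alter the
ground-truth process by design, and the experiment is meant to measure
estimator fidelity, not smoothing bias. Smoothing behaviour is validated
separately (identity at lambda = 0, merge-rule examples, monotone
segment-count effect).

## Group statistics

* `chi_square_2x2()` is Pearson's test *without* continuity correction
  (the convention under which published demographic statistics
  reproduce exactly); Yates is available behind a flag.
* `mixed_design_anova()` is a split-plot general linear model with
  Type III (drop-one-term) sums of squares under sum-to-zero coding,
  computed in two strata: between-subject terms (crossed factors plus
  additive covariates) on subject means against the
  subject-within-group error, and within-subject terms (the within
  factor and its interactions with between factors and covariates)
  against the subject x within residual, with the subject factor
  absorbing all between-subject variance. The within-stratum design
  matrix is assembled explicitly from contrast-column products so
  interaction terms keep their correct degrees of freedom. No
  sphericity correction is applied. Both classical eta^2 (effect SS
  over the stratum's total corrected SS) and partial eta^2 are
  reported, with a 90% CI from inverting the noncentral-F distribution
  at the observed F - the one-sided convention standard for effect
  sizes.
* `holm_adjust()` implements step-down Holm with an explicit running
  maximum, a cap at 1, and support for a family size m larger than the
  number of supplied p-values.
* `eta2_to_d()` uses d = 2 sqrt(eta2/(1-eta2)); `bayes_factor_bic()`
  uses the BIC approximation BF01 = exp((BIC_alt - BIC_null)/2), which
  stands in for full default-prior Bayes-factor ANOVA integration
  (deliberately out of scope).

## Meta-analysis

`hedges_g()` applies the small-sample correction J = 1 - 3/(4 df - 1).
`reml_tau2()` maximizes the restricted likelihood of
g_i ~ N(mu, v_i + tau^2) by Fisher scoring with the analytic score and
expected information, refined by bisection on the score function to a
tolerance of 1e-10 and floored at zero; the test suite checks it
against both a dense grid search and an independent implementation.
`pool_random_effects()` uses inverse-variance weights with normal-
quantile CIs and z-tests - no Knapp-Hartung adjustment, matching the
classical random-effects convention. Positive g means patients exceed
controls. `run_meta()` applies these per parameter x class cell with a
joint Holm correction (default family 12 = 3 parameters x 4 classes)
and reports expected-but-missing cells instead of skipping them.

## Numerical conventions worth knowing

* Ties in assignment and backfitting always resolve to the lowest class
  index; single-frame merges prefer the earlier neighbour on ties.
* Sub-seeds are derived from the master seed by a fixed affine counter
  scheme (`seed * 1009 + counter`, reduced into integer range), so any
  stage can be re-run in isolation.
* Zero-variance maps are rejected by `spatial_correlation()` but
  tolerated (with diagnostics) by the backfitter.
* Problem sizes in the shipped validation experiments (10 subjects x
  5 minutes for recovery, 1000 replicates for the ANOVA null
  calibration, 9 studies for meta recovery) were chosen to mirror the
  scale of the study design while keeping a full validation run in the
  order of a minute on a laptop.

## Known limitations

* Only one within-subject factor is supported by the ANOVA layer; the
  microstate analyses need exactly one (class).
* EDF/BDF ingestion is not provided; the exchange format is a delimited
  matrix with a JSON sidecar, which round-trips bit-faithfully and is
  trivial to produce from any EEG toolbox.
* The clustering family is fixed to polarity-invariant k-means with
  k = 4 by default (comparability across studies); AAHC, PCA or HMM
  segmentations are out of scope.
* The smoothing penalty follows one defensible reading of the windowed
  Besag scheme; implementations differ in bookkeeping details, so
  smoothed parameter values should be compared across packages with
  that in mind.
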