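# microstatr

EEG microstate analysis in R: segmentation of resting-state EEG into a
small set of quasi-stable scalp topographies, their temporal dynamics,
and the statistical machinery used to compare those dynamics between
groups and across studies.

Resting EEG does not drift continuously between configurations: the
scalp potential field stays quasi-stable for ~60–120 ms and then
switches abruptly. These epochs — *microstates*, conventionally four
classes labelled A–D — are summarized per class by three temporal
parameters: **mean duration** (ms), **time coverage** (%), and
**occurrence** (segments/s). Altered microstate dynamics (notably
increased presence of class C and decreased class D) are among the
candidate electrophysiological endophenotypes of schizophrenia, which
is the kind of study design this package serves: clinical groups,
covariate-adjusted repeated-measures comparisons, and meta-analytic
pooling.

## What the package implements

* **GFP machinery** — global field power (per-sample population SD
  across electrodes), strict-maximum peak extraction, zero-phase FIR
  band-pass / decimation / average re-referencing
  (`global_field_power`, `gfp_peaks`, `preprocess_recording`).
* **Polarity-invariant modified k-means** on GFP-peak topographies:
  assignment by maximal squared spatial correlation, template update by
  the leading eigenvector of the cluster cross-product, best of
  `n_restarts` by global explained variance
  GEV = Σ(GFP·corr)² / ΣGFP²; two-level (individual → group)
  aggregation and optimal template alignment/labelling
  (`microstate_kmeans`, `two_level_clustering`, `align_templates`).
* **Backfitting** — per-sample labelling by maximal |spatial
  correlation|, windowed Besag-penalty temporal smoothing
  (fit + λ·N_b, defaults b = 5, λ = 10) with single-frame rejection,
  and the temporal parameters with their exact identity
  occurrence × duration/1000 = coverage/100
  (`competitive_fit`, `smooth_labels`, `microstate_parameters`).
* **Group statistics** — Pearson chi-square (no continuity correction),
  pooled t from summaries, Cohen's d (independent and one-sample),
  Bonferroni–Holm step-down, split-plot ANOVA with covariates and
  Type III sums of squares (η² with 90% noncentral-F CIs),
  η² → d conversion, BIC Bayes factors, Pearson correlations
  (`mixed_design_anova`, `holm_adjust`, ...).
* **Random-effects meta-analysis** — Hedges' g with the small-sample
  J correction, REML estimation of the between-study variance τ²
  (Fisher scoring + bisection), inverse-variance pooling with z-tests,
  and a per parameter × class driver with joint Holm correction
  (`hedges_g`, `reml_tau2`, `pool_random_effects`, `run_meta`).
* **Surrogate EEG generator** — semi-Markov class switching with
  truncated-geometric segment lengths, GFP-modulated template signal,
  average-referenced Gaussian noise at a GFP-defined SNR, with full
  ground truth (`make_templates`, `simulate_microstate_eeg`), plus the
  published demographic tables and p-value lists used by the
  statistics layer (`demographics_fixtures`).
* **Pipeline orchestration** — `run_pipeline(pipeline_config(...))`
  runs simulate → cluster → backfit → parameters deterministically
  under one master seed and writes every intermediate as delimited text
  with a content-hash manifest.

## Worked example

Simulate a 5-minute, 64-channel recording with four planted template
maps and mean durations 70/80/90/100 ms at SNR 4, then recover the
templates and dynamics:

```r
library(microstatr)

tpl  <- make_templates(64, 4, min_separation = 0.5, seed = 7)
spec <- simulation_spec(tpl, sampling_rate = 128, duration = 300,
                        mean_durations = c(70, 80, 90, 100),
                        snr = 4, seed = 7)
sim  <- simulate_microstate_eeg(spec)
sim$recording
#> <eeg_recording> 64 channels x 38400 samples @ 128 Hz (300.0 s), average reference

peaks <- gfp_peaks(global_field_power(sim$recording))
length(peaks)
#> [1] 3770

fit <- microstate_kmeans(sim$recording$data[, peaks], k = 4, seed = 7)
fit
#> <microstate_kmeans> k=4 on 3770 maps, GEV = 0.9614

al <- align_templates(fit$templates, tpl)
round(al$correlation, 4)     # recovered vs planted maps
#> [1] 1 1 1 1

seg <- backfit(al$aligned, sim$recording, smooth = FALSE)
microstate_parameters(seg)
#> Microstate temporal parameters (total 300.00 s):
#>  class mean_duration coverage occurrence n_segments
#>      1         71.70    20.48      2.857        857
#>      2         77.76    23.66      3.043        913
#>      3         88.84    25.71      2.893        868
#>      4         99.94    30.15      3.017        905
```

The fitted templates match the planted ones to |correlation| 1 (to four
decimals), GEV says 96% of the GFP-weighted topographic variance at the
peaks is explained, and the recovered mean durations sit within a
couple of milliseconds of the planted 70/80/90/100 ms — the residual
gap is the sampling variability of one 5-minute realization, not
estimator bias.

Pooling standardized group differences across studies:

```r
df <- data.frame(study_id = paste0("s", 1:5), n1 = 25, n2 = 25,
                 d = c(0.35, 0.61, 0.48, 0.72, 0.55))
meta_random_effects(df)
#> Random-effects pooled estimate (k = 5 studies)
#>   g* = 0.532, 95% CI [0.283, 0.780], z = 4.190, p = 2.79e-05, tau2 = 0.0000
```

## Documentation

The methods vignette (`vignettes/microstate-analysis.Rmd`) describes
the models, the tunable parameters and their defaults, what the
surrogate generator does and does not emulate, and the numerical
conventions (tie-breaking, seeding, degenerate inputs).
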