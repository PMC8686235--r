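---
title: "Localizing the motor hotspot from EEG band-power topographies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing the motor hotspot from EEG band-power topographies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(hotspotr)
```

## The problem

Transcranial electrical stimulation of the motor cortex needs a target: the
*motor hotspot*, the scalp position whose stimulation most reliably drives a
hand muscle. The reference procedure finds it with TMS — a site is accepted
when more than 5 of 10 single pulses evoke a motor potential above 50 µV in
the first dorsal interosseous ([`mep_accepts_hotspot()`]) — but TMS hardware
is expensive and not portable. hotspotr implements an EEG-only alternative:
movement-related spectral power is focally organized around the motor
cortex, so the *topography* of band power across a 63-channel montage
carries information about where, in 3D scalp coordinates, a subject's
hotspot sits. A shallow neural network regresses those coordinates from
per-trial power spectral density (PSD) features, and an evaluation layer
quantifies the localization error against the TMS-defined ground truth.

All coordinates live in a Cz-origin frame (x toward the right preauricular
point, y toward the nasion, z dorsal, centimeters). Accuracy is summarized
as the Euclidean error distance between predicted and true hotspot.

## Pipeline

1. **Preprocessing** (`preprocess_recording()`), in fixed order: decimation
   1000 → 200 Hz behind a zero-phase anti-alias low-pass (cutoff
   0.4·200 Hz); common average reference (CAR); zero-phase 3rd-order
   Butterworth band-pass 0.5–50.5 Hz (forward–backward, so 6th-order
   magnitude and no phase shift); optional ICA artifact removal; epoching
   into press-locked trials.
2. **Features** (`psd_epochs()`, `build_feature_table()`): each 1-s epoch
   (half-open window \[−0.5, 0.5) s, exactly 200 samples) gets a
   rectangular-window FFT power spectrum with 1 Hz bins; band features are
   the arithmetic mean of the bins in delta 1–4, theta 4–8, alpha 8–13,
   beta 13–30, gamma 30–50, or full 1–50 Hz. Band edges are half-open, so
   4 Hz belongs to theta, not delta, and the five narrow bands tile 1–49 Hz
   exactly.
3. **Regression** (`fit_mlp()`, `cross_validate()`): a 63–40–3 multilayer
   perceptron (tanh hidden units, linear output, squared-error loss) maps
   features to coordinates. Cross-validation is tenfold with the 9:1 ratio
   enforced *within every subject*: each subject's 30 trials are permuted
   and dealt round-robin, so every fold tests exactly 3 trials of every
   subject. This deliberately mixes each subject's trials across training
   and test — the design treats the cohort as a fixed set of identities
   whose hotspots must be recalled from trial-level features, not as a
   transfer problem to unseen subjects.
4. **Evaluation** (`run_band_study()`, `run_channel_ablation()`,
   `run_erp_study()`): per-trial errors are averaged within subject;
   condition effects are tested with one-way repeated-measures ANOVA
   (Greenhouse–Geisser-corrected p reported and used when ε < 0.75) and
   Bonferroni-corrected pairwise paired t-tests; hands are compared with
   paired t-tests over the subjects that have both hands.

## Why these epoching and PSD choices

A 1-s epoch at 200 Hz has exactly N = 200 samples, so the FFT bin spacing is
exactly 1 Hz and band edges fall on bins — the half-open \[−0.5, 0.5)
convention exists to make N = fs hold exactly. No taper is applied: with
band *averages* over ≥ 3 bins as features, rectangular-window leakage is a
second-order effect, and the single-FFT estimate keeps the resolution
contract literal. `psd_epoch()`'s normalization makes a unit sinusoid on an
integer bin carry power 0.5 and makes the one-sided sum equal the mean
square of the series (Parseval), which the tests verify against a
brute-force O(N²) DFT.

## The synthetic cohort generator

No public recordings accompany this problem, so `simulate_subject()` /
`simulate_cohort()` generate cohorts with the statistical structure the
pipeline assumes, plus a known latent hotspot per subject and hand:

* **Paradigm**: cue onsets jittered uniformly 1.5–3.5 s apart; presses
  follow cues by N(690, 25²) ms; 30 press markers per hand.
* **Background**: 1/f noise, 5 µV RMS per channel, independent across
  channels (no volume-conduction correlation — see limitations).
* **Movement-related potential**: a 400 ms Hann-shaped negativity peaking
  at −320 ms before the press. Its scalp pattern is a broad (6 cm FWHM)
  Gaussian pair — contralateral peak −2.24 µV, ipsilateral −1.11 µV as
  hemisphere-group means — solved to be *zero-mean across channels* so the
  CAR leaves it untouched, and its temporal kernel is pre-filtered to the
  0.5–50.5 Hz analysis band and rescaled so that the baseline-corrected,
  twice-filtered peak equals the nominal amplitude. Injected amplitude and
  latency are therefore defined in the units the evaluator measures; the
  recovery tests close this loop.
* **Band oscillations**: per configured band, band-limited unit-variance
  noise gated by a per-trial envelope (flat ±0.5 s around the press, 0.2 s
  cosine ramps) and weighted spatially by a focal Gaussian (2 cm FWHM) at
  the hotspot. This is the forward model under which "PSD topography
  encodes location" holds by construction. The default is a gamma-band
  modulation of 32 µV RMS at the topography peak.
* **Artifacts**: optional blink transients (80 µV, 0.3 s, frontal-weighted)
  for exercising the ICA stage; off by default.
* **Cohorts**: per-subject hotspots are the C3 (right hand) or mirrored C4
  (left hand) position plus isotropic N(0, 1 cm²) jitter; all randomness
  derives from one cohort seed, and identical seeds reproduce recordings
  byte-for-byte.

### Operating point: two deliberately generous amplitudes

Two generator defaults are intentionally stronger than typical physiology,
and both were chosen once, against the package's own recovery requirements,
then frozen:

* The 32 µV gamma modulation makes the *single-trial* power topography
  informative at the electrodes adjacent to the hotspot (first-ring
  signal-to-background ≈ 4), which is what lets a regression resolve the
  1 cm inter-subject hotspot jitter against a 2.8 cm electrode pitch. At
  realistic scalp-gamma amplitudes (≲ 1 µV) single trials carry essentially
  no location signal and every predictor collapses to the cohort centroid —
  the generator would then refute, rather than validate, the premise it
  exists to encode.
* The 5 µV background RMS (clean, post-ICA laboratory EEG) keeps the
  20-subject grand-average potential's residual noise near 0.1 µV so that
  peak amplitude and latency are recoverable to ±10% / ±10 ms.

Passing tests on this cohort therefore show that the pipeline's information
flow — preprocessing preserves the encoding, features expose it, the
network exploits it, the statistics detect its band structure — is correct.
They do not show that real-world error distances at realistic SNR would be
small; the original study's reported numbers are not reproducible without
its (undeposited) recordings.

## Model-stage choices

The network sees each trial's features as *relative power*: the 63 band
powers divided by their within-trial mean. Per-trial overall power
fluctuates by ~20% (finite-bandwidth chi-square statistics of a 1-s
estimate), and this common factor is nuisance; dividing it out leaves the
topography, in whose geometry nearby trials mean nearby hotspots.
Per-column z-scoring — the more conventional default — is available
(`mlp_spec(input = "raw")`) but is counterproductive here: it rescales the
~58 channels that carry only noise up to the same variance as the ~5
informative ones, destroying that proximity structure (a k-NN probe
degrades from ≈ 0.6 cm to ≈ 1.5 cm on the default cohort).

Training is full-batch Adam (step 0.05) with L2 weight decay 10⁻³ on the
connection weights, early stopping on a 15% subject-stratified validation
split with patience 50 epochs (max 1000) and best-weight restore, and a
3-network random-initialization ensemble whose predictions are averaged.
The decay and ensemble exist because a 2560-parameter network fits ~600
trials to machine-precision training loss long before it generalizes;
patience 50 (rather than a handful of epochs) is needed because the
validation trace under full-batch Adam is noisy on the epoch scale. The
output bias is initialized at the training-target mean, so the network
starts as the mean predictor and early stopping can only improve on it.
All of this is seeded; fold k of a cross-validation uses seed + k.

Targets are regressed in centimeters in the Cz frame without scaling. The
reference level for judging errors is `mean_predictor_baseline()`: the mean
distance of the cohort's true hotspots to their centroid (≈ 1.6·jitter_sd
for isotropic 3D jitter), i.e. the error of a predictor that has learned
nothing subject-specific.

## Statistics

`rm_anova()` computes the one-way repeated-measures F through the standard
within-subject decomposition (`aov` with an `Error(subject/condition)`
stratum); the test suite checks it against a textbook sums-of-squares
oracle to 10⁻⁸. Greenhouse–Geisser ε comes from the double-centered
covariance of the subject × condition matrix; both raw and corrected p are
reported. Pairwise comparisons are paired t-tests with Bonferroni
multiplication capped at 1, and the ordering statement (e.g.
`delta = theta = alpha > beta = gamma = full`) groups conditions, sorted by
mean, that are mutually non-significant at the corrected level — a
readable summary, not an inference procedure in itself. Degenerate paired
tests are explicit: zero differences give t = 0, p = 1; constant non-zero
differences are flagged rather than silently returning infinity.

## ICA artifact removal

The original workflow rejected components by visual inspection, which is
not reproducible; `remove_artifacts(method = "ica_auto")` substitutes two
automatic criteria on a symmetric FastICA decomposition (tanh contrast,
eigenvalue whitening that drops the rank lost to CAR): a component is
removed if its topography peaks on a prefrontal channel and > 50% of its
power lies below 4 Hz (ocular), or if its excess-kurtosis z-score across
components exceeds 3 (transients). Thresholds are arguments;
`method = "none"` bypasses the stage. ICA runs on the continuous filtered
record, not on epochs, so decomposition artifacts cannot leak across epoch
boundaries. The study runners default to `artifacts = "none"` because the
default cohorts inject no ocular activity; the blink-injection tests
exercise the stage explicitly (frontal delta power must drop ≥ 70% while
central gamma moves < 10%).

## Numerical and degenerate-input policies

* Filters are applied to the continuous recording so edge transients stay
  outside analysis windows; tests assert passband gain within 2% and
  cross-correlation peak at lag 0 on interior samples.
* Epochs whose window would cross the record edge are dropped and reported,
  never zero-padded.
* `detect_erp_peak()` is a raw argmin over the search window — a
  single-sample spike is located exactly — with onset defined as the start
  of the sustained excursion below 2 baseline SDs. `run_erp_study()`
  quantifies peaks on a 12 Hz zero-phase low-passed copy of the grand
  average (the returned waveform is unfiltered), appropriate for a < 8 Hz
  deflection.
* Standardization guards zero-variance columns; relative-power transforms
  guard all-zero trials; RM-ANOVA on identical columns reports F = 0 rather
  than 0/0.
* `to_cz_frame()` refuses collinear fiducials; montage loaders refuse
  duplicate labels and missing Cz.

## Problem sizes used by the tests and the acceptance script

Simulating one subject-hand (≈ 80 s of 63-channel signal at 1 kHz) plus
preprocessing takes a few seconds, so the shipped studies use compact but
statistically adequate cohorts: 10 subjects × 2 hands for the
gamma-recovery study, 12 subjects (right hand) for the six-band comparison
— the band effect sizes are several times the between-subject SD, so
Bonferroni-corrected significance is comfortably reached at n = 12 — 12
subjects for the five-set ablation, 10–20 subjects for potential recovery.
The vignette and README examples are smaller still. Channel-set
memberships beyond the fixed 63/17/9 counts, the four-channel hemisphere
groups ({FC3, C3, C1, CP3} and mirror), and all thresholds above are
config-level defaults, not claims about the original study.

## Known limitations

* Channel noise is spatially white; real EEG has strong volume-conduction
  correlations, reference effects, and non-stationarities the generator
  does not emulate.
* The forward model is a Gaussian weight on a spherical montage, not a
  biophysical head model; depth information reaches the features only
  through the spread of the topography, and the anterior–posterior axis
  dominates the residual error on default cohorts.
* The cross-validation scheme shares subjects between training and test by
  design; nothing here measures generalization to unseen subjects.
* Hotspot coordinates are on-scalp points in an idealized spherical frame;
  no MRI-based anatomy is involved.

## A worked micro-example

```{r example, eval = FALSE}
cohort <- simulate_cohort(cohort_spec(n_subjects = 4, hands = "right"), seed = 1)
report <- run_band_study(cohort, bands = c("delta", "gamma"), seed = 1)
tidy(report)       # per-band mean error, SD, SE across subjects
glance(report)     # RM-ANOVA per hand with the ordering statement
autoplot(report)   # bar chart with SE whiskers
```

On this cohort the gamma condition reaches a few-millimeter mean error
while delta stays near the centroid baseline, and the ANOVA orders
`delta > gamma` — the qualitative signature the full band study reproduces
with all six bands.
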