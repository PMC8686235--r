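# hotspotr

Locating the primary-motor-cortex "hotspot" — the scalp position whose
stimulation most reliably drives a hand muscle — normally requires
transcranial magnetic stimulation (TMS): a site counts as the hotspot when
more than 5 of 10 single pulses evoke a motor potential above 50 µV.
hotspotr implements an EEG-only alternative and everything needed to
validate it: movement-related spectral power is focally organized around
the motor cortex, so the topography of band power across a 63-channel
montage encodes where, in 3D Cz-origin coordinates (cm), the hotspot sits.

The package is for neural-engineering researchers who want a tested,
end-to-end reference pipeline:

* **Preprocessing** — decimation 1000 → 200 Hz behind a zero-phase
  anti-alias filter, common average reference, zero-phase 3rd-order
  Butterworth band-pass 0.5–50.5 Hz, automatic ICA artifact removal,
  press-locked epoching into 1-s trials.
* **Features** — per-trial rectangular-window FFT power spectra at exactly
  1 Hz resolution, averaged into delta (1–4), theta (4–8), alpha (8–13),
  beta (13–30), gamma (30–50) and full (1–50 Hz) band features per channel.
* **Model** — a 63–40–3 multilayer perceptron (tanh hidden layer, linear
  output) regressing the three hotspot coordinates

  $$\hat{\mathbf{h}} = W_2 \tanh(W_1 \mathbf{x} + b_1) + b_2,\qquad
    \text{error} = \lVert\hat{\mathbf{h}} - \mathbf{h}_{\text{TMS}}\rVert_2,$$

  trained with early stopping and evaluated by tenfold cross-validation
  with a 9:1 train:test split enforced within every subject (3 of each
  subject's 30 trials per test fold).
* **Evaluation** — Euclidean error distances aggregated trial → subject →
  condition, repeated-measures ANOVA with Greenhouse–Geisser correction and
  Bonferroni post-hocs across bands or channel sets, paired t-tests between
  hands, and movement-related potential characterization (baseline
  −1…−0.5 s, peak amplitude/latency detection).
* **Synthetic cohorts** — a fully seeded generator
  (`simulate_cohort()`) producing press-task recordings whose band-power
  topographies provably encode a latent per-subject hotspot, with 1/f
  background, a contralateral-dominant movement potential
  (−2.24 µV @ −320 ms by default), optional blinks, and TSV/BrainVision
  export. It stands in for the unavailable original recordings and gives
  every test a known ground truth.

Montage utilities (extended 10-20 positions on an idealized spherical
head, the Cz-origin frame transform, five nested channel sets
Ch_Set1 ⊃ … ⊃ Ch_Set5 with 63 … 9 channels) round out the toolkit.

## Worked example

Simulate a small cohort with gamma-encoded hotspots, run the band
comparison, and look at the result:

```r
library(hotspotr)

cohort <- simulate_cohort(cohort_spec(n_subjects = 4, hands = "right"), seed = 1)
report <- run_band_study(cohort, bands = c("delta", "gamma"), seed = 1)
tidy(report)
#> # A tibble: 2 × 7
#>   hand  band  channel_set n_subjects mean_error_cm   sd_cm   se_cm
#>   <chr> <chr> <chr>            <int>         <dbl>   <dbl>   <dbl>
#> 1 right delta Ch_Set1              4        1.18   0.306   0.153
#> 2 right gamma Ch_Set1              4        0.0820 0.00930 0.00465
glance(report)$ordering
#> [1] "delta > gamma"
```

Delta-band power carries no location information in this cohort, so its
cross-validated error (≈1.2 cm) sits at the level of always answering the
cohort centroid, while the gamma topography localizes the hotspot to a
millimeter; the repeated-measures ANOVA orders the bands accordingly.
`autoplot(report)` draws the error bars, `run_channel_ablation()` repeats
the analysis over shrinking channel sets, and `run_erp_study()` recovers
the injected movement-related potential:

```r
run_erp_study(cohort)$right$peaks
#> # A tibble: 2 × 5
#>   group         amplitude_uv latency_ms onset_ms flat
#>   <chr>                <dbl>      <dbl>    <dbl> <lgl>
#> 1 contralateral       -2.20        -335     -440 FALSE
#> 2 ipsilateral         -0.998       -390     -460 FALSE
```

(The injected potential peaks at −2.24 µV, −320 ms; a four-subject grand
average recovers it to within a few percent and samples, and the 20-subject
cohorts in the test suite tighten this to the ±10% / ±10 ms checks.)

## Command line

A thin CLI over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec", "hotspotr", package = "hotspotr"))')" \
  band-study --seed 1 --out run1
```

Subcommands `simulate`, `band-study`, `ablation` and `erp` accept a YAML
config (see `default_run_config()`); flags override config keys. Each run
writes TSV tables, a JSON statistics summary, and a provenance record
(config hash, seeds, package version).
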