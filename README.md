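# motorpheno

Motor phenotyping and cell-type attrition analysis for longitudinal mouse
models of Parkinson's disease.

Parkinsonian mouse models (e.g. MitoPark, with progressive dopaminergic
neuron degeneration) develop bradykinesia, akinesia and — rarely quantified
in genetic models — tremor. This package implements the analysis chain that
turns raw recordings into those phenotypes, plus the statistics that link
them to cell-type loss:

* **Tremor quantification** from body-mounted tri-axial accelerometry
  (200 Hz): zero-phase 5th-order 1 Hz Butterworth gravity separation, body
  acceleration \(a_{body} = a_{raw} - a_{grav}\), short-time Fourier
  spectrogram of the dorso-ventral axis (256-sample segments, 50% overlap),
  per-window 0–1 normalization, and the band-power summary
  \(\mathrm{BP} = \mathrm{median}_w\big(\mathrm{mean}_{k: 12 \le f_k \le 18}\ \tilde P_{k,w}\big)\),
  optionally gated to immobile epochs; cohort age trends via Pearson r and
  OLS.
* **Locomotion kinematics** from pose tracking (30 Hz, DeepLabCut-style
  CSVs): likelihood filtering (< 0.95 excluded), centroid speed, immobility
  bouts (speed < 0.5 cm/s strictly longer than 0.5 s), immobility time,
  mobility-only mean speed, stop counts, stop/move duration densities, and
  rearing detection in the cylinder test (height above threshold for at
  least 0.5 s).
* **Differential cell-type abundance** for snRNA-seq cohorts: per-cluster
  mixed-effects logistic membership models
  \(\mathrm{logit}\,P(\text{cell} \in k) = \beta_0 + \beta_{cond}\,x_{cond} + \beta_{sex}\,x_{sex} + u_{mouse}\),
  likelihood-ratio p-values, natural-log odds ratios with Wald CIs, and
  Benjamini–Hochberg FDR across clusters; plus proportion-level two-way
  ANOVA (genotype × age interaction) with Tukey HSD.
* **Group statistics and tracing tables**: exact/tie-corrected two-sided
  Mann–Whitney U, and monosynaptic input / neurite output fraction tables
  with the pooled-count (> 200) and mean-fraction (> 0.2%) region filters.
* **Synthetic-data generators** for all four input families with known
  ground truth (injected tremor amplitude schedules, semi-Markov
  mobility bouts, planted rearing events, multinomial-logit cell cohorts
  with genotype/sex effects and per-mouse random intercepts), so every
  stage is testable without any animal data.

## Worked example

Simulate one late-stage tremor cohort and quantify it:

```r
library(motorpheno)

band_power_of <- function(amp, seed) {
  p <- tremor_sim_params(duration = 30, noise_sd = 1, seed = seed,
                         tremor_amp = list(age_weeks = 24, amp = amp))
  tremor_band_power(simulate_accel(p, age_weeks = 24)$recording)$band_power
}
null_g <- sapply(1:12, \(s) band_power_of(0, s))        # no tremor
trem_g <- sapply(1:12, \(s) band_power_of(1, s + 100))  # amplitude/noise = 1
round(c(null = mean(null_g), tremor = mean(trem_g)), 3)
#>   null tremor
#>  0.043  0.150
mannwhitney(trem_g, null_g)
#> # A tibble: 1 × 6
#>   statistic p_two_sided    n1    n2 direction method
#>       <dbl>       <dbl> <int> <int>     <dbl> <chr>
#> 1       144   0.0000366    12    12         1 normal_tie_corrected
```

The normalized 12–18 Hz band power of tremor animals (~0.15) cleanly
exceeds the no-tremor floor (~0.04); U = 144 is complete separation of the
two groups of 12, rejected at p ≈ 3.7e-5. An age trend over the default
amplitude schedule (0 / 0.5 / 1.0 at 8 / 16 / 24 weeks):

```r
ages <- rep(c(8, 16, 24), each = 4)
bp <- sapply(seq_along(ages), \(i) {
  p <- tremor_sim_params(duration = 30, noise_sd = 1, seed = 7000 + i)
  tremor_band_power(simulate_accel(p, ages[i])$recording)$band_power
})
tremor_trend(tibble::tibble(age_weeks = ages, band_power = bp))
#> <trend_fit> n = 12: r = 0.930 (p = 1.21e-05), y = 0.0068x + -0.00165, R^2 = 0.864
```

r and slope are on the same scale as the study-style fits (band power
rising by ~0.007 per week). Kinematics and
abundance follow the same pattern — `simulate_pose()` →
`filter_pose()` → `compute_speed()` → `segment_bouts()` →
`locomotion_metrics()`, and `simulate_cell_composition()` →
`differential_abundance()`, whose `log_or` column recovers injected
depletions (e.g. −1.5 log-odds on one cluster) with covering CIs.

A command-line front end (`inst/cli/motorpheno`) exposes `simulate`,
`tremor`, `kinematics`, `abundance` and `report` subcommands; every run
writes a JSON manifest from which it can be reproduced byte for byte
(`--manifest run/manifest.json`).

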