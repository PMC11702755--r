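---
title: "Methods: tremor quantification, locomotion metrics and differential cell-type abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tremor quantification, locomotion metrics and differential cell-type abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorpheno)
```

motorpheno implements the quantitative core of a longitudinal motor-phenotyping
study of parkinsonian mouse models: accelerometer-based tremor quantification,
pose-tracking locomotion metrics, and per-cluster differential cell-type
abundance for single-nucleus cohorts. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## Tremor quantification from body-mounted accelerometry

A body-mounted tri-axial sensor sampled at 200 Hz records gravity, voluntary
movement and - in parkinsonian animals - a pathological oscillation in the
12-18 Hz band of the dorso-ventral axis. The pipeline is:

1. **Gravity separation.** Each axis is low-pass filtered with a 5th-order
   1 Hz Butterworth filter; the filtered series is the gravitational
   component, and its residual is the *body acceleration*. The filter is
   applied forward-backward (zero phase) so the gravity estimate is not
   delayed relative to the raw series before subtraction; the price is that
   the effective attenuation is the *squared* magnitude response, which is
   documented behaviour (at 15 Hz the residual gain is about 1.4e-12, i.e.
   leakage below 1e-4 in amplitude). Numerically the filter is built and run
   in second-order-sections form: at a normalized cutoff of 0.005 the
   expanded order-5 polynomial form is ill-conditioned enough to leave
   visible (~1e-7) errors even on constant input, whereas the biquad cascade
   passes DC to ~1e-13. Start-up transients are absorbed by symmetric-extension
   padding of ten filter time constants with per-section steady-state
   initialization (an odd reflection would shift the pad's mean by twice
   the boundary value, which a low-pass passes straight into the data).
   The first and last `max(2, 3/cutoff)` seconds are flagged as edge
   region: the boundary response to worst-case-phase band content stays
   above the filter's leak tolerance until about 2.7 s at the 1 Hz
   default, so a fixed 2 s flag would under-cover it.
2. **Spectrogram.** Consecutive Fourier transforms of the dorso-ventral body
   acceleration over 256-sample segments with 50% overlap, Tukey(0.25)
   taper and per-segment mean removal (the conventional defaults of the
   standard spectrogram routine; both are exposed parameters). The frequency
   grid is `f_k = k * 200 / 256 = k * 0.78125` Hz. Power is scaled so that a
   rectangular-window, no-overlap, no-detrend configuration satisfies
   Parseval's identity per segment; the scale is irrelevant downstream.
3. **Per-window normalization.** Each window column is mapped to the 0-1
   range, `(p - min) / (max - min)`. A constant column maps to all zeros:
   absence of spectral structure must not masquerade as full band power.
4. **Band power.** Band bins are all `f_k` inside [12, 18] Hz, inclusive at
   both edges on the analytic grid (k = 16..23). The per-window statistic is
   the *mean* normalized power over band bins; the animal-level summary is
   the *median* of per-window values. The study's description mixes
   "median" and "mean" wording across sections; mean-over-bins /
   median-over-windows is the adopted reading, and a median-over-all-cells
   variant is available via `spectral_params(band_stat = "median_cells")`.
5. **Immobility gating (optional).** Windows are 1.28 s long, longer than
   the 0.5 s minimum immobility bout, so requiring windows to lie entirely
   inside immobile intervals would discard valid tremor epochs. A window is
   retained when at least 75% of its span overlaps immobile intervals
   (`gate_overlap_min`, exposed). Gated and ungated summaries coincide when
   the gate covers the recording.
6. **Age trend.** Pearson correlation of per-animal band power against age
   (two-sided p from the t distribution on n-2 df) plus the ordinary
   least-squares line, reported as r, slope, intercept and R².

Whether the spectrogram input should be the raw or the gravity-subtracted
dorso-ventral axis is not fully pinned down by the study's description; the
processing order implies the body (gravity-subtracted) axis, which is the
default, and `spectral_params(use_raw_axis = TRUE)` retains the raw-axis
variant.

## Locomotion and rearing from pose tracking

Open-field video is tracked at 30 Hz; the spine2 bodypart serves as the
centroid. Estimates with likelihood below 0.95 are excluded outright - they
break runs and are never interpolated into metrics - and coordinates are
median-filtered (5 frames) over the remaining valid frames. Speed at frame t
is the backward-difference displacement from t-1 to t, scaled by frame rate
and the pixel calibration; the first frame and frames adjacent to exclusions
carry no speed. Analyses use the 5-20 minute window of a 30-minute session
(animals behave atypically right after placement).

Immobility is a maximal run of frames with speed below 0.5 cm/s lasting
**strictly more than** 0.5 s (15 frames at 30 Hz do not count; 16 do).
Rearing in the cylinder test is a maximal run of sensor height above a
setup-specific threshold sustained **at least** 0.5 s (inclusive). The
asymmetry mirrors the study's wording exactly. Rearing thresholds were a
manual, setup-specific step in the study; the package requires an explicit
numeric threshold and does not infer it. "Number of stops" counts immobile
bouts; a mobile-excluded-mobile sequence does not create a stop. Reported
metrics are immobility time (akinesia), mean speed during mobility only
(bradykinesia), stop count, and total distance. Stop/move duration densities
are Gaussian KDEs with Silverman's rule-of-thumb bandwidth, renormalized to
integrate to 1 on their grid; a single interval (or zero spread) degrades to
a point-mass/histogram fallback with a warning.

Bout intervals use the convention that a frame's speed covers the
inter-frame interval ending at its timestamp, so a run of frames at times
`t1..t2` yields `[t1 - 1/30, t2)`; intervals tile the analysis window.

## Differential cell-type abundance

For each cluster (cell type), membership of every cell is modelled as a
mixed-effects logistic regression: condition (genotype contrast, or age
contrast within genotype) and sex as fixed effects, a per-mouse random
intercept, fitted on per-mouse aggregated binomial counts (identical
likelihood to the cell-level model, far faster). The condition p-value is a
likelihood-ratio test of the full against the condition-dropped model; the
effect is the condition coefficient - a **natural-log odds ratio** (the
study prints negative "OR" values such as -1.26, impossible for an odds
ratio; they are log odds ratios, and this package says `log_or` to remove
the ambiguity). Wald confidence intervals are reported at 95%.

Benjamini-Hochberg adjustment runs across the successfully fitted clusters.
The published significance rule "FDR-adjusted P<0.05 and absolute odds ratio
>0" is vacuous for any nonzero estimate; the default here requires the CI to
exclude zero in addition to `fdr_q < 0.05`, with the literal rule available
via `abundance_params(significance_rule = "nonzero_estimate")`. Degenerate
designs (e.g. one mouse per condition) and glmer failures fall back to plain
logistic regression - exactly the model with the random-intercept variance
constrained to zero - and are flagged in the `model` column; boundary
(singular) fits are legitimate zero-variance estimates, not failures.
A cluster entirely absent from one condition is a complete-separation case
and is reported qualitatively rather than as a divergent number.

One-vs-rest models are fitted independently per cluster. A consequence worth
knowing: depleting one cluster necessarily raises every other cluster's
share of the remaining cells, so strong depletions induce genuine (small)
positive log odds ratios in the other clusters. These compensatory effects
are a property of compositional data, not false positives of the method.

Proportion-level ANOVA complements the model: per cluster, a type-II two-way
ANOVA of per-mouse proportions on genotype x age reports the interaction
p-value, followed by Tukey HSD over the genotype-by-age cell means. With
noise-free input the residual variance is zero and the standard F statistic
is undefined; the implementation then decides directly from the interaction
sum of squares (0 if exactly null, significant otherwise).

## Group statistics and tracing fractions

Group comparisons use the two-sided Mann-Whitney U test: exact null
distribution when the combined n is at most 20 and tie-free, otherwise the
normal approximation with midranks, tie-corrected variance and continuity
correction; the method used is recorded in the output. Monosynaptic-input
tables report each region's fraction of all labeled cells per animal (and
per hemisphere when present); regions are kept when pooled count > 200 *and*
mean fraction > 0.2% - the study states both conditions without precedence,
so they are independent parameters applied as a conjunction, and the mean
is a group mean (a per-animal variant is exposed). Output (neurite) fraction
tables carry group means with SEM and no filter.

## Synthetic data: what it emulates, and what it does not

Every analysis stage can be exercised against generators with known truth:

* **Accelerometer** (`simulate_accel`): static gravity projection, AR(1)
  broadband noise (first-lag autocorrelation 0.9 - body micro-motion and
  sensor drift weight real acceleration spectra toward low frequencies,
  which is exactly what makes the per-window 0-1 normalization informative),
  Gaussian-windowed 2-8 Hz locomotion transients, and a sinusoidal tremor on
  the dorso-ventral axis whose amplitude follows an age schedule (default
  0 / 0.5 / 1.0 at 8 / 16 / 24 weeks, amplitude/noise = 1 at 24 weeks).
  The default tremor frequency 15.625 Hz sits exactly on spectrogram bin 20,
  keeping spectral oracles analytic while staying inside the 12-18 Hz band.
* **Trajectories** (`simulate_pose`): a two-state semi-Markov process with
  log-normal dwell times (chosen over exponential dwells so segmentation can
  be probed near the 0.5 s boundary), log-normal mobile speeds around
  8 cm/s, persistent random heading, specular reflection at the walls of a
  40 cm arena, and likelihood dropout below the 0.95 cutoff. Truth records
  the frame-quantized state intervals, so noise-free runs are recovered
  exactly up to one frame per boundary.
* **Rearing traces** (`simulate_height_trace`): baseline sensor height with
  plateaus during planted, non-overlapping events.
* **Cell cohorts** (`simulate_cell_composition`): the study's design - per
  age group, n mice per genotype split evenly by sex - with per-mouse
  cluster probabilities from a multinomial logit: baseline log-odds,
  genotype and sex effects on designated clusters, independent per-mouse
  logit-normal random intercepts, and negative-binomial cells per mouse
  (unequal nuclear capture). Because only the targeted cluster's logit is
  shifted, the injected genotype effect equals that cluster's one-vs-rest
  log odds ratio exactly - the estimand of the abundance model.

Not emulated: biomechanical gait structure, grooming or other ethogram
states, arena zone preferences, transcript counts (composition only), and
tracking errors other than likelihood dropout. Passing tests on this
synthetic ground truth therefore demonstrates correctness of the *analysis*
under the stated generative assumptions, not robustness to every artifact of
real video or sequencing data.

## Problem sizes and determinism

Simulated examples in the tests and the acceptance script use 30-120 s
recordings, cohorts of 12 animals per group, and composition cohorts of 16
mice with a few hundred cells each - smaller than the study's 30-minute
sessions and thousands of nuclei, chosen as comfortable example sizes while
leaving the per-window, per-frame and per-cluster logic identical. All
generators draw from an explicitly pinned RNG (Mersenne-Twister, inversion
normals), so a seed fully determines every dataset across platforms, and the
CLI records config + seed in a JSON manifest from which any run can be
reproduced byte for byte.

## Known limitations

* Gating uses a window-overlap fraction; the study does not state how
  windows were matched to immobile bouts, and other conventions (e.g. full
  containment) give systematically fewer windows.
* The accelerometer and camera streams are aligned by shared timestamps when
  present, else by assuming a simultaneous start; the mode is recorded in
  the manifest rather than guessed silently.
* Complete-separation clusters yield qualitative results only; a
  penalized-likelihood (Firth-type) estimate would give numbers but is out
  of scope.
* The Mann-Whitney exact path deliberately switches off in the presence of
  ties; midrank handling then matches the large-sample convention.
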