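---
title: "Modelling pre-ejection period stress reactivity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pre-ejection period stress reactivity: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepstress)
```

## Why the pre-ejection period matters

The pre-ejection period (PEP) is the delay between the onset of ventricular
depolarization (the ECG Q-wave) and the actual start of blood ejection from
the left ventricle. It is the sum of the electromechanical delay and the
isovolumetric contraction time, and it shortens when cardiac inotropy rises
— that is, with sympathetic activation. Every ECG-referenced
pulse-wave-velocity (PWV) application measures the pulse-arrival time

$$\mathrm{PAT} = \mathrm{PEP} + \mathrm{PTT},$$

but only the transit component PTT (arterial path length divided by PWV)
carries blood-pressure information. Whether the PEP can be neglected,
estimated, or must be measured is therefore the central design question for
cuff-less blood-pressure devices. This package implements the full analysis
chain for that question on a synthetic cohort that emulates a laboratory
protocol of rest, standardized mental stress (a Trier Social Stress Test,
TSST, with four interview and four mental-arithmetic questions) and
incremental recumbent ergometry in 71 young, healthy adults (34 male, 37
female).

## The generative model

### Subject level

Each subject carries latent parameters drawn once per cohort
(`cohort_config()` holds every default; all draws are Gaussian, truncated
to physiological bounds via the inverse-CDF method so a fixed number of
uniforms is consumed regardless of truncation):

* **Anthropometrics.** Sex-specific age, height and weight (height–weight
  correlation 0.5 within sex); the maximum heart rate is the age-predicted
  `220 − age`.
* **Resting PEP** (ms):
  `104.5 + 0.15·(weight − E[weight]) − 3.2·(female − p_female) + N(0, 6.8)`.
  The direct female offset plus the weight path yields an expected observed
  sex difference of −6.2 ms and weak positive weight/height dependences
  (R² ≈ 0.13 and ≈ 0.08 at the cohort level). The between-subject SD
  (≈ 8.8 ms observed) dwarfs the within-subject epoch noise (4.5 ms).
* **Resting heart rate**: mean 65 bpm, SD 8 bpm, with a latent correlation
  of −0.25 with resting PEP — enough to make the rest-stratum PEP~HR
  regression nearly, but not exactly, flat (R² ≈ 0.05).
* **Mental reactivity** `m`: fractional PEP reduction at the first TSST
  question, mean 0.15, SD 0.08 (large spread on purpose: interindividual
  differences under mental load exceed those at rest). The heart-rate
  response is driven by the same latent reactivity
  (`Δhr = 160·m + N(0, 8)` bpm), which is what gives the mental stratum its
  moderate PEP~HR coupling.
* **Physical response**: a slope-heterogeneity multiplier (mean 1,
  SD 0.22) and an aerobic capacity (W/kg at the heart-rate stop threshold,
  mean 2.2, SD 0.25, bounded to [1.6, 2.6] so the first ascent takes 5–7
  weight-adapted steps).
* **Q–R interval**: per-subject mean 32 ± 5 ms, per-beat jitter 2 ms,
  drawn independently of heart rate — so its per-subject SD stays below
  4 ms and it shows no load dependence, which justifies referencing the
  PEP to the Q-wave.

### Phase expectations

`simulate_phase_pep()` is the deterministic core:

* **Rest**: the subject's resting PEP.
* **Mental, question q**: `PEP = rest · (1 − m · h^{q−1})` with a geometric
  habituation rate `h = 0.97` per question.
* **Physical, load fraction `lf`** (the heart-rate position between rest
  and 80% of maximum): `PEP = rest · (1 − onset(lf) − 0.335 · s · lf)`,
  where the onset term (0.12, ramping in over the first 0.15 of the range)
  captures the immediate inotropic shift at exercise onset and `s` is the
  subject's heterogeneity multiplier. The total deficit is capped at 0.68
  so extreme responders keep a plausible PEP. At the stop rule this yields
  a reduction of ≈ 48–52% — the "physical stress halves the PEP" regime.
* **Breaks**: heart rate and PEP decay exponentially back toward rest
  (τ = 60 s and 45 s); applying the physical formula to the decaying
  residual makes recovery monotone and load-response symmetric.

On the habituation shape: the three printed anchors this model must honour
— a first-question reduction of about 14%, a TSST-wide mean PEP of
90.0 ms, and a vanishing effect at the last question — cannot all hold
simultaneously under any monotone habituation (a 90.0 ms TSST mean implies
a ~14% *average* reduction, which leaves no room for the effect to decay
to zero by Q8). We resolve the conflict in favour of the two quantitative
anchors: reactivity 0.15 with mild habituation (h = 0.97, Q8 retains ≈ 80%
of the Q1 effect). The rate is configurable for users who prefer a steeper
decay at the cost of the TSST-wide mean.

### The protocol

Each subject produces one baseline rest epoch, eight TSST epochs, a first
ergometer ascent in 0.4 W/kg steps (one BP measurement per step, stop after
the measured heart rate exceeds 80% of maximum, capped at 7 steps), a
three-measurement break, a short second ascent (second-to-last step once,
top step twice), and a final three-measurement break. Epochs are spaced
100 s apart (60 s gap + 40 s cuff cycle). Measured values are the phase
expectation plus epoch noise (PEP 4.5 ms; HR 2 bpm at rest, 3 bpm under
load). The first measurement of each break is labelled *recovery* and
excluded from the three-state analyses; the later break measurements count
as rest once heart rate has essentially returned to baseline.

### Surrogates

Heather index, LVET and systolic BP are generated as linear couplings to
the *expected* (noise-free) PEP plus Gaussian noise:

| surrogate | coupling | noise SD | pooled R² target |
|---|---|---|---|
| Heather index | `25 − 0.14·PEP` | 1.8 | 0.64 |
| LVET (ms) | `185 + 1.25·PEP` | 33 | 0.31 |
| ΔSBP (mmHg) | `−1.0·ΔPEP` from rest | 12.5 | 0.45 |

The Heather index has no absolute physical scale here; only its covariance
with PEP is meaningful. The noise SDs are calibration constants: they were
set once so that the pooled coefficients of determination land on the
values the analysis is designed to recover, and they are not revisited.
The same applies to the mental heart-rate gain (160 bpm per unit
reactivity), its noise (8 bpm), and the physical slope heterogeneity
(0.22): these jointly fix the stratified PEP~HR R² surface
(≈ 0.06 / 0.29 / 0.65 at rest / mental / physical).

### Beat level

Beat series are simulated for the window preceding each measurement (60 s
for the resting calibration; the full 100-s segment in `beats = "full"`
mode, i.e. a continuous recording). Within-subject resting variability is
deliberately *not* white noise:

* a slow vasomotor-band oscillation (period 8–15 s per subject, SD
  5.4 ms) that survives 4-beat averaging — this is why the averaged
  resting series keeps an SD of ≈ 4.5 ms;
* a small white component (2.2 ms) that averaging suppresses;
* a minute-scale autonomic drift (8 ms, constant within a window) that
  decorrelates windows from each other without inflating the 60-s
  within-window SD;
* settling transients after each state change: heart rate approaches its
  new steady value with τ = 55 s while the PEP settles with τ = 15 s
  (chronotropic responses lag inotropic ones), so beats recorded during
  transitions fall off the steady-state PEP~HR relation. Pooled beat-level
  correlations are therefore weaker (R² ≈ 0.55–0.60) than a naive pooling
  of steady-state epochs would suggest — `correlate_surrogates()` accepts
  the beat table for exactly this reason.

Artifact injection (heart-rate jumps) and cuff-curve disturbances are off
by default — artifact prevalence in real recordings is equipment- and
site-specific — and are switched on explicitly by the QC tests.

## Quality control

Three rules, applied by `qc_cohort()` before any statistics:

1. a beat whose heart rate differs by more than 30% from *any* beat less
   than 3 s earlier is an artifact (strictest pairwise reading;
   epoch-level exclusion by default, since a contaminated window taints
   its 4-beat averages);
2. a BP measurement whose cuff deflation contains a cumulative pressure
   rise of more than 8 mmHg is excluded ("more than" is strict; the rise
   is measured from a running minimum, robust to sampling rate);
3. beat-to-beat data are averaged over four heartbeats (right-aligned
   sliding mean over valid beats, preserving series length).

## Statistical choices

* The original mixed-model machinery for state contrasts is not fully
  specified anywhere we could follow; `matched_hr_contrast()` instead fits
  an HR-adjusted least-squares state contrast with cluster-robust (by
  subject) standard errors — the same estimand, a documented estimator.
* Phase-summary confidence intervals are percentile bootstrap over
  subjects (1000 resamples, seeded), since the original interval method is
  unstated.
* The supplementary polynomial for the curved PEP~HR cloud has degree 2 by
  default (configurable).
* Pooled correlations use all valid measurements across phases; the
  PEP~HR relation may instead be fitted on the 4-beat-averaged beat series
  when available (the densest data, including transients).

## The classifier

One feature point per subject and state: the state-mean PEP and heart rate
as deltas to the subject's single resting calibration measurement (the
rest-state mean uses the recovered late-break measurements, not the
calibration itself). Evaluation is strictly subject-wise: fold assignment
partitions subjects, never points, and z-scoring statistics are fitted on
training folds only. The k-NN (k = 13, Euclidean distance on z-scored
features) breaks ties deterministically — all neighbours tied at the k-th
distance are included, votes are resolved by the smaller summed neighbour
distance, then by fixed class order — so predictions are invariant to the
ordering of the training data. Because a single five-fold split of 71
subjects is noisy, the report averages 20 reshuffled repetitions; macro
PPV and sensitivity are computed from each repeat's pooled confusion
matrix and averaged.

## Blood-pressure uncertainty propagation

The published PWV–BP relations underlying real devices print their
coefficients in varied, sometimes inaccessible forms, so the relation here
is a pluggable component with two built-in monotone, closed-form-invertible
shapes (exponential PWV growth in SBP, default `1.5·e^{0.0073·SBP}` m/s;
and quadratic SBP in PWV). Every acceptance property of this module is
form-agnostic. The arterial path length is `height × 0.5` (1.80 m
"standard" adult by default) — a heart-to-periphery convention, flagged as
an assumption. The model curve is interpreted as the *arrival-time*
relation (the delay such devices actually measure); subtracting the
polynomial PEP-on-SBP fit yields the central transit-time curve, and the
fit's residual SD (pooled by default; per-bin optionally) widens it into
1-SD and 2-SD bands taken at face value as ±1σ/±2σ. Mapping band edges
back through the inverted central curve gives the SBP error induced by
estimating the PEP; because the PWV relation steepens with pressure, that
error inflates toward high SBP. Numerical details: the central curve is
inverted by monotone interpolation on a dense grid extended (polynomial
extrapolation) over the model support; edges beyond the invertible range
are clipped to the support with a warning and flagged per grid point, so
monotonicity diagnostics can exclude capped values. The strategy
comparison (`compare_neglect_vs_estimate()`) inverts each measurement's
simulated arrival time under three policies — estimate, neglect,
calibrate — with out-of-range inversions clipped, which caps rather than
inflates the reported errors.

## What the synthetic cohort does and does not show

The generator reproduces the *statistical structure* the analyses assume:
means and spreads of resting PEP, the mental and physical response
magnitudes and their heterogeneity, the state-dependent PEP–HR coupling,
surrogate covariances, beat-level fine structure, and the protocol's
declining n across ergometer steps. Passing tests therefore demonstrate
that the pipeline recovers known structure from data of this shape — not
that real recordings satisfy the model. Known simplifications: couplings
are linear with Gaussian noise; mental heart-rate and PEP responses share
a single latent drive; no circadian or posture effects; no ECG/ICG
waveform morphology (beat-level timing only); no dropouts by default; the
cohort is young and healthy by construction, so nothing here speaks to
aging or disease, where both PEP dynamics and vascular stiffness differ.

## Problem sizes

The test suite exercises small cohorts (n = 12–24) for unit tests, the
full 71-subject default for statistical checks, and a 5000-subject cohort
once for a law-of-large-numbers check. The acceptance script uses 50
replicate cohorts for the resting mean, 10–20 for the regression and
anthropometric targets, and single cohorts for the classifier and
beat-level targets; it completes in well under a minute on one core.
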