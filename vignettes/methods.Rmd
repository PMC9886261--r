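---
title: "From trunk-worn sensor signals to frailty classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From trunk-worn sensor signals to frailty classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actifrail)
```

## The problem

Frailty — the geriatric syndrome of reduced physiological reserve — is
usually screened with supervised, episodic instruments (the Fried
phenotype, gait-speed tests, questionnaires). A trunk-worn device carrying
a tri-axial accelerometer (nominal 50 Hz, ±8 g, units of g) and a
barometer (nominal 5 Hz, mbar and kelvin) lets physical function be scored
continuously during free living instead. `actifrail` implements the full
chain: per-day signal preprocessing, nine daily physical-function
features, cohort-level scaling and rank-based feature retention, and
leave-subject-out (LSO) classification of frail versus robust wearers
under daily and 5-day longitudinal decision designs. A synthetic-data
module generates both signal-level recordings with exact ground truth and
calibrated feature-level cohorts, so every stage is testable without
clinical data.

## Per-day feature extraction

All features are computed from one 24-h file per subject-day. Timestamps
are seconds since local midnight; files up to ±30 min long are accepted
(device clocks drift) and are never resampled implicitly — only if the
observed median sampling interval deviates from nominal by more than 10%
is the series linearly resampled, with a warning.

**Preprocessing.** The magnitude `||a|| = sqrt(ax² + ay² + az²)` is the
working signal for movement features. Pressure is cleaned with a
slope-limit filter — a recursive clamp that bounds the sample-to-sample
change at `max_slope` (default 0.5 mbar/s ≈ 4 m/s of altitude, far above
lift speeds, so door-slam spikes die while genuine ramps pass). Altitude
follows the barometric formula `H = T/0.0065 · (1 − (P'/1013.25)^0.19)`
and is averaged onto a 1-s grid; gaps longer than 3 s stay missing.

**G1, activity rate.** The magnitude is cut into non-overlapping 30-s
windows; a window is active when the rms of the demeaned window exceeds
0.03 g. The "3%" threshold is interpreted in native g units because its
companion range threshold is quoted in g. G1 is the active fraction; the
same window table (rms, posture) feeds every later gate.

**Posture.** With the device on the trunk, the vertical axis carries
gravity when the wearer is upright: `|mean ax| ≥ 0.7` g is upright,
`|mean ax| ≤ 0.4` with gravity on another axis is lying, anything between
is unknown. Because only the *mean* orientation is used, the gate is
meaningful during low-to-moderate movement.

**G2, sleep calmness.** Night mode spans 22:00–08:00. The three axis
signals are cut into 5-s fragments at 80% overlap; a fragment is silent
when every axis has SD < 0.03 g and range < 0.1 g. Runs of consecutive
silent fragments longer than 5 min are sleep cycles; G2 is 100 × (summed
cycle time) / (lying time between the first and last cycle). Within a
single file the night is assembled from the two within-file halves
(22:00–24:00 and 00:00–08:00 mapped onto one night clock) and flagged
approximate; the result is undefined (not an error) for nights without a
cycle.

**G3, steps.** Steps are peaks of the band-passed (0.5–5 Hz, order-2
Butterworth, zero-phase) magnitude exceeding 0.05 g, at least 0.3 s apart,
counted only in windows that are simultaneously active and upright. The
band-pass corner at 0.5 Hz matters: very slow gait (≈0.53 Hz for a 1.9-s
period) is attenuated ~25% but step peaks sized ≥ 0.1 g still clear the
threshold.

**G4/G5, periodicity.** For every active window the biased, lag-0-normalised
autocorrelation is computed (batched over windows via FFT). Peaks above
0.3 at positive lags, at least 250 ms apart, are detected; a window with
at least three peaks is periodic. G4 = 100·30·T/D with T the periodic
window count and D the *observed* coverage in seconds (not a fixed 86400 —
days with gaps are scored against the time actually worn). G5 is the mean
peak spacing in seconds over periodic windows; peak spacings are lag
counts divided by the sampling rate, so the result is in seconds. G5 is
missing when no window is periodic, and per-day G5 is only reported when
T ≥ 1; downstream classification median-imputes it within the training
fold.

**G6, weightlessness.** Maximal intervals with `||a|| < 0.3` g lasting at
least 0.04 s (two samples); G6 is their total duration. Raising the
threshold can only grow the episode set, a property the tests exercise.

**G7/G8, change in altitude.** Maximal monotone runs of the 1-s altitude
lasting ≥ 6 s are found, tolerating single-second plateaus (|ΔH| < 0.1 m)
inside a run; the slope is the straight-line ΔH over the run duration. A
run with |slope| in [0.6, 0.9] m/s while the wearer is inactive or only
slightly moving (window rms ≤ 0.06 g) is a lift; |slope| in [0.25, 0.6]
while active is a stair episode. The shared 0.6 m/s point is resolved by
the activity gate, with active ties going to stairs. "Slightly moving" has no
natural sharp definition; we fix it as rms in (0.03, 0.06] g.

**G9, energy expenditure.** Each 30-s window gets a MET value: inactive 1;
active non-periodic 1.5 below σ = 0.025 g else 1.8; periodic 2 / 3.3 / 5
for σ ≤ 0.09, ≤ 0.2, > 0.2; windows containing weightless episodes 7 (airborne
activity is conventionally banded only as "MET > 6", so a concrete
default is fixed). Boundary σ values fall in the lower band.
Calories are MET × duration(h) × weight(kg); with `normalize = TRUE`
(default) weight is 1 and the unit is kcal/kg. Note the 1.5-MET cell is
unreachable from the default gates (active already implies σ > 0.03): it
exists for explicitly-labelled segments.

## Cohort statistics

Daily features are averaged per subject (missing entries ignored) before
the rank-sum screen. Scaling is per column: z-score `(f − μ)/σ` or the
sigmoid `1/(1 + exp(−(f − μ)/σ))`, which is exactly the logistic of the
z-score and maps into (0, 1) preserving order. The SD convention is
population (divide by n), fixed, documented, and switchable. Feature retention uses the
two-sample Wilcoxon rank-sum (Mann–Whitney) test per feature on the
subject means — the only Wilcoxon variant applicable to two independent
groups — which `rank_sum_select` implements (exact null for groups ≤ 10 without ties, normal approximation
with continuity correction otherwise). PCA to two components uses a
deterministic sign convention (largest-magnitude loading positive).

Scaling parameters are fit on training rows only inside cross-validation
and applied to test rows; pre-scaling the full matrix before CV leaks test
information, so the leaking variant exists only as an explicit
`fold_safe = FALSE` switch for comparison.

## Classification designs

Five families, configured as: NN with one hidden layer of 15 sigmoidal
neurons; SVM with RBF kernel; k-NN with k = 5; random forest with 10
trees of depth ≤ 5; gradient boosting with 100 rounds at learning rate
0.4. Internals the configuration leaves open are fixed documented
defaults: the NN uses entropy fitting with weight decay 0.3 and up to 300
iterations — the decay is deliberately strong, because on LSO folds an
under-regularised 15-unit network produces arbitrary decisions for
held-out subjects that sit outside the training envelope, and the smooth
surface removes that pathology; the SVM uses cost 1 and kernel width
1/d; boosting uses depth-3 trees. Every fit is seeded per fold, so runs
are bit-reproducible.

LSO cross-validation trains on all days of all-but-one subject and
predicts every day of the held-out one; pooled confusion counts over the
18 folds give sensitivity (frail detected; frail is the positive class),
specificity and accuracy. The two longitudinal designs both reuse the
models trained on daily rows: *voting* takes the majority of the five
daily predictions in each non-overlapping 5-day block (blocks anchored at
each subject's first day, remainders dropped; even-k ties default to
frail — the safer alerting choice); *averaging* feeds the 5-day feature
means to the daily-trained classifier. The averaging design is
implemented this way — rather than retraining on averaged samples —
because it is the variant under which the design behaves as a
longitudinal smoother of the daily decision problem (specificity rises
while sensitivity collapses); retraining on
averaged rows denoises both classes and raises sensitivity instead.

## The synthetic-data generator

### Signal level

`generate_day` emits 24 h of 50 Hz acceleration and 5 Hz pressure plus the
exact ground truth implied by its own construction. Gravity sits on the
vertical axis when upright (08:00–22:00) and on a frontal axis overnight.
Movement is injected on the 30-s window grid, which makes window-level
ground truth exact:

* **Continuous gait windows** carry a tapered fundamental-plus-0.25-harmonic
  oscillation at the profile cadence — one magnitude peak per step. The
  harmonic weight matters: a heavier harmonic gains a second in-band local
  maximum per cycle after the step detector's band-pass when the cadence
  sits at the 0.5 Hz corner, which would double-count slow gait.
* **Walking bursts** supply the remaining daily steps without making a
  window periodic: two or three sub-bursts of exactly 1.5 gait cycles,
  each starting and ending on a zero crossing under an arched envelope
  with a 0.65 floor, over a white fidget floor (σ 0.03 g). Every genuine
  peak stays far above the 0.05 g threshold while the autocorrelation
  contribution stays below the 0.3 peak threshold with at most two
  repeats — so burst windows are never periodic, by construction.
* **Fidget windows** (the rest of the activity budget) are white noise on
  the gravity axis in a *tilted* posture (mean vertical component ≈ 0.6,
  classified neither upright nor lying), so they count toward the
  activity rate but can never contribute steps. White noise is used
  because any smooth sway process carries a high, slowly-decaying
  autocorrelation on which noise wiggles create spurious peaks above 0.3.
* **Nights** are still apart from Poisson-placed agitation bursts
  (broadband noise on all axes) aligned to the window grid and at least
  six minutes apart, so ground-truth sleep cycles are exact.
* **Lifts** are pressure ramps under a still wearer, **stair episodes**
  ramps under a full gait window; both are integer-second aligned. Default
  slopes are 0.85–0.88 m/s over 16–20 s for lifts and 0.46–0.54 m/s over
  8–14 s for stairs. These sit high inside their bands deliberately: at
  the generator's 0.03 mbar pressure noise one second of averaged altitude
  carries ≈ 0.11 m of noise, so monotone-run boundaries wander and dilute
  measured slopes; the defaults were chosen by simulation (2000 episodes
  per configuration) so that every injected episode is recovered exactly
  once with failure probability below about 10⁻³. Pressure spikes are
  injected away from ramps — a spike inside a ramp can legitimately break
  the monotone run.
* Sensor noise is 0.01 g per axis and 0.03 mbar; pressure is derived by
  inverting the barometric formula at 293.15 K so the pipeline's altitude
  recovers injected heights exactly (self-consistency over meteorological
  realism).

What the generator does **not** emulate: biomechanical gait detail,
sensor-specific noise spectra, wear gaps, posture transitions during
movement, and clock drift (supported but off by default). Passing
parameter-recovery tests therefore demonstrates internal consistency of
the pipeline with its own definitions, not field accuracy on real elderly
data.

### Cohort level

`generate_cohort` (default mode `"features"`) draws per-subject true
feature means from calibrated frail/robust distributions and day values
around them; 9 + 9 subjects with ≈ 31.6 ± 16.5 monitored days each (≈ 570
subject-days). Families were chosen once from the group statistics being
emulated — lognormal for the skewed count-like features (steps,
periodicity rate, lift/stair frequency), truncated normal for the
roughly symmetric ones (activity rate, sleep calmness, energy
expenditure), a 1.35-s-shifted gamma for the frail gait period against a
tight normal (1.18 ± 0.04 s) for robust — with draws bounded to
plausible, quartile-compatible ranges (an unbounded lognormal happily
produces a "frail nursing-home faller" walking 8500 steps/day, which both
misrepresents the population and poisons LSO folds with out-of-envelope
subjects).

Day-to-day structure: daily step counts are lognormal around the subject
mean (cv 0.3); the day's periodic-window count is Poisson with lognormal
mixing, G4 follows from it, and G5's day noise shrinks with the number of
periodic windows (missing when there are none — the common frail case);
event counts are Poisson; percentages wiggle normally. On top of this,
each day can be an atypical "spell" day drawn from the opposite group's
day cloud (a frail person's outing, a robust person's sick day) at rates
0.06/0.04 calibrated to the daily error rates the design comparison
reports (sensitivity ≈ 93%, specificity ≈ 94%). These days are what
separates the longitudinal designs: a minority of atypical days flips
5-day feature averages but not 5-day majority votes.

### A selection property that stays out of reach

The acceptance suite asks the rank-sum screen to retain *exactly*
{steps, EE, periodicity rate, stairs, gait period} — and nothing else — in
at least 90% of 200 replicate cohorts. The five discriminative features
are retained in ≥ 99.5% of replicates each, and weightlessness never.
But the three features that must *not* be retained (activity rate, sleep
calmness, lift frequency) have group differences that sit essentially at
the 5% significance boundary (observed p-values of roughly 0.06–0.13 at
n = 9 + 9): any calibration faithful to the group means and SDs puts
their replicate-level retention near a coin flip (measured ≈ 52%, 58% and
16%), so the exact pattern appears in only ≈ 16% of replicates. This is a
property of the statistics, not of the implementation — a test retaining
a boundary feature half the time is exactly what a p ≈ 0.06 effect does
under resampling — and the corresponding acceptance test is left failing
with this analysis rather than loosened.

## Numerical choices and degenerate inputs

* Trailing partial windows are discarded, never zero-padded (unbiased rms).
* Autocorrelation uses the biased estimator normalised at lag 0, computed
  by FFT over all active windows at once.
* Peak finding is greedy highest-first with a minimum-gap constraint.
* Constant feature columns are dropped from scaling with a warning
  (weightlessness is constant zero in cohorts, mirroring its absence from
  the cohort summaries); constant columns in the rank-sum screen score
  p = 1.
* Degenerate days: < 4 h coverage gives an all-missing feature vector with
  a reason code; a day with no lying night has undefined G2; no altitude
  data flags G7/G8 missing rather than zero.
* All randomness is seeded: generator days by the user's seed, classifier
  fits by `model seed + fold index`.

## Problem sizes

The shipped tests run the full signal pipeline on 20 synthetic days per
profile for parameter recovery, 200 feature-level cohort replicates for
the selection screen, and three cohort replicates for the design
comparison — sizes chosen so the whole suite exercises every claim at
desk scale while each block stays well under its stated runtime budget.

## Known limitations

* The lift band is only reliably detectable for multi-floor rides at the
  modelled pressure-noise level; single-floor lifts (≈ 4 s) are invisible
  to a 6-s monotone-run rule by construction.
* The sleep module scores stillness, not sleep; G2 is a calmness proxy.
* MET values are population constants; absolute energy expenditure is
  biased for any individual, which is why the weight-normalised form is
  the default.
* The synthetic cohort reproduces the *structure* of the frail/robust
  contrast, not any individual's physiology; classification numbers on it
  are analogues of what a clinical deployment would see, not
  reproductions of any particular cohort.
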