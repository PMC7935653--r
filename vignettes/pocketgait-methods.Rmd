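---
title: "Pocket-IMU gait analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pocket-IMU gait analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketgait)
```

## The measurement problem

A smartphone carried loosely in a trouser pocket records 3-axis acceleration
and angular rate at ~100 Hz while its wearer walks a short hallway course
(two straight ~10 m legs joined by a 180° turn). From these signals we want
per-trial **stride time** (time between consecutive heel strikes of the same
leg), **stride time variability** (the coefficient of variation
$100 \cdot \mathrm{SD}/\mathrm{mean}$, in %), and the **dual-task cost**
(percent change of each metric from quiet walking to walking while performing
a serial-subtraction task). Elevated stride-time variability and dual-task
cost are established digital markers of parkinsonian gait, fall risk and
cognitive-motor interference.

The obstacle is that the phone's orientation in the pocket is arbitrary and
unknown. The pipeline therefore works in an Earth-referenced frame:

1. **Attitude.** If the recording carries attitude quaternions (as phone OS
   APIs can supply), they are used as-is. Otherwise `estimate_orientation()`
   runs a complementary filter: the tilt is anchored to the low-frequency
   accelerometer gravity direction (default anchor cutoff 0.25 Hz, i.e. a
   correction time constant of ~0.64 s) while the gyroscope is integrated for
   short-term dynamics. Yaw is left arbitrary: only the vertical axis and the
   rotation rate about it are consumed downstream, and both are invariant
   under yaw.
2. **Rotation and gravity removal.** `rotate_to_earth()` resamples to a
   uniform rate (linear interpolation; filter theory assumes uniform
   sampling), rotates each sample by its quaternion so Z is vertical, and
   subtracts a scalar gravity magnitude (default 9.81 m/s²) from Z.
   Rotation is an isometry; per-sample norms are preserved exactly, which the
   tests assert at 1e-9.
3. **Filtering.** `lowpass()` applies a 4th-order Butterworth low-pass at
   3 Hz, forward and backward. The order is a package choice; zero-phase
   filtering matters because event *timing* is the measurand and a causal
   filter would bias every event late. The two-pass amplitude response is
   $|H(f)|^2 = \left(1 + (\tan(\pi f/f_s)/\tan(\pi f_c/f_s))^{2\cdot4}\right)^{-1}$,
   which the tests verify against measured sinusoid gains. Ends are padded by
   odd reflection, and each pass removes the edge value first so the
   zero-state transient acts on a signal starting at zero.
4. **Turn removal.** Yaw is integrated from the (unfiltered) Earth-frame
   vertical angular rate in a sliding 4 s window; wherever the accumulated
   yaw reaches 120° a turn is declared (the threshold sits below the nominal
   180° so hesitant or under-rotated turns are still caught). Candidate
   regions are refined to the span where the briefly smoothed vertical rate
   exceeds 10% of its regional peak, and intervals closer than 0.5 s merge.
   Straight-walking segments are the trial span minus each turn dilated by
   0.5 s (gait is unsteady entering and leaving a turn); segments shorter
   than 3 s are discarded.
5. **Gait events.** During straight walking the filtered vertical
   acceleration oscillates twice per stride with alternating higher
   (phone-side step) and lower (contralateral step) peaks. Local maxima are
   found subject to (a) topographic prominence of at least 0.3 × the IQR of
   the filtered signal within ±2 s of the candidate, (b) a minimum spacing
   of 0.35 s (above the physiological step-rate limit), and (c) an amplitude
   of at least 25% of the median retained-peak amplitude — this last floor
   rejects residual low-amplitude artifacts in the short walk
   initiation/termination ramps, which would otherwise contribute spurious
   events with badly biased trough times. Peaks are scored against the
   median of their ≤4 neighbouring peaks and labelled high/low by the
   alternating phase that maximises total score agreement, so the high/low
   sequence is strictly alternating by construction. The **heel strike** of
   the phone-side leg is the trough nadir between each high peak and the
   next peak; the **toe-off** is the trough after each low peak. Trough
   times get three-point parabolic refinement (≤ half a sample). Events
   within 0.5 s of a segment boundary are dropped, and troughs are only
   accepted *between* consecutive peaks — the nadir after a segment's final
   peak lies in the walk-termination ramp and is unreliable.
6. **Metrics.** Stride times are heel-strike differences within a segment
   (never spanning a removed turn), gated to the physiological range
   0.3–3 s. The summary uses the sample (n−1) SD: trials hold only ~9–15
   strides, where the estimator choice is material. Dual-task cost is
   $100\,(\text{dual} - \text{single})/\text{single}$ per metric; across a
   participant's repeated trials the per-trial costs are averaged (not the
   cost of averaged metrics). The 0/0 case (identical zero-variability
   records) is defined as zero cost.

## The synthetic walking model

`simulate_trial()` generates device-frame recordings with *exact* ground
truth, emulating the hallway protocol: ~1 s quiet standing, one straight
leg, a 180° turn, the return leg, ~1 s standing.

- **Stride clock.** Stride durations are i.i.d. Normal(mean, cv·mean),
  truncated at ±3 SD so the phase clock stays monotone; the phase advances
  2π per stride. Defaults follow the cohort-typical conditions: mean 1.09 s
  single task and 1.17 s dual task. Trial-level CVs of 3%/5% and
  cohort-level CV distributions (mean 3.5%, SD 2%, single task; ×1.6 dual)
  are package choices in the physiological range reported for PD gait;
  published cohort tables sometimes print variability values (tens of %)
  that are not plausible coefficients of variation, and those magnitudes are
  deliberately not emulated.
- **Waveform.** Vertical Earth-frame acceleration is
  $A\,[\cos(2\phi) + a\cos\phi]$ with base amplitude $A = 2.5$ m/s² and step
  asymmetry $a = 0.35$: two peaks per stride with alternating amplitudes
  $A(1{+}a)$ and $A(1{-}a)$. Its troughs are closed-form — they sit at
  $\cos\phi = -a/4$ — so true heel strikes (trough after the high peak) and
  toe-offs (trough after the low peak) are *analytic*, never themselves
  detected; simulator and detector cannot be circular. Horizontal body-frame
  components (anterior-posterior at step rate, medio-lateral at stride rate)
  and consistent heading rotation make the orientation problem real.
- **Turn.** A raised-cosine yaw-rate pulse integrating exactly to 180° over
  2.5 s, with gait amplitude damped 50% during the turn. Only its
  detectability matters downstream.
- **Pocket attitude.** Every sample is rotated into the device frame by the
  walker's heading composed with a fixed random pocket quaternion, gravity is
  added, and white Gaussian noise (SD 0.15) is applied to all six channels.
- **Ground truth** records the analytic event times (stride times are their
  differences, exactly), the turn interval, the walk span, and the noiseless
  vertical trace. `ground_truth_metrics()` summarises the true events under
  the same straight-walking protocol (turn dilated 0.5 s, 0.5 s boundary
  margin), playing the role the gold-standard reference system plays in a
  validation study.

`simulate_cohort()` adds a latent severity factor per participant: it shifts
stride-time variability upward and generates UPDRS III, MoCA (negative),
HAM-A and HAM-D scores with chosen standardized effects around
cohort-typical means and SDs, plus age/sex/education covariates — enough
structure for the statistics layer to be tested by parameter recovery.

**What the simulator does not emulate:** real foot-strike transients and
their harmonic content above 3 Hz, soft-tissue and pocket-slip artifacts,
sensor bias/drift/temperature effects, freezing-of-gait or festination
episodes, asymmetric pathology between legs, and integer-valued clinical
scales. Passing tests therefore demonstrate correctness of the signal
processing and statistics under a controlled morphology, not clinical
performance on real recordings.

## Statistics layer

- `validity()`: Pearson r (two-sided p) between matched pipeline and
  reference values plus mean/SD of absolute differences.
- `condition_anova()`: the task-condition effect is estimated on stacked
  participant-condition rows by ANCOVA, `metric ~ condition + age + sex +
  education`, with the condition F from the nested-model comparison. The
  repeated-measures correlation within participant is knowingly ignored
  (rows enter as independent), a simplification inherited from the analysis
  style this layer reproduces; the reported degrees of freedom are the
  correct ones for the fitted model.
- `adjusted_association()`: `score ~ metric + age + sex + education` with
  score and metric z-scored, so the metric coefficient is a standardized β
  (covariates stay raw). No multiple-testing correction is applied.

## Numerical and degenerate-input choices

- Resampling and quaternion interpolation are linear (with renormalisation);
  at 100 Hz and gait frequencies ≤ 3 Hz the interpolation error is
  negligible against sensor noise.
- Trough refinement is parabolic and clamped to ±half a sample.
- Classification ties are resolved by the global alternating phase per
  segment, which also guarantees the alternation invariant.
- Fewer than 4 retained peaks in every segment raises an "insufficient
  gait" error; fewer than 2 strides, "insufficient strides"; fewer than 5
  strides flags `few_strides`. Free-fall-like input (near-zero mean
  acceleration norm) makes orientation estimation fail loudly rather than
  return garbage.
- Validation tolerances on trial construction: strictly increasing
  timestamps, median sampling interval within ±10% of nominal, quaternion
  norms within 1e-6. Sampling gaps are flagged, not fatal.

## Problem sizes used in the shipped checks

The package's own validation (tests and `scripts/acceptance.R`) uses 52
simulated participants × 2 conditions × 2 trials for the validity analysis;
200 single trials spanning stride times 0.9–1.4 s and CVs 1–10% for the
event-detection sweep; and 20 replicates of 52-participant cohorts (one
trial per participant-condition, simulator-supplied attitude) for
association parameter recovery. Event-detection sensitivity is scored
against true heel strikes outside a 0.75 s guard band around trial
boundaries and the true turn (detection margin 0.5 s plus worst-case
turn-edge localisation ~0.25 s); precision counts any detection not within
50 ms of *some* true heel strike as false. The guard band is standard
boundary-ambiguity handling for event-detection scoring.

## Known limitations

- Only the phone-side leg's events are detected; left/right is not labelled.
- Gait during turns is discarded, not analysed; no turning metrics.
- No spatial metrics (speed, stride length) — a pocket IMU alone cannot
  provide them without further modelling.
- The complementary filter assumes quasi-constant pocket attitude; a phone
  tumbling inside a loose pocket violates it.
- Association models treat clinical scores as continuous and ignore
  within-participant correlation across conditions.
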