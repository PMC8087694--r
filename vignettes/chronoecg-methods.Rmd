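---
title: "Methods: circadian analysis of longitudinal ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian analysis of longitudinal ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronoecg)
```

## What the package computes

`chronoecg` analyses long-term ECG recordings — mouse telemetry (10-s sweeps
of 10,000 samples every 5 min at 1 kHz, with locomotor activity and body
temperature per 5-min bin) and continuous human laboratory recordings
(256 Hz, or 128 Hz after downsampling; 10,000-sample sweeps then span ~39 s
and ~78 s) — and quantifies the daily rhythms of the interval parameters
derived from them:

* **RR** (sinoatrial rate), **PR segment** (P-wave offset to QRS onset,
  indexing atrioventricular conduction delay) and **QT** (QRS onset to
  T-wave offset, ventricular de- plus repolarization), each reduced to a
  per-sweep median over valid beats; HR is `60000 / RR(ms)`.
* A geometric heart-rate-variability (HRV) measure on *relative* RR
  intervals, robust to outliers and absolute heart rate.
* Cosinor rhythm parameters (mesor, amplitude, acrophase), circular
  acrophase comparisons, cross-correlogram phase delays between parameters,
  and acute-coupling summaries (delta-RR dependency curves,
  activity-aligned responses).
* Rule-based ventricular-arrhythmia calling (VPC labeling, VT and
  bidirectional-VT episodes) and chi-square incidence comparisons.

Because the underlying laboratory recordings are not publicly deposited,
the package ships a synthetic generator (`synth_*`) that emulates their
statistical structure with exact ground truth; every validation claim in
the test suite is made against that ground truth, not against real data.

## The per-sweep pipeline

1. **R-peak detection** (`detect_r_peaks`): local maxima of the rectified,
   baseline-centred signal inside an amplitude window, thinned by a
   refractory period (mouse 50 ms, human 250 ms — physiological upper HR
   bounds; larger peaks win, ties go to the earlier sample). Detection is
   polarity-insensitive so inverted ectopic beats are found. The default
   window is `[0.25, 2]` times the median per-second maximum of the
   rectified signal. A quantile-of-signal rule was rejected: the R wave
   occupies ~5% of samples in mouse but ~1% in human, so any fixed signal
   quantile lands on different waves in the two species; and a lower limit
   near 0.4 of the R amplitude would make the first QC rule (mean beat
   amplitude at least 3 times the lower limit) fail on perfectly clean
   recordings. Both bounds remain operator settings.
2. **Template filtering** (`template_filter`): the sweep's template is the
   mean beat waveform over fixed windows centred on R (odd length; half
   width 40 ms mouse / 350 ms human, covering P through T). Beat mismatch
   is `1 - r` with `r` the Pearson correlation to the template; mismatch
   above `theta = 0.2` excludes the beat. Correlation was chosen because it
   is scale-free and tolerant of slow amplitude drift; `theta` is exposed.
3. **Quality control** (`sweep_qc`): a sweep is excluded when the mean
   discriminated beat amplitude is below 3 times the window's lower limit,
   when the baseline variation (1.4826 times the median absolute deviation
   of the samples outside all beat windows) exceeds 1/3 of that limit, or
   when more than 20% of detected events were rejected by template
   matching.
4. **Delineation** (`annotate_sweep`): a *deflection* is a local extremum
   of the lightly smoothed trace (an upward deflection is a local minimum,
   a downward one a local maximum); a *crossing* of the isoelectric line is
   linearly interpolated. The isoelectric level is the median of the
   baseline segment between the previous beat's T offset and a guard gap
   before the P wave (landmarks needing it are invalidated when fewer than
   5 samples are available). Mouse rules: P peak is the maximum between the
   previous beat and R; P offset the first upward deflection right of the P
   peak; Q onset the first upward deflection left of R; T peak the minimum
   between R and the next P; T offset the return to the isoelectric line
   after T. Human rules: P offset is the isoelectric crossing right of the
   P peak; Q onset the first downward deflection left of the Q trough; T
   peak the maximum between R and the next P; T offset the first upward
   deflection after the trace crosses the isoelectric line. Narrow (QRS)
   landmarks use a 3-sample moving average at both rates; human P/T
   landmarks use a 9-sample window, because at 256 Hz the human T wave
   spans ~25 samples and its shallow repolarization undershoot is otherwise
   dominated by sample noise. Both widths are arguments. First/last beats
   contribute only the intervals their windows allow; an ordering violation
   invalidates only the affected landmarks.
5. **Reduction** (`summarize_sweep`): per-sweep medians over valid beats.
   The PR *segment* (P offset to Q onset) is used throughout, not the PR
   interval, because P onset is never defined by the delineation rules; QT
   is measured from Q onset and left rate-uncorrected.

## HRV

`relative_rr` computes `r[i] = 2 (RR[i] - RR[i-1]) / (RR[i] + RR[i-1])`,
which is exactly invariant under `RR -> c RR`. `geometric_hrv` summarizes
the Poincare cloud of consecutive pairs `(r[i], r[i+1])` as 100 times the
median Euclidean distance from the component-wise median — a deliberate
double use of medians so that isolated ectopic or missed beats barely move
the measure. The aggregation is isolated behind this one function so an
alternative (e.g. a trimmed mean) can be swapped without touching callers.
Frequency-domain HRV is out of scope: it presumes stationary, continuous
beat series that cadenced telemetry sweeps do not provide.

## Rhythmometry

Z-scoring is per subject across the whole session (sample SD, n-1);
excluded sweeps do not influence the normalization. Series are binned on a
5-min grid, and a subject drops out of profile analyses when fewer than 70%
of bins are covered.

`cosinor_fit` fits `M + A cos(2*pi*(t - phi)/24)` by linear harmonic
regression; rhythmicity is the F-test of the two harmonic regressors
against the intercept-only model (zero-amplitude test), with a permutation
variant available for irregular designs. `acrophase_stats` implements the
Watson–Williams circular one-way test with the standard
`1 + 3/(8 kappa)` correction, flagged unreliable when the pooled mean
resultant length falls below 0.45.

`crosscorr_phase` computes the lagged Pearson correlogram (lags within
±12 h, pairwise-complete bins) and fits a Gaussian (height, mean, SD) to
the contiguous positive region around the argmax — restricting the fit to
that region keeps the Gaussian from chasing the correlogram's periodic side
lobes. If the nonlinear fit fails the argmax lag is used and flagged. The
cohort-level test is a one-sample t of per-subject fitted means against 0.

`delta_dependency` differences consecutive nonempty bins and averages the
concurrent change of the second parameter within delta-RR bins (width 0.25
SD for human z-scores, 0.5 SD for mouse); `rr_heatmap` bins RR by time of
day (15 min x 1.5 ms), converts columns to probabilities, smooths with a
2-D Gaussian kernel (SD 5 bins, truncated at 3 SD; "5 SD window" is read
as the kernel's SD, an isolated exposed constant) with circular padding in
time and reflection in RR, and renormalizes the columns.

## Activity coupling

Activity is nonnegative counts per 5-min bin; a bin is *inactive* iff its
count is zero, and a *bout* is a maximal run of nonzero bins. The at-rest
circadian profile is a 24-h constrained sine fitted to points preceded by
30 min of strict inactivity (the "complete inactivity" reading); it
requires at least 8 rest points spanning more than 12 h of phase.
`inactivity_aligned_response` isolates bouts followed by 45 min of complete
inactivity, aligns to the cessation, and reports deviations from the rest
fit at the matching clock phase — so the circadian component cancels and
only the acute effect remains. `transient_bout_response` anchors at bout
onset and normalizes to the preceding 5-min rest bin. The default siesta
window is the 2-h window minimizing mean activity within ZT 18–24,
overridable.

## Arrhythmia calling

A beat is a VPC when its QRS is widened (width at 25% of its own R
amplitude exceeding 1.5 times the template's) *and* its QRS axis deviates
from the template: the signed R amplitude, as a fraction of the template's,
falls below 0.5. Sign flips (inverted QRS) give negative ratios and always
satisfy the clause; a widened beat of normal upright amplitude does not.
This axis-deviation reading (rather than a strict sign flip) is required
for bidirectional VT, whose beats alternate between two abnormal axes:
under a strict inversion rule the upright half of a bidirectional run could
never be labeled VPC and no alternating run of four could exist. Runs of at
least four consecutive VPCs are VT; a run whose signed amplitudes alternate
in sign beat-to-beat is bidirectional VT. Prematurity (preceding RR below
0.8 of the local median) is recorded but not required — the delineation
rules define VPCs morphologically. Incidence tables are compared with the
Pearson chi-square without continuity correction.

## The synthetic generator

`synth_beat_train` accumulates beat times from
`RR(t) = M + A cos(2*pi*(t - phi)/24) + g a(t) + e`, where `a(t)` is the
exponentially smoothed (15-min time constant) activity count and `g` the
activity gain (default -0.5 ms per unit: activity shortens RR). QT adds
`coupling_qt_rr` (default 0.8) times the beat's RR deviation to its own
cosinor; the PR segment has an independent cosinor whose acrophase sits
+1.5 h after RR's and zero RR coupling — giving the phase-delay and
dependency analyses known targets. Species presets: mouse RR/PRseg/QT
mesors 100/15/40 ms with amplitudes 8/1.2/2 ms; human 900/60/400 ms with
70/5/10 ms. The mouse telemetry rate is not dictated by the sweep
arithmetic alone; 1 kHz follows from 10,000 points spanning 10 s and stays
configurable.

`synth_ecg_waveform` renders each beat as Gaussian bumps in three
complexes. All delineation rules are defined through extrema and
isoelectric crossings, which are exactly solvable on smooth bumps: the
per-complex landmark offsets are computed once on a 0.05-ms oversampled
noise-free rendering, then each P complex is shifted so its P-offset
landmark sits exactly `PRseg` before Q onset, and each T complex so its
T-offset landmark sits exactly `QT` after it. Both species carry a small
opposite-sign companion bump after P and after T so the offset rules have a
noise-free answer (mouse T is negative with a positive overshoot; human T
positive with an undershoot). Emitted annotations are therefore
sample-accurate ground truth. Noise and baseline wander are added last; a
configurable fraction of sweeps receives large wander, emulating movement
artefact, and is expected to fail QC. `synth_behavior` draws Poisson
activity counts from a nocturnal rate profile (6/0.3 counts per bin
dark/light, 0.2 in the siesta window) driven by an internal phase that
re-entrains at a configurable rate after an LD shift; temperature
phase-locks to the same internal phase.

What the generator does *not* emulate: real electrode noise spectra,
T-wave morphology variants (biphasic, flat), sleep staging, drug effects,
and any ionic/autonomic physiology. Green tests therefore demonstrate that
the estimators recover known structure at realistic noise levels — not that
the delineation rules are optimal on clinical recordings.

## Numerical choices and degenerate inputs

* All randomness flows from one explicit seed per generator call.
* Non-positive RR draws are resampled and counted; above 1% the call
  aborts.
* Zero-variance series refuse to z-score; degenerate cosinor designs
  (under 8 points, or no phase spread) error rather than returning
  unstable estimates.
* An empty sweep is valid detector output and fails QC as `low_amplitude`.
* Crossing landmarks are fractional (linearly interpolated) samples;
  interval errors at 1 kHz are dominated by noise, not quantization.
* Heatmap columns with no observations stay zero and are flagged rather
  than renormalized.

## Problem sizes used in validation

The test-suite study fixture is a full 5-day mouse recording (1,440 sweeps,
~144,000 beats) at 1 kHz with noise SD 5% of the R amplitude and 4%
artifact sweeps; rhythmometry calibration uses 1,000 white-noise
simulations (type-I error), 300 acrophase-recovery simulations on the
5-day 5-min grid, and a 12-subject phase-delay cohort. These sizes keep the
whole validation run in a few minutes on one CPU while leaving the
Monte-Carlo confidence intervals well inside the asserted bounds. At
amplitude-to-noise 1 on a single day (288 bins) the asymptotic acrophase SD
is `sqrt(2/n) * 24/(2*pi)` ≈ 0.32 h, so ±0.5 h recovery is only reliable
across the full multi-day series — the study condition used here.

## Known limitations

* Human delineation at 128 Hz carries ~8 ms quantization per landmark;
  RR/HR remain accurate but PR-segment precision degrades.
* The human T-offset rule depends on T-wave morphology; atypical shapes
  (no undershoot) yield flagged, not guessed, offsets — matching the
  practice of excluding subjects whose T-wave end cannot be determined.
* The Watson–Williams test assumes comparable concentrations across
  groups; the `reliable` flag only guards the pooled resultant length.
* Multiple-testing corrections across parameter families are left to the
  caller.
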