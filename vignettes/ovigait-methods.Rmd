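---
title: "Quantifying post-stroke gait and neurological deficit in sheep: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying post-stroke gait and neurological deficit in sheep: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovigait)
```

## The problem

Large-animal stroke models need functional outcome measures that are
repeatable in healthy animals and sensitive to deficit afterwards.  This
package implements a complete analysis chain for an ovine middle cerebral
artery occlusion (MCAo) model assessed at three pre-stroke baselines
(8-, 5- and 1-day, sessions `B1`-`B3`) and 3 days post-stroke (`D3`):

1. optical motion capture of 42 retro-reflective landmarks at 200 Hz
   during straight overland walking (axial markers HEAD/T1/T13/L7 plus a
   seven-marker forelimb chain and a twelve-marker hindlimb chain per
   side);
2. trajectory conditioning, velocity-threshold gait-event detection,
   planar joint angles and spatiotemporal parameters;
3. a ten-criterion composite neurological score;
4. the study statistics: intraclass-correlation repeatability, velocity
   adjustment, pre/post linear mixed models, and a principal component
   analysis relating gait, neuroscore and infarct volume.

Because per-animal raw trajectories are not publicly deposited, the
package carries a deterministic synthetic gait generator with known
ground truth; every processing stage is validated against it.

## Coordinate and unit conventions

The global coordinate system has z vertical (positive up), y along the
direction of progression and x lateral with positive x to the animal's
right.  Positions are millimetres internally; study tables report the
conventional units (s, cm, m/s, degrees).  The on-disk TSV dialect
writes a 0-based `frame` column (`time = frame / rate`); in-memory frame
indices follow R's 1-based convention.  C3D files are written with
single-precision floats (the format's point storage), so they round-trip
to about 1e-4 mm; the TSV dialect round-trips at double precision.

## Trajectory conditioning

Occlusion gaps up to 20 frames (0.1 s) are filled; longer gaps flag the
trial.  The spline method interpolates each coordinate with a cubic
spline through observed frames and is exact on locally polynomial
motion.  The cyclic method copies the displacement pattern of the
corresponding phase one period away (period estimated from the
autocorrelation of the observed signal, or taken from a donor marker)
and linearly offset-matches the copy at the gap edges; it is intended
for gaps during periodic limb motion that spline interpolation would cut
short.

Filtering is a fourth-order low-pass Butterworth, cut-off 10 Hz
specified per pass, applied forward and backward for zero net phase.
The combined response is the squared magnitude `1/(1 + (f/10)^8)`, so
the two-pass -3 dB point sits near 8 Hz; quoting the per-pass cut-off
matches common biomechanics practice.  Endpoints use odd-reflection
padding of `3 * order` samples with steady-state initial conditions, so
constants pass through exactly.  Derivatives are central differences
(one-sided at the ends) in m/s.

## Gait events and cycles

Following the velocity-threshold method for hoof-marker kinematics,
stance is any maximal run of frames whose sagittal-plane hoof speed
`sqrt(v_y^2 + v_z^2)` stays below 50 mm/s (the method's original
threshold; configurable).  Runs shorter than 0.1 s are treated as
threshold chatter and absorbed into the longer neighbouring phase.  A
foot strike is a swing-to-stance transition, a toe off the reverse; the
first run of a trial has no preceding phase and therefore yields no
event.  Cycles run strike-to-strike (stance first), matching how stance
and swing are reported.  One cycle per limb per trial is analysed: the
one whose mid-cycle hoof position lies nearest the capture-volume
centre, ties to the earlier cycle.

## Kinematic outcome measures

Global parameters are whole-trial means: forward velocity of T1 and the
vertical offsets HEAD-T1, T1-T13, T13-L7 plus the lateral HEAD-T1
offset.  Limb parameters are computed on the extracted cycle: phase
durations and ratios, stride length (hoof progression displacement
strike to strike), hoof height range and lateral x-range in swing, mean
absolute forward/vertical hoof swing velocities, the mean planar
left-right hoof distance while both limbs of a pair are in stance, and
per-joint minima/maxima/ranges within stance and swing.  Joint angles
are planar: both segment vectors are projected to the sagittal plane,
and the angle is the signed rotation from proximal to distal vector — 0
at full extension, negative in flexion, a convention chosen to match the
reported stifle excursions (about -81 to -35 degrees in swing).  Where a
named measure had no published definition (hoof lateral deviation,
swing velocities, inter-limb stance distance), the definitions above are
fixed and documented rather than guessed per analysis.  Four-marker
joints take the first listed marker pair as the proximal vector and the
second as the distal.  Session-level values are means over the trials
reconstructed for that session.

## The synthetic gait generator

`generate_trial()` builds a trial from a `gait_design()`: hooves are
exactly stationary in stance and advance by one stride per cycle along a
smooth lift-and-advance path; the trunk advances at the design velocity
with a small vertical oscillation; limb chains are placed by planar
forward kinematics from the hoof upward so that the joint angles the
kinematics module computes reproduce the designed waveforms.  Defaults
are the healthy condition: 1.28 m/s, cycle 0.77 s, stance 0.41 s, the
implied ~98.6 cm stride, 5 cm hoof lift, lateral-sequence phasing
(HL_L 0, FL_L 0.25, HL_R 0.5, FL_R 0.75), head ~12 cm above and ~3 cm to
the right of T1, and per-joint phase extremes including the published
stifle values.  `stroke_effect_preset()` injects the observed 3-day
deficits (velocity -0.28 m/s, head drop -8.21 cm, stance +0.13/+0.14/
+0.13/+0.12 s, swing +0.02/+0.02/+0.03/+0.03 s, fetlock swing range
-3.9/-3.31/-8.34/-8.19 degrees for FL_L/FL_R/HL_L/HL_R).  Because steady
gait needs one shared cycle duration while the per-limb deltas differ
slightly, the applied cycle duration is the mean of the per-limb totals
and the residual differences are absorbed into per-limb duty factors, so
each limb's stance duration is realised exactly.

Two numerical choices make the generator and the measurement chain
mutually consistent, and both are fixed constants rather than tuning
knobs:

* **Swing advance profile.**  The swing velocity is a `sin^4` hump
  carrying the stride plus a square-root "approach taper" to a low
  plateau (0.27 m/s forelimbs, 0.30 m/s hindlimbs, over 17% of swing at
  each edge).  A 10 Hz zero-lag filter necessarily smears any velocity
  transition over tens of milliseconds; the taper shapes the filtered
  hoof speed so it crosses the 50 mm/s threshold at the true phase
  boundary.  With it, detected stance and stride on noiseless trials
  match the design within one frame (5 ms) for every limb, healthy or
  post-stroke.  The fore/hind distinction reflects the different
  sub-frame alignment of their phase boundaries (and, loosely, the
  firmer forelimb touch-down of a walking sheep).
* **Joint waveforms.**  Each phase's angle curve is a baseline with two
  raised-cosine bumps (maximum centred at 0.28, minimum at 0.72 of the
  phase, width 0.56), so the designed extremes are attained exactly at
  the bump centres with no overshoot, and the waveform's spectral
  content stays low enough that filtering moves the extremes by less
  than 0.5 degrees.  Waveform extremes must leave a few degrees of
  margin around the inter-phase baseline; the defaults do.

The noise model adds white marker noise (0.5 mm), a random-phase
skin-motion sinusoid (2 mm at 3 Hz) and random occlusion gaps
(2e-4 per marker-frame, mean 4 frames), all reproducible from one seed.
What the generator does *not* emulate: genuine skin-tissue dynamics,
soft-tissue wobble correlated across markers, labelling errors,
camera-dependent occlusion geometry, or within-trial speed drift.
Passing tests on synthetic data therefore demonstrate correctness of the
processing chain, not robustness to every artefact of live capture.

Cohorts (`generate_cohort()`) draw per-animal random effects once
(velocity SD 0.15 m/s, cycle SD 0.03 s, head height SD 2 cm by default —
free parameters, since the published inter-trial variability is not
decomposed) and share them across sessions; post sessions apply the
stroke effect.  For mixed-model studies at scale, the measure-level
simulator `simulate_stance_cohort()` generates session values directly
(animal intercept SD 0.03 s, per-trial residual SD 0.03 s averaged over
5 trials), which is the appropriate level for validating the statistics
without paying marker-level cost.

## Neurological scoring

The rubric encodes ten criteria: demeanour (0-3); five behaviour items
(food debris 0-1, torticollis 0-1, partial fetlock/carpus flexion 0-1,
ataxia/dysmetria 0-3, circling 0-2); three lateralised postural tests —
hemi-standing 0-4 per side with a 0.25 knuckling modifier per limb (two
limbs per side), forelimb hopping 0-2 per side with one knuckling
modifier, lateral dragging 0-2 per limb with 0.25 partial-correction and
0.25 drag-on-return modifiers per limb; and wheelbarrowing 0-2.
Subscores are demeanour, behaviour (sum of 2-6), postural left/right
(side-wise sums of 7-9) and wheelbarrow; the total is their sum.  Read
literally, the rubric's maximum is 11.75 per postural side and 36.5 in
total, while the protocol text states 36; the package computes the
maximum from the rubric structure and reports the half-point discrepancy
(`rubric_max()`) instead of silently resolving it.  Score sheets are
long-format CSVs (`animal, session, criterion, component, value`) so
modifiers stay separable from base scores; base scores must be integers
in range and modifiers multiples of 0.25.

## Statistics

* **Percentiles** follow the convention of the study's analysis
  software: for `n*p` integral, the mean of order statistics `n*p` and
  `n*p + 1`, else order statistic `ceiling(n*p)`.  This is what
  reproduces the published infarct-volume summary 2.7 (1.4-11.9) cm^3
  from the shipped values; a linear-interpolation variant is provided
  for comparison.
* **ICC(A,k)** — absolute agreement, mean of k = 3 sessions, two-way
  model — is computed from the mean-squares decomposition.  Parametric
  confidence limits use the F-based single-rating bounds mapped through
  the Spearman-Brown relation; bootstrap limits resample animals with
  replacement (2000 resamples, percentile method, seeded).
* **Velocity adjustment** regresses a measure on the session mean
  forward velocity (one slope over the analysis set) and reports
  residual + grand mean, removing the self-selected walking-speed
  confound before repeatability or mixed-model analysis.
* **Pre/post mixed models** average the three baselines into one pre
  value per animal and side, then fit `value ~ time * side + (1 |
  animal)` by REML; per-side post-minus-pre contrasts come from the
  fixed-effect estimates with Wald normal-approximation intervals and
  p-values (a single fixed inference choice, stated in the output).
  A grouping factor (sex, infarct-size class) can replace time for
  between-group analyses, optionally velocity-adjusted.  Singular fits
  (zero animal variance) warn and report the variance as zero.
* **PCA** operates on the correlation matrix of complete cases.
  Variables are first pruned while any |r| > 0.85 (the member with the
  larger mean absolute correlation leaves, ties to the later column),
  then screened by iteratively dropping the lowest per-variable KMO
  below 0.5.  Components with eigenvalue > 1 are retained; loadings are
  unit-norm eigenvectors with PC1 anchored to load positively on the
  total neurological score (remaining components flip their largest
  loading positive).  Bartlett's sphericity statistic is
  `-(n - 1 - (2p + 5)/6) ln det(R)` on `p(p-1)/2` degrees of freedom.
  A two-variable matrix has per-variable KMO exactly 0.5 and an identity
  matrix is assigned KMO 0 by convention.  No factor rotation and no
  multiple-testing correction are applied, matching the reported
  analysis.

## The shipped post-stroke table

`poststroke_pca_table()` returns the 20-animal, 8-variable table used for the
published PCA (infarct volume, total neuroscore, mean velocity, mean
head-to-T1, three forelimb durations, and a left-fetlock swing minimum),
shipped verbatim.  Recomputing the PCA from these printed values
reproduces the retention structure (exactly two components past the
Kaiser rule) and most PC1 loadings to within a few hundredths, but not
the printed summary statistics: this build obtains PC1 = 49.4% (51.5%
published), overall KMO 0.587 (0.67) and Bartlett chi-squared 95.0
(91.7), with the discrepancy concentrated on the fetlock variable, whose
printed column (a swing minimum) disagrees with the loading table's
label (a stance minimum).  The package computes from the printed data
and leaves the disagreement visible — the acceptance-level tests assert
the published values and fail honestly on those quantities.

## Problem sizes and determinism

The test-suite and acceptance runs use noiseless or lightly noised
trials of 3-6 cycles, cohorts of 2-24 animals and 20 replicate fits —
sizes at which every stage's contract (1-frame timing, 1 mm stride,
0.5 degree angles, CI coverage) is already binding.  All randomness
flows from explicit seeds; `run_study()` stamps every output with a hash
of its configuration, and regenerating with the same seed reproduces
files byte-for-byte.

## Known limitations

Joint angles are 2D sagittal projections relative to the global frame,
not 3D anatomical-frame rotations, so out-of-plane walking inflates
angle error; trials with more than 0.5 m of lateral T1 drift are
excluded by default.  The cyclic gap-fill assumes locally periodic
motion and will mis-fill aperiodic segments.  The generator's consistency
contract is verified for waveform excursions of the defaults' magnitude
with a few degrees of baseline margin; extreme waveforms (phase extremes
approaching +/-120 degrees, or maxima within ~1 degree of the
inter-phase baseline) recover less accurately through the 10 Hz filter.
ICC confidence limits can be erratic below ~6 subjects.
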