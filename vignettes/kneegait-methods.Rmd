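---
title: "Methods: from raw 9-DoF streams to knee-specific outcome parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw 9-DoF streams to knee-specific outcome parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`kneegait` turns raw recordings from three body-worn inertial units (pelvis,
thigh, shank of the operated limb) into the gait parameters used to judge a
knee replacement: spatiotemporal values, knee flexion statistics, stair and
timed-up-and-go metrics, knee angular-velocity "power" during sprinting and
abrupt stopping, a knee-stability surrogate, step symmetry, and fatigue
trends. This vignette documents the model behind each stage, the parameters
that matter, the numerical choices, and what the bundled simulator does and
does not emulate.

## Orientation estimation

Each sensor's orientation (unit quaternion, sensor frame to a world frame
with z up and magnetic-north x) is estimated by a complementary filter
(`estimate_orientation()`):

* **Propagation.** The gyro is integrated as
  $q_{k+1} = q_k \otimes \exp(\tfrac{1}{2}(\omega_k - \hat b)\,\Delta t)$.
  On noise-free input with zero gain this is exact, which the tests exploit
  by comparing against closed-form integration.
* **Correction.** At every update the estimate is rotated toward the
  accelerometer/magnetometer attitude along the measured error direction,
  at most `gain` radians per second (default 0.033) and never past the
  error itself. A bounded rate budget — rather than a fixed fractional
  correction — caps how fast residual linear accelerations during swing can
  corrupt the attitude, while remaining ample for absorbing gyro bias.
* **Gating.** Accelerometer corrections are hard-gated when the specific
  force deviates from $g$ by more than `acc_gate` (default 0.5 g) and
  soft-weighted by two confidence ramps: full trust only very near 1 g and
  at low angular rate, a down-weighted loose ramp otherwise. The
  magnetometer error vector is applied with weight `mag_weight` (default
  0.5); the magnetometer is unit-normalised, so the output is invariant to
  its scale.
* **Bias.** During sustained standstill (|ω| < 0.05 rad/s for 0.4 s) the
  gyro reads its own bias; it is captured with a 0.5-s low-pass, the way
  commercial IMUs capture bias at standstill. A slow magnetometer-driven
  integral absorbs residual drift during motion.
* **Initialisation.** The first `init_window` seconds (default 0.5 s) are
  assumed quasi-static — the protocol prescribes standing before activity —
  and a TRIAD construction (accelerometer fixes "up", magnetometer fixes
  heading) provides $q_0$.

**Known limitation.** Rotation about the local magnetic-field axis is
unobservable to the magnetometer, and during continuous walking the
accelerometer rarely sees clean gravity. On the longest uninterrupted
walking bouts the absolute thigh/shank attitude can therefore accumulate a
few degrees of error about that axis for unfavourable bias directions. The
error is common-mode between thigh and shank: the *relative* orientation —
from which every knee metric is computed — stays well under a degree, which
is what the test suite asserts.

## Anatomical calibration

The calibration capture set (`estimate_segment_frames()`) consists of 5 s of
upright standing and three quasi-static supine poses at nominal knee flexion
angles (defaults 0°, 45°, 90° — user-supplied, since any three well-spread
angles work). For a hinge joint the thigh-relative shank orientations of the
three poses differ by rotations about the (segment-fixed) flexion axis, so
the axis is estimated as the dominant direction (SVD) of the pairwise
relative rotation vectors, sign-aligned so that rotating from the most
extended to the most flexed pose is positive — i.e. knee flexion is
positive. The standing capture defines the zero-flexion reference, the
pelvis neutral attitude, and — with the axis — the mediolateral and
anteroposterior plane directions (sagittal = plane normal to the flexion
axis; coronal = plane spanned by the vertical and the flexion axis).

Degenerate inputs (poses spanning less than 15° of rotation, e.g. the
standing capture reused three times) are rejected as "degenerate
calibration", and captures with gyro RMS above 0.05 rad/s are rejected as
not quasi-static (that threshold separates held poses from motion at
consumer-IMU noise levels). Sensors are deliberately simulated with
non-trivial mounting misalignment so this stage is exercised for real.

## Knee and pelvis kinematics

Knee flexion is the swing–twist angle of the thigh-relative shank rotation
about the calibrated axis, zero at the standing reference
(`knee_flexion_series()`). Swing–twist is exactly invariant to
ab/adduction cross-talk about the perpendicular axes, which is why it is
preferred over a full three-angle Euler sequence: only flexion is reported
clinically. Knee angular velocity is the gyro difference resolved in the
thigh frame via the orientation tracks — differentiating measured rates
rather than estimated angles avoids amplifying orientation noise. Pelvic
tilt (sagittal lean) and obliquity (sidewise bend) are the components of the
pelvis rotation relative to standing about the mediolateral and
anteroposterior world axes (`pelvis_series()`).

## Event detection

* **Heel strike / toe-off.** The shank gyro projected on the flexion axis,
  low-pass filtered at 6 Hz and sign-normalised so the mid-swing peak is
  positive, crosses zero downward at heel strike and upward at toe-off.
  Crossings are sub-sample interpolated. This rule was chosen over
  accelerometer impact peaks because it behaves identically for walking and
  running. Intervals yielding fewer than four strides are rejected as "too
  short to analyze".
* **Strides.** Consecutive heel strikes bound strides; the first and last
  `n_exclude` (default 2) strides of every interval are *flagged* excluded,
  never dropped — gait is not yet steady there.
* **Single-leg support** of the instrumented limb is approximated as the
  10–50 % fraction of each gait cycle after ipsilateral heel strike. With
  no sensor on the contralateral limb the contralateral events cannot be
  observed directly; this window is the normal-gait expectation and is the
  documented approximation behind the stability metric.
* **Stairs.** Staircase steps alternate feet, so the time per stair step is
  half the interval between successive ipsilateral contacts. Flexion at
  heel strike is sampled at the contact. A stair interval whose median
  contact flexion is below 5° does not look like stair gait (level walking
  lands essentially straight-kneed; stair gait lands visibly flexed even in
  the arthritic condition) and is flagged `low_confidence`.
* **TUG.** Sit-to-stand begins when the (2-Hz low-passed) pelvic tilt
  leaves a 2° band around the seated baseline and ends when it comes within
  2° of the upright reference; stand-to-sit is symmetric. The half-way turn
  is read from the pelvic heading; walk-out/walk-back fill the gaps.

## Activity metrics

Spatiotemporal values use the annotated path length $L$: speed $= L/T$,
cadence $=$ step count $/T \times 60$, step length $= L/$ step count, with
steps counted as pelvic tilt-oscillation peaks (two per stride). This makes
the triplet internally consistent by construction —
$|$step length $- 60\,v/$cadence$| \le 0.05$ m is asserted on every analyzed
session and on every row of the bundled cohort table. "Power of
acceleration/deceleration" is defined as the peak knee angular-velocity
magnitude in the acceleration and stop sub-windows of the sprint interval
(configurable to the 95th percentile); the split point is the last time the
low-passed pelvic gyro-magnitude envelope is within 90 % of its maximum — a
proxy for peak forward speed, after which the envelope collapses into the
stop. Stability amplitudes aggregate per-stride single-leg-support peaks
with the median (robust to single missteps); spatiotemporal values use the
mean (they are reported as means in outcome tables). The fatigue trend is
the least-squares slope of per-stride evasive excursion (peak-to-peak
obliquity + tilt) against time, in deg/min, over walks of at least 60 s.

## Outcome analysis

`delta_table()` computes per-patient post−pre deltas and cohort means over
patients with both timepoints. KSS bands are <60 poor, 60–69 fair, 70–79
good, 80–100 excellent; OKS bands 0–19, 20–29, 30–39, 40–48 — the standard
published bandings, verified in the tests to reproduce all 24 labels of the
bundled cohort. Correlations default to Spearman: n = 6 and ordinal scores
make rank correlation the defensible choice, and no p-values or
multiple-testing corrections are attached — at this cohort size the
correlations are descriptive. The bundled walking table's speed/cadence/
step-length columns are mutually consistent; note that cohort means
computed from the tables (e.g. a step-length delta of 0.067 m) are the
package's reference statistics, and summary figures quoted elsewhere that
round per-patient values first may differ slightly.

## The simulator: what it emulates, what it does not

`simulate_session()` builds each activity from a sagittal-plane kinematic
chain: a designed shank angular-velocity profile (slow stance lobe, fast
opposite swing lobe, zero crossings exactly at toe-off and heel strike), a
knee flexion waveform of raised-cosine bumps (stance bump 17°, swing peak =
configured maximum, snapped to the sample grid so the configured maximum is
attained exactly), and the thigh defined through the hinge relation. The
pelvis carries one tilt bump per step (alternating intervals implement step
asymmetry), a stride-frequency obliquity oscillation whose amplitude grows
with `fatigue_slope`, and seated/upright tilt ramps for the TUG. IMU signals
are synthesised exactly: the gyro is the relative rotation between
consecutive samples (so noise-free integration is exact), the accelerometer
sees gravity plus the attachment-point linear acceleration from rigid lever
arms (thigh sensor 20 cm above, shank sensor 20 cm below the joint line),
and the magnetometer a homogeneous field with 60° dip. Activities are
joined by C¹ standing blends.

Default conditions are the cohort's: pre-surgery walking at 110 steps/min ×
0.65 m (1.19 m/s), running 1.66 m/s, sit-to-stand 2.2 s, stand-to-sit
2.5 s, stair step 0.56 s; post-surgery 120 × 0.70 (1.40 m/s), 2.13 m/s,
1.7 s, 1.9 s, 0.48 s. Sensor noise is typical of consumer IMUs: gyro
0.01 rad/s, accelerometer 0.15 m/s², gyro bias 0.005 rad/s in a fixed
seeded direction per sensor.

Two simulator semantics deserve explanation:

* **Transfer durations.** The seated-to-upright pelvic tilt ramp is a
  raised cosine whose span is scaled so that the 2°-band crossing interval —
  the quantity the detector measures — equals the configured duration
  exactly. The ground truth is therefore analytic, and detector error is
  attributable to estimation noise alone.
* **Abrupt stop.** The stop window (default 0.5 s) contains a sharp
  flexion catch concentrated in its first quarter, producing the violent
  knee-velocity transient that makes an abrupt stop mechanically demanding.

Not emulated: soft-tissue artefact (sensors are rigidly attached — the tape
fixation the protocol uses minimises, but does not eliminate, skin motion),
magnetic disturbances (the pipeline deliberately limits its dependence on
magnetometer fidelity, but indoor field inhomogeneity would add heading
error), double support and contralateral events (no contralateral sensor),
and inter-subject variability of waveform shape. Passing the recovery tests
therefore demonstrates the pipeline's correctness on idealised signals with
realistic sensor error — not its robustness to skin motion or magnetic
clutter, which only real recordings can show.

## Problem sizes and tolerances

The test suite and the acceptance script run the full pipeline at desk
scale: 40-m walks (about 35 strides), 12-step stair flights, single TUG
repetitions, 70-s warm-ups for the fatigue regression, 100 Monte-Carlo
seeds for calibration noise, and 20 seeded sessions for parameter recovery.
These sizes keep a complete run in tens of seconds while leaving every
estimator with ample support; the full protocol (2-min warm-up, 100-m walk,
50-m run, four stair flights, TUG ×3) is the default for
`simulate_session()` and is exercised end-to-end in the protocol test.
Numerical tolerances follow the measurement resolution: event timing is
asserted to 30 ms (three samples), stride-aggregated angles to 3°,
transfer durations to 0.15 s, and closed-form identities (quaternion
integration, the $2\pi f A$ angular-velocity peak) to machine precision or
the stated 2 %.
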