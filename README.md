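# kneegait

Mobile inertial gait analysis for outcome measurement after knee
arthroplasty.

Clinical scores (KSS, OKS) and stationary gait labs are the usual yardsticks
for judging a knee replacement, but they miss what active patients care
about: running, stopping abruptly, stairs, fatigue over real walking
distances. A three-sensor inertial setup — one 9-DoF unit (triaxial
accelerometer + gyroscope + magnetometer) on the lumbosacral junction, one
on the thigh and one on the shank of the affected limb — can measure those
activities outside the lab. `kneegait` implements the complete analysis
chain for such recordings, plus a parametric gait simulator so every stage
is testable without patient data:

1. **Session I/O** — CSV sensor streams, annotation tracks with known path
   lengths, calibration captures, clinical score tables, YAML session
   manifests (`read_stream()`, `read_session()`, `write_report()`).
2. **Orientation fusion** — a complementary quaternion filter
   (`estimate_orientation()`): gyro integration, corrected toward the
   accelerometer (tilt, gated during high dynamics) and magnetometer
   (heading) with a bounded angular-rate budget, standstill gyro-bias
   capture, TRIAD initialisation from the first quasi-static 0.5 s.
3. **Anatomical calibration** — the knee flexion axis is identified
   functionally from three supine flexed-knee captures as the dominant axis
   of the pairwise thigh-relative shank rotations; 5 s of upright standing
   defines zero flexion and the pelvic neutral (`estimate_segment_frames()`).
4. **Joint kinematics** — knee flexion as the swing–twist angle of the
   thigh-relative shank rotation about the calibrated axis; knee angular
   velocity from the gyro difference resolved in the thigh frame; pelvic
   tilt/obliquity series (`knee_flexion_series()`, `pelvis_series()`).
5. **Event detection** — heel strikes and toe-offs from zero crossings of
   the sagittal shank angular velocity around the mid-swing peak; stair
   steps from ipsilateral contacts (time per step = half the contact
   interval); instrumented TUG phases from the pelvic tilt leaving/entering
   2° bands around the seated and upright references
   (`detect_gait_events()`, `detect_stair_steps()`, `segment_tug()`).
6. **Activity metrics** — walking/running speed, cadence and step length
   over the annotated path length (speed = L/T, steps counted from pelvic
   oscillations, two per stride); per-stride maximum knee flexion with
   initial/final strides excluded; stair times and flexion at heel strike;
   sit-to-stand / stand-to-sit durations; "power" of acceleration and
   deceleration as the peak knee angular-velocity magnitude in the sprint
   and abrupt-stop windows; knee-stability surrogate as the coronal shank
   gyro amplitude during single-leg support; step symmetry; evasive-movement
   fatigue slope (`analyze_session()`).
7. **Outcome analysis** — per-patient pre/post deltas, cohort means,
   KSS/OKS quality banding, Spearman correlations between gait metrics and
   clinical scores (`delta_table()`, `band_scores()`, `correlate()`). A
   six-patient example cohort (pre / 12-months-post) ships with the package
   (`cohort_tables()`).
8. **Simulator** — `simulate_session()` / `simulate_protocol()` generate
   full annotated 9-DoF sessions (2-min warm-up, TUG ×3, 100-m walk, 50-m
   run, sprint with abrupt stop, four stair flights) from a sagittal-plane
   kinematic leg model with ground-truth events, angles and parameters,
   configurable joint instability, fatigue drift, step asymmetry, sensor
   noise, bias and mounting misalignment.

## Worked example

```r
library(kneegait)

params  <- default_params("pre", seed = 42, walk_path_m = 40)
session <- simulate_session(params,
                            activities = c("walk", "stairs_down", "tug"),
                            seed = 42)
res <- analyze_session(session)
round(t(res$row[, -(1:2)]), 2)
```

```
walking_speed                       1.15
cadence                           110.00
step_length                         0.62
symmetry_index                      1.00
max_knee_flexion_mean              57.87
stability_coronal                   1.27
stability_sagittal                  2.10
stairs_time_per_step_down           0.56
stairs_max_flexion_down            75.03
stairs_flexion_at_heelstrike_down  13.97
tug_sit_to_stand                    2.13
tug_stand_to_sit                    2.53
tug_max_transfer_flexion           88.92
tug_evasive_excursion               9.04
```

The pre-surgery defaults walk at 110 steps/min with a 0.65-m step; the
pipeline recovers the cadence exactly and the walking speed (1.15 m/s over
the 40-m annotated path), the 58° swing-phase flexion ceiling, the 0.56-s
stair step time, and the 2.2-s / 2.5-s transfer durations within the
detector's resolution. The coronal stability amplitude (1.27 rad/s) reflects
the simulated pre-operative joint instability; it falls towards zero as the
`instability_gain` parameter is reduced.

Outcome statistics on the bundled cohort:

```r
tabs <- cohort_tables()
w <- split_timepoints(tabs$walking)
delta_table(w$pre, w$post)
```

```
<outcome_report> cohort mean deltas:
        metric   mean_pre   mean_post  mean_delta n
 walking_speed   1.221667   1.4400000  0.21833333 6
       cadence 110.333333 120.6666667 10.33333333 6
   step_length   0.650000   0.7166667  0.06666667 6
 running_speed   1.661667   2.1333333  0.47166667 6
```

```r
correlate(tabs$walking$running_speed_post, tabs$scores$oks_post)
#> [1] 0.9428571
```

Twelve months after surgery the cohort walks on average 0.22 m/s faster at
10 more steps per minute, and the fastest feasible running speed correlates
strongly (Spearman ρ = 0.94) with the patient-reported Oxford Knee Score —
the load-limit activities, not comfortable walking, track the clinical
outcome.

## Command line

A thin wrapper over the same functions lives in `inst/cli/kneegait.R`:

```sh
Rscript inst/cli/kneegait.R simulate --out sim_dir --seed 1
Rscript inst/cli/kneegait.R analyze  --in sim_dir/sim_pre_session.yaml --out metrics_dir
Rscript inst/cli/kneegait.R report   --in pre.csv --post post.csv --scores scores.csv --out report_dir
```

Exit codes: 0 ok, 2 validation error, 3 detection failure.

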