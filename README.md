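# mocapfuse

Markerless human pose tracking by fusing sparse 3D lidar point clouds with
wearable IMU orientation streams, for motion-capture, gait-analysis and
rehabilitation tooling where optical systems are impractical.

The two sensor families are complementary:

* **IMUs** (10 body-worn sensors, 60 Hz unit quaternions) measure bone
  *orientations* accurately but positions only by dead reckoning, which
  accumulates displacement drift;
* **lidars** (two 16-channel scanners, 360° × ±15° field of view, 10–20 Hz)
  measure *positions* directly but far too sparsely for articulation.

`mocapfuse` implements the full pipeline:

1. **Calibration** — the subject's height `Ah` is estimated from the
   ceiling lidar: octree-style change detection isolates the user cloud
   `Pt` from a reference scan, the ground point `g` is the deepest return,
   the mounting-tilt floor slope is `m = (maxy − gy)/(maxx − gx)`, and

   `Ah = (gy − miny) + cx · m`.

2. **Skeleton** — a 16-joint / 15-segment tree whose lengths derive from
   the head unit `Hh = Ah / 7.5`.

3. **Kinematics** — streams are aligned by the attention-pose frame,
   `Aq_i = q_i q_0^{-1}` (cancelling constant mounting offsets); the bone
   direction is the conjugation `Rv = Aq (0, v̂) Aq^{-1}`; joints chain by
   `P_c = P_n + Jv̂ · S_length`, bottom-up from the stance foot to the
   pelvis, then top-down to all extremities.

4. **Fusion** — a per-leg particle filter tracks the lower-leg clusters in
   the real-time clouds; whenever the solved stance foot strays from the
   lidar-detected foot beyond a threshold `δ = 10 cm`, the whole pose is
   rigidly snapped back, bounding drift by `δ`.

A capsule-body lidar simulator and motion generator (`simulate_session()`)
provide fully ground-truthed synthetic sessions, so everything is testable
without hardware.

## Worked example

```r
library(mocapfuse)

# simulate a 6 s squat session: reference scan, calibration clouds,
# 15 Hz lidar frames, 60 Hz IMU quaternions, and exact ground truth
ses <- simulate_session("squat", duration = 6, height = 1.75, seed = 5)

# calibrate: height and skeleton from the clouds alone
cal <- calibrate_session(ses$reference, ses$calib_clouds,
                         ses$sensors$l1_transform)
cal$height
#> [1] 1.758137

# fused tracking against the calibrated skeleton
trk <- track_sequence(ses$imu, ses$clouds, cal$skeleton, fusion_config(),
                      seed = 1, reference = ses$reference,
                      init_pose = ses$init_pose)
err <- joint_position_error(trk, ses$truth)
err$overall_mean_cm
#> [1] 0.4107862
```

The estimated height is within 1 cm of the true 1.75 m (1 cm lidar range
noise, 1° ceiling-mount tilt), and the mean per-joint error of the fused
track is ≈ 0.4 cm — dominated entirely by the 0.5 % segment-length error
the calibrated height induces; with the true skeleton the squat closes to
machine precision. Walking sequences add stance hand-off dead reckoning,
and the 14-key-pose replication with 1° IMU noise lands at ≈ 2.5 cm mean
error; with an injected 0.05 m/s base drift the stance-foot error stays
bounded by δ = 10 cm (see `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`).

Export and inspection:

```r
write_bvh(trk, cal$skeleton, "walk.bvh")     # motion-capture export
write_pose_csv(trk, "walk.csv")
trk$diagnostics                               # stance foot, corrections, flags
```

## Command line

```sh
inst/cli/mocapfuse simulate --kind walk --duration 10 --height 1.75 --seed 1 --out session/
inst/cli/mocapfuse calibrate --session session/
inst/cli/mocapfuse track --session session/ --out track.csv --bvh track.bvh
inst/cli/mocapfuse evaluate --track track.csv --truth session/ground_truth.csv --out report
```

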