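---
title: "Fusing lidar and inertial sensors for human pose tracking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing lidar and inertial sensors for human pose tracking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mocapfuse)
```

## The problem

Wearable IMUs measure bone-segment *orientations* superbly (gimbal-free, 60 Hz,
unit quaternions) but give no direct position: joint positions must be dead
reckoned through the kinematic chain, so any error in which foot is planted,
or in where that foot is, accumulates as **displacement drift**. Scanning
lidars measure *position* directly but sparsely (16 scan lines, one cloud
every 1/10–1/20 s), too sparsely to observe elbow or spine articulation.
`mocapfuse` implements the complementary fusion: the skeleton and the
subject's height come from the lidar point cloud, the articulated pose comes
from quaternion forward kinematics over the IMU streams, and the lidar's view
of the lower legs pins the pose to the world, bounding drift by a threshold
`delta` (10 cm).

## Body model

The skeleton is a tree of 16 joints and 15 segments `b1..b15` rooted at the
pelvis. All lengths derive from the subject's standing height `Ah` through
the head unit `Hh = Ah / 7.5` (an average body is 7.5 heads tall). The
published anthropometry behind that rule does not fix every segment, so the
default proportion table (`default_proportions()`) is a documented stand-in
whose vertical chain — foot, knee, hip, pelvis, spine, torso, head, plus one
head unit above the head joint — sums to exactly 7.5 head units; users can
substitute any published table via the `proportions` argument or the session
config, subject to the same constraint.

Ten segments carry an IMU. The five remaining segments follow a trunk
sensor: the two torso–shoulder offsets and the spine–torso segment copy the
upper-trunk sensor (`b1`), the two pelvis–hip offsets copy the lower-trunk
sensor (`b2`). With 16 joints there are only two sensed trunk segments, so
this mapping is forced once the derived set is fixed.

## Orientation processing

Sensors are strapped on with arbitrary constant mounting offsets. The
calibration contract is one upright *attention pose* held at frame 0; every
stream is aligned by its first sample, `Aq_i = q_i q_0^{-1}`, which cancels
any constant right-multiplied offset exactly (verified to 1e-9 in the test
suite). Streams are renormalized and sign-continuized on ingest because unit
quaternions double-cover rotations.

A segment's current direction is the conjugation `Aq (0, v) Aq^{-1}` of its
rest direction `v`, and joints chain as
`P_current = P_neighbor + Jv * Slength` — *bottom-up* from the stance foot to
the pelvis (rotated rest directions negated, distal-to-proximal), then
*top-down* from the pelvis to all extremities. The round trip reproduces the
stance foot to 1e-9 m, and every solved pose preserves all 15 segment
lengths exactly, because each update is a pure direction-times-length step.

At a stance swap the new foot is anchored where the *current frame's*
solution (still anchored on the old foot) places it. Anchoring it at its
previous-frame position instead leaves a one-frame-stale error that shows up
as millimeter back-steps of the pelvis at every swap.

## Lidar processing

**Height.** The ceiling lidar's frame (`L1`) points `y` down, so the floor
has maximal depth. The ground point is the argmax-`y` return; the mounting
tilt makes the floor appear sloped, and the height formula
`Ah = (gy - miny) + cx * m` corrects for the slope at the subject's
location. Two numerical caveats drove design choices here:

* *Slope source.* The literal slope formula uses extrema of the
  change-detected user cloud, but voxel change detection removes user points
  sharing voxels with the reference floor, so the user cloud stops one voxel
  above the floor and the literal slope inherits an error of roughly
  voxel-size over user-distance. The calibration default therefore fits the
  floor band of the reference cloud (`slope_mode = "floor_fit"`), with the
  literal mode available as a config switch.
* *Extreme-value bias.* `gy` is a maximum and `miny` a minimum over noisy
  returns, so each is biased outward by ~2–4 noise standard deviations, and
  averaging per-frame *heights* does not remove the bias. The synthetic scan
  grid is deterministic, so the pipeline averages the calibration clouds
  ray-wise first (default 10 frames), shrinking the effective noise before
  the extrema are taken.

**Subject extraction.** Octree-style voxel differencing against the
reference scene, with the reference occupancy dilated by one voxel: with
centimeter range noise a few percent of all scene returns flip into a
neighboring voxel every frame, and without dilation the "user" cloud is the
whole room. Points of a genuinely new object at least three voxels from any
reference surface are never suppressed. The default voxel size is 0.05 m —
large against the 1 cm range noise, small enough to keep the lower ~10 cm of
the legs, which matter for foot tracking. A largest-cluster filter removes
stray survivors.

**Leg tracking.** Points below knee height (2 head units) are gated to
within 0.5 m of the previous pose's knees/ankles and assigned point-wise to
the nearer leg; the joint positions of the fused pose drive this assignment,
which is what keeps it stable when a leg swings out of the band. Each foot
is tracked on the ground plane by a particle filter (constant-position
motion model with diffusion `sigma_proc = 0.5 m/sqrt(s)`, Gaussian
likelihood `sigma_lik = 0.1 m`, 200 particles, systematic resampling). The
likelihood's target is the cluster's ground-plane observation: lidar samples
only the surface facing each sensor, so the raw centroid sits off the bone
axis by a fraction of the shank radius; the default observation de-biases
each return by the assumed shank radius (5 cm) along its horizontal viewing
direction, fits the principal axis of the de-biased cluster, and intersects
it with the floor — which also removes the forward offset of a tilted shank
(squats, swing phase). The plain centroid mode is kept for the filter's
convergence contract.

## Fusion

Per IMU frame the tracker selects the stance foot, solves the pose, and
compares the solved stance foot with the lidar one. Selection uses a
ground-contact cue first — the solved pose knows the two feet's *relative*
heights regardless of anchor, and a clearly lower foot (by 1.5 cm) is the
planted one — falling back to the smaller lidar displacement over a 15-frame
window, with a 1 cm/frame hysteresis band and a right-foot default at the
first frame. A leg with no usable cluster for 0.5 s is stale: it is never
selected over a fresh one and never attracts corrections.

The correction itself translates the *whole* pose rigidly (inter-joint
distances are untouched). Three modes are provided; the default is the
**gate**: correct (snap fully) only when the stance discrepancy exceeds
`delta`, leave it alone below. The alternative of blending sub-threshold
discrepancies looks smoother but converges the pose onto the lidar
observation's own bias — with a gate, a drift-free sequence is passed
through bit-exactly, while injected drift is still bounded: the
post-correction stance discrepancy can never exceed `delta` (above it, the
pose snaps to the lidar foot). `"blend"` and `"bound"` modes expose the
other readings of the threshold.

Between cloud frames the newest foot estimates are held (the causal
counterpart of offline linear resampling, which `resample_lidar_positions()`
provides and the contract tests cover); the output frame rate is always the
IMU rate.

## The synthetic world

The simulator emulates the stated hardware: two 16-channel lidars with 360°
horizontal and ±15° vertical field of view, 0.4° azimuth steps, range noise
std 1 cm (the ±3 cm hardware accuracy claim read as a 3-sigma band), 10–20
Hz clouds; ten 60 Hz IMUs with constant random mounting offsets and optional
small-angle orientation noise; an 8 × 4 × 3 m room. The ceiling sensor is
mounted over one end with a 1° tilt (the reason the slope correction
exists); the front sensor sits low (0.6 m) on the opposite wall so its scan
fan actually covers the legs. The body is a set of capsules (limbs ~5–7 cm,
trunk 14 cm, head 11 cm radius); clouds are exact ray–capsule/room
intersections plus range noise, so every session carries exact ground truth.

Motions: `attention` (static), `walk` (sinusoidal 8° leg swing, 2.4 s cycle
chosen as an integer number of 60 Hz frames so stance swaps land on
symmetric double-support frames; 30° swing-knee flexion lifts the swing foot
~6 cm, as real gait does; starts on the right foot to match the tracker's
documented first-frame default; ~0.22 m/s so a 30 s walk fits the room),
`squat` (feet fixed by symmetry), `key_poses_14` (fourteen held poses
spanning arm raises and rotations, trunk bends and twist, leg swings, squat
and knee flexion, ordered so stance transfers happen only while both feet
are grounded), and `walk_squat_pattern`.

What a green test does and does not establish: the simulator shares the
package's capsule geometry and quaternion conventions, so closure tests
verify the *pipeline's* internal consistency and its noise/drift behavior
under the stated sensor physics (angular quantization, one-sided surface
sampling, occlusion by the room geometry are all real in it). It does not
model soft tissue, clothing, reflectance dropouts, multi-path, or sensor
sync jitter; accuracy numbers on real hardware will be worse.

## Numerical choices and degenerate inputs

* Quaternions are Hamilton, scalar-first, active; all rotation code is
  tested against an independent rotation-matrix oracle.
* Zero-norm quaternions and zero rest vectors are rejected; stream norms
  beyond 1e-3 of unity are validation errors, smaller deviations are
  renormalized.
* The ground-point argmax breaks ties by smallest `x`, then `z`.
* `floor_slope` refuses a vertical reference line (`maxx = gx`).
* Empty clouds: change detection warns and returns an empty user cloud; leg
  clustering raises the occlusion signal; metrics refuse misaligned tracks.
* All randomness flows through per-call seeded generator streams that do not
  touch the session's global RNG state, so every pipeline output is
  bit-reproducible from (config, seed).

## Known limitations

* Stance-swap detection lags the true ground contact by a few frames; each
  swap contributes ~1 cm of dead-reckoning drift on a walk, which is exactly
  the drift the `delta` correction bounds (visible as occasional snaps in
  long walks even without injected drift).
* Orientation drift is not corrected — only displacement, from the feet.
* Airborne phases (running, jumping) violate the fixed-stance-foot
  assumption and are out of scope.
* The literal extrema-based slope mode is faithful to the published formula
  but interacts badly with voxel change detection (see above); it is not the
  calibration default.
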