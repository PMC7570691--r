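Package: mocapfuse
Title: Lidar and Inertial Sensor Fusion for Human Pose Tracking
Version: 0.1.0
Authors@R: person("Mocapfuse", "Developers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: Tools for markerless human motion capture that fuse sparse 3D
    lidar point clouds with wearable inertial measurement unit (IMU)
    orientation streams. The package estimates a subject's height and an
    anthropometric 16-joint skeleton from ceiling-mounted lidar scans,
    reconstructs full-body poses from per-segment unit quaternions by
    quaternion forward kinematics with bottom-up (stance foot) and top-down
    (pelvis) chain updates, tracks the lower legs in real-time point clouds
    with a particle filter, and corrects inertial displacement drift against
    the lidar-detected foot positions. A capsule-body lidar simulator and
    motion generator provide fully ground-truthed synthetic capture sessions
    for testing, plus readers and writers for PCD, PLY, quaternion CSV and
    BVH files and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
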