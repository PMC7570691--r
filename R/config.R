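#' Session configuration and session directories
#'
#' A session directory holds everything one capture needs:
#' `session.yaml` (sensor parameters, fusion parameters, proportions,
#' seed), `reference.pcd`, `frames/NNNNN.pcd` with a frame index CSV,
#' `imu.csv` and, for synthetic sessions, `ground_truth.csv`.
#'
#' @name config
NULL

default_config <- function() {
  list(
    seed = 1L,
    height = NA,
    start_position = c(2.2, 0),
    sensors = list(lidar_rate = 15, range_noise = 0.01, azimuth_step = 0.4,
                   channels = 16, vfov = 15, ceiling_tilt_deg = 1,
                   imu_rate = 60, imu_noise_deg = 0, imu_offsets = "random",
                   room = c(8, 4, 3)),
    fusion = list(delta = 0.10, blend = 0.2, stance_window = 15,
                  correction_mode = "gate", voxel_resolution = 0.05,
                  cluster_threshold = 0.15, n_particles = 200,
                  sigma_proc = 0.5, sigma_lik = 0.1, floor_z = 0),
    calibration = list(slope_mode = "floor_fit", n_frames = 10)
  )
}

#' Read a session config (YAML), merging package defaults
#' @param path YAML file; `NULL` returns the defaults.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

#' @rdname read_config
#' @param cfg config list to write.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

config_sensors <- function(cfg) do.call(sensor_model, cfg$sensors)

config_fusion <- function(cfg) {
  f <- cfg$fusion
  fusion_config(delta = f$delta, blend = f$blend,
                stance_window = f$stance_window,
                imu_rate = cfg$sensors$imu_rate,
                lidar_rate = cfg$sensors$lidar_rate,
                correction_mode = f$correction_mode,
                voxel_resolution = f$voxel_resolution,
                cluster_threshold = f$cluster_threshold,
                n_particles = f$n_particles, sigma_proc = f$sigma_proc,
                sigma_lik = f$sigma_lik, floor_z = f$floor_z)
}

#' Write a simulated session to a directory
#'
#' @param session result of [simulate_session()].
#' @param dir output directory (created).
#' @param cfg config list used to generate the session.
#' @export
write_session <- function(session, dir, cfg = default_config()) {
  dir.create(file.path(dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  write_point_cloud(session$reference, file.path(dir, "reference.pcd"))
  idx <- data.frame(path = character(0), timestamp = numeric(0),
                    kind = character(0))
  wr <- function(cl, name, kind) {
    write_point_cloud(cl, file.path(dir, "frames", name))
    data.frame(path = file.path("frames", name), timestamp = cl$timestamp,
               kind = kind)
  }
  for (i in seq_along(session$calib_clouds)) {
    idx <- rbind(idx, wr(session$calib_clouds[[i]],
                         sprintf("calib_%03d.pcd", i), "calibration"))
  }
  for (i in seq_along(session$clouds)) {
    idx <- rbind(idx, wr(session$clouds[[i]],
                         sprintf("frame_%05d.pcd", i), "realtime"))
  }
  utils::write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  write_quaternion_csv(session$imu, file.path(dir, "imu.csv"))
  truth_track <- pose_track(session$truth$times, session$truth$joints,
                            stance = session$truth$stance)
  write_pose_csv(truth_track, file.path(dir, "ground_truth.csv"))
  cfg$height <- session$skeleton$actual_height
  write_config(cfg, file.path(dir, "session.yaml"))
  invisible(dir)
}

#' Read a session directory
#'
#' @param dir session directory written by [write_session()] (or arranged
#'   manually in the same layout).
#' @return list: `cfg`, `sensors`, `reference`, `calib_clouds`, `clouds`,
#'   `imu`, and `truth` when `ground_truth.csv` is present.
#' @export
read_session <- function(dir) {
  cfg <- read_config(file.path(dir, "session.yaml"))
  sensors <- config_sensors(cfg)
  reference <- read_point_cloud(file.path(dir, "reference.pcd"),
                                variant = "reference")
  idx <- utils::read.csv(file.path(dir, "index.csv"), stringsAsFactors = FALSE)
  load_frames <- function(kind, variant) {
    sub <- idx[idx$kind == kind, ]
    lapply(seq_len(nrow(sub)), function(i) {
      read_point_cloud(file.path(dir, sub$path[i]), variant = variant,
                       timestamp = sub$timestamp[i])
    })
  }
  truth <- NULL
  gt_path <- file.path(dir, "ground_truth.csv")
  if (file.exists(gt_path)) {
    tr <- read_pose_csv(gt_path)
    truth <- list(times = tr$times, joints = tr$positions, stance = tr$stance)
  }
  list(cfg = cfg, sensors = sensors, reference = reference,
       calib_clouds = load_frames("calibration", "full_body"),
       clouds = load_frames("realtime", "realtime"),
       imu = read_quaternion_csv(file.path(dir, "imu.csv")),
       truth = truth)
}
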