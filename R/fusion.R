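#' Lidar/IMU fusion: timeline alignment, stance selection, drift correction
#'
#' Inertial pose solving accumulates displacement drift because the stance
#' foot's world position is only known by dead reckoning. The lidar foot
#' positions, linearly interpolated onto the IMU timestamp grid, anchor the
#' pose: whenever the solved stance foot strays from the lidar-detected
#' foot by more than the threshold `delta` (10 cm) the whole pose is
#' snapped onto it; smaller discrepancies are blended away smoothly. The
#' correction is a rigid translation, so inter-joint distances are never
#' altered.
#'
#' @name fusion
NULL

#' Fusion configuration
#'
#' @param delta drift threshold in meters (default 0.10).
#' @param blend blend coefficient in (0, 1] applied to sub-threshold
#'   corrections in `"blend"` mode.
#' @param stance_window window length, in IMU frames, for stance-foot
#'   selection.
#' @param imu_rate IMU rate in Hz.
#' @param lidar_rate lidar frame rate in Hz.
#' @param correction_mode `"gate"` (default): the threshold gates when a
#'   correction is applied at all — snap fully when the stance-foot error
#'   exceeds `delta`, leave the pose alone below it (sub-threshold
#'   discrepancies are dominated by the lidar observation's own bias, so
#'   chasing them couples the pose to lidar artifacts). `"blend"`: snap
#'   beyond `delta`, proportional blend below it (smooth but biased).
#'   `"bound"`: always correct, capping the translation at `delta`.
#' @param voxel_resolution change-detection voxel size (meters).
#' @param cluster_threshold leg cluster distance (meters).
#' @param n_particles,sigma_proc,sigma_lik particle-filter parameters.
#' @param leg_obs leg observation model, see [leg_ground_observation()].
#' @param floor_z floor plane height in the world frame.
#' @export
fusion_config <- function(delta = 0.10, blend = 0.2, stance_window = 15L,
                          imu_rate = 60, lidar_rate = 15,
                          correction_mode = c("gate", "blend", "bound"),
                          voxel_resolution = 0.05, cluster_threshold = 0.15,
                          n_particles = 200L, sigma_proc = 0.5,
                          sigma_lik = 0.1, leg_obs = c("axis", "centroid"),
                          floor_z = 0) {
  stopifnot(delta > 0, blend > 0, blend <= 1, stance_window >= 1,
            imu_rate > 0, lidar_rate > 0)
  structure(list(delta = delta, blend = blend,
                 stance_window = as.integer(stance_window),
                 imu_rate = imu_rate, lidar_rate = lidar_rate,
                 correction_mode = match.arg(correction_mode),
                 voxel_resolution = voxel_resolution,
                 cluster_threshold = cluster_threshold,
                 n_particles = as.integer(n_particles),
                 sigma_proc = sigma_proc, sigma_lik = sigma_lik,
                 leg_obs = match.arg(leg_obs), floor_z = floor_z),
            class = "fusion_config")
}

#' Resample lidar foot positions onto the IMU timestamp grid
#'
#' Componentwise linear interpolation. Query times outside the lidar span
#' are clamped to the nearest endpoint and flagged.
#'
#' @param times lidar timestamps, strictly increasing (>= 2 samples).
#' @param positions n x 3 matrix of positions at `times`.
#' @param query_times IMU timestamps.
#' @return m x 3 matrix with attribute `clamped` (logical vector).
#' @export
resample_lidar_positions <- function(times, positions, query_times) {
  if (length(times) < 2L) stop("insufficient track: need at least 2 lidar samples")
  stopifnot(!is.unsorted(times, strictly = TRUE),
            nrow(positions) == length(times))
  out <- vapply(1:3, function(j) {
    stats::approx(times, positions[, j], xout = query_times, rule = 2)$y
  }, numeric(length(query_times)))
  out <- matrix(out, ncol = 3L)
  attr(out, "clamped") <- query_times < times[1] | query_times > times[length(times)]
  out
}

#' Select the stance foot from recent foot motion
#'
#' Returns the foot with the smaller mean per-frame displacement over the
#' window; ties (displacements within `tol`, a hysteresis band that
#' prevents flapping between two nearly static feet) keep the previous
#' stance foot, and with no history the right foot is the default. A foot
#' whose lidar observation is stale (`right_ok`/`left_ok` FALSE) is never
#' selected over a fresh one.
#'
#' @param right_window,left_window k x 3 (or k x 2) matrices of recent foot
#'   positions, most recent last; `NULL` or fewer than 2 rows falls back to
#'   the previous stance foot.
#' @param previous previous stance foot id.
#' @param tol displacement tie tolerance in meters per frame.
#' @param right_ok,left_ok is the foot's observation fresh?
#' @export
select_stance_foot <- function(right_window, left_window, previous = "RFoot",
                               tol = 0.01, right_ok = TRUE, left_ok = TRUE) {
  if (right_ok != left_ok) return(if (right_ok) "RFoot" else "LFoot")
  if (is.null(right_window) || is.null(left_window) ||
      nrow(right_window) < 2L || nrow(left_window) < 2L) {
    return(previous)
  }
  disp <- function(w) mean(sqrt(rowSums(diff(w)^2)))
  dr <- disp(right_window)
  dl <- disp(left_window)
  if (abs(dr - dl) <= tol) previous else if (dr < dl) "RFoot" else "LFoot"
}

#' Correct displacement drift against the lidar feet
#'
#' Translates the whole pose by the stance-foot discrepancy
#' `e = lidar_foot - pose_foot` according to the configured mode (see
#' [fusion_config()]): in the default gate mode the pose snaps fully onto
#' the lidar foot when `|e| > delta` and is left untouched below the
#' threshold. After correction the stance-foot discrepancy never exceeds
#' `delta`.
#'
#' @param pose a `pose_frame` with stance annotation.
#' @param lidar_feet 2 x 3 matrix with rows `RFoot`, `LFoot`, or `NULL` /
#'   occluded (pose returned unchanged).
#' @param config a [fusion_config()].
#' @param occluded set `TRUE` to skip the correction for this frame.
#' @return corrected `pose_frame` with attribute `correction` (the applied
#'   translation).
#' @export
drift_correct <- function(pose, lidar_feet, config, occluded = FALSE) {
  stopifnot(inherits(pose, "pose_frame"))
  if (is.null(lidar_feet) || occluded || is.na(pose$stance)) {
    attr(pose, "correction") <- c(0, 0, 0)
    return(pose)
  }
  e <- lidar_feet[pose$stance, ] - pose$positions[pose$stance, ]
  nrm <- sqrt(sum(e^2))
  shift <- switch(config$correction_mode,
    gate = if (nrm > config$delta) e else e * 0,
    blend = if (nrm > config$delta) e else config$blend * e,
    bound = if (nrm > config$delta) e * (config$delta / nrm) else e)
  pose$positions <- sweep(pose$positions, 2, -shift)
  attr(pose, "correction") <- shift
  pose
}

#' Track a full capture sequence
#'
#' The complete fused pipeline: aligns the raw IMU stream by its
#' calibration frame, tracks the feet through the real-time clouds,
#' resamples the lidar foot track onto the IMU grid, and per IMU frame
#' derives the unsensed orientations, solves the pose from the current
#' stance foot and corrects drift. Without clouds the output degrades to
#' the inertial-only solution.
#'
#' @param imu_stream raw [quat_stream()] (attention pose at frame 0). A
#'   drift attribute attached by [inject_drift()] is honored.
#' @param cloud_stream list of real-time `pc_frame`s (world frame), or
#'   `NULL` for inertial-only tracking.
#' @param skeleton the skeleton.
#' @param config a [fusion_config()].
#' @param seed master integer seed.
#' @param reference optional reference cloud for change detection.
#' @param init_pose starting `pose_frame`; defaults to the attention pose
#'   at the origin.
#' @param stance optional known per-frame stance schedule overriding the
#'   lidar-based selection (used when evaluating the inertial-only path
#'   against ground truth, where no lidar observes which foot is planted).
#' @return a `pose_track` with per-frame diagnostics (stance foot,
#'   correction magnitude, post-correction stance discrepancy, occlusion
#'   and merge flags).
#' @export
track_sequence <- function(imu_stream, cloud_stream, skeleton, config =
                             fusion_config(), seed = 1L, reference = NULL,
                           init_pose = NULL, stance = NULL) {
  stopifnot(inherits(imu_stream, "quat_stream"))
  aligned <- if (imu_stream$aligned) imu_stream else align_quaternions(imu_stream)
  times <- aligned$times
  n <- length(times)
  if (is.null(init_pose)) init_pose <- attention_pose(skeleton)
  have_lidar <- !is.null(cloud_stream) && length(cloud_stream) > 0L

  # The lidar path runs interleaved with the pose loop: each cloud frame is
  # clustered with the *latest fused pose* as prior (the joint positions
  # aid the leg clustering), and between cloud frames the newest foot
  # estimates are held (the causal counterpart of the offline linear
  # resampling in [resample_lidar_positions()]).
  occ <- NULL
  pr <- pl <- NULL
  if (have_lidar) {
    cloud_times <- vapply(cloud_stream, function(cl) cl$timestamp, numeric(1))
    ord <- order(cloud_times)
    cloud_stream <- cloud_stream[ord]
    cloud_times <- cloud_times[ord]
    if (!is.null(reference)) {
      occ <- voxel_occupancy(reference, config$voxel_resolution)
    }
    pr <- pf_init(init_pose$positions["RFoot", 1:2], config$n_particles,
                  config$sigma_proc, config$sigma_lik, seed = seed * 7L + 1L)
    pl <- pf_init(init_pose$positions["LFoot", 1:2], config$n_particles,
                  config$sigma_proc, config$sigma_lik, seed = seed * 7L + 2L)
  }
  rfeet <- lfeet <- matrix(NA_real_, n, 3L)
  stale_limit <- 0.5  # seconds without a usable cluster
  last_up_r <- last_up_l <- -Inf
  last_cloud_t <- if (have_lidar) cloud_times[1] - 1 / config$lidar_rate else NA
  j <- 1L

  known_stance <- stance
  if (!is.null(known_stance) && length(known_stance) != n) {
    stop("stance schedule length must match the IMU stream")
  }
  drift <- attr(imu_stream, "drift")
  drift_off <- drift_offsets(drift, times)

  pos <- array(NA_real_, c(n, 16L, 3L),
               dimnames = list(NULL, JOINT_NAMES, c("x", "y", "z")))
  qarr <- array(NA_real_, c(n, 15L, 4L),
                dimnames = list(NULL, skeleton$segments$id, c("w", "x", "y", "z")))
  stance <- character(n)
  corr_mag <- post_disc <- rep(NA_real_, n)
  occl <- rep(FALSE, n)

  prev_pose <- init_pose
  prev_stance <- "RFoot"
  seen_correction <- FALSE
  first_corr_frame <- NA_integer_
  win <- config$stance_window

  for (i in seq_len(n)) {
    frame_q <- aligned$quats[i, , , drop = TRUE]
    if (is.null(dim(frame_q))) frame_q <- matrix(frame_q, ncol = 4L,
                                                 dimnames = list(aligned$segments, NULL))
    orient <- derive_unsensed_orientations(frame_q, skeleton)

    # consume cloud frames due by now, clustering with the latest pose
    while (have_lidar && j <= length(cloud_stream) &&
             cloud_times[j] <= times[i] + 1e-9) {
      user <- if (is.null(occ)) cloud_stream[[j]] else {
        extract_user_cloud(occ, cloud_stream[[j]], realtime = TRUE)
      }
      dt <- max(cloud_times[j] - last_cloud_t, 1e-6)
      pr <- pf_predict(pr, dt, seed = seed + 13L * j)
      pl <- pf_predict(pl, dt, seed = seed + 13L * j + 5L)
      legs <- cluster_leg_points(user, skeleton, prev_pose,
                                 config$cluster_threshold, config$floor_z)
      if (!legs$occluded) {
        if (n_points(legs$right) >= 3L) {
          pr <- pf_update(pr, legs$right, seed = seed + 31L * j,
                          obs_mode = config$leg_obs, floor_z = config$floor_z)
          last_up_r <- cloud_times[j]
        }
        if (n_points(legs$left) >= 3L) {
          pl <- pf_update(pl, legs$left, seed = seed + 31L * j + 7L,
                          obs_mode = config$leg_obs, floor_z = config$floor_z)
          last_up_l <- cloud_times[j]
        }
      }
      last_cloud_t <- cloud_times[j]
      j <- j + 1L
    }
    if (have_lidar) {
      fp <- foot_positions(pr, pl, config$floor_z)
      rfeet[i, ] <- fp["RFoot", ]
      lfeet[i, ] <- fp["LFoot", ]
    }
    fresh_r <- have_lidar && (times[i] - last_up_r) <= stale_limit
    fresh_l <- have_lidar && (times[i] - last_up_l) <= stale_limit
    occl[i] <- have_lidar && !fresh_r && !fresh_l

    if (!is.null(known_stance)) {
      stance[i] <- known_stance[i]
    } else if (have_lidar && i > 1L) {
      # ground-contact cue first: the solved pose knows the relative foot
      # heights regardless of which foot anchors it; a clearly lower foot
      # is the planted one. Otherwise fall back to lidar displacement.
      rel <- top_down_update(orient, c(0, 0, 0), skeleton)
      zd <- rel$positions["RFoot", 3] - rel$positions["LFoot", 3]
      if (zd < -0.015 && fresh_r) {
        stance[i] <- "RFoot"
      } else if (zd > 0.015 && fresh_l) {
        stance[i] <- "LFoot"
      } else {
        lo <- max(1L, i - win + 1L)
        stance[i] <- select_stance_foot(rfeet[lo:i, , drop = FALSE],
                                        lfeet[lo:i, , drop = FALSE], prev_stance,
                                        right_ok = fresh_r, left_ok = fresh_l)
      }
    } else {
      stance[i] <- prev_stance
    }

    if (stance[i] != prev_stance && i > 1L) {
      hand <- solve_pose(orient, skeleton, prev_stance,
                         prev_pose$positions[prev_stance, ],
                         floor_z = config$floor_z, timestamp = times[i])
      base <- hand$positions[stance[i], ]
    } else {
      base <- prev_pose$positions[stance[i], ]
    }
    if (i > 1L) base <- base + drift_off[i, ] - drift_off[i - 1L, ]
    base[3] <- config$floor_z

    pf <- solve_pose(orient, skeleton, stance[i], base,
                     floor_z = config$floor_z, timestamp = times[i])

    stance_fresh <- if (stance[i] == "RFoot") fresh_r else fresh_l
    if (have_lidar && !occl[i] && stance_fresh) {
      lidar_feet <- rbind(RFoot = rfeet[i, ], LFoot = lfeet[i, ])
      pf <- drift_correct(pf, lidar_feet, config)
      corr_mag[i] <- sqrt(sum(attr(pf, "correction")^2))
      post_disc[i] <- sqrt(sum((lidar_feet[stance[i], ] -
                                  pf$positions[stance[i], ])^2))
      if (!seen_correction) { seen_correction <- TRUE; first_corr_frame <- i }
    }

    pos[i, , ] <- pf$positions
    qarr[i, , ] <- orient
    prev_pose <- pf
    prev_stance <- stance[i]
  }

  diag <- data.frame(time = times, stance = stance,
                     correction = corr_mag, stance_discrepancy = post_disc,
                     occluded = occl)
  attr(diag, "first_correction_frame") <- first_corr_frame
  pose_track(times, pos, stance = stance, quaternions = qarr,
             skeleton = skeleton, diagnostics = diag)
}

# Per-frame cumulative base-position drift offsets (n x 3).
drift_offsets <- function(drift, times) {
  n <- length(times)
  off <- matrix(0, n, 3L)
  if (is.null(drift) || drift$rate == 0 && drift$rw_std == 0) return(off)
  t0 <- times - times[1]
  off[, 1] <- drift$direction[1] * drift$rate * t0
  off[, 2] <- drift$direction[2] * drift$rate * t0
  if (drift$rw_std > 0) {
    rng <- local_rng(drift$seed)
    dt <- c(0, diff(t0))
    off[, 1] <- off[, 1] + cumsum(rng$rnorm(n, 0, drift$rw_std * sqrt(dt)))
    off[, 2] <- off[, 2] + cumsum(rng$rnorm(n, 0, drift$rw_std * sqrt(dt)))
  }
  off
}
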