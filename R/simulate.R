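#' Synthetic capture sessions: motion, lidar clouds, IMU streams
#'
#' The simulator stands in for the live hardware: two 16-channel scanning
#' lidars (360 degree horizontal, +/-15 degree vertical field of view,
#' centimeter-level range noise, 10-20 Hz) observing an 8 x 4 x 3 m room,
#' and ten 60 Hz body-worn IMUs with arbitrary constant mounting offsets.
#' The body is approximated by capsules around each bone segment; lidar
#' returns are exact ray intersections with the capsules and the room box
#' plus Gaussian range noise, so every generated session carries exact
#' ground truth.
#'
#' @name simulate
NULL

#' Sensor model for a synthetic session
#'
#' @param lidar_rate cloud frame rate, Hz (10-20).
#' @param range_noise lidar range noise standard deviation in meters
#'   (default 0.01; the hardware accuracy claim of +/-3 cm is its 3-sigma
#'   band).
#' @param azimuth_step horizontal angular resolution in degrees.
#' @param channels number of scan lines spread over the vertical FoV.
#' @param vfov half vertical field of view in degrees.
#' @param ceiling_tilt_deg mounting tilt of the ceiling sensor (degrees);
#'   the source of the floor slope the height pipeline corrects.
#' @param imu_rate IMU rate, Hz.
#' @param imu_noise_deg IMU orientation noise standard deviation, degrees.
#' @param imu_offsets `"random"` (constant random mounting offset per
#'   sensor) or `"identity"`.
#' @param room c(xmax, ywidth, zmax): the room spans `[0, xmax] x
#'   [-ywidth/2, ywidth/2] x [0, zmax]`.
#' @export
sensor_model <- function(lidar_rate = 15, range_noise = 0.01,
                         azimuth_step = 0.4, channels = 16L, vfov = 15,
                         ceiling_tilt_deg = 1, imu_rate = 60,
                         imu_noise_deg = 0, imu_offsets = "random",
                         room = c(8, 4, 3)) {
  stopifnot(lidar_rate > 0, imu_rate > 0, range_noise >= 0, imu_noise_deg >= 0)
  box <- c(0, room[1], -room[2] / 2, room[2] / 2, 0, room[3])
  ceiling_pos <- c(0.2, 0, room[3] - 0.1)
  tf <- l1_transform(ceiling_pos, ceiling_tilt_deg)
  front_pos <- c(room[1] - 0.2, 0, 0.6)
  front_axes <- cbind(c(-1, 0, 0), c(0, -1, 0), c(0, 0, 1))
  structure(list(
    lidar_rate = lidar_rate, range_noise = range_noise,
    azimuth_step = azimuth_step, channels = as.integer(channels), vfov = vfov,
    ceiling_tilt_deg = ceiling_tilt_deg, box = box,
    lidars = list(
      L1 = list(id = "L1", position = ceiling_pos, axes = t(tf$R)),
      L2 = list(id = "L2", position = front_pos, axes = front_axes)
    ),
    l1_transform = tf,
    imu_rate = imu_rate, imu_noise_deg = imu_noise_deg,
    imu_offsets = imu_offsets
  ), class = "sensor_model")
}

# Scan-grid ray directions (world frame) for one lidar; cached in the
# sensor list element on first use.
lidar_ray_dirs <- function(lidar, channels, vfov, azimuth_step) {
  az <- seq(0, 360 - azimuth_step, by = azimuth_step) * pi / 180
  el <- seq(-vfov, vfov, length.out = channels) * pi / 180
  g <- expand.grid(az = az, el = el)
  d <- cbind(cos(g$el) * cos(g$az), cos(g$el) * sin(g$az), sin(g$el))
  d %*% t(lidar$axes)
}

ray_cache <- new.env(parent = emptyenv())

get_ray_dirs <- function(sensors, id) {
  key <- paste(id, sensors$channels, sensors$vfov, sensors$azimuth_step,
               sensors$ceiling_tilt_deg, sep = "|")
  if (is.null(ray_cache[[key]])) {
    ray_cache[[key]] <- lidar_ray_dirs(sensors$lidars[[id]], sensors$channels,
                                       sensors$vfov, sensors$azimuth_step)
  }
  ray_cache[[key]]
}

# Capsule surface model of a posed body: one capsule per segment plus a
# head capsule reaching the top of the head, m x 7 (p0, p1, radius).
body_capsules <- function(pose, skeleton) {
  segs <- skeleton$segments
  radius <- c(b1 = 0.05, b2 = 0.14, b3 = 0.07, b4 = 0.07, b5 = 0.045,
              b6 = 0.045, b7 = 0.14, b8 = 0.045, b9 = 0.045, b10 = 0.07,
              b11 = 0.07, b12 = 0.055, b13 = 0.07, b14 = 0.07, b15 = 0.055)
  p <- pose$positions
  caps <- matrix(NA_real_, 16L, 7L)
  for (i in seq_len(15L)) {
    caps[i, ] <- c(p[segs$proximal[i], ], p[segs$distal[i], ], radius[segs$id[i]])
  }
  r_head <- 0.11
  up <- if (!is.null(pose$quaternions)) {
    rotate_bone_vector(pose$quaternions["b1", ], c(0, 0, 1))
  } else c(0, 0, 1)
  caps[16L, ] <- c(p["Head", ], p["Head", ] + up * (skeleton$head_top - r_head),
                   r_head)
  caps
}

raycast_scene <- function(sensors, id, capsules, noise_seed, range_noise) {
  dirs <- get_ray_dirs(sensors, id)
  org <- sensors$lidars[[id]]$position
  if (is.null(capsules)) capsules <- matrix(numeric(0), 0, 7)
  hit <- cpp_raycast(org, dirs, capsules, sensors$box)
  rng <- local_rng(noise_seed)
  r <- hit$range
  if (range_noise > 0) r <- r + rng$rnorm(length(r), 0, range_noise)
  pts <- dirs * r
  pts <- sweep(pts, 2, -org)
  list(points = pts, hit = hit$hit)
}

#' Reference scene cloud (room without the subject)
#'
#' Samples the floor, walls and ceiling of the room on the deterministic
#' scan grids of both lidars.
#'
#' @param sensors a [sensor_model()].
#' @param seed integer seed for the range noise.
#' @param timestamp seconds.
#' @return merged `pc_frame` (variant `reference`, world frame) with
#'   per-point sensor ids.
#' @export
make_room_reference <- function(sensors, seed = 1L, timestamp = 0) {
  parts <- lapply(names(sensors$lidars), function(id) {
    rc <- raycast_scene(sensors, id, NULL, seed + match(id, names(sensors$lidars)),
                        sensors$range_noise)
    list(points = rc$points, id = id)
  })
  pts <- do.call(rbind, lapply(parts, `[[`, "points"))
  sens <- unlist(lapply(parts, function(p) rep(p$id, nrow(p$points))))
  out <- pc_frame(pts, timestamp, "reference", "world", sensor = sens)
  attr(out, "sensor_positions") <- lapply(sensors$lidars, `[[`, "position")
  out
}

#' Sample one lidar cloud of a posed body
#'
#' Intersects the scan grids of both lidars with the capsule body model and
#' the room, adding Gaussian range noise.
#'
#' @param track a `gt_track` (or any object with `times`, `joints`,
#'   `quats`).
#' @param skeleton the skeleton.
#' @param sensors a [sensor_model()].
#' @param frame_index lidar frame number (1-based); the cloud timestamp is
#'   `(frame_index - 1) / lidar_rate` and the nearest ground-truth frame is
#'   posed.
#' @param seed integer noise seed.
#' @param variant cloud variant tag (default `realtime`).
#' @param body_only drop the room-surface returns (debug aid).
#' @return merged `pc_frame` in the world frame.
#' @export
sample_lidar_cloud <- function(track, skeleton, sensors, frame_index,
                               seed = 1L, variant = "realtime",
                               body_only = FALSE) {
  t_cloud <- (frame_index - 1) / sensors$lidar_rate
  i <- which.min(abs(track$times - t_cloud))
  pose <- pose_frame(track$joints[i, , ], timestamp = t_cloud,
                     quaternions = track$quats[i, , ])
  caps <- body_capsules(pose, skeleton)
  parts <- lapply(names(sensors$lidars), function(id) {
    rc <- raycast_scene(sensors, id, caps,
                        seed + 1000L * match(id, names(sensors$lidars)) +
                          frame_index, sensors$range_noise)
    keep <- if (body_only) rc$hit > 0 else rep(TRUE, nrow(rc$points))
    list(points = rc$points[keep, , drop = FALSE], id = id)
  })
  pts <- do.call(rbind, lapply(parts, `[[`, "points"))
  sens <- unlist(lapply(parts, function(p) rep(p$id, nrow(p$points))))
  out <- pc_frame(pts, t_cloud, variant, "world", sensor = sens)
  attr(out, "sensor_positions") <- lapply(sensors$lidars, `[[`, "position")
  out
}

# ---- motion generation ------------------------------------------------------

quat_about <- function(axis = c("x", "y", "z"), deg) {
  axis <- match.arg(axis)
  h <- deg * pi / 360
  z <- numeric(length(deg))
  s <- sin(h)
  switch(axis,
         x = cbind(cos(h), s, z, z, deparse.level = 0),
         y = cbind(cos(h), z, s, z, deparse.level = 0),
         z = cbind(cos(h), z, z, s, deparse.level = 0))
}

SENSED_IDS <- c("b1", "b2", "b5", "b6", "b8", "b9", "b11", "b12", "b14", "b15")

# expand sensed-segment quaternions (n x 10 x 4) to all 15 segments using
# the derivation rule, keeping ground truth consistent with reconstruction
expand_sensed <- function(qs, skeleton) {
  n <- dim(qs)[1]
  segs <- skeleton$segments
  out <- array(0, c(n, 15L, 4L),
               dimnames = list(NULL, segs$id, c("w", "x", "y", "z")))
  out[, , 1] <- 1
  for (id in SENSED_IDS) out[, id, ] <- qs[, id, ]
  for (i in which(!segs$sensed)) out[, segs$id[i], ] <- out[, segs$source[i], ]
  out
}

empty_sensed <- function(n) {
  qs <- array(0, c(n, length(SENSED_IDS), 4L),
              dimnames = list(NULL, SENSED_IDS, c("w", "x", "y", "z")))
  qs[, , 1] <- 1
  qs
}

# the 14 key poses: per-pose sensed-segment rotations and stance foot
key_pose_table <- function() {
  rx <- function(d) quat_axis_angle(c(1, 0, 0), d)
  ry <- function(d) quat_axis_angle(c(0, 1, 0), d)
  rz <- function(d) quat_axis_angle(c(0, 0, 1), d)
  list(
    list(name = "attention", stance = "RFoot", q = list()),
    list(name = "arms_front", stance = "RFoot",
         q = list(b5 = ry(-90), b8 = ry(-90), b6 = ry(-90), b9 = ry(-90))),
    list(name = "arms_lateral", stance = "RFoot",
         q = list(b5 = rx(-90), b6 = rx(-90), b8 = rx(90), b9 = rx(90))),
    list(name = "arms_overhead", stance = "RFoot",
         q = list(b5 = ry(180), b6 = ry(180), b8 = ry(180), b9 = ry(180))),
    list(name = "elbows_flexed", stance = "RFoot",
         q = list(b6 = ry(-90), b9 = ry(-90))),
    list(name = "arm_rotation", stance = "RFoot",
         q = list(b5 = rz(60), b6 = rz(60), b8 = rz(-60), b9 = rz(-60))),
    list(name = "forward_bend", stance = "RFoot",
         q = list(b2 = ry(30), b1 = ry(45))),
    list(name = "side_bend", stance = "RFoot",
         q = list(b2 = rx(20), b1 = rx(30))),
    list(name = "trunk_twist", stance = "RFoot",
         q = list(b2 = rz(30), b1 = rz(45))),
    list(name = "right_leg_swing", stance = "LFoot",
         q = list(b11 = ry(-45), b12 = ry(-45))),
    list(name = "head_nod", stance = "LFoot", q = list(b1 = ry(25))),
    list(name = "left_leg_swing", stance = "RFoot",
         q = list(b14 = ry(-45), b15 = ry(-45))),
    list(name = "squat", stance = "RFoot",
         q = list(b11 = ry(-30), b14 = ry(-30), b12 = ry(30), b15 = ry(30),
                  b2 = ry(10), b1 = ry(10))),
    list(name = "right_knee_flex", stance = "LFoot", q = list(b12 = ry(75)))
  )
}

walk_block <- function(t, amp_deg = 8, knee_deg = 30, period = 2.4,
                       ramp_down = FALSE) {
  w <- 2 * pi / period
  ramp <- pmin(1, t / (period / 4))
  if (ramp_down) ramp <- pmin(ramp, pmax(0, (max(t) - t) / (period / 4)))
  s <- amp_deg * ramp * sin(w * t)
  phase <- (w * t) %% (2 * pi)
  # gait starts on the right foot, matching the tracker's first-frame
  # stance default; swaps at the symmetric double-support extremes
  stance <- ifelse(phase >= pi / 2 & phase < 3 * pi / 2, "LFoot", "RFoot")
  # swing-knee flexion lifts the swing foot clear of the floor; zero at the
  # stance swaps so both feet are grounded at double support
  k_r <- knee_deg * ramp * pmax(0, -cos(phase))^2
  k_l <- knee_deg * ramp * pmax(0, cos(phase))^2
  n <- length(t)
  qs <- empty_sensed(n)
  qs[, "b11", ] <- quat_about("y", s)
  qs[, "b12", ] <- quat_about("y", s + k_r)
  qs[, "b14", ] <- quat_about("y", -s)
  qs[, "b15", ] <- quat_about("y", -s + k_l)
  qs[, "b5", ] <- qs[, "b6", ] <- quat_about("y", -0.5 * s)
  qs[, "b8", ] <- qs[, "b9", ] <- quat_about("y", 0.5 * s)
  list(quats = qs, stance = stance)
}

squat_block <- function(t, amp_deg = 60, period = 4) {
  phi <- amp_deg * (1 - cos(2 * pi * t / period)) / 2
  n <- length(t)
  qs <- empty_sensed(n)
  qs[, "b11", ] <- qs[, "b14", ] <- quat_about("y", -phi / 2)
  qs[, "b12", ] <- qs[, "b15", ] <- quat_about("y", phi / 2)
  qs[, "b2", ] <- qs[, "b1", ] <- quat_about("y", phi / 6)
  list(quats = qs, stance = rep("RFoot", n))
}

key_poses_block <- function(t, transition_frac = 0.4) {
  poses <- key_pose_table()
  np <- length(poses)
  slot <- max(t) * (1 + 1e-9) / np
  n <- length(t)
  qs <- empty_sensed(n)
  stance <- character(n)
  for (i in seq_len(n)) {
    k <- min(np, floor(t[i] / slot) + 1L)
    u <- (t[i] - (k - 1) * slot) / slot
    prev <- if (k == 1L) poses[[1L]] else poses[[k - 1L]]
    cur <- poses[[k]]
    s <- if (u >= transition_frac) 1 else (1 - cos(pi * u / transition_frac)) / 2
    for (id in SENSED_IDS) {
      q0 <- if (!is.null(prev$q[[id]])) prev$q[[id]] else c(1, 0, 0, 0)
      q1 <- if (!is.null(cur$q[[id]])) cur$q[[id]] else c(1, 0, 0, 0)
      qs[i, id, ] <- quat_slerp(q0, q1, s)
    }
    stance[i] <- cur$stance
  }
  list(quats = qs, stance = stance)
}

#' Generate a ground-truthed motion
#'
#' Produces smooth per-segment orientation trajectories and the exactly
#' consistent joint positions (solved with the same stance-anchored forward
#' kinematics used for tracking). All motions start from the attention
#' pose, satisfying the calibration contract.
#'
#' Kinds: `attention` (static), `walk` (alternating stance, pelvis advances
#' monotonically along `+x`), `squat` (feet fixed), `key_poses_14`
#' (fourteen held poses spanning arm swings and rotations, trunk bends and
#' twist, leg swings, a squat and knee flexion), and `walk_squat_pattern`
#' (walk and squat phases in alternation).
#'
#' @param kind motion name.
#' @param duration seconds (> 0).
#' @param rate frame rate, Hz (> 0).
#' @param skeleton the skeleton.
#' @param seed integer seed (reserved for stochastic variants; the default
#'   generators are deterministic).
#' @param start_position pelvis ground position `(x, y)` at the first frame.
#' @return a `gt_track`: `times`, `quats` (n x 15 x 4), `stance`, `joints`
#'   (n x 16 x 3), `skeleton`.
#' @export
generate_motion <- function(kind = c("attention", "walk", "squat",
                                     "key_poses_14", "walk_squat_pattern"),
                            duration, rate, skeleton, seed = 1L,
                            start_position = c(2.2, 0)) {
  if (is.character(kind)) kind <- match.arg(kind)
  stopifnot(duration > 0, rate > 0)
  n <- max(2L, round(duration * rate))
  t <- (seq_len(n) - 1L) / rate
  blk <- switch(kind,
    attention = list(quats = empty_sensed(n), stance = rep("RFoot", n)),
    walk = walk_block(t),
    squat = squat_block(t),
    key_poses_14 = key_poses_block(t),
    walk_squat_pattern = {
      cuts <- round(n * c(0.4, 0.6, 0.8))
      i1 <- seq_len(cuts[1]); i2 <- (cuts[1] + 1):cuts[2]
      i3 <- (cuts[2] + 1):cuts[3]; i4 <- (cuts[3] + 1):n
      b1 <- walk_block(t[i1] - t[i1][1], ramp_down = TRUE)
      b2 <- squat_block(t[i2] - t[i2][1])
      b3 <- walk_block(t[i3] - t[i3][1], ramp_down = TRUE)
      b4 <- squat_block(t[i4] - t[i4][1])
      qs <- empty_sensed(n)
      for (id in SENSED_IDS) {
        qs[, id, ] <- rbind(b1$quats[, id, ], b2$quats[, id, ],
                            b3$quats[, id, ], b4$quats[, id, ])
      }
      list(quats = qs, stance = c(b1$stance, b2$stance, b3$stance, b4$stance))
    },
    stop("unknown motion kind: ", kind)
  )
  quats <- expand_sensed(blk$quats, skeleton)
  ap <- attention_pose(skeleton)
  init_foot <- ap$positions[blk$stance[1], ] + c(start_position, 0)
  track <- solve_track(t, quats, blk$stance, skeleton,
                       init_stance_position = init_foot)
  structure(list(times = t, quats = quats, stance = blk$stance,
                 joints = track$positions, skeleton = skeleton,
                 kind = kind, start_position = start_position),
            class = "gt_track")
}

#' @export
print.gt_track <- function(x, ...) {
  cat(sprintf("<gt_track %s> %d frames over %.2f s\n", x$kind,
              length(x$times), diff(range(x$times))))
  invisible(x)
}

#' Sample an IMU quaternion stream from a ground-truth track
#'
#' Per sensed segment, `q_i = R_i * n_i * c`: the true segment orientation,
#' a small-angle Gaussian orientation noise `n_i`, and the constant
#' mounting offset `c` of that sensor. Frame 0 is the attention reading, so
#' first-frame alignment applies.
#'
#' @param track a `gt_track` at the IMU rate.
#' @param sensors a [sensor_model()].
#' @param seed integer seed.
#' @return a raw [quat_stream()] over the 10 sensed segments.
#' @export
sample_imu_stream <- function(track, sensors, seed = 1L) {
  n <- length(track$times)
  rng <- local_rng(seed * 11L + 3L)
  qs <- array(NA_real_, c(n, length(SENSED_IDS), 4L),
              dimnames = list(NULL, SENSED_IDS, c("w", "x", "y", "z")))
  for (s in seq_along(SENSED_IDS)) {
    id <- SENSED_IDS[s]
    q <- track$quats[, id, ]
    if (sensors$imu_noise_deg > 0) {
      ax <- matrix(rng$rnorm(3L * n), ncol = 3L)
      ax <- ax / sqrt(rowSums(ax^2))
      ang <- rng$rnorm(n, 0, sensors$imu_noise_deg) * pi / 180
      noise <- cbind(cos(ang / 2), sin(ang / 2) * ax)
      q <- quat_multiply(q, noise)
    }
    if (identical(sensors$imu_offsets, "random")) {
      v <- rng$rnorm(4L)
      off <- v / sqrt(sum(v^2))
      q <- quat_multiply(q, matrix(off, 1))
    }
    qs[, s, ] <- q
  }
  quat_stream(track$times, qs, aligned = FALSE)
}

#' Inject base-position displacement drift
#'
#' Emulates inertial dead-reckoning drift: attaches a linear (plus optional
#' random-walk) ground-plane offset that [track_sequence()] adds to the
#' stance-foot base position of the inertial-only solve. Orientations are
#' untouched. A zero rate with no random walk returns the input unchanged.
#'
#' @param stream a [quat_stream()].
#' @param rate drift rate in m/s (>= 0).
#' @param seed integer seed (drift direction and random walk).
#' @param rw_std random-walk standard deviation in m/sqrt(s).
#' @param direction optional unit ground-plane direction (length 2).
#' @export
inject_drift <- function(stream, rate, seed = 1L, rw_std = 0,
                         direction = NULL) {
  stopifnot(inherits(stream, "quat_stream"), rate >= 0, rw_std >= 0)
  if (rate == 0 && rw_std == 0) return(stream)
  if (is.null(direction)) {
    rng <- local_rng(seed * 17L + 5L)
    a <- rng$runif(1, 0, 2 * pi)
    direction <- c(cos(a), sin(a))
  }
  direction <- direction / sqrt(sum(direction^2))
  attr(stream, "drift") <- list(rate = rate, direction = direction,
                                rw_std = rw_std, seed = seed)
  stream
}

#' Simulate a complete capture session
#'
#' Generates the reference scene, calibration full-body clouds (attention
#' stance), the motion ground truth, real-time clouds at the lidar rate and
#' the raw IMU stream.
#'
#' @param kind motion kind, see [generate_motion()].
#' @param duration seconds.
#' @param height subject height in meters (ground truth).
#' @param sensors a [sensor_model()].
#' @param seed master integer seed.
#' @param n_calibration number of calibration full-body frames.
#' @param start_position pelvis ground position at the first frame.
#' @param with_clouds set `FALSE` to skip lidar cloud generation (fast,
#'   IMU-only studies).
#' @return list: `truth`, `imu`, `clouds`, `reference`, `calib_clouds`,
#'   `skeleton`, `sensors`, `init_pose`.
#' @export
simulate_session <- function(kind, duration, height = 1.75,
                             sensors = sensor_model(), seed = 1L,
                             n_calibration = 10L,
                             start_position = c(2.2, 0),
                             with_clouds = TRUE) {
  skeleton <- build_skeleton(height)
  truth <- generate_motion(kind, duration, sensors$imu_rate, skeleton,
                           seed = seed, start_position = start_position)
  imu <- sample_imu_stream(truth, sensors, seed = seed + 1L)
  ap <- attention_pose(skeleton)
  init_pos <- ap$positions
  init_pos[, 1] <- init_pos[, 1] + start_position[1]
  init_pos[, 2] <- init_pos[, 2] + start_position[2]
  init_pose <- pose_frame(init_pos, timestamp = 0)
  reference <- NULL; calib <- NULL; clouds <- NULL
  if (with_clouds) {
    reference <- make_room_reference(sensors, seed = seed + 2L)
    calib_track <- list(times = 0,
                        joints = array(init_pos, c(1, 16, 3),
                                       dimnames = list(NULL, JOINT_NAMES, c("x", "y", "z"))),
                        quats = array(rep(quat_identity(1), each = 1),
                                      c(1, 15, 4),
                                      dimnames = list(NULL, skeleton$segments$id, NULL)))
    calib_track$quats[, , 1] <- 1; calib_track$quats[, , 2:4] <- 0
    calib <- lapply(seq_len(n_calibration), function(k) {
      cl <- sample_lidar_cloud(calib_track, skeleton, sensors, 1L,
                               seed = seed + 100L + k, variant = "full_body")
      cl$timestamp <- (k - 1) / sensors$lidar_rate
      cl
    })
    n_cloud <- max(2L, floor(duration * sensors$lidar_rate))
    clouds <- lapply(seq_len(n_cloud), function(k) {
      sample_lidar_cloud(truth, skeleton, sensors, k, seed = seed + 10000L)
    })
  }
  list(truth = truth, imu = imu, clouds = clouds, reference = reference,
       calib_clouds = calib, skeleton = skeleton, sensors = sensors,
       init_pose = init_pose)
}
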