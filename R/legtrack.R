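#' Lower-leg clustering and particle-filter foot tracking
#'
#' The lidars only need to localize the feet: the lower-leg points of the
#' real-time user cloud are clustered, assigned left/right with the help of
#' the previous pose, and each leg is followed on the ground plane by a
#' small particle filter (constant-position motion model with Gaussian
#' diffusion, Gaussian likelihood on the distance to the leg-cluster
#' centroid, systematic resampling).
#'
#' @name legtrack
NULL

#' Cluster the lower-leg points of a user cloud
#'
#' Keeps points in the vertical band from the floor to knee height
#' (2 head units), gates them to within 0.5 m of a prior leg landmark, and
#' assigns each point to the leg whose prior knee/ankle is nearer. The
#' Euclidean cluster structure is kept as a diagnostic: a single cluster
#' (legs too close to separate geometrically, e.g. crossed) raises the
#' `merged` flag; too few usable points raise the `occluded` flag.
#'
#' @param user_cloud `pc_frame` in the world frame.
#' @param skeleton the skeleton (knee height = 2 head units).
#' @param prior_pose `pose_frame` used for left/right assignment (the
#'   attention pose on the first frame).
#' @param cluster_threshold Euclidean cluster distance (meters).
#' @param floor_z floor plane height.
#' @return list: `right`, `left` (leg-variant `pc_frame`s), `merged`,
#'   `occluded`.
#' @export
cluster_leg_points <- function(user_cloud, skeleton, prior_pose,
                               cluster_threshold = 0.15, floor_z = 0) {
  stopifnot(inherits(user_cloud, "pc_frame"), inherits(prior_pose, "pose_frame"))
  knee_h <- floor_z + 2 * skeleton$head_unit
  p <- user_cloud$points
  sens <- user_cloud$sensor
  band <- p[, 3] >= floor_z & p[, 3] <= knee_h
  p <- p[band, , drop = FALSE]
  sens <- sens[band]
  empty <- pc_frame(matrix(numeric(0), 0, 3), user_cloud$timestamp, "leg", user_cloud$frame)
  ref <- prior_pose$positions[c("RKnee", "LKnee", "RFoot", "LFoot"),
                              1:2, drop = FALSE]
  if (nrow(p) > 0L) {
    # gate: each point's ground distance to the nearer prior leg landmark
    dr <- pmin(sqrt(rowSums(sweep(p[, 1:2, drop = FALSE], 2, ref["RKnee", ])^2)),
               sqrt(rowSums(sweep(p[, 1:2, drop = FALSE], 2, ref["RFoot", ])^2)))
    dl <- pmin(sqrt(rowSums(sweep(p[, 1:2, drop = FALSE], 2, ref["LKnee", ])^2)),
               sqrt(rowSums(sweep(p[, 1:2, drop = FALSE], 2, ref["LFoot", ])^2)))
    keep <- pmin(dr, dl) <= 0.5
    p <- p[keep, , drop = FALSE]
    sens <- sens[keep]
    dr <- dr[keep]; dl <- dl[keep]
  }
  if (nrow(p) < 3L) {
    return(list(right = empty, left = empty, merged = FALSE, occluded = TRUE))
  }
  # cluster count is diagnostic only: a single cluster means the legs are
  # too close to separate geometrically (crossed or adjacent)
  nclus <- max(euclidean_cluster_labels(p, cluster_threshold))
  mk <- function(sel) {
    out <- pc_frame(p[sel, , drop = FALSE], user_cloud$timestamp, "leg",
                    user_cloud$frame, sensor = sens[sel])
    attr(out, "sensor_positions") <- attr(user_cloud, "sensor_positions")
    out
  }
  right <- dr <= dl
  list(right = mk(right), left = mk(!right),
       merged = nclus < 2L, occluded = FALSE)
}

#' Initialize a per-leg particle filter
#'
#' @param center initial ground-plane position (length 2).
#' @param n_particles particle count (>= 10).
#' @param sigma_proc process diffusion, meters per sqrt(second).
#' @param sigma_lik likelihood bandwidth, meters.
#' @param spread standard deviation of the initial particle scatter.
#' @param seed integer seed.
#' @export
pf_init <- function(center, n_particles = 200L, sigma_proc = 0.5,
                    sigma_lik = 0.1, spread = 0.05, seed = 1L) {
  stopifnot(n_particles >= 10L)
  rng <- local_rng(seed)
  particles <- cbind(rng$rnorm(n_particles, center[1], spread),
                     rng$rnorm(n_particles, center[2], spread))
  structure(list(particles = particles,
                 weights = rep(1 / n_particles, n_particles),
                 estimate = as.numeric(center),
                 n = n_particles, sigma_proc = sigma_proc,
                 sigma_lik = sigma_lik, last_time = NA_real_),
            class = "pf_state")
}

# Deterministic stand-alone RNG stream (does not disturb .Random.seed).
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  }
  with_state <- function(fun) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- fun()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(
    rnorm = function(n, mean = 0, sd = 1) with_state(function() stats::rnorm(n, mean, sd)),
    runif = function(n, min = 0, max = 1) with_state(function() stats::runif(n, min, max))
  )
}

#' Particle-filter prediction step
#'
#' Diffuses every particle by zero-mean Gaussian noise with standard
#' deviation `sigma_proc * sqrt(dt)`; weights are unchanged.
#'
#' @param state a `pf_state`.
#' @param dt elapsed time in seconds (> 0).
#' @param seed integer seed (deterministic per call).
#' @export
pf_predict <- function(state, dt, seed) {
  stopifnot(inherits(state, "pf_state"), dt > 0)
  sd <- state$sigma_proc * sqrt(dt)
  if (sd > 0) {
    rng <- local_rng(seed)
    noise <- matrix(rng$rnorm(2L * state$n, 0, sd), ncol = 2L)
    state$particles <- state$particles + noise
  }
  state
}

#' Ground-plane observation of a leg cluster
#'
#' `"centroid"` projects the cluster centroid to the ground plane. The
#' default `"axis"` first moves every surface return inward by the assumed
#' shank radius along its horizontal viewing direction (lidar samples only
#' the surface facing each sensor, so the raw centroid is biased off the
#' bone axis by a fraction of the radius; the de-biased points lie near
#' the axis with error bounded by the radius), then fits the dominant
#' principal axis of the de-biased cluster (the shank direction) and
#' intersects it with the floor plane, which removes the systematic
#' forward offset whenever the lower leg is tilted (squatting, swing
#' phase). It falls back to the centroid when the cluster is too small or
#' not elongated enough for a stable axis.
#'
#' @param leg_cloud non-empty leg-variant `pc_frame`.
#' @param floor_z floor plane height.
#' @param mode `"axis"` or `"centroid"`.
#' @param radius assumed lower-leg (shank) radius in meters for the
#'   known-radius cylinder fit; lidar samples only the surface facing the
#'   sensors, so the raw centroid sits off the bone axis by a fraction of
#'   the radius even with perfect returns.
#' @return length-2 ground-plane position.
#' @export
leg_ground_observation <- function(leg_cloud, floor_z = 0,
                                   mode = c("axis", "centroid"),
                                   radius = 0.05) {
  mode <- match.arg(mode)
  p <- leg_cloud$points
  if (mode == "centroid") return(colMeans(p)[1:2])
  # de-bias surface returns toward the bone axis using each point's
  # horizontal viewing direction
  sens_pos <- attr(leg_cloud, "sensor_positions")
  if (!is.null(leg_cloud$sensor) && !is.null(sens_pos)) {
    for (id in unique(leg_cloud$sensor)) {
      sel <- leg_cloud$sensor == id
      org <- sens_pos[[id]]
      if (is.null(org)) next
      d <- cbind(p[sel, 1] - org[1], p[sel, 2] - org[2])
      dn <- sqrt(rowSums(d^2))
      idx <- which(sel)[dn > 1e-9]
      d <- d[dn > 1e-9, , drop = FALSE] / dn[dn > 1e-9]
      p[idx, 1:2] <- p[idx, 1:2, drop = FALSE] + radius * d
    }
  }
  ctr <- colMeans(p)
  if (nrow(p) < 5L) return(ctr[1:2])
  # fit on the lower half of the cluster: above-knee points (a dropped knee
  # during squats pulls thigh returns into the band) would bend the axis
  low <- p[p[, 3] <= stats::median(p[, 3]) + 1e-9, , drop = FALSE]
  if (nrow(low) >= 8L) p <- low
  ctr_fit <- colMeans(p)
  eg <- eigen(stats::cov(p), symmetric = TRUE)
  v <- eg$vectors[, 1]
  elongated <- eg$values[1] > 1.5 * max(eg$values[2], 1e-12)
  if (!elongated || abs(v[3]) < 0.5) return(ctr[1:2])
  if (v[3] < 0) v <- -v
  shift <- (floor_z - ctr_fit[3]) / v[3]
  obs <- ctr_fit + v * shift
  # cap the horizontal extrapolation at half a lower-leg length
  h <- obs[1:2] - ctr_fit[1:2]
  hn <- sqrt(sum(h^2))
  if (hn > 0.25) obs[1:2] <- ctr_fit[1:2] + h * (0.25 / hn)
  obs[1:2]
}

#' Particle-filter measurement update
#'
#' Weights particles by a Gaussian likelihood on the distance to the
#' ground-plane observation of the leg cluster (see
#' [leg_ground_observation()]), resamples systematically when the
#' effective sample size drops below half the particle count, and sets the
#' estimate to the weighted mean.
#'
#' @param state a `pf_state`.
#' @param leg_cloud non-empty leg-variant `pc_frame`.
#' @param seed integer seed for the resampling offset.
#' @param obs_mode observation model, see [leg_ground_observation()].
#' @param floor_z floor plane height.
#' @export
pf_update <- function(state, leg_cloud, seed = 1L, obs_mode = "axis",
                      floor_z = 0) {
  stopifnot(inherits(state, "pf_state"), inherits(leg_cloud, "pc_frame"))
  if (n_points(leg_cloud) == 0L) stop("empty leg cloud")
  obs <- leg_ground_observation(leg_cloud, floor_z, obs_mode)
  d2 <- rowSums(sweep(state$particles, 2, obs)^2)
  w <- state$weights * exp(-d2 / (2 * state$sigma_lik^2))
  if (sum(w) < 1e-300) {
    # all weights underflowed: reinitialize around the observation
    rng <- local_rng(seed)
    state$particles <- cbind(rng$rnorm(state$n, obs[1], state$sigma_lik),
                             rng$rnorm(state$n, obs[2], state$sigma_lik))
    w <- rep(1, state$n)
  }
  w <- w / sum(w)
  ess <- 1 / sum(w^2)
  if (ess < state$n / 2) {
    rng <- local_rng(seed + 1L)
    u0 <- rng$runif(1) / state$n
    cum <- cumsum(w)
    idx <- findInterval(u0 + (seq_len(state$n) - 1L) / state$n, cum) + 1L
    idx[idx > state$n] <- state$n
    state$particles <- state$particles[idx, , drop = FALSE]
    w <- rep(1 / state$n, state$n)
  }
  state$weights <- w
  state$estimate <- colSums(state$particles * w)
  state
}

#' Foot ground positions from a pair of filter states
#'
#' @param right,left `pf_state`s for the two legs.
#' @param floor_z floor plane height.
#' @return 2 x 3 matrix with rows `RFoot`, `LFoot` on the floor plane.
#' @export
foot_positions <- function(right, left, floor_z = 0) {
  rbind(RFoot = c(right$estimate, floor_z),
        LFoot = c(left$estimate, floor_z))
}

#' Track both feet across a sequence of real-time clouds
#'
#' Runs change detection (when a reference is supplied), leg clustering and
#' the per-leg particle filters over a list of cloud frames.
#'
#' @param clouds list of `pc_frame`s in the world frame, time-ordered.
#' @param reference optional reference `pc_frame` for change detection;
#'   `NULL` means the clouds already contain only the subject.
#' @param skeleton the skeleton.
#' @param init_pose starting `pose_frame` (attention pose at the session
#'   start position).
#' @param config a [fusion_config()].
#' @param seed master seed; per-frame sub-seeds are derived from it.
#' @return list: `times`, `right`, `left` (n x 3 foot positions),
#'   `merged`, `occluded` (logical vectors), `updated` (n x 2: did each
#'   leg receive a usable cluster this frame).
#' @export
track_feet <- function(clouds, reference, skeleton, init_pose, config, seed = 1L) {
  n <- length(clouds)
  times <- vapply(clouds, function(cl) cl$timestamp, numeric(1))
  right <- matrix(NA_real_, n, 3L)
  left <- matrix(NA_real_, n, 3L)
  merged <- logical(n)
  occluded <- logical(n)
  updated <- matrix(FALSE, n, 2L, dimnames = list(NULL, c("right", "left")))
  floor_z <- config$floor_z
  pr <- pf_init(init_pose$positions["RFoot", 1:2], config$n_particles,
                config$sigma_proc, config$sigma_lik, seed = seed * 7L + 1L)
  pl <- pf_init(init_pose$positions["LFoot", 1:2], config$n_particles,
                config$sigma_proc, config$sigma_lik, seed = seed * 7L + 2L)
  prior <- init_pose
  knee_off <- c(0, 0, skeleton$head_unit)  # nominal knee above the foot estimate
  last_t <- times[1] - 1 / config$lidar_rate
  occ <- if (is.null(reference)) NULL else {
    voxel_occupancy(reference, config$voxel_resolution)
  }
  for (i in seq_len(n)) {
    user <- if (is.null(occ)) clouds[[i]] else {
      extract_user_cloud(occ, clouds[[i]], realtime = TRUE)
    }
    dt <- max(times[i] - last_t, 1e-6)
    pr <- pf_predict(pr, dt, seed = seed + 13L * i)
    pl <- pf_predict(pl, dt, seed = seed + 13L * i + 5L)
    legs <- cluster_leg_points(user, skeleton, prior, config$cluster_threshold,
                               floor_z)
    occluded[i] <- legs$occluded
    merged[i] <- legs$merged
    if (!legs$occluded) {
      if (n_points(legs$right) >= 5L) {
        pr <- pf_update(pr, legs$right, seed = seed + 31L * i,
                        obs_mode = config$leg_obs, floor_z = floor_z)
        updated[i, "right"] <- TRUE
      }
      if (n_points(legs$left) >= 5L) {
        pl <- pf_update(pl, legs$left, seed = seed + 31L * i + 7L,
                        obs_mode = config$leg_obs, floor_z = floor_z)
        updated[i, "left"] <- TRUE
      }
    }
    fp <- foot_positions(pr, pl, floor_z)
    right[i, ] <- fp["RFoot", ]
    left[i, ] <- fp["LFoot", ]
    # synthetic prior pose for the next assignment: knees above the feet
    pp <- prior$positions
    pp["RKnee", ] <- fp["RFoot", ] + knee_off
    pp["LKnee", ] <- fp["LFoot", ] + knee_off
    prior <- pose_frame(pp, timestamp = times[i])
    last_t <- times[i]
  }
  list(times = times, right = right, left = left, merged = merged,
       occluded = occluded, updated = updated)
}
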