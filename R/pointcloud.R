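#' Point-cloud frames and the height-from-cloud pipeline
#'
#' A `pc_frame` holds one timestamped set of 3D points from one or both
#' lidars. Clouds are tagged with a coordinate frame: `"world"` (`+z` up,
#' used by all kinematics) or `"L1"` (the ceiling sensor frame, `+y`
#' pointing down toward the floor so that the floor has maximal `y`).
#' Variants follow the capture pipeline: `reference` (scene without the
#' subject), `full_body` (calibration scan with the subject), `user`
#' (subject only, after change detection), `realtime`, and `leg`.
#'
#' @name pointcloud
NULL

PC_VARIANTS <- c("reference", "full_body", "user", "realtime", "leg")

#' Construct a point-cloud frame
#'
#' @param points n x 3 numeric matrix (meters); may have zero rows.
#' @param timestamp seconds from session start.
#' @param variant one of `r paste(PC_VARIANTS, collapse = ", ")`.
#' @param frame `"world"` or `"L1"`.
#' @param sensor optional per-point sensor id (length-1 or length-n).
#' @export
pc_frame <- function(points, timestamp = 0, variant = "reference",
                     frame = "world", sensor = NULL) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  points <- as.matrix(points)
  colnames(points) <- c("x", "y", "z")
  stopifnot(ncol(points) == 3L, all(is.finite(points)))
  variant <- match.arg(variant, PC_VARIANTS)
  frame <- match.arg(frame, c("world", "L1"))
  if (!is.null(sensor) && length(sensor) == 1L && nrow(points) > 0L) {
    sensor <- rep(sensor, nrow(points))
  }
  structure(list(points = points, timestamp = timestamp, variant = variant,
                 frame = frame, sensor = sensor),
            class = "pc_frame")
}

#' @export
print.pc_frame <- function(x, ...) {
  cat(sprintf("<pc_frame %s/%s> %d points, t = %.3f s\n",
              x$variant, x$frame, nrow(x$points), x$timestamp))
  invisible(x)
}

n_points <- function(cloud) nrow(cloud$points)

# Integer voxel indices packed into one double (exact for |index| < 2048,
# i.e. clouds within +/-200 m at 0.1 m resolution).
voxel_keys <- function(points, resolution) {
  if (nrow(points) == 0L) return(numeric(0))
  i <- floor(points / resolution) + 2048
  i[, 1] + 4096 * (i[, 2] + 4096 * i[, 3])
}

#' Precompute the voxel occupancy of a reference cloud
#'
#' Returns the set of voxel keys occupied by the cloud, optionally dilated
#' by one voxel in all 26 neighbor directions. Dilation makes change
#' detection robust to range noise (a noisy return from a known surface
#' lands at most one voxel away when the noise is small against the voxel
#' size); points of a genuinely new object further than two voxels from
#' every reference surface are never suppressed.
#'
#' @param reference a `pc_frame`.
#' @param resolution voxel edge length (meters).
#' @param dilate 0 (literal occupancy) or 1 (26-neighborhood dilation).
#' @export
voxel_occupancy <- function(reference, resolution, dilate = 1L) {
  keys <- unique(voxel_keys(reference$points, resolution))
  if (dilate > 0L) {
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    keys <- unique(as.numeric(outer(keys, offs[, 1] + 4096 * (offs[, 2] + 4096 * offs[, 3]), "+")))
  }
  structure(list(keys = keys, resolution = resolution, frame = reference$frame),
            class = "voxel_occupancy")
}

#' Grid-connectivity Euclidean clustering
#'
#' Approximate single-linkage clustering: points are binned at the cluster
#' distance, and occupied bins whose indices differ by at most one in every
#' axis are merged (union-find). Points in the same component are closer
#' than `2 * sqrt(3) * threshold`; points further apart than that are never
#' merged, and points within `threshold` always are.
#'
#' @param points n x 3 matrix.
#' @param threshold cluster distance in meters.
#' @return integer vector of cluster labels (1 = largest cluster).
#' @export
euclidean_cluster_labels <- function(points, threshold) {
  n <- nrow(points)
  if (n == 0L) return(integer(0))
  key <- voxel_keys(points, threshold)
  cells <- unique(key)
  cell_of <- match(key, cells)
  m <- length(cells)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  off_key <- offs[, 1] + 4096 * (offs[, 2] + 4096 * offs[, 3])
  for (k in seq_len(nrow(offs))) {
    j <- match(cells + off_key[k], cells)
    hit <- which(!is.na(j))
    for (i in hit) {
      ri <- find(i); rj <- find(j[i])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  comp <- match(roots, unique(roots))
  labels <- comp[cell_of]
  sizes <- tabulate(labels)
  match(labels, order(sizes, decreasing = TRUE))
}

#' Extract the subject's points by voxel change detection
#'
#' Implements octree-style change detection between the reference scene and
#' an observed cloud: points of the observed cloud falling in voxels that
#' contain no reference point are kept, then only the largest Euclidean
#' cluster is retained (stray changed voxels from noise or reflections are
#' dropped).
#'
#' @param reference reference `pc_frame` (scene without the subject), or a
#'   precomputed [voxel_occupancy()] (cheaper when diffing many frames).
#' @param observed observed `pc_frame` in the same coordinate frame.
#' @param voxel_resolution voxel edge length in meters (default 0.05).
#' @param cluster_threshold Euclidean cluster distance for the post-filter
#'   (meters); `NULL` disables the cluster filter.
#' @param realtime tag the result `realtime` instead of `user`.
#' @param dilate reference-occupancy dilation passed to
#'   [voxel_occupancy()]; ignored when `reference` is already an occupancy.
#' @return `pc_frame` with variant `user` (or `realtime`).
#' @export
extract_user_cloud <- function(reference, observed, voxel_resolution = 0.05,
                               cluster_threshold = 0.25, realtime = FALSE,
                               dilate = 1L) {
  stopifnot(inherits(observed, "pc_frame"))
  if (voxel_resolution <= 0) stop("voxel_resolution must be > 0")
  occ <- if (inherits(reference, "voxel_occupancy")) reference else {
    stopifnot(inherits(reference, "pc_frame"))
    voxel_occupancy(reference, voxel_resolution, dilate)
  }
  if (!identical(occ$frame, observed$frame)) {
    stop("invalid frame: reference is in '", occ$frame,
         "' but observed is in '", observed$frame, "'")
  }
  variant <- if (realtime) "realtime" else "user"
  if (n_points(observed) == 0L) {
    warning("observed cloud is empty; returning empty user cloud")
    return(pc_frame(observed$points, observed$timestamp, variant, observed$frame))
  }
  keep <- !(voxel_keys(observed$points, occ$resolution) %in% occ$keys)
  pts <- observed$points[keep, , drop = FALSE]
  sens <- observed$sensor[keep]
  if (nrow(pts) > 0L && !is.null(cluster_threshold)) {
    lab <- euclidean_cluster_labels(pts, cluster_threshold)
    pts <- pts[lab == 1L, , drop = FALSE]
    sens <- sens[lab == 1L]
  }
  out <- pc_frame(pts, observed$timestamp, variant, observed$frame, sensor = sens)
  attr(out, "sensor_positions") <- attr(observed, "sensor_positions")
  out
}

#' Ground point of a cloud in the ceiling-sensor frame
#'
#' The floor is the deepest surface seen from the ceiling-mounted lidar, so
#' the ground point `g` is the point with maximal `y` component in the L1
#' frame. Ties are broken by smallest `x`, then smallest `z`.
#'
#' @param full_cloud `pc_frame` in the L1 frame.
#' @return length-3 named vector.
#' @export
ground_point <- function(full_cloud) {
  stopifnot(inherits(full_cloud, "pc_frame"))
  if (n_points(full_cloud) == 0L) stop("empty cloud: no ground point")
  p <- full_cloud$points
  i <- order(-p[, 2], p[, 1], p[, 3])[1]
  p[i, ]
}

#' Floor slope from the user cloud extrema
#'
#' The ceiling lidar is mounted with a slight tilt, so the floor appears
#' sloped in its frame. The slope is taken literally from the maxima of the
#' user cloud against the ground point:
#' `m = (maxy - gy) / (maxx - gx)`.
#'
#' @param user_cloud user-variant `pc_frame` in the L1 frame.
#' @param g ground point from [ground_point()].
#' @return dimensionless slope `m`.
#' @export
floor_slope <- function(user_cloud, g) {
  stopifnot(inherits(user_cloud, "pc_frame"))
  if (n_points(user_cloud) == 0L) stop("empty cloud: cannot estimate slope")
  maxx <- max(user_cloud$points[, 1])
  maxy <- max(user_cloud$points[, 2])
  if (abs(maxx - g[1]) < 1e-12) {
    stop("degenerate geometry: maxx equals gx (vertical reference line)")
  }
  (maxy - g[2]) / (maxx - g[1])
}

#' Robust floor slope from the reference scene
#'
#' Alternative slope estimate: selects reference points within a depth band
#' below the deepest return and fits `y ~ x` by iteratively reweighted
#' least squares, trimming residuals beyond 3 cm (wall-bottom points).
#' Change detection truncates the user cloud one voxel above the floor,
#' which biases the literal extrema-based slope; this estimate is immune to
#' that and is the calibration default.
#'
#' @param reference_l1 reference `pc_frame` in the L1 frame.
#' @param band depth band below the maximal `y` to treat as floor (meters).
#' @return slope `dy/dx` of the floor in the L1 frame.
#' @export
fit_floor_slope <- function(reference_l1, band = 0.2) {
  stopifnot(inherits(reference_l1, "pc_frame"))
  p <- reference_l1$points
  if (nrow(p) < 10L) stop("too few points to fit the floor")
  sel <- p[, 2] > max(p[, 2]) - band
  fp <- p[sel, , drop = FALSE]
  fit <- stats::lm.fit(cbind(1, fp[, 1]), fp[, 2])
  for (it in 1:3) {
    keep <- abs(fit$residuals) < 0.03
    if (sum(keep) < 10L) break
    fp <- fp[keep, , drop = FALSE]
    fit <- stats::lm.fit(cbind(1, fp[, 1]), fp[, 2])
  }
  unname(fit$coefficients[2])
}

#' Centroid of a cloud
#' @param cloud a `pc_frame`.
#' @export
centroid <- function(cloud) {
  stopifnot(inherits(cloud, "pc_frame"))
  if (n_points(cloud) == 0L) stop("empty cloud: no centroid")
  colMeans(cloud$points)
}

#' Estimate the subject's standing height
#'
#' `Ah = (gy - miny) + cx * m`: depth from the ground point to the top of
#' the head, corrected for the floor slope at the subject's location, where
#' `miny` is the minimal `y` of the user cloud (top of the head in the L1
#' frame) and `cx` the `x` component of its centroid.
#'
#' @param user_cloud user-variant `pc_frame` in the L1 frame.
#' @param g ground point.
#' @param m floor slope.
#' @return height `Ah` in meters.
#' @export
estimate_height <- function(user_cloud, g, m) {
  stopifnot(inherits(user_cloud, "pc_frame"))
  if (n_points(user_cloud) == 0L) stop("empty cloud: cannot estimate height")
  miny <- min(user_cloud$points[, 2])
  cx <- centroid(user_cloud)[1]
  ah <- (g[2] - miny) + cx * m
  if (ah <= 0) warning(sprintf("implausible height %.3f m", ah))
  unname(ah)
}

# ---- rigid transforms between the world and L1 frames -----------------------

#' Rigid world-to-L1 transform of the ceiling sensor
#'
#' The L1 frame keeps `x` along the room's long axis, points `y` downward
#' (so the floor has maximal `y`) and `z` across the room, then applies the
#' mounting tilt of the sensor.
#'
#' @param position sensor position in world coordinates.
#' @param tilt_deg mounting tilt about the L1 `z` axis, degrees. Positive
#'   tilt makes the floor appear deeper toward small `x`.
#' @return list with rotation `R` and translation such that
#'   `p_L1 = R %*% (p_world - position)`.
#' @export
l1_transform <- function(position, tilt_deg = 0) {
  M <- matrix(c(1, 0, 0,
                0, 0, -1,
                0, 1, 0), 3, 3, byrow = TRUE)
  a <- -tilt_deg * pi / 180
  Rz <- matrix(c(cos(a), -sin(a), 0,
                 sin(a), cos(a), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  list(R = Rz %*% M, origin = as.numeric(position))
}

#' Transform a cloud between the world and L1 frames
#'
#' @param cloud a `pc_frame`.
#' @param transform result of [l1_transform()].
#' @param to target frame, `"L1"` or `"world"`.
#' @export
transform_cloud <- function(cloud, transform, to = c("L1", "world")) {
  to <- match.arg(to)
  stopifnot(inherits(cloud, "pc_frame"))
  if (identical(cloud$frame, to)) return(cloud)
  p <- cloud$points
  if (to == "L1") {
    q <- sweep(p, 2, transform$origin) %*% t(transform$R)
  } else {
    q <- p %*% transform$R  # inverse rotation: R is orthonormal
    q <- sweep(q, 2, -transform$origin)
  }
  out <- pc_frame(q, cloud$timestamp, cloud$variant, to, sensor = cloud$sensor)
  out
}

#' Calibrate height and skeleton from a capture session
#'
#' Averages the calibration full-body clouds ray-wise (they share the same
#' deterministic scan grid), extracts the subject by change detection,
#' estimates the floor slope and height in the L1 frame, and builds the
#' skeleton.
#'
#' @param reference reference `pc_frame` (world frame, both sensors).
#' @param full_frames list of full-body calibration `pc_frame`s.
#' @param transform world-to-L1 transform of the ceiling sensor.
#' @param voxel_resolution change-detection voxel size (meters).
#' @param slope_mode `"floor_fit"` (default) fits the reference floor;
#'   `"literal"` uses the user-cloud extrema formula.
#' @param sensor_id id of the ceiling sensor in the per-point sensor tags.
#' @param proportions optional proportion table for [build_skeleton()].
#' @return list: `skeleton`, `height`, `slope`, `ground`, `user_cloud`.
#' @export
calibrate_session <- function(reference, full_frames, transform,
                              voxel_resolution = 0.05,
                              slope_mode = c("floor_fit", "literal"),
                              sensor_id = "L1",
                              proportions = default_proportions()) {
  slope_mode <- match.arg(slope_mode)
  if (!length(full_frames)) stop("no calibration frames supplied")
  l1_only <- function(fr) {
    if (is.null(fr$sensor)) return(fr)
    keep <- fr$sensor == sensor_id
    pc_frame(fr$points[keep, , drop = FALSE], fr$timestamp, fr$variant,
             fr$frame, sensor = fr$sensor[keep])
  }
  refs1 <- l1_only(reference)
  fulls <- lapply(full_frames, l1_only)
  npts <- vapply(fulls, n_points, integer(1))
  if (length(unique(npts)) == 1L && length(fulls) > 1L) {
    acc <- Reduce(`+`, lapply(fulls, function(f) f$points)) / length(fulls)
    full <- pc_frame(acc, fulls[[1]]$timestamp, "full_body", fulls[[1]]$frame,
                     sensor = fulls[[1]]$sensor)
  } else {
    full <- fulls[[1]]
  }
  ref_l1 <- transform_cloud(refs1, transform, "L1")
  full_l1 <- transform_cloud(full, transform, "L1")
  user <- extract_user_cloud(ref_l1, full_l1, voxel_resolution)
  g <- ground_point(full_l1)
  m <- if (slope_mode == "literal") floor_slope(user, g) else fit_floor_slope(ref_l1)
  ah <- estimate_height(user, g, m)
  list(skeleton = build_skeleton(ah, proportions), height = ah, slope = m,
       ground = g, user_cloud = user)
}
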