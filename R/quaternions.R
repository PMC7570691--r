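#' Quaternion utilities
#'
#' Quaternions are stored scalar-first as rows `(qw, qx, qy, qz)` of a
#' numeric matrix. All rotations are active, right-handed Hamilton
#' rotations: a unit quaternion `q` rotates a vector `v` by the conjugation
#' `q (0, v) q^-1`.
#'
#' @param q,a,b quaternion matrices (n x 4) or length-4 vectors.
#' @name quaternions
NULL

as_quat <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, ncol = 4L)
  stopifnot(ncol(q) == 4L)
  q
}

quat_norm <- function(q) {
  q <- as_quat(q)
  sqrt(rowSums(q * q))
}

#' @describeIn quaternions Scale rows to unit norm.
#' @export
quat_normalize <- function(q) {
  q <- as_quat(q)
  n <- quat_norm(q)
  if (any(n < 1e-12)) stop("cannot normalize a zero quaternion")
  q / n
}

#' @describeIn quaternions Conjugate `(qw, -qx, -qy, -qz)`.
#' @export
quat_conjugate <- function(q) {
  q <- as_quat(q)
  q[, 2:4] <- -q[, 2:4]
  q
}

#' @describeIn quaternions Multiplicative inverse (conjugate over squared norm).
#' @export
quat_inverse <- function(q) {
  q <- as_quat(q)
  quat_conjugate(q) / rowSums(q * q)
}

#' @describeIn quaternions Hamilton product `a %*% b`, vectorized over rows;
#'   a single-row argument is recycled.
#' @export
quat_multiply <- function(a, b) {
  a <- as_quat(a); b <- as_quat(b)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  stopifnot(nrow(a) == nrow(b))
  w <- a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4]
  x <- a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3]
  y <- a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2]
  z <- a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  cbind(w, x, y, z, deparse.level = 0L)
}

#' Rotate a vector by unit quaternion conjugation
#'
#' Embeds `v` as the pure quaternion `(0, v)` and evaluates
#' `q (0, v) q^-1`, returning the vector part. With `q` an n x 4 matrix and
#' `v` a single vector (or n x 3 matrix) the operation is vectorized.
#'
#' @param q unit quaternion(s), n x 4.
#' @param v vector(s) to rotate, length 3 or n x 3.
#' @return n x 3 matrix of rotated vectors.
#' @export
quat_rotate <- function(q, v) {
  q <- as_quat(q)
  if (is.null(dim(v))) v <- matrix(v, ncol = 3L)
  if (nrow(v) == 1L && nrow(q) > 1L) v <- v[rep(1L, nrow(q)), , drop = FALSE]
  if (nrow(q) == 1L && nrow(v) > 1L) q <- q[rep(1L, nrow(v)), , drop = FALSE]
  if (any(abs(rowSums(v * v)) < 1e-24)) stop("cannot rotate a zero vector")
  qv <- cbind(0, v, deparse.level = 0L)
  rv <- quat_multiply(quat_multiply(q, qv), quat_inverse(q))
  rv[, 2:4, drop = FALSE]
}

#' @describeIn quaternions Unit quaternion for a rotation of `angle_deg`
#'   degrees about `axis`.
#' @param axis rotation axis (length 3, need not be unit).
#' @param angle_deg rotation angle in degrees.
#' @export
quat_axis_angle <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  half <- angle_deg * pi / 360
  c(cos(half), sin(half) * axis)
}

quat_identity <- function(n = 1L) {
  cbind(rep(1, n), 0, 0, 0, deparse.level = 0L)
}

#' @describeIn quaternions Convert unit quaternion(s) to a 3 x 3 rotation
#'   matrix (single row only).
#' @export
quat_to_matrix <- function(q) {
  q <- as_quat(q)
  stopifnot(nrow(q) == 1L)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    j <- i %% 3L + 1L; k <- j %% 3L + 1L
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- 0.25 * s
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

#' Enforce sign continuity on a quaternion time series
#'
#' Unit quaternions double-cover rotations: `q` and `-q` encode the same
#' orientation, and hardware streams may flip sign between frames. Flips the
#' sign of any frame whose dot product with its predecessor is negative.
#'
#' @param q n x 4 matrix, rows ordered in time.
#' @export
quat_continuize <- function(q) {
  q <- as_quat(q)
  if (nrow(q) < 2L) return(q)
  s <- 1
  for (i in 2:nrow(q)) {
    if (sum(q[i, ] * q[i - 1L, ]) < 0) q[i, ] <- -q[i, ]
  }
  q
}

#' Spherical linear interpolation between two unit quaternions
#'
#' @param q0,q1 unit quaternions (length 4).
#' @param t interpolation parameter(s) in `[0, 1]`.
#' @return length(t) x 4 matrix.
#' @export
quat_slerp <- function(q0, q1, t) {
  d <- sum(q0 * q1)
  if (d < 0) { q1 <- -q1; d <- -d }
  if (d > 1 - 1e-10) {
    out <- outer(1 - t, q0) + outer(t, q1)
    return(quat_normalize(out))
  }
  th <- acos(min(1, d))
  (outer(sin((1 - t) * th), q0) + outer(sin(t * th), q1)) / sin(th)
}

#' Relative rotation angle between two unit quaternions (degrees)
#' @param q1,q2 unit quaternions (length 4).
#' @export
quat_relative_angle <- function(q1, q2) {
  d <- abs(sum(as_quat(q1) * as_quat(q2)))
  2 * acos(min(1, d)) * 180 / pi
}
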