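#' Quaternion streams and forward-kinematic pose solving
#'
#' Wearable IMUs report one unit quaternion per sensed segment at a fixed
#' rate. Calibration is a single upright attention stance held at frame 0:
#' aligning every stream by its first sample cancels arbitrary constant
#' mounting offsets. Aligned quaternions rotate the rest-pose segment
#' directions, and joint positions follow by chaining
#' `P_current = P_neighbor + Jv * Slength` from a fixed base: bottom-up
#' from the stance foot to the pelvis, then top-down from the pelvis to all
#' extremities.
#'
#' @name kinematics
NULL

#' Construct a quaternion stream
#'
#' @param times strictly increasing timestamps (seconds), length n.
#' @param quats n x s x 4 array; `dimnames[[2]]` are sensed segment ids
#'   (`b1`, `b2`, ...). Rows are renormalized and sign-continuized.
#' @param aligned has the stream already been aligned by its first frame?
#' @export
quat_stream <- function(times, quats, aligned = FALSE) {
  stopifnot(length(dim(quats)) == 3L, dim(quats)[3] == 4L,
            dim(quats)[1] == length(times))
  if (is.unsorted(times, strictly = TRUE)) {
    stop("timestamps must be strictly increasing")
  }
  segs <- dimnames(quats)[[2]]
  if (is.null(segs)) stop("quaternion array must carry segment ids")
  for (s in seq_along(segs)) {
    q <- quats[, s, , drop = TRUE]
    if (is.null(dim(q))) q <- matrix(q, ncol = 4L)
    n <- sqrt(rowSums(q * q))
    if (any(abs(n - 1) > 1e-3)) {
      stop(sprintf("segment %s: %d quaternions deviate from unit norm by > 1e-3",
                   segs[s], sum(abs(n - 1) > 1e-3)))
    }
    quats[, s, ] <- quat_continuize(q / n)
  }
  structure(list(times = times, quats = quats, segments = segs,
                 aligned = aligned),
            class = "quat_stream")
}

#' @export
print.quat_stream <- function(x, ...) {
  cat(sprintf("<quat_stream> %d frames x %d segments, %s\n", length(x$times),
              length(x$segments), if (x$aligned) "aligned" else "raw"))
  invisible(x)
}

#' Align a stream by its calibration frame
#'
#' `Aq_i = q_i * q_0^-1` for every frame and segment. After alignment the
#' first frame is the identity, and any constant right-multiplied mounting
#' offset cancels. Re-aligning an aligned stream is refused.
#'
#' @param stream a raw [quat_stream()].
#' @return the aligned stream.
#' @export
align_quaternions <- function(stream) {
  stopifnot(inherits(stream, "quat_stream"))
  if (stream$aligned) stop("stream is already aligned; refusing to align twice")
  if (!length(stream$times)) stop("empty stream")
  out <- stream$quats
  for (s in seq_along(stream$segments)) {
    q <- out[, s, , drop = TRUE]
    if (is.null(dim(q))) q <- matrix(q, ncol = 4L)
    q0inv <- quat_inverse(q[1, , drop = FALSE])
    out[, s, ] <- quat_multiply(q, q0inv)
  }
  quat_stream(stream$times, out, aligned = TRUE)
}

#' Rotate a rest-pose bone vector by an aligned quaternion
#'
#' Embeds the rest direction as the pure quaternion `(0, v)` and conjugates:
#' `Rv = Aq (0, v) Aq^-1`; the vector part is the current bone direction.
#'
#' @param aq unit quaternion (length 4 or 1 x 4).
#' @param rest_vector unit 3-vector.
#' @return unit 3-vector.
#' @export
rotate_bone_vector <- function(aq, rest_vector) {
  if (sum(rest_vector^2) < 1e-24) stop("rest_vector must be non-zero")
  drop(quat_rotate(as_quat(aq), rest_vector))
}

#' Update a joint position along a segment
#'
#' `P_current = P_neighbor + Jv * Slength`.
#'
#' @param neighbor_position known neighbor joint position (length 3).
#' @param jv unit bone direction (length 3).
#' @param slength segment length in meters (>= 0).
#' @export
update_joint_position <- function(neighbor_position, jv, slength) {
  stopifnot(slength >= 0)
  neighbor_position + jv * slength
}

#' Fill in the orientations of unsensed segments
#'
#' The two torso-shoulder offsets and the spine-torso segment copy the
#' upper-trunk sensor; the two pelvis-hip offsets copy the lower-trunk
#' (pelvis) sensor. Sensed entries pass through unchanged.
#'
#' @param frame_q matrix of per-segment quaternions with rownames `b1` ...;
#'   must contain every sensed segment.
#' @param skeleton the skeleton (defines the sensed/derived split).
#' @return 15 x 4 matrix ordered `b1..b15`.
#' @export
derive_unsensed_orientations <- function(frame_q, skeleton) {
  segs <- skeleton$segments
  out <- matrix(NA_real_, 15L, 4L, dimnames = list(segs$id, c("w", "x", "y", "z")))
  have <- rownames(frame_q)
  sensed_ids <- segs$id[segs$sensed]
  missing <- setdiff(sensed_ids, have)
  for (i in which(!segs$sensed)) {
    src <- segs$source[i]
    if (src %in% missing || !(src %in% have)) {
      stop("missing sensor for segment ", segs$id[i],
           ": source segment ", src, " has no quaternion")
    }
  }
  if (length(missing)) {
    stop("missing sensor quaternions for segment(s) ",
         paste(missing, collapse = ", "))
  }
  out[sensed_ids, ] <- frame_q[sensed_ids, ]
  der <- which(!segs$sensed)
  out[der, ] <- frame_q[segs$source[der], ]
  out
}

leg_chain <- function(foot) {
  if (foot == "RFoot") c("b12", "b11", "b10") else c("b15", "b14", "b13")
}

#' Bottom-up chain update from a fixed foot
#'
#' Walks the stance leg from the foot toward the pelvis, applying the joint
#' update with each segment's rotated rest direction negated (the traversal
#' runs distal to proximal). The foot position is preserved exactly.
#'
#' @param orientations 15 x 4 matrix of per-segment quaternions (`b1..b15`).
#' @param fixed_foot `"RFoot"` or `"LFoot"`.
#' @param foot_position world position of the fixed foot.
#' @param skeleton the skeleton.
#' @return named list of positions: foot, knee, hip, and `Pelvis`.
#' @export
bottom_up_update <- function(orientations, fixed_foot, foot_position, skeleton) {
  stopifnot(fixed_foot %in% c("RFoot", "LFoot"))
  segs <- skeleton$segments
  pos <- list()
  pos[[fixed_foot]] <- as.numeric(foot_position)
  cur <- fixed_foot
  for (id in leg_chain(fixed_foot)) {
    row <- segs[segs$id == id, ]
    jv <- rotate_bone_vector(orientations[id, ], rest_direction(row))
    pos[[row$proximal]] <- update_joint_position(pos[[cur]], -jv, row$length)
    cur <- row$proximal
  }
  pos
}

#' Top-down chain update from the pelvis
#'
#' Traverses the segment tree from the pelvis outward, updating every joint
#' from its proximal neighbor.
#'
#' @inheritParams bottom_up_update
#' @param pelvis_position world position of the pelvis.
#' @param timestamp carried into the output frame.
#' @return a `pose_frame` with all 16 joints.
#' @export
top_down_update <- function(orientations, pelvis_position, skeleton,
                            timestamp = 0) {
  segs <- skeleton$segments
  pos <- matrix(NA_real_, 16L, 3L, dimnames = list(skeleton$joints, c("x", "y", "z")))
  pos["Pelvis", ] <- as.numeric(pelvis_position)
  remaining <- seq_len(nrow(segs))
  while (length(remaining)) {
    ready <- remaining[!is.na(pos[segs$proximal[remaining], 1])]
    if (!length(ready)) stop("segment graph is not connected")
    for (i in ready) {
      jv <- rotate_bone_vector(orientations[segs$id[i], ],
                               rest_direction(segs[i, ]))
      pos[segs$distal[i], ] <- update_joint_position(pos[segs$proximal[i], ],
                                                     jv, segs$length[i])
    }
    remaining <- setdiff(remaining, ready)
  }
  pose_frame(pos, timestamp = timestamp, quaternions = orientations)
}

#' Solve one full-body pose from a fixed stance foot
#'
#' Composes the bottom-up update (stance foot to pelvis) with the top-down
#' update (pelvis to all joints), then translates the pose vertically so
#' the stance foot lies on the floor plane.
#'
#' @inheritParams bottom_up_update
#' @param stance_foot `"RFoot"` or `"LFoot"`.
#' @param stance_position world position of the stance foot.
#' @param floor_z height of the floor plane (world frame).
#' @param timestamp carried into the output frame.
#' @return a `pose_frame` with stance annotation.
#' @export
solve_pose <- function(orientations, skeleton, stance_foot, stance_position,
                       floor_z = 0, timestamp = 0) {
  bu <- bottom_up_update(orientations, stance_foot, stance_position, skeleton)
  pf <- top_down_update(orientations, bu$Pelvis, skeleton, timestamp = timestamp)
  dz <- floor_z - pf$positions[stance_foot, 3]
  pf$positions[, 3] <- pf$positions[, 3] + dz
  pf$stance <- stance_foot
  pf
}

#' Construct a pose track
#'
#' @param times timestamps, strictly increasing.
#' @param positions n x 16 x 3 array of joint positions.
#' @param stance per-frame stance annotation.
#' @param quaternions optional n x 15 x 4 array of segment orientations.
#' @param skeleton the skeleton the track was solved against.
#' @param diagnostics optional per-frame diagnostics data.frame.
#' @export
pose_track <- function(times, positions, stance = NULL, quaternions = NULL,
                       skeleton = NULL, diagnostics = NULL) {
  stopifnot(length(dim(positions)) == 3L, dim(positions)[2] == 16L,
            dim(positions)[1] == length(times))
  if (is.unsorted(times, strictly = TRUE)) {
    stop("timestamps must be strictly increasing")
  }
  if (is.null(dimnames(positions)[[2]])) dimnames(positions)[[2]] <- JOINT_NAMES
  structure(list(times = times, positions = positions, stance = stance,
                 quaternions = quaternions, skeleton = skeleton,
                 diagnostics = diagnostics),
            class = "pose_track")
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track> %d frames, %.2f s at ~%.0f Hz\n", length(x$times),
              diff(range(x$times)),
              1 / stats::median(diff(x$times))))
  invisible(x)
}

#' Solve a whole orientation timeline into a pose track
#'
#' Sequentially anchors each frame at the current stance foot: the stance
#' foot keeps the position it had in the previous frame, and stance hand-off
#' transfers the anchor to the other foot at its current solved position
#' (projected to the floor). This is the inertial-only path with no lidar
#' correction.
#'
#' @param times timestamps (seconds).
#' @param quats n x 15 x 4 array of completed segment orientations.
#' @param stance per-frame stance foot (`"RFoot"`/`"LFoot"`).
#' @param skeleton the skeleton.
#' @param init_stance_position world position of the stance foot at frame 1.
#' @param floor_z floor plane height.
#' @return a `pose_track`.
#' @export
solve_track <- function(times, quats, stance, skeleton,
                        init_stance_position = c(0, 0, 0), floor_z = 0) {
  n <- length(times)
  pos <- array(NA_real_, c(n, 16L, 3L), dimnames = list(NULL, JOINT_NAMES, c("x", "y", "z")))
  base <- as.numeric(init_stance_position)
  base[3] <- floor_z
  prev_stance <- stance[1]
  for (i in seq_len(n)) {
    if (stance[i] != prev_stance && i > 1L) {
      # hand-off: anchor the new stance foot where this frame's solution
      # (still anchored on the old foot) places it
      tmp <- solve_pose(quats[i, , ], skeleton, prev_stance, base,
                        floor_z = floor_z, timestamp = times[i])
      base <- tmp$positions[stance[i], ]
      base[3] <- floor_z
    }
    pf <- solve_pose(quats[i, , ], skeleton, stance[i], base,
                     floor_z = floor_z, timestamp = times[i])
    pos[i, , ] <- pf$positions
    base <- pf$positions[stance[i], ]
    prev_stance <- stance[i]
  }
  pose_track(times, pos, stance = stance, quaternions = quats,
             skeleton = skeleton)
}
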