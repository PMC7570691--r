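#' The 16-joint / 15-segment kinematic body model
#'
#' The skeleton is a tree rooted at the pelvis with 16 named joints and 15
#' bone segments `b1..b15`. Segment lengths are parameterized by the head
#' unit `Hh = Ah / 7.5`, where `Ah` is the subject's standing height: an
#' average body is 7.5 head heights tall, and each segment is assigned a
#' length in head units. Ten segments carry an IMU (sensed); the two
#' torso-shoulder offsets and the spine-torso segment follow the upper-trunk
#' sensor, and the two pelvis-hip offsets follow the lower-trunk (pelvis)
#' sensor (derived).
#'
#' Rest-pose directions are expressed in the world frame of the upright
#' attention stance: `+z` up, `+x` forward, `+y` to the subject's left.
#'
#' @name skeleton
NULL

JOINT_NAMES <- c(
  "Head", "Torso", "Spine", "Pelvis",
  "RShoulder", "RElbow", "RWrist", "LShoulder", "LElbow", "LWrist",
  "RHip", "RKnee", "RFoot", "LHip", "LKnee", "LFoot"
)

#' Default anthropometric proportion table
#'
#' Segment lengths and rest directions in head units. The vertical chain
#' (foot, knee, hip, pelvis, spine, torso, head, plus the head extent above
#' the head joint) sums to exactly 7.5 head units so that the skeleton's
#' standing height reproduces the input height. The published anthropometry
#' behind the 7.5-head rule does not fix every segment; this table is the
#' package default and can be replaced via the `proportions` argument of
#' [build_skeleton()] or the session config.
#'
#' @return data.frame with one row per segment `b1..b15`: proximal/distal
#'   joints, length in head units (`hu`), rest direction, sensed flag, and
#'   for derived segments the id of the sensed source segment.
#' @export
default_proportions <- function() {
  tab <- data.frame(
    id       = paste0("b", 1:15),
    proximal = c("Torso", "Pelvis", "Torso", "Torso", "RShoulder", "RElbow",
                 "Spine", "LShoulder", "LElbow", "Pelvis", "RHip", "RKnee",
                 "Pelvis", "LHip", "LKnee"),
    distal   = c("Head", "Spine", "RShoulder", "LShoulder", "RElbow",
                 "RWrist", "Torso", "LElbow", "LWrist", "RHip", "RKnee",
                 "RFoot", "LHip", "LKnee", "LFoot"),
    hu       = c(0.5, 1.0, 0.75, 0.75, 1.5, 1.25, 1.0, 1.5, 1.25,
                 0.5, 2.0, 2.0, 0.5, 2.0, 2.0),
    dx       = rep(0, 15),
    dy       = c(0, 0, -1, 1, 0, 0, 0, 0, 0, -1, 0, 0, 1, 0, 0),
    dz       = c(1, 1, 0, 0, -1, -1, 1, -1, -1, 0, -1, -1, 0, -1, -1),
    sensed   = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE,
                 FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
    source   = c(NA, NA, "b1", "b1", NA, NA, "b1", NA, NA,
                 "b2", NA, NA, "b2", NA, NA),
    stringsAsFactors = FALSE
  )
  attr(tab, "head_top_hu") <- 1.0
  tab
}

# segments on the foot-to-head vertical chain whose head units, plus the
# head extent, must total 7.5
vertical_chain_ids <- function() c("b12", "b11", "b10", "b2", "b7", "b1")

#' Build a skeleton from a standing height
#'
#' Computes the head unit `Hh = actual_height / 7.5` and scales the
#' proportion table into segment lengths in meters.
#'
#' @param actual_height standing height `Ah` in meters (> 0).
#' @param proportions optional proportion table in the format of
#'   [default_proportions()]; its vertical chain (including the head extent
#'   attribute) must sum to 7.5 head units.
#' @return an object of class `skeleton`.
#' @export
build_skeleton <- function(actual_height, proportions = default_proportions()) {
  if (!is.numeric(actual_height) || length(actual_height) != 1L ||
      !is.finite(actual_height) || actual_height <= 0) {
    stop("actual_height must be a positive number (meters)")
  }
  tab <- proportions
  head_top_hu <- attr(tab, "head_top_hu")
  if (is.null(head_top_hu)) head_top_hu <- 1.0
  chain <- vertical_chain_ids()
  vert <- sum(tab$hu[match(chain, tab$id)] *
                abs(tab$dz[match(chain, tab$id)])) + head_top_hu
  if (abs(vert - 7.5) > 1e-9) {
    stop(sprintf(
      "inconsistent proportions: vertical chain sums to %.6f head units, not 7.5",
      vert))
  }
  hh <- actual_height / 7.5
  nrm <- sqrt(tab$dx^2 + tab$dy^2 + tab$dz^2)
  tab$dx <- tab$dx / nrm; tab$dy <- tab$dy / nrm; tab$dz <- tab$dz / nrm
  tab$length <- tab$hu * hh
  sk <- list(
    actual_height = actual_height,
    head_unit = hh,
    head_top = head_top_hu * hh,
    joints = JOINT_NAMES,
    segments = tab
  )
  class(sk) <- "skeleton"
  stopifnot(nrow(tab) == 15L, length(unique(c(tab$proximal, tab$distal))) == 16L)
  sk
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> height %.3f m, head unit %.4f m, %d joints, %d segments (%d sensed)\n",
              x$actual_height, x$head_unit, length(x$joints),
              nrow(x$segments), sum(x$segments$sensed)))
  invisible(x)
}

segment_by_distal <- function(skeleton, joint) {
  i <- match(joint, skeleton$segments$distal)
  if (is.na(i)) stop("no segment with distal joint ", joint)
  skeleton$segments[i, ]
}

rest_direction <- function(seg_row) {
  c(seg_row$dx, seg_row$dy, seg_row$dz)
}

#' Joint coordinates of the upright attention (calibration) stance
#'
#' Places every joint according to the rest-pose directions and segment
#' lengths, anchored at the pelvis. By default the pelvis sits at the
#' height that puts both feet on the floor plane `z = 0`.
#'
#' @param skeleton a [build_skeleton()] result.
#' @param pelvis_position optional pelvis coordinates (length 3).
#' @return a `pose_frame` (16 x 3 joint matrix plus metadata).
#' @export
attention_pose <- function(skeleton, pelvis_position = NULL) {
  stopifnot(inherits(skeleton, "skeleton"))
  if (is.null(pelvis_position)) {
    leg <- sum(skeleton$segments$length[match(c("b11", "b12"), skeleton$segments$id)])
    pelvis_position <- c(0, 0, leg)
  }
  pos <- matrix(NA_real_, 16L, 3L, dimnames = list(JOINT_NAMES, c("x", "y", "z")))
  pos["Pelvis", ] <- pelvis_position
  segs <- skeleton$segments
  remaining <- seq_len(nrow(segs))
  while (length(remaining)) {
    placed <- FALSE
    for (i in remaining) {
      p <- segs$proximal[i]
      if (!anyNA(pos[p, ])) {
        pos[segs$distal[i], ] <- pos[p, ] +
          c(segs$dx[i], segs$dy[i], segs$dz[i]) * segs$length[i]
        remaining <- setdiff(remaining, i)
        placed <- TRUE
      }
    }
    if (!placed) stop("segment graph is not connected")
  }
  pose_frame(pos, timestamp = 0, stance = NA_character_)
}

#' Construct a pose frame
#'
#' @param positions 16 x 3 matrix of joint coordinates (meters, world
#'   frame), rows named by joint.
#' @param timestamp time in seconds.
#' @param stance stance foot annotation (`"RFoot"`, `"LFoot"` or `NA`).
#' @param quaternions optional 15 x 4 matrix of per-segment orientations.
#' @export
pose_frame <- function(positions, timestamp = 0, stance = NA_character_,
                       quaternions = NULL) {
  stopifnot(is.matrix(positions), nrow(positions) == 16L, ncol(positions) == 3L,
            all(is.finite(positions)))
  if (is.null(rownames(positions))) rownames(positions) <- JOINT_NAMES
  structure(list(positions = positions, timestamp = timestamp,
                 stance = stance, quaternions = quaternions),
            class = "pose_frame")
}

#' Serialize a skeleton to JSON
#'
#' @param skeleton a skeleton object.
#' @param path optional file; when omitted the JSON string is returned.
#' @export
skeleton_to_json <- function(skeleton, path = NULL) {
  segs <- skeleton$segments
  obj <- list(
    actual_height = skeleton$actual_height,
    head_unit = skeleton$head_unit,
    head_top = skeleton$head_top,
    joints = data.frame(name = skeleton$joints, id = seq_along(skeleton$joints) - 1L),
    segments = data.frame(
      id = segs$id, proximal = segs$proximal, distal = segs$distal,
      length_m = segs$length,
      rest_dx = segs$dx, rest_dy = segs$dy, rest_dz = segs$dz,
      sensed = segs$sensed, source = segs$source
    )
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a skeleton from its JSON serialization
#' @param path file written by [skeleton_to_json()].
#' @export
skeleton_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  tab <- data.frame(
    id = obj$segments$id, proximal = obj$segments$proximal,
    distal = obj$segments$distal,
    hu = obj$segments$length_m / obj$head_unit,
    dx = obj$segments$rest_dx, dy = obj$segments$rest_dy,
    dz = obj$segments$rest_dz,
    sensed = obj$segments$sensed, source = obj$segments$source,
    stringsAsFactors = FALSE
  )
  attr(tab, "head_top_hu") <- obj$head_top / obj$head_unit
  build_skeleton(obj$actual_height, tab)
}
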