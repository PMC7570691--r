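#' File formats: PCD, PLY, quaternion CSV, pose-track CSV, BVH
#'
#' @name io
NULL

#' Read a point cloud file (PCD or PLY)
#'
#' ASCII and binary PCD dialects and ASCII PLY are supported; the format is
#' chosen by file extension.
#'
#' @param path file path ending in `.pcd` or `.ply`.
#' @param ... passed to [pc_frame()] (timestamp, variant, frame, sensor).
#' @export
read_point_cloud <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pcd = read_pcd(path, ...),
         ply = read_ply(path, ...),
         stop("unsupported format: .", ext, " (expected .pcd or .ply)"))
}

#' @rdname read_point_cloud
#' @param cloud a `pc_frame` to write.
#' @param binary write binary PCD instead of ASCII (PCD only).
#' @export
write_point_cloud <- function(cloud, path, binary = FALSE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pcd = write_pcd(cloud, path, binary = binary),
         ply = write_ply(cloud, path),
         stop("unsupported format: .", ext, " (expected .pcd or .ply)"))
}

read_pcd <- function(path, ...) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  n_lines <- 0L
  repeat {
    line <- readLines(con, 1L)
    n_lines <- n_lines + 1L
    if (!length(line)) stop("malformed PCD header: no DATA line (line ", n_lines, ")")
    if (grepl("^#", line)) next
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (!length(tok)) next
    hdr[[toupper(tok[1])]] <- tok[-1]
    if (toupper(tok[1]) == "DATA") break
  }
  need <- c("FIELDS", "SIZE", "TYPE", "POINTS", "DATA")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) {
    stop("malformed PCD header: missing ", paste(miss, collapse = ", "),
         " (after line ", n_lines, ")")
  }
  fields <- hdr$FIELDS
  npts <- as.integer(hdr$POINTS)
  ix <- match(c("x", "y", "z"), fields)
  if (anyNA(ix)) stop("PCD file lacks x/y/z fields")
  mode <- hdr$DATA[1]
  if (npts == 0L) return(pc_frame(matrix(numeric(0), 0, 3), ...))
  if (mode == "ascii") {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    m <- do.call(rbind, lapply(strsplit(trimws(txt), "\\s+"), as.numeric))
    pts <- m[, ix, drop = FALSE]
  } else if (mode == "binary") {
    sizes <- as.integer(hdr$SIZE)
    types <- hdr$TYPE
    counts <- if (!is.null(hdr$COUNT)) as.integer(hdr$COUNT) else rep(1L, length(fields))
    if (!all(types == "F" & sizes == 4L)) {
      stop("binary PCD reader supports float32 fields only")
    }
    per <- sum(counts)
    raw <- readBin(con, "numeric", n = npts * per, size = 4L)
    m <- matrix(raw, ncol = per, byrow = TRUE)
    col0 <- cumsum(c(0L, counts))[seq_along(fields)] + 1L
    pts <- m[, col0[ix], drop = FALSE]
  } else {
    stop("unsupported PCD DATA mode: ", mode)
  }
  pc_frame(pts, ...)
}

write_pcd <- function(cloud, path, binary = FALSE) {
  stopifnot(inherits(cloud, "pc_frame"))
  p <- cloud$points
  hdr <- c("# .PCD v0.7 - Point Cloud Data file format",
           "VERSION 0.7", "FIELDS x y z", "SIZE 4 4 4", "TYPE F F F",
           "COUNT 1 1 1", paste("WIDTH", nrow(p)), "HEIGHT 1",
           "VIEWPOINT 0 0 0 1 0 0 0", paste("POINTS", nrow(p)),
           paste("DATA", if (binary) "binary" else "ascii"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (binary) {
    writeBin(as.numeric(t(p)), con, size = 4L)
  } else if (nrow(p)) {
    writeLines(paste(format(p[, 1], digits = 9, trim = TRUE, scientific = FALSE),
                     format(p[, 2], digits = 9, trim = TRUE, scientific = FALSE),
                     format(p[, 3], digits = 9, trim = TRUE, scientific = FALSE)),
               con)
  }
  invisible(path)
}

read_ply <- function(path, ...) {
  lines <- readLines(path)
  endh <- which(lines == "end_header")[1]
  if (is.na(endh)) stop("malformed PLY header: no end_header")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", lines, value = TRUE)[1]))
  if (is.na(nv)) stop("malformed PLY header: no vertex element")
  if (nv == 0L) return(pc_frame(matrix(numeric(0), 0, 3), ...))
  body <- lines[(endh + 1L):(endh + nv)]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  pc_frame(m[, 1:3, drop = FALSE], ...)
}

write_ply <- function(cloud, path) {
  p <- cloud$points
  hdr <- c("ply", "format ascii 1.0", paste("element vertex", nrow(p)),
           "property float x", "property float y", "property float z",
           "end_header")
  body <- if (nrow(p)) paste(format(p[, 1], digits = 9, trim = TRUE),
                             format(p[, 2], digits = 9, trim = TRUE),
                             format(p[, 3], digits = 9, trim = TRUE)) else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read and write quaternion CSV streams
#'
#' Long format: one row per segment per frame with columns `timestamp`,
#' `segment_name`, `qw`, `qx`, `qy`, `qz`. On read the rows are sorted by
#' timestamp, validated (norms within 1e-3 of unit, known segment names,
#' one common timestamp grid), renormalized and sign-continuized.
#'
#' @param path CSV file.
#' @return [quat_stream()] (raw).
#' @export
read_quaternion_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "segment_name", "qw", "qx", "qy", "qz")
  if (!all(need %in% names(df))) {
    stop("quaternion CSV must have columns ", paste(need, collapse = ", "))
  }
  bad_seg <- setdiff(unique(df$segment_name), paste0("b", 1:15))
  if (length(bad_seg)) {
    stop("unknown segment names: ", paste(bad_seg, collapse = ", "))
  }
  nrm <- sqrt(df$qw^2 + df$qx^2 + df$qy^2 + df$qz^2)
  bad <- which(abs(nrm - 1) > 1e-3)
  if (length(bad)) {
    stop("non-unit quaternions (|norm - 1| > 1e-3) at rows: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  df <- df[order(df$timestamp, df$segment_name), ]
  segs <- sort(unique(df$segment_name))
  times <- sort(unique(df$timestamp))
  qs <- array(NA_real_, c(length(times), length(segs), 4L),
              dimnames = list(NULL, segs, c("w", "x", "y", "z")))
  for (s in segs) {
    sub <- df[df$segment_name == s, ]
    if (nrow(sub) != length(times) || any(sub$timestamp != times)) {
      stop("segment ", s, " does not share the common timestamp grid")
    }
    qs[, s, ] <- as.matrix(sub[, c("qw", "qx", "qy", "qz")])
  }
  quat_stream(times, qs, aligned = FALSE)
}

#' @rdname read_quaternion_csv
#' @param stream a [quat_stream()] to write.
#' @export
write_quaternion_csv <- function(stream, path) {
  stopifnot(inherits(stream, "quat_stream"))
  rows <- lapply(stream$segments, function(s) {
    data.frame(timestamp = stream$times, segment_name = s,
               qw = stream$quats[, s, 1], qx = stream$quats[, s, 2],
               qy = stream$quats[, s, 3], qz = stream$quats[, s, 4])
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$timestamp, df$segment_name), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and write pose-track CSV
#'
#' Wide format: `timestamp`, `stance`, then `<Joint>_x/_y/_z` for each of
#' the 16 joints (meters).
#'
#' @param track a `pose_track`.
#' @param path CSV file.
#' @export
write_pose_csv <- function(track, path) {
  n <- length(track$times)
  df <- data.frame(timestamp = track$times,
                   stance = if (is.null(track$stance)) NA_character_ else track$stance)
  for (j in dimnames(track$positions)[[2]]) {
    df[[paste0(j, "_x")]] <- track$positions[, j, 1]
    df[[paste0(j, "_y")]] <- track$positions[, j, 2]
    df[[paste0(j, "_z")]] <- track$positions[, j, 3]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pose_csv
#' @export
read_pose_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  pos <- array(NA_real_, c(nrow(df), 16L, 3L),
               dimnames = list(NULL, JOINT_NAMES, c("x", "y", "z")))
  for (j in JOINT_NAMES) {
    pos[, j, ] <- as.matrix(df[, paste0(j, c("_x", "_y", "_z"))])
  }
  pose_track(df$timestamp, pos, stance = df$stance)
}

#' Write a foot track as CSV
#'
#' Columns: `timestamp`, left and right foot coordinates, and the per-frame
#' merged/occluded flags.
#'
#' @param feet result of [track_feet()].
#' @param path CSV file.
#' @export
write_foot_track <- function(feet, path) {
  df <- data.frame(timestamp = feet$times,
                   left_x = feet$left[, 1], left_y = feet$left[, 2],
                   left_z = feet$left[, 3],
                   right_x = feet$right[, 1], right_y = feet$right[, 2],
                   right_z = feet$right[, 3],
                   merged = feet$merged, occluded = feet$occluded)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write per-frame tracker diagnostics as line-delimited JSON
#'
#' One JSON record per IMU frame: timestamp, stance foot, applied
#' correction magnitude, post-correction stance discrepancy, occlusion
#' flag. An audit trail of every fusion decision.
#'
#' @param track a `pose_track` from [track_sequence()].
#' @param path output file.
#' @export
write_diagnostics <- function(track, path) {
  d <- track$diagnostics
  if (is.null(d)) stop("track carries no diagnostics")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(d))) {
    writeLines(jsonlite::toJSON(as.list(d[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  }
  invisible(path)
}

# ---- BVH export -------------------------------------------------------------

# Each segment becomes a BVH node positioned at its proximal joint and
# carrying the segment's rotation (local to the parent segment) — the
# standard convention where a joint node rotates the bone leaving it. A
# node's offset is its parent segment's rest vector times length (all
# children of one segment share it, so branching is consistent). Leaf
# segments emit an End Site with their own rest vector, completing all 16
# joints. Nodes are named by their proximal joint; where several segments
# leave one joint (Pelvis, Torso) the distal joint disambiguates.

bvh_children <- function(skeleton, joint) {
  which(skeleton$segments$proximal == joint)
}

euler_zxy_deg <- function(q) {
  M <- quat_to_matrix(matrix(q, 1))
  sa <- max(-1, min(1, M[3, 2]))
  a <- asin(sa)
  if (abs(abs(sa) - 1) > 1e-9) {
    c_ <- atan2(-M[1, 2], M[2, 2])
    b <- atan2(-M[3, 1], M[3, 3])
  } else {
    c_ <- atan2(M[2, 1], M[1, 1])
    b <- 0
  }
  c(z = c_, x = a, y = b) * 180 / pi
}

#' Write a pose track as a BVH motion-capture file
#'
#' The hierarchy mirrors the skeleton tree (offsets from the rest pose);
#' per-frame channels are derived from the track's per-segment
#' quaternions, so the track must carry orientations (tracks from
#' [track_sequence()] and [generate_motion()] do).
#'
#' @param track a `pose_track` with `quaternions`.
#' @param skeleton the skeleton.
#' @param path output file.
#' @export
write_bvh <- function(track, skeleton, path) {
  stopifnot(inherits(track, "pose_track"))
  if (is.null(track$quaternions)) stop("track carries no segment orientations")
  if (!length(track$times)) stop("empty track")
  segs <- skeleton$segments
  node_lines <- character(0)
  channel_segs <- character(0)  # segment id per 3-rotation channel block
  parent_of <- function(i) {
    j <- which(segs$distal == segs$proximal[i])
    if (length(j)) j else NA_integer_
  }
  node_name <- function(i) {
    if (sum(segs$proximal == segs$proximal[i]) > 1L) {
      paste0(segs$proximal[i], "_", segs$distal[i])
    } else {
      segs$proximal[i]
    }
  }
  emit <- function(i, depth) {
    ind <- strrep("  ", depth)
    pi_ <- parent_of(i)
    off <- if (is.na(pi_)) c(0, 0, 0) else {
      c(segs$dx[pi_], segs$dy[pi_], segs$dz[pi_]) * segs$length[pi_]
    }
    node_lines <<- c(node_lines,
      sprintf("%sJOINT %s", ind, node_name(i)),
      paste0(ind, "{"),
      sprintf("%s  OFFSET %.6f %.6f %.6f", ind, off[1], off[2], off[3]),
      sprintf("%s  CHANNELS 3 Zrotation Xrotation Yrotation", ind))
    channel_segs <<- c(channel_segs, segs$id[i])
    kids <- bvh_children(skeleton, segs$distal[i])
    if (length(kids)) {
      for (k in kids) emit(k, depth + 1L)
    } else {
      off2 <- c(segs$dx[i], segs$dy[i], segs$dz[i]) * segs$length[i]
      node_lines <<- c(node_lines,
        sprintf("%s  End Site", ind), paste0(ind, "  {"),
        sprintf("%s    OFFSET %.6f %.6f %.6f", ind, off2[1], off2[2], off2[3]),
        paste0(ind, "  }"))
    }
    node_lines <<- c(node_lines, paste0(ind, "}"))
  }
  for (k in bvh_children(skeleton, "Pelvis")) emit(k, 1L)

  header <- c("HIERARCHY", "ROOT Pelvis", "{", "  OFFSET 0 0 0",
              "  CHANNELS 6 Xposition Yposition Zposition Zrotation Xrotation Yrotation",
              node_lines, "}")

  n <- length(track$times)
  qarr <- track$quaternions
  frames <- character(n)
  for (f in seq_len(n)) {
    vals <- c(track$positions[f, "Pelvis", ], 0, 0, 0)
    for (id in channel_segs) {
      i <- match(id, segs$id)
      pi_ <- parent_of(i)
      qloc <- if (is.na(pi_)) qarr[f, id, ] else {
        drop(quat_multiply(quat_inverse(matrix(qarr[f, segs$id[pi_], ], 1)),
                           matrix(qarr[f, id, ], 1)))
      }
      vals <- c(vals, euler_zxy_deg(qloc))
    }
    frames[f] <- paste(format(vals, digits = 8, trim = TRUE, scientific = FALSE),
                       collapse = " ")
  }
  ft <- if (n > 1L) stats::median(diff(track$times)) else 1 / 60
  motion <- c("MOTION", paste("Frames:", n),
              sprintf("Frame Time: %.8f", ft), frames)
  writeLines(c(header, motion), path)
  invisible(path)
}
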