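# Shared fixtures. Simulations in the test suite are scaled down (shorter
# durations and, where noted, a coarser azimuth grid) to keep the suite
# fast; scaling is stated next to each use.

identity_orientations <- function(skeleton) {
  matrix(rep(c(1, 0, 0, 0), each = 15L), 15L, 4L,
         dimnames = list(skeleton$segments$id, c("w", "x", "y", "z")))
}

random_unit_quat <- function(n = 1L) {
  m <- matrix(stats::rnorm(4L * n), ncol = 4L)
  m / sqrt(rowSums(m^2))
}

# sensors with a coarser azimuth grid: 3x fewer rays per cloud
fast_sensors <- function(...) {
  sensor_model(azimuth_step = 1.2, ...)
}

# rotation-matrix oracle for quaternion rotation, independent of the
# conjugation path used by the package
oracle_rotate <- function(q, v) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
  as.numeric(R %*% v)
}

oracle_rotmat <- function(q) {
  vapply(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
         function(e) oracle_rotate(q, e), numeric(3))
}

# independent minimal BVH parser + forward kinematics, used as the oracle
# for the writer round trip
parse_bvh <- function(path) {
  lines <- trimws(readLines(path))
  i <- 1L
  nodes <- list()
  stack <- list()   # open blocks: list(type = "node"/"es", id = node index)
  pending <- NULL   # block announced but "{" not yet seen
  top_node <- function() {
    for (k in rev(seq_along(stack))) {
      if (stack[[k]]$type == "node") return(stack[[k]]$id)
    }
    NA_integer_
  }
  while (lines[i] != "MOTION") {
    tok <- strsplit(lines[i], "\\s+")[[1]]
    if (tok[1] %in% c("ROOT", "JOINT")) {
      id <- length(nodes) + 1L
      nodes[[id]] <- list(name = tok[2], offset = NULL, channels = character(0),
                          parent = top_node(), end_site = NULL)
      pending <- list(type = "node", id = id)
    } else if (tok[1] == "End") {
      pending <- list(type = "es", id = top_node())
    } else if (tok[1] == "{") {
      stack[[length(stack) + 1L]] <- pending
    } else if (tok[1] == "}") {
      stack[[length(stack)]] <- NULL
    } else if (tok[1] == "OFFSET") {
      off <- as.numeric(tok[2:4])
      ctx <- stack[[length(stack)]]
      if (ctx$type == "node") nodes[[ctx$id]]$offset <- off
      else nodes[[ctx$id]]$end_site <- off
    } else if (tok[1] == "CHANNELS") {
      ctx <- stack[[length(stack)]]
      nodes[[ctx$id]]$channels <- tok[-(1:2)]
    }
    i <- i + 1L
  }
  nframes <- as.integer(sub("Frames:\\s*", "", lines[i + 1L]))
  vals <- do.call(rbind, lapply(lines[(i + 3L):(i + 2L + nframes)], function(l)
    as.numeric(strsplit(l, "\\s+")[[1]])))
  list(nodes = nodes, motion = vals)
}

# FK over a parsed BVH: returns per-frame named joint positions
bvh_fk <- function(parsed) {
  nodes <- parsed$nodes
  rot <- function(deg, axis) {
    a <- deg * pi / 180
    c_ <- cos(a); s <- sin(a)
    switch(axis,
      X = matrix(c(1, 0, 0, 0, c_, -s, 0, s, c_), 3, byrow = TRUE),
      Y = matrix(c(c_, 0, s, 0, 1, 0, -s, 0, c_), 3, byrow = TRUE),
      Z = matrix(c(c_, -s, 0, s, c_, 0, 0, 0, 1), 3, byrow = TRUE))
  }
  nfr <- nrow(parsed$motion)
  out <- vector("list", nfr)
  for (f in seq_len(nfr)) {
    vals <- parsed$motion[f, ]
    k <- 0L
    pos <- list(); R <- list()
    res <- list()
    for (id in seq_along(nodes)) {
      nd <- nodes[[id]]
      if (is.na(nd$parent)) {
        p <- vals[k + 1:3]; k <- k + 3L
        Rm <- diag(3)
        for (ch in nd$channels[-(1:3)]) {
          k <- k + 1L
          Rm <- Rm %*% rot(vals[k], substr(ch, 1, 1))
        }
        pos[[id]] <- p; R[[id]] <- Rm
      } else {
        p <- pos[[nd$parent]] + as.numeric(R[[nd$parent]] %*% nd$offset)
        Rm <- R[[nd$parent]]
        for (ch in nd$channels) {
          k <- k + 1L
          Rm <- Rm %*% rot(vals[k], substr(ch, 1, 1))
        }
        pos[[id]] <- p; R[[id]] <- Rm
        res[[nd$name]] <- p
        if (!is.null(nd$end_site)) {
          res[[paste0(nd$name, "_end")]] <- p + as.numeric(Rm %*% nd$end_site)
        }
      }
    }
    res[["Pelvis"]] <- pos[[1]]
    out[[f]] <- res
  }
  out
}
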