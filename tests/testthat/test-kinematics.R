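test_that("quaternion rotation matches the rotation-matrix oracle", {
  set.seed(42)
  q <- random_unit_quat(1000)
  v <- matrix(stats::rnorm(3000), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  got <- quat_rotate(q, v)
  want <- t(vapply(seq_len(1000), function(i) oracle_rotate(q[i, ], v[i, ]),
                   numeric(3)))
  expect_lt(max(abs(got - want)), 1e-9)
})

test_that("rotate_bone_vector follows the stated conjugation", {
  # identity leaves the rest vector; the foot rest axis (0,0,1) embeds as
  # the pure quaternion (0,0,0,1)
  expect_equal(rotate_bone_vector(c(1, 0, 0, 0), c(0, 0, 1)), c(0, 0, 1))
  # 90 degrees about x takes +z to -y (right-handed active rotation)
  q <- quat_axis_angle(c(1, 0, 0), 90)
  expect_equal(rotate_bone_vector(q, c(0, 0, 1)), c(0, -1, 0),
               tolerance = 1e-12)
  expect_error(rotate_bone_vector(q, c(0, 0, 0)), "non-zero")
})

test_that("alignment cancels the calibration frame and mounting offsets", {
  set.seed(7)
  n <- 50L
  qs <- array(NA_real_, c(n, 2L, 4L),
              dimnames = list(NULL, c("b1", "b2"), NULL))
  for (s in 1:2) qs[, s, ] <- quat_continuize(random_unit_quat(n))
  st <- quat_stream(seq_len(n) / 60, qs)
  al <- align_quaternions(st)
  expect_true(al$aligned)
  expect_equal(al$quats[1, 1, ], c(1, 0, 0, 0), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(align_quaternions(al), "already aligned")

  # q0 = 90 deg about z, q1 = 180 deg about z -> Aq1 = 90 deg about z
  qz <- array(NA_real_, c(2L, 1L, 4L), dimnames = list(NULL, "b1", NULL))
  qz[1, 1, ] <- quat_axis_angle(c(0, 0, 1), 90)
  qz[2, 1, ] <- quat_axis_angle(c(0, 0, 1), 180)
  alz <- align_quaternions(quat_stream(c(0, 1), qz))
  expect_equal(alz$quats[2, 1, ], quat_axis_angle(c(0, 0, 1), 90),
               tolerance = 1e-12, ignore_attr = TRUE)

  # right-multiplying every frame by a constant offset changes nothing
  off <- random_unit_quat(1)
  qs2 <- qs
  for (s in 1:2) qs2[, s, ] <- quat_multiply(qs[, s, ], off)
  al2 <- align_quaternions(quat_stream(st$times, qs2))
  expect_lt(max(abs(al$quats - al2$quats)), 1e-9)
})

test_that("constant streams align to the identity", {
  q0 <- random_unit_quat(1)
  qs <- array(rep(q0, each = 20L), c(20L, 1L, 4L),
              dimnames = list(NULL, "b5", NULL))
  al <- align_quaternions(quat_stream(seq_len(20) / 60, qs))
  expect_lt(max(abs(sweep(al$quats[, 1, ], 2, c(1, 0, 0, 0)))), 1e-9)
})

test_that("update_joint_position is Eq.-(5) arithmetic", {
  expect_equal(update_joint_position(c(0, 0, 0), c(0, 0, 1), 0.4),
               c(0, 0, 0.4))
  expect_equal(update_joint_position(c(1, 2, 3), c(1, 0, 0), 0),
               c(1, 2, 3))
  # chained segments equal the matrix forward-kinematics oracle
  set.seed(1)
  q1 <- random_unit_quat(1); q2 <- random_unit_quat(1)
  p1 <- update_joint_position(c(0, 0, 0), quat_rotate(q1, c(0, 0, -1)), 0.4)
  p2 <- update_joint_position(drop(p1), drop(quat_rotate(q2, c(0, 0, -1))), 0.4)
  want <- oracle_rotmat(q1) %*% c(0, 0, -0.4) + oracle_rotmat(q2) %*% c(0, 0, -0.4)
  expect_equal(drop(p2), drop(want), tolerance = 1e-9)
})

test_that("unsensed segments copy their trunk source quaternions", {
  sk <- build_skeleton(1.7)
  sensed <- sk$segments$id[sk$segments$sensed]
  idq <- matrix(rep(c(1, 0, 0, 0), each = 10), 10, 4,
                dimnames = list(sensed, NULL))
  out <- derive_unsensed_orientations(idq, sk)
  expect_equal(unname(out), matrix(rep(c(1, 0, 0, 0), each = 15), 15, 4))

  q30 <- quat_axis_angle(c(0, 0, 1), 30)
  fr <- idq; fr["b1", ] <- q30
  out <- derive_unsensed_orientations(fr, sk)
  for (id in c("b3", "b4", "b7")) expect_equal(out[id, ], q30, ignore_attr = TRUE)
  for (id in c("b10", "b13")) expect_equal(out[id, ], c(1, 0, 0, 0), ignore_attr = TRUE)

  set.seed(9)
  for (rep in 1:100) {
    fr <- matrix(random_unit_quat(10), 10, 4, dimnames = list(sensed, NULL))
    out <- derive_unsensed_orientations(fr, sk)
    expect_identical(unname(out["b3", ]), unname(out["b1", ]))
    expect_identical(unname(out["b10", ]), unname(out["b2", ]))
    expect_identical(unname(out["b13", ]), unname(out["b2", ]))
    expect_identical(unname(out[sensed, ]), unname(fr[sensed, ]))
  }

  expect_error(derive_unsensed_orientations(idq[-1, , drop = FALSE], sk),
               "missing sensor")
})

test_that("bottom-up update anchors the foot and inverts top-down", {
  sk <- build_skeleton(1.8)
  idq <- identity_orientations(sk)
  foot <- c(0.4, -0.12, 0)
  bu <- bottom_up_update(idq, "RFoot", foot, sk)
  expect_identical(bu$RFoot, foot)
  leg <- sum(sk$segments$length[match(c("b11", "b12"), sk$segments$id)])
  expect_equal(bu$Pelvis, c(foot[1], foot[2] + 0.5 * sk$head_unit, leg),
               tolerance = 1e-9)

  # knee flexed 90 degrees: pelvis height drops by the lower-leg length
  # (trigonometric 2-link oracle: thigh vertical, shank horizontal)
  q <- idq
  q["b12", ] <- quat_axis_angle(c(0, 1, 0), 90)
  bu2 <- bottom_up_update(q, "RFoot", foot, sk)
  shank <- sk$segments$length[sk$segments$id == "b12"]
  expect_equal(unname(bu2$Pelvis[3]), leg - shank, tolerance = 1e-9)

  # round trip: pelvis from bottom-up feeds top-down and reproduces the foot
  set.seed(3)
  rq <- idq
  for (id in rownames(rq)) rq[id, ] <- random_unit_quat(1)
  bu3 <- bottom_up_update(rq, "LFoot", c(0.1, 0.2, 0), sk)
  td <- top_down_update(rq, bu3$Pelvis, sk)
  expect_equal(unname(td$positions["LFoot", ]), c(0.1, 0.2, 0),
               tolerance = 1e-9)
})

test_that("top-down update is rotation- and translation-equivariant", {
  sk <- build_skeleton(1.75)
  set.seed(11)
  q <- identity_orientations(sk)
  for (id in rownames(q)) q[id, ] <- random_unit_quat(1)
  base <- top_down_update(q, c(0, 0, 1), sk)

  t0 <- c(0.5, -1, 0.2)
  tr <- top_down_update(q, c(0, 0, 1) + t0, sk)
  expect_equal(tr$positions, sweep(base$positions, 2, -t0), tolerance = 1e-9)

  g <- random_unit_quat(1)
  qg <- q
  for (id in rownames(q)) qg[id, ] <- quat_multiply(g, matrix(q[id, ], 1))
  rot <- top_down_update(qg, c(0, 0, 1), sk)
  R <- oracle_rotmat(drop(g))
  want <- sweep(base$positions, 2, c(0, 0, 1)) %*% t(R)
  want <- sweep(want, 2, -c(0, 0, 1))
  expect_equal(rot$positions, want, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("poses preserve segment lengths", {
  sk <- build_skeleton(1.68)
  segs <- sk$segments
  set.seed(21)
  for (rep in 1:20) {
    q <- identity_orientations(sk)
    for (id in rownames(q)) q[id, ] <- random_unit_quat(1)
    pf <- solve_pose(q, sk, "RFoot", c(0.2, 0, 0))
    d <- sqrt(rowSums((pf$positions[segs$distal, ] -
                         pf$positions[segs$proximal, ])^2))
    expect_lt(max(abs(d - segs$length)), 1e-9)
    expect_equal(unname(pf$positions["RFoot", 3]), 0, tolerance = 1e-9)
  }
})

test_that("solve_pose with identity orientations is the attention pose", {
  sk <- build_skeleton(1.8)
  ap <- attention_pose(sk)
  pf <- solve_pose(identity_orientations(sk), sk, "RFoot",
                   ap$positions["RFoot", ])
  expect_equal(pf$positions, ap$positions, tolerance = 1e-9)
})

test_that("head height drops monotonically with knee flexion", {
  sk <- build_skeleton(1.8)
  heads <- vapply(seq(0, 90, by = 15), function(a) {
    q <- identity_orientations(sk)
    q["b11", ] <- q["b14", ] <- quat_axis_angle(c(0, 1, 0), -a / 2)
    q["b12", ] <- q["b15", ] <- quat_axis_angle(c(0, 1, 0), a / 2)
    solve_pose(q, sk, "RFoot", c(0, -0.1, 0))$positions["Head", 3]
  }, numeric(1))
  expect_true(all(diff(heads) < 0))
})
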