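test_that("lidar resampling is componentwise linear interpolation", {
  t <- c(0, 0.1)
  p <- rbind(c(0, 0, 0), c(0.1, -0.2, 0.3))
  out <- resample_lidar_positions(t, p, 0.05)
  expect_equal(out, matrix(c(0.05, -0.1, 0.15), 1), ignore_attr = TRUE)
  # exact lidar timestamps return the samples unchanged
  ex <- resample_lidar_positions(t, p, t)
  expect_equal(ex, p, ignore_attr = TRUE)
  # clamping outside the span is flagged
  cl <- resample_lidar_positions(t, p, c(-1, 0.05, 2))
  expect_identical(attr(cl, "clamped"), c(TRUE, FALSE, TRUE))
  expect_equal(cl[1, ], p[1, ]); expect_equal(cl[3, ], p[2, ])
  expect_error(resample_lidar_positions(0, p[1, , drop = FALSE], 0.5),
               "insufficient")
  # convexity: interpolants stay within the bracketing samples
  set.seed(14)
  tt <- cumsum(stats::runif(20, 0.05, 0.2))
  pp <- matrix(stats::rnorm(60), ncol = 3)
  q <- sort(stats::runif(50, min(tt), max(tt)))
  ii <- findInterval(q, tt)
  out <- resample_lidar_positions(tt, pp, q)
  for (j in 1:3) {
    lo <- pmin(pp[ii, j], pp[ii + 1L, j])
    hi <- pmax(pp[ii, j], pp[ii + 1L, j])
    expect_true(all(out[, j] >= lo - 1e-12 & out[, j] <= hi + 1e-12))
  }
})

test_that("stance-foot selection prefers the static, fresh foot", {
  static <- matrix(rep(c(1, 0, 0), 10), ncol = 3, byrow = TRUE)
  swing <- cbind(seq(0, 2.7, 0.3), 0, 0)
  expect_identical(select_stance_foot(static, swing, "LFoot"), "RFoot")
  expect_identical(select_stance_foot(swing, static, "RFoot"), "LFoot")
  # both static -> previous retained (tie rule)
  expect_identical(select_stance_foot(static, static, "LFoot"), "LFoot")
  # no history -> previous / default right foot
  expect_identical(select_stance_foot(NULL, NULL), "RFoot")
  # staleness overrides displacement
  expect_identical(select_stance_foot(swing, static, "LFoot",
                                      right_ok = TRUE, left_ok = FALSE),
                   "RFoot")
})

test_that("drift correction is a rigid translation bounded by delta", {
  sk <- build_skeleton(1.75)
  cfg <- fusion_config()
  pf <- solve_pose(identity_orientations(sk), sk, "RFoot", c(0, -0.1, 0))
  feet0 <- rbind(RFoot = pf$positions["RFoot", ], LFoot = pf$positions["LFoot", ])
  # e = 0 -> unchanged
  same <- drift_correct(pf, feet0, cfg)
  expect_equal(same$positions, pf$positions)
  # |e| = 0.5 > delta -> snap: post-correction discrepancy 0
  feet1 <- feet0; feet1["RFoot", ] <- feet1["RFoot", ] + c(0.3, 0.4, 0)
  snap <- drift_correct(pf, feet1, cfg)
  expect_equal(unname(snap$positions["RFoot", ]), unname(feet1["RFoot", ]),
               tolerance = 1e-12)
  # rigid: all 16 joints shifted by the same vector
  shift <- snap$positions - pf$positions
  expect_lt(max(abs(sweep(shift, 2, shift[1, ]))), 1e-12)
  # sub-threshold, gate mode (default): pose left untouched
  feet2 <- feet0; feet2["RFoot", ] <- feet2["RFoot", ] + c(0.06, 0, 0)
  gated <- drift_correct(pf, feet2, cfg)
  expect_equal(gated$positions, pf$positions)
  # sub-threshold, blend mode: blended, discrepancy stays below delta
  cfg_b <- fusion_config(correction_mode = "blend")
  soft <- drift_correct(pf, feet2, cfg_b)
  post <- sqrt(sum((soft$positions["RFoot", ] - feet2["RFoot", ])^2))
  expect_equal(post, 0.06 * (1 - cfg_b$blend), tolerance = 1e-12)
  expect_lte(post, cfg_b$delta)
  # occlusion leaves the pose untouched
  occl <- drift_correct(pf, feet1, cfg, occluded = TRUE)
  expect_equal(occl$positions, pf$positions)
  # bound mode caps the applied correction at delta
  cfgb <- fusion_config(correction_mode = "bound")
  bnd <- drift_correct(pf, feet1, cfgb)
  expect_equal(sqrt(sum((bnd$positions - pf$positions)[1, ]^2)), cfgb$delta,
               tolerance = 1e-12)
})

test_that("noise-free streams reproduce ground truth through the tracker", {
  # inverse-path closure: simulator quaternions (random constant mounting
  # offsets, no noise) -> aligned -> solved; also identical output with
  # identity offsets (right-invariance of the alignment)
  sk <- build_skeleton(1.75)
  sens_r <- sensor_model(imu_offsets = "random")
  sens_i <- sensor_model(imu_offsets = "identity")
  tr <- generate_motion("walk", 4, 60, sk)
  ip <- attention_pose(sk)$positions
  ip[, 1] <- ip[, 1] + 2.2
  init <- pose_frame(ip)
  for (sens in list(sens_r, sens_i)) {
    imu <- sample_imu_stream(tr, sens, seed = 2)
    out <- track_sequence(imu, NULL, sk, fusion_config(), seed = 1,
                          init_pose = init, stance = tr$stance)
    expect_lt(max(abs(out$positions - tr$joints)), 1e-6)
  }
})

test_that("the tracker degrades to the inertial-only path without clouds", {
  sk <- build_skeleton(1.7)
  tr <- generate_motion("squat", 2, 60, sk)
  imu <- sample_imu_stream(tr, sensor_model(), seed = 3)
  ip <- attention_pose(sk)$positions; ip[, 1] <- ip[, 1] + 2.2
  a <- track_sequence(imu, NULL, sk, fusion_config(), seed = 1,
                      init_pose = pose_frame(ip))
  b <- track_sequence(imu, list(), sk, fusion_config(), seed = 1,
                      init_pose = pose_frame(ip))
  expect_equal(a$positions, b$positions)
  expect_true(all(is.na(a$diagnostics$correction)))
})

test_that("output frame rate equals the IMU rate regardless of lidar rate", {
  # 2 s scaled-down walk with the coarse test scan grid
  ses <- simulate_session("walk", 2, height = 1.7, sensors = fast_sensors(),
                          seed = 11)
  out <- track_sequence(ses$imu, ses$clouds, ses$skeleton, fusion_config(),
                        seed = 1, reference = ses$reference,
                        init_pose = ses$init_pose)
  expect_length(out$times, length(ses$imu$times))
  expect_equal(stats::median(diff(out$times)), 1 / 60)
  # corrections never alter inter-joint distances
  segs <- ses$skeleton$segments
  for (i in c(1L, 60L, 119L)) {
    d <- sqrt(rowSums((out$positions[i, segs$distal, ] -
                         out$positions[i, segs$proximal, ])^2))
    expect_lt(max(abs(d - segs$length)), 1e-9)
  }
})

test_that("injected drift grows unbounded inertial-only but stays bounded fused", {
  # scaled down from the 30 s acceptance experiment: 8 s walk, coarse grid
  ses <- simulate_session("walk", 8, height = 1.75, sensors = fast_sensors(),
                          seed = 21, start_position = c(1.2, 0))
  cfg <- fusion_config()
  drift_rate <- 0.05
  imu_d <- inject_drift(ses$imu, rate = drift_rate, seed = 4)
  # inertial-only: stance-foot error ~ rate * t
  solo <- track_sequence(imu_d, NULL, ses$skeleton, cfg, seed = 1,
                         init_pose = ses$init_pose, stance = ses$truth$stance)
  t_end <- max(ses$truth$times)
  e_end <- sqrt(sum((solo$positions[length(solo$times), "Pelvis", 1:2] -
                       ses$truth$joints[length(solo$times), "Pelvis", 1:2])^2))
  expect_equal(e_end, drift_rate * t_end, tolerance = 0.02)
  # fused: post-correction stance discrepancy bounded by delta throughout
  fused <- track_sequence(imu_d, ses$clouds, ses$skeleton, cfg, seed = 1,
                          reference = ses$reference, init_pose = ses$init_pose)
  d <- fused$diagnostics
  fc <- attr(d, "first_correction_frame")
  expect_false(is.na(fc))
  post <- d$stance_discrepancy[fc:nrow(d)]
  expect_lte(max(post, na.rm = TRUE), cfg$delta)
  # and the fused pose itself stays near truth
  err <- joint_position_error(fused, ses$truth)
  expect_lt(err$overall_mean_cm, 10)
})
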