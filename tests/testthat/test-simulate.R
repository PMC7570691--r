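test_that("motion kinds satisfy their defining contracts", {
  sk <- build_skeleton(1.75)
  att <- generate_motion("attention", 1, 60, sk)
  expect_true(all(att$quats[, , 1] == 1) && all(att$quats[, , 2:4] == 0))

  sq <- generate_motion("squat", 3, 60, sk)
  for (f in c("RFoot", "LFoot")) {
    expect_lt(max(abs(sweep(sq$joints[, f, ], 2, sq$joints[1, f, ]))), 1e-9)
  }

  wk <- generate_motion("walk", 6, 60, sk)
  expect_length(wk$times, 360L)
  expect_true(all(diff(wk$joints[, "Pelvis", 1]) > -1e-9))
  expect_setequal(unique(wk$stance), c("RFoot", "LFoot"))

  kp <- generate_motion("key_poses_14", 21, 60, sk)  # >= 1 s per pose
  # 14 distinct held poses: compare mid-slot orientation snapshots
  mids <- round((seq_len(14) - 0.55) * length(kp$times) / 14)
  snaps <- vapply(mids, function(i) as.numeric(kp$quats[i, , ]), numeric(60))
  expect_equal(nrow(unique(t(round(snaps, 6)))), 14L)

  expect_error(generate_motion("moonwalk", 1, 60, sk))
})

test_that("ground-truth tracks preserve segment lengths at every frame", {
  sk <- build_skeleton(1.66)
  tr <- generate_motion("key_poses_14", 14, 60, sk)
  segs <- sk$segments
  for (i in seq(1, length(tr$times), by = 97)) {
    d <- sqrt(rowSums((tr$joints[i, segs$distal, ] -
                         tr$joints[i, segs$proximal, ])^2))
    expect_lt(max(abs(d - segs$length)), 1e-9)
  }
})

test_that("generated sessions are reproducible from config and seed", {
  a <- simulate_session("squat", 1, sensors = fast_sensors(), seed = 5,
                        n_calibration = 2L)
  b <- simulate_session("squat", 1, sensors = fast_sensors(), seed = 5,
                        n_calibration = 2L)
  expect_identical(a$reference$points, b$reference$points)
  expect_identical(a$clouds[[3]]$points, b$clouds[[3]]$points)
  expect_identical(a$imu$quats, b$imu$quats)
})

test_that("noiseless lidar returns lie exactly on a surface", {
  sens <- fast_sensors(range_noise = 0)
  sk <- build_skeleton(1.8)
  tr <- generate_motion("attention", 0.2, 60, sk)
  cl <- sample_lidar_cloud(tr, sk, sens, 1L, seed = 1)
  box <- sens$box
  p <- cl$points
  on_box <- abs(p[, 1] - box[1]) < 1e-9 | abs(p[, 1] - box[2]) < 1e-9 |
    abs(p[, 2] - box[3]) < 1e-9 | abs(p[, 2] - box[4]) < 1e-9 |
    abs(p[, 3] - box[5]) < 1e-9 | abs(p[, 3] - box[6]) < 1e-9
  pose <- pose_frame(tr$joints[1, , ], quaternions = tr$quats[1, , ])
  caps <- mocapfuse:::body_capsules(pose, sk)
  seg_dist <- function(q, a, b, r) {
    ab <- b - a
    t <- sum((q - a) * ab) / max(sum(ab^2), 1e-12)
    t <- min(1, max(0, t))
    abs(sqrt(sum((q - (a + t * ab))^2)) - r)
  }
  body <- !on_box
  dmin <- vapply(which(body), function(i) {
    min(vapply(seq_len(nrow(caps)), function(k)
      seg_dist(p[i, ], caps[k, 1:3], caps[k, 4:6], caps[k, 7]), numeric(1)))
  }, numeric(1))
  expect_gt(sum(body), 50)
  expect_lt(max(dmin), 1e-9)
})

test_that("ceiling-lidar floor returns have maximal depth in the L1 frame", {
  sens <- fast_sensors(range_noise = 0)
  ref <- make_room_reference(sens, seed = 1)
  l1 <- transform_cloud(pc_frame(ref$points[ref$sensor == "L1", , drop = FALSE]),
                        sens$l1_transform, "L1")
  g <- ground_point(l1)
  # deepest return is a floor point (world z = 0)
  w <- ref$points[ref$sensor == "L1", , drop = FALSE]
  expect_lt(abs(w[which.max(l1$points[, 2]), 3]), 1e-6)
  # and its depth is close to the mounting height
  expect_gt(g[2], 2.8)
})

test_that("a body outside the front sensor's vertical FoV yields no returns", {
  sens <- fast_sensors(range_noise = 0)
  sk <- build_skeleton(1.7)
  # place the subject far off to the side but near the front sensor's wall:
  # elevation from the sensor exceeds +/-15 degrees for every body point
  tr <- generate_motion("attention", 0.2, 60, sk, start_position = c(7.6, 1.6))
  cl <- sample_lidar_cloud(tr, sk, sens, 1L, seed = 2, body_only = TRUE)
  front <- which(cl$sensor == "L2")
  # every front-sensor return must lie inside the +/-15 degree fan, so the
  # upper body (above the fan at this close range) yields no returns
  org <- sens$lidars$L2$position
  for (i in front) {
    h <- sqrt(sum((cl$points[i, 1:2] - org[1:2])^2))
    el <- atan2(cl$points[i, 3] - org[3], h) * 180 / pi
    expect_lte(abs(el), 15 + 0.1)
  }
  if (length(front)) expect_lt(max(cl$points[front, 3]), 1.2)
})

test_that("IMU sampling respects noise and offset settings", {
  sk <- build_skeleton(1.75)
  tr <- generate_motion("squat", 2, 60, sk)
  clean <- sample_imu_stream(tr, sensor_model(imu_offsets = "identity"), seed = 1)
  # without noise and offsets the stream equals the ground truth
  for (id in c("b2", "b11")) {
    expect_lt(max(abs(clean$quats[, id, ] - tr$quats[, id, ])), 1e-12)
  }
  noisy <- sample_imu_stream(tr, sensor_model(imu_noise_deg = 1,
                                              imu_offsets = "identity"), seed = 1)
  ang <- vapply(seq_along(noisy$times), function(i) {
    quat_relative_angle(noisy$quats[i, "b2", ], tr$quats[i, "b2", ])
  }, numeric(1))
  expect_gt(mean(ang), 0.3)  # noise present
  expect_lt(mean(ang), 3)    # but small-angle
})

test_that("orientation noise accumulates with chain depth", {
  sk <- build_skeleton(1.75)
  tr <- generate_motion("attention", 4, 60, sk)
  sens <- sensor_model(imu_noise_deg = 1, imu_offsets = "identity")
  imu <- sample_imu_stream(tr, sens, seed = 8)
  ip <- attention_pose(sk)$positions; ip[, 1] <- ip[, 1] + 2.2
  out <- track_sequence(imu, NULL, sk, fusion_config(), seed = 1,
                        init_pose = pose_frame(ip), stance = tr$stance)
  err <- joint_position_error(out, tr)
  pj <- stats::setNames(err$per_joint$mean_cm, err$per_joint$joint)
  # error grows along the chain from the anchored stance foot outward
  expect_gt(pj["RKnee"], pj["RFoot"])
  expect_gt(pj["Pelvis"], pj["RKnee"])
  expect_gt(pj["RWrist"], pj["Pelvis"])
  expect_gt(pj["LWrist"], pj["Pelvis"])
})

test_that("drift injection is linear with a zero-rate identity", {
  sk <- build_skeleton(1.7)
  tr <- generate_motion("attention", 2, 60, sk)
  imu <- sample_imu_stream(tr, sensor_model(), seed = 1)
  expect_identical(inject_drift(imu, 0), imu)
  drifted <- inject_drift(imu, rate = 0.1, seed = 2)
  expect_identical(drifted$quats, imu$quats)  # orientations untouched
  ip <- attention_pose(sk)$positions; ip[, 1] <- ip[, 1] + 2.2
  out <- track_sequence(drifted, NULL, sk, fusion_config(), seed = 1,
                        init_pose = pose_frame(ip), stance = tr$stance)
  e <- sqrt(rowSums((out$positions[, "RFoot", 1:2] -
                       tr$joints[, "RFoot", 1:2])^2))
  t_rel <- tr$times - tr$times[1]
  expect_equal(e, 0.1 * t_rel, tolerance = 1e-6)
})

test_that("the room reference closes the loop with change detection", {
  sens <- fast_sensors()
  ref <- make_room_reference(sens, seed = 3)
  box <- sens$box
  p <- ref$points
  pad <- 4 * sens$range_noise
  expect_true(all(p[, 1] > box[1] - pad & p[, 1] < box[2] + pad &
                    p[, 2] > box[3] - pad & p[, 2] < box[4] + pad &
                    p[, 3] > box[5] - pad & p[, 3] < box[6] + pad))
  expect_identical(make_room_reference(sens, seed = 3)$points, p)
  self <- extract_user_cloud(ref, ref, 0.1)
  expect_equal(nrow(self$points), 0L)
})

test_that("height estimation closes end to end on synthetic clouds", {
  # noiseless: recover the body height to within the vertical ray spacing
  sens <- sensor_model(range_noise = 0)
  for (h in c(1.62, 1.84)) {
    ses <- simulate_session("attention", 0.5, height = h, sensors = sens,
                            seed = 30, n_calibration = 1L)
    cal <- calibrate_session(ses$reference, ses$calib_clouds,
                             sens$l1_transform)
    # vertical ray spacing at the head from the ceiling sensor
    spacing <- (2.9 - h) * sens$azimuth_step * pi / 180 * 3
    expect_lt(abs(cal$height - h), max(spacing, 0.02))
  }
})
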