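make_leg_blob <- function(center, n = 60L, spread = 0.03, zmax = 0.4) {
  cbind(stats::rnorm(n, center[1], spread), stats::rnorm(n, center[2], spread),
        stats::runif(n, 0.05, zmax))
}

test_that("leg clustering splits, flags merging and signals occlusion", {
  sk <- build_skeleton(1.75)
  ap <- attention_pose(sk)
  set.seed(1)
  # two well-separated shanks near the attention ankles
  pts <- rbind(make_leg_blob(c(0.0, -0.12)), make_leg_blob(c(0.0, 0.35)))
  legs <- cluster_leg_points(pc_frame(pts, variant = "realtime"), sk, ap)
  expect_false(legs$merged); expect_false(legs$occluded)
  expect_lt(sqrt(sum((colMeans(legs$right$points)[1:2] - c(0, -0.12))^2)), 0.05)
  expect_lt(sqrt(sum((colMeans(legs$left$points)[1:2] - c(0, 0.35))^2)), 0.05)

  # empty cloud -> occlusion
  legs0 <- cluster_leg_points(pc_frame(matrix(numeric(0), 0, 3)), sk, ap)
  expect_true(legs0$occluded)

  # clusters below the distance threshold -> merged, split by prior side
  pts2 <- rbind(make_leg_blob(c(0, -0.05), spread = 0.01),
                make_leg_blob(c(0, 0.05), spread = 0.01))
  legs2 <- cluster_leg_points(pc_frame(pts2), sk, ap)
  expect_true(legs2$merged)
  expect_gt(nrow(legs2$right$points), 0)
  expect_gt(nrow(legs2$left$points), 0)
  expect_true(all(legs2$right$points[, 2] <= legs2$left$points[, 2] + 0.06))

  # points above knee height are ignored
  high <- cbind(0, 0, seq(1, 1.6, 0.05))
  legs3 <- cluster_leg_points(pc_frame(rbind(make_leg_blob(c(0, -0.12)), high)),
                              sk, ap)
  expect_true(all(legs3$right$points[, 3] <= 2 * sk$head_unit))
})

test_that("pf_predict diffuses deterministically with sqrt(dt) scaling", {
  st <- pf_init(c(1, 2), n_particles = 1000L, sigma_proc = 0.3, seed = 4L)
  frozen <- pf_init(c(1, 2), n_particles = 1000L, sigma_proc = 0, seed = 4L)
  expect_identical(pf_predict(frozen, 0.5, seed = 9L)$particles,
                   frozen$particles)
  a <- pf_predict(st, 0.1, seed = 9L)
  b <- pf_predict(st, 0.1, seed = 9L)
  expect_identical(a$particles, b$particles)  # same seed -> bit identical
  big <- pf_predict(st, 1.0, seed = 10L)
  grow <- function(s) mean(apply(s$particles, 2, stats::var))
  expect_gt(grow(big), grow(a))
  v0 <- grow(st)
  # variance increment ~ sigma^2 * dt (sample-variance oracle, 10% slack)
  expect_equal(grow(big) - v0, 0.3^2, tolerance = 0.1)
})

test_that("pf_update weights, resamples and converges to the observation", {
  set.seed(6)
  cl <- pc_frame(cbind(stats::rnorm(80, 2, 0.02), stats::rnorm(80, 1, 0.02),
                       stats::runif(80, 0, 0.05)))
  st <- pf_init(c(2.3, 1.3), n_particles = 200L, sigma_proc = 0.2, seed = 1L)
  for (i in 1:50) {
    st <- pf_predict(st, 1 / 15, seed = 100L + i)
    st <- pf_update(st, cl, seed = 200L + i, obs_mode = "centroid")
    expect_equal(sum(st$weights), 1, tolerance = 1e-9)
    expect_true(all(st$weights >= 0))
  }
  truth <- colMeans(cl$points[, 1:2])  # brute-force centroid oracle
  expect_lt(sqrt(sum((st$estimate - truth)^2)), 0.01)

  # all particles equidistant from the observation -> uniform weights
  ring <- pf_init(c(0, 0), n_particles = 12L, sigma_proc = 0, seed = 2L)
  th <- 2 * pi * (1:12) / 12
  ring$particles <- cbind(cos(th), sin(th))
  ring$weights <- rep(1 / 12, 12)
  one <- pc_frame(matrix(c(0, 0, 0), 1))
  expect_equal(pf_update(ring, one, obs_mode = "centroid")$weights,
               rep(1 / 12, 12))
  expect_error(pf_update(ring, pc_frame(matrix(numeric(0), 0, 3))), "empty")
})

test_that("axis observation removes the tilted-shank centroid bias", {
  set.seed(12)
  # shank tilted 30 degrees: surface points along the axis from the ankle
  ankle <- c(1.5, 0.2)
  s <- seq(0.08, 0.45, length.out = 100)
  pts <- cbind(ankle[1] + s * tan(30 * pi / 180) + stats::rnorm(100, 0, 0.01),
               ankle[2] + stats::rnorm(100, 0, 0.01), s)
  cl <- pc_frame(pts)
  obs_c <- leg_ground_observation(cl, mode = "centroid")
  obs_a <- leg_ground_observation(cl, mode = "axis")
  expect_gt(sqrt(sum((obs_c - ankle)^2)), 0.10)   # centroid is biased
  expect_lt(sqrt(sum((obs_a - ankle)^2)), 0.02)   # axis fit recovers the ankle
})

test_that("foot positions sit on the floor plane", {
  r <- pf_init(c(1, 0), seed = 1L); l <- pf_init(c(1, 0.3), seed = 2L)
  fp <- foot_positions(r, l, floor_z = 0)
  expect_equal(unname(fp[, 3]), c(0, 0))
  expect_equal(unname(fp["RFoot", 1:2]), r$estimate)
})

test_that("with small process noise the filter tracks a static target", {
  # sigma_proc -> 0 limit: the estimate converges to the observation
  set.seed(3)
  cl <- pc_frame(cbind(stats::rnorm(60, -1, 0.01), stats::rnorm(60, 0.5, 0.01),
                       stats::runif(60, 0, 0.05)))
  st <- pf_init(c(-1.2, 0.7), n_particles = 300L, sigma_proc = 0.02, seed = 5L)
  for (i in 1:80) {
    st <- pf_predict(st, 1 / 15, seed = 300L + i)
    st <- pf_update(st, cl, seed = 400L + i, obs_mode = "centroid")
  }
  expect_lt(sqrt(sum((st$estimate - colMeans(cl$points[, 1:2]))^2)), 0.01)
})

test_that("left/right labels stay consistent on separated walking legs", {
  sk <- build_skeleton(1.75)
  ap <- attention_pose(sk)
  cfg <- fusion_config()
  set.seed(17)
  # synthetic straight-line walk of two blobs 0.4 m apart laterally
  times <- seq(0, 3, by = 1 / 15)
  clouds <- lapply(times, function(t) {
    x <- 1 + 0.3 * t
    pc_frame(rbind(make_leg_blob(c(x, -0.2)), make_leg_blob(c(x, 0.2))),
             timestamp = t, variant = "realtime")
  })
  ip <- ap$positions; ip[, 1] <- ip[, 1] + 1
  ip["RFoot", 2] <- -0.2; ip["LFoot", 2] <- 0.2
  feet <- track_feet(clouds, NULL, sk, pose_frame(ip), cfg, seed = 2L)
  expect_true(all(feet$right[, 2] < feet$left[, 2]))
  # straight-line RMSE within 5 cm of the true feet
  err_r <- sqrt((feet$right[, 1] - (1 + 0.3 * times))^2 + (feet$right[, 2] + 0.2)^2)
  err_l <- sqrt((feet$left[, 1] - (1 + 0.3 * times))^2 + (feet$left[, 2] - 0.2)^2)
  expect_lt(sqrt(mean(c(err_r^2, err_l^2))), 0.05)
})

test_that("doubling the particle count never hurts on the walking fixture", {
  sk <- build_skeleton(1.75)
  ap <- attention_pose(sk)
  set.seed(23)
  times <- seq(0, 2, by = 1 / 15)
  clouds <- lapply(times, function(t) {
    x <- 1 + 0.3 * t
    pc_frame(rbind(make_leg_blob(c(x, -0.2)), make_leg_blob(c(x, 0.2))),
             timestamp = t, variant = "realtime")
  })
  ip <- ap$positions; ip[, 1] <- ip[, 1] + 1
  ip["RFoot", 2] <- -0.2; ip["LFoot", 2] <- 0.2
  rmse <- function(n, seed) {
    cfg <- fusion_config(n_particles = n)
    feet <- track_feet(clouds, NULL, sk, pose_frame(ip), cfg, seed = seed)
    sqrt(mean((feet$right[, 1] - (1 + 0.3 * times))^2 +
                (feet$right[, 2] + 0.2)^2))
  }
  # paired comparison over 10 seeds
  small <- vapply(1:10, function(s) rmse(100L, s), numeric(1))
  large <- vapply(1:10, function(s) rmse(200L, s), numeric(1))
  expect_lte(mean(large), mean(small) + 0.005)
})
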