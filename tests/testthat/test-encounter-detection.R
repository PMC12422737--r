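test_that("signed_distance computes elementary geometry", {
  arena <- generate_world("custom", patches = data.frame(
    patch_id = 1:2, x = c(0, 5), y = 0, radius = 0.9, density = 10),
    arena_radius = 10)
  tr <- data.frame(x_mm = c(0, 0.9, 1.0, 5), y_mm = 0)
  d <- signed_distance(tr, arena)
  expect_equal(d$d, c(0.9, 0, -0.1, 0.9), tolerance = 1e-12)
  expect_equal(d$nearest_patch_id, c(1L, 1L, 1L, 2L))
  # equidistant tie goes to the lowest patch id
  tie <- signed_distance(data.frame(x_mm = 2.5, y_mm = 0), arena)
  expect_equal(tie$nearest_patch_id, 1L)
  # no patches: flagged undefined
  empty <- generate_world("custom", patches = data.frame(
    patch_id = integer(), x = numeric(), y = numeric(),
    radius = numeric(), density = numeric()), arena_radius = 10)
  nd <- signed_distance(tr, empty)
  expect_true(attr(nd, "no_patches"))
  expect_true(all(is.na(nd$d)))
  expect_error(detect_candidates(nd, fps = 3), "no patches")
})

test_that("detect_candidates finds threshold runs and censoring", {
  th <- detection_thresholds()
  # never approaches: no encounters
  none <- detect_candidates(distance_series(rep(-1, 300)), th, fps = 3)
  expect_equal(nrow(none), 0L)
  # constructed crossing: inside margin frames 101..401 -> 100 s at 3 fps
  d <- rep(-1, 500); d[101:401] <- 0
  one <- detect_candidates(distance_series(d), th, fps = 3)
  expect_equal(nrow(one), 1L)
  expect_equal(one$entry_frame, 101L)
  expect_equal(one$exit_frame, 401L)
  expect_equal(one$duration_s, 100)
  expect_false(one$start_censored)
  # recording starts inside the patch -> start_censored
  d2 <- c(rep(0.2, 50), rep(-1, 100))
  cens <- detect_candidates(distance_series(d2), th, fps = 3)
  expect_true(cens$start_censored[1])
  # run touching the last frame -> end_censored
  d3 <- c(rep(-1, 100), rep(0.1, 50))
  expect_true(detect_candidates(distance_series(d3), th, fps = 3)$end_censored)
})

test_that("filter_near_miss applies the 0.28758 mm rule", {
  th <- detection_thresholds()
  cand <- data.frame(patch_id = 1L, entry_frame = c(1, 100, 200),
                     exit_frame = c(50, 150, 250), duration_s = 10,
                     max_d = c(-0.40, -0.10, 0.3),
                     start_censored = FALSE, end_censored = FALSE)
  out <- filter_near_miss(cand, th)
  expect_equal(nrow(out), 2L)                   # -0.40 dropped
  expect_equal(out$max_d, c(-0.10, 0.3))
  expect_equal(out$midpoint_entered, c(FALSE, TRUE))
  # an encounter whose midpoint entered is never removed
  expect_true(all(out$midpoint_entered[out$max_d > 0]))
})

test_that("merge_false_exits merges low-variance gaps to a fixed point", {
  th <- detection_thresholds()
  fps <- 3
  # three candidates; both gaps are constant-distance (sd = 0) -> one merge
  d <- rep(-2, 400)
  d[21:60] <- 0.2; d[61:80] <- -0.5      # gap 1: constant
  d[81:120] <- 0.2; d[121:140] <- -0.5   # gap 2: constant
  d[141:180] <- 0.2
  cand <- detect_candidates(distance_series(d), th, fps)
  expect_equal(nrow(cand), 3L)
  merged <- merge_false_exits(cand, distance_series(d), th, fps)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$entry_frame, 21L)
  expect_equal(merged$exit_frame, 180L)
  expect_equal(merged$duration_s, (180 - 21) / fps)   # gap time counted
  # idempotent
  expect_identical(merge_false_exits(merged, distance_series(d), th, fps),
                   merged)
  # high-variance gap (mm-scale excursion): not merged
  d2 <- rep(-2, 400)
  d2[21:60] <- 0.2
  d2[61:140] <- -0.5 - 5 * abs(sin(seq(0, pi, length.out = 80)))
  d2[141:180] <- 0.2
  cand2 <- detect_candidates(distance_series(d2), th, fps)
  expect_equal(nrow(merge_false_exits(cand2, distance_series(d2), th, fps)),
               2L)
  # different-patch candidates never merge
  ds3 <- structure(data.frame(d = c(rep(0.1, 30), rep(-0.5, 20),
                                    rep(0.1, 30)),
                              nearest_patch_id = c(rep(1L, 40),
                                                   rep(2L, 40))),
                   no_patches = FALSE)
  cand3 <- detect_candidates(ds3, th, fps)
  expect_equal(nrow(merge_false_exits(cand3, ds3, th, fps)), nrow(cand3))
})

test_that("instantaneous_velocity matches analytic tracks", {
  fps <- 3
  still <- straight_track(0, fps, 30)
  expect_true(all(instantaneous_velocity(still, fps) == 0))
  mov <- straight_track(0.1, fps, 60)
  v <- instantaneous_velocity(mov, fps, smooth = FALSE)
  inner <- v[2:(length(v) - 1)]
  expect_true(all(abs(inner - 100) / 100 <= 1e-3))
  # smoothing preserves a constant-speed track
  vs <- instantaneous_velocity(mov, fps, smooth = TRUE)
  expect_equal(vs[5:20], rep(100, 16), tolerance = 1e-9)
  dup <- mov; dup$time_s[5] <- dup$time_s[4]
  expect_error(instantaneous_velocity(dup, fps), "timestamps")
})

test_that("extract_features computes s, t, u and the z features", {
  fps <- 4
  n <- 200
  time_s <- (seq_len(n) - 1) / fps
  th <- detection_thresholds()
  enc <- data.frame(entry_frame = 81L, exit_frame = 160L,
                    start_censored = FALSE)
  # constant velocity: no slowdown at all
  vc <- rep(150, n)
  f <- extract_features(enc, vc, time_s, th, fps)
  expect_equal(f$s_k, 150)
  expect_equal(f$t_k, 0, tolerance = 1e-10)
  expect_equal(f$u_k, 0)
  expect_equal(f$log_dur, log((160 - 81) / fps))
  expect_equal(f$log_vel, log(150))
  # linear ramp 200 -> 40 spanning the whole [-1.5, +6.5] s window: exact
  # OLS slope -20 um/s^2
  t0 <- time_s[81]
  vr <- rep(200, n)
  ramp <- time_s >= t0 - 1.5 & time_s <= t0 + 6.5
  vr[ramp] <- 200 - 20 * (time_s[ramp] - (t0 - 1.5))
  vr[time_s > t0 + 6.5] <- 40
  f2 <- extract_features(enc, vr, time_s, th, fps)
  expect_equal(f2$t_k, -20, tolerance = 1e-9)
  expect_equal(f2$s_k, 40)
  expect_equal(f2$u_k, 200 - 40)   # peak in the 10 s before entry is 200
  expect_error(extract_features(data.frame(entry_frame = 10L,
                                           exit_frame = 9L,
                                           start_censored = FALSE),
                                vc, time_s, th, fps), "shorter")
})

test_that("derive_exit_threshold splits bimodal gap variabilities", {
  set.seed(19)
  sds <- c(exp(rnorm(150, log(0.05), 0.4)),   # false exits: low variance
           exp(rnorm(150, log(2), 0.4)))      # true excursions
  th <- derive_exit_threshold(sds)
  expect_gt(as.numeric(th), 0.1)
  expect_lt(as.numeric(th), 1)
  # threshold separates the two generating modes almost perfectly
  expect_gt(mean(sds[1:150] < th), 0.97)
  expect_gt(mean(sds[151:300] > th), 0.97)
  expect_error(derive_exit_threshold(rep(0, 20)), ">= 10")
})

test_that("simulated sensed encounters show paper-scale slowdown", {
  arena <- generate_world("isometric_grid", 10, 1)
  pars <- behavior_params(sensing_fn = function(d) 1)
  sim <- simulate_worms(arena, pars, 900, n_worms = 4, seed = 13)
  enc <- detect_encounters(sim$trajectory, arena, detection_thresholds(),
                           fps = pars$fps)
  expect_gt(nrow(enc), 3)
  # mean deceleration negative and of order -20 um/s^2 (order check only)
  expect_lt(mean(enc$t_k), -5)
  expect_gt(mean(enc$t_k), -60)
  # off-patch speed within 10% of the 198 um/s default
  tr1 <- sim$trajectory[sim$trajectory$worm_id == 1, ]
  v <- instantaneous_velocity(tr1, pars$fps)
  off <- signed_distance(tr1, arena)$d < -0.46024
  expect_lt(abs(mean(v[off]) - 198) / 198, 0.10)
})
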