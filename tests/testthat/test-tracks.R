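test_that("a constant-velocity track is one censored run with no tumbles", {
  tr <- track_table(straight_track(60), frame_dt = 0.1)
  seg <- segment_runs(tr)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$label, "run")
  expect_true(seg$censored)
})

test_that("an inserted stop produces exactly one overlapping tumble segment", {
  u <- 15; dt <- 0.1
  t <- seq(0, 6, by = dt)
  # swim, stop for 0.3 s at t in [3.0, 3.3), swim on in a new direction
  x <- ifelse(t < 3, u * t, ifelse(t < 3.3, u * 3, u * 3))
  y <- ifelse(t < 3.3, 0, u * (t - 3.3) * 0.9)
  x[t >= 3.3] <- u * 3 + u * (t[t >= 3.3] - 3.3) * sqrt(1 - 0.81)
  tr <- track_table(data.frame(track_id = 1L, t = t, x = x, y = y),
                    frame_dt = dt)
  seg <- segment_runs(tr)
  tum <- seg[seg$label == "tumble", ]
  expect_equal(nrow(tum), 1)
  expect_lt(tum$start, 3.3)
  expect_gt(tum$end, 3.0)
  runs <- seg[seg$label == "run", ]
  expect_equal(nrow(runs), 2)
})

test_that("a stationary jittering track is almost entirely tumble", {
  set.seed(7)
  t <- seq(0, 20, by = 0.1)
  tr <- track_table(data.frame(track_id = 1L, t = t,
                               x = rnorm(length(t), 0, 0.1),
                               y = rnorm(length(t), 0, 0.1)),
                    frame_dt = 0.1, noise_sd = 0.1)
  seg <- segment_runs(tr)
  tumble_time <- sum(seg$end[seg$label == "tumble"] -
                     seg$start[seg$label == "tumble"])
  expect_gt(tumble_time / (max(t) - min(t)), 0.9)
})

test_that("segmentation is invariant under translation and rotation", {
  set.seed(8)
  tr0 <- rt_oracle_track(1.15, noise_sd = 0.2)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- as.matrix(tr0[, c("x", "y")]) %*% R
  tr1 <- data.frame(track_id = 1L, t = tr0$t,
                    x = rot[, 1] + 500, y = rot[, 2] - 300)
  s0 <- segment_runs(track_table(tr0, 0.1, noise_sd = 0.2))
  s1 <- segment_runs(track_table(tr1, 0.1, noise_sd = 0.2))
  expect_equal(s0$start, s1$start)
  expect_equal(s0$label, s1$label)
})

test_that("run durations: exact fixture and the boundary convention", {
  # three 2 s runs separated by exact 0.3 s stops (frame-aligned)
  dt <- 0.1; u <- 15
  step_x <- c(rep(u * dt, 20), rep(0, 3), rep(0, 20), rep(0, 3),
              rep(u * dt, 20))
  step_y <- c(rep(0, 20), rep(0, 3), rep(u * dt, 20), rep(0, 3),
              rep(0, 20))
  x <- cumsum(c(0, step_x))
  y <- cumsum(c(0, step_y))
  t <- seq(0, by = dt, length.out = length(x))
  tr <- track_table(data.frame(track_id = 1L, t = t, x = x, y = y),
                    frame_dt = dt)
  seg <- segment_runs(tr)
  m <- mean_run_time(seg)
  # the single interior run spans 2 s; the half-frame boundary correction
  # adds one frame interval
  expect_equal(m$n, 1)
  expect_equal(m$mean, 2 + dt, tolerance = 0.11)
  expect_true(is.na(m$sem) || m$sem == 0)
  # the left-truncation floor shifts the estimate down by the floor
  m2 <- mean_run_time(seg, resolution_floor = 2 * dt)
  expect_equal(m$mean - m2$mean, 2 * dt, tolerance = 1e-9)
})

test_that("run-time estimator recovers exponential means across tau", {
  set.seed(9)
  # low-noise oracle tracks: smoothing off so the detection resolution is
  # the raw frame grid that the truncation floor describes
  for (tau in c(0.5, 1.15, 2.4)) {
    tracks <- do.call(rbind, lapply(1:40, function(i)
      rt_oracle_track(tau, T = 60, noise_sd = 0.05, track_id = i)))
    tt <- track_table(tracks, frame_dt = 0.1, noise_sd = 0.05)
    m <- mean_run_time(segment_runs(tt, smooth_window = 1),
                       resolution_floor = 0.2)
    expect_lt(abs(m$mean - tau), 3 * m$sem + 0.02)
  }
})

test_that("normalization is a plain division by the baseline", {
  set.seed(10)
  tracks <- do.call(rbind, lapply(1:30, function(i)
    rt_oracle_track(2.415, T = 60, noise_sd = 0.05, track_id = i)))
  seg <- segment_runs(track_table(tracks, 0.1, noise_sd = 0.05))
  m <- mean_run_time(seg, resolution_floor = 0.2)
  expect_equal(normalized_run_time(seg, 1.15, resolution_floor = 0.2),
               m$mean / 1.15, tolerance = 1e-12)
})

test_that("run speed is exact on clean tracks and noise-debiased on noisy ones", {
  # clean: two straight planar tracks at exactly 15 um/s
  tr <- rbind(straight_track(80),
              transform(straight_track(80, angle = 1.1), track_id = 2L))
  tt <- track_table(tr, frame_dt = 0.1)
  sp <- mean_run_speed(segment_runs(tt), tt)
  expect_equal(sp$mean, 15, tolerance = 1e-9)
  expect_equal(sp$sd, 0, tolerance = 1e-9)
  # noisy: de-biasing removes the localization inflation
  set.seed(11)
  trn <- do.call(rbind, lapply(1:30, function(i)
    rt_oracle_track(1.15, T = 60, noise_sd = 0.3, track_id = i)))
  ttn <- track_table(trn, frame_dt = 0.1, noise_sd = 0.3)
  spn <- mean_run_speed(segment_runs(ttn), ttn)
  expect_lt(abs(spn$mean - 15), 3 * spn$sem + 0.15)
  # inserting stops does not change the measured running speed
  expect_lt(abs(spn$mean - sp$mean), 0.5)
})

test_that("turn-angle statistics handle right angles and the no-tumble case", {
  # deterministic 90-degree turns: mean cosine zero
  dt <- 0.1; u <- 15
  blocks <- 40
  dirs <- rep(c(0, pi / 2, pi, -pi / 2), length.out = blocks)
  xs <- 0; ys <- 0; x <- 0; y <- 0; tt <- 0; tv <- 0
  for (b in seq_len(blocks)) {
    for (i in 1:10) { x <- x + u * dt * cos(dirs[b]); y <- y + u * dt * sin(dirs[b])
      xs <- c(xs, x); ys <- c(ys, y); tv <- c(tv, tv[length(tv)] + dt) }
    for (i in 1:3) { xs <- c(xs, x); ys <- c(ys, y)
      tv <- c(tv, tv[length(tv)] + dt) }  # stop
  }
  tr <- track_table(data.frame(track_id = 1L, t = tv, x = xs, y = ys),
                    frame_dt = dt)
  seg <- segment_runs(tr)
  ta <- turn_angle_stats(seg, tr)
  expect_gt(ta$n, 10)
  expect_lt(abs(ta$cos_phi), 0.05)
  # no tumbles: flagged undefined
  tstraight <- track_table(straight_track(60), frame_dt = 0.1)
  ta0 <- turn_angle_stats(segment_runs(tstraight), tstraight)
  expect_true(is.na(ta0$cos_phi))
  expect_equal(ta0$n, 0L)
})

test_that("short tracks are skipped with a count", {
  tr <- track_table(data.frame(track_id = c(1L, 1L, 2L, 2L, 2L, 2L),
                               t = c(0, 0.1, 0, 0.1, 0.2, 0.3),
                               x = c(0, 1, 0, 1, 2, 3),
                               y = 0), frame_dt = 0.1)
  seg <- segment_runs(tr)
  expect_equal(attr(seg, "n_skipped"), 1L)
  expect_true(all(seg$track_id == 2L))
})

test_that("track tables validate uniform increasing timestamps", {
  expect_error(track_table(data.frame(track_id = 1, t = c(0, 0.1, 0.1),
                                      x = 0, y = 0), 0.1),
               "strictly increasing")
})
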