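test_that("exponential filter reaches the kernel-integral steady state", {
  k <- response_kernel(2, 1.5, 0.2)
  conc <- rep(3, 4000)  # 80 s at dt = 0.02: >> memory time
  Q <- kernel_filter_response(k, conc, 0.02)
  expect_equal(Q[length(Q)], k$K0 * k$A * 3, tolerance = 1e-6)
  # precise adaptation: steady state returns to zero
  k0 <- response_kernel(2, 1.5, 0)
  Q0 <- kernel_filter_response(k0, conc, 0.02)
  expect_lt(abs(Q0[length(Q0)]), 1e-9)
})

test_that("filter transient matches the quadrature convolution oracle", {
  k <- response_kernel(1.3, 0.8, 0.1)
  dt <- 0.01
  tt <- seq(dt, 12, by = dt)
  Q <- kernel_filter_response(k, rep(2, length(tt)), dt)
  for (tq in c(0.5, 1, 2, 5, 10)) {
    oracle <- 2 * integrate(function(s) kernel_eval(k, s), 0, tq,
                            rel.tol = 1e-10)$value
    expect_equal(Q[which.min(abs(tt - tq))], oracle, tolerance = 1e-3)
  }
})

test_that("tumble rate follows the clipped rate law", {
  expect_equal(tumble_rate(0, 1.15), 1 / 1.15)
  expect_equal(tumble_rate(1.5, 1.15), 0)   # clipped at zero
  expect_equal(tumble_rate(-20, 1.15), 10 / 1.15)  # capped
  expect_equal(tumble_rate(0.5, 2), 0.25)
})

test_that("a non-tumbling agent without rotational diffusion swims straight", {
  mp <- motility_params(u = 15, tau_r = 1e9, D_rot = 0)
  cfg <- sim_config(dt = 0.02, T = 10, n_agents = 3, seed = 1)
  tr <- simulate_tracks(cfg, default_uniform_env(), null_sensing(),
                        motility = mp)
  for (d in split(tr, tr$track_id)) {
    n <- nrow(d)
    disp <- sqrt((d$x[n] - d$x[1])^2 + (d$y[n] - d$y[1])^2 +
                 (d$z[n] - d$z[1])^2)
    expect_equal(disp, 15 * 10, tolerance = 1e-6)
  }
})

test_that("direction correlation decays at exp(-2 D_rot t) without tumbling", {
  mp <- motility_params(u = 15, tau_r = 1e9, D_rot = 0.1)
  cfg <- sim_config(dt = 0.02, T = 2, n_agents = 500, seed = 2)
  tr <- simulate_tracks(cfg, default_uniform_env(), null_sensing(),
                        motility = mp)
  # displacement directions per frame
  cors <- sapply(split(tr, tr$track_id), function(d) {
    v <- cbind(diff(d$x), diff(d$y), diff(d$z))
    v <- v / sqrt(rowSums(v^2))
    sum(v[1, ] * v[nrow(v), ])
  })
  lag <- 1.9  # s between first and last frame interval (2 s, 0.1 s frames)
  se <- sd(cors) / sqrt(length(cors))
  expect_lt(abs(mean(cors) - exp(-2 * 0.1 * lag)), 3 * se)
})

test_that("empirical tumble-angle cosine matches the configured mean", {
  mp <- motility_params(tau_r = 0.3)  # fast tumbling for statistics
  cfg <- sim_config(dt = 0.005, T = 40, n_agents = 100, seed = 3)
  tr <- simulate_tracks(cfg, default_uniform_env(), null_sensing(),
                        motility = mp, record_runs = TRUE)
  tc <- attr(tr, "tumble_cos")
  expect_gt(length(tc), 1e4)
  expect_lt(abs(mean(tc) - 0.3), 0.02)
})

test_that("seeded simulations are bit-identical and symmetric without gradients", {
  cfg <- sim_config(dt = 0.02, T = 30, n_agents = 60, seed = 9)
  a <- simulate_tracks(cfg, default_uniform_env(), null_sensing())
  b <- simulate_tracks(cfg, default_uniform_env(), null_sensing())
  expect_identical(a$x, b$x)
  expect_identical(a$z, b$z)
  # zero-gradient drift consistent with zero
  dv <- measure_drift_velocity(a)
  expect_lt(abs(dv$v), 3 * dv$se)
})

test_that("long-time dispersion matches the persistent-random-walk diffusivity", {
  mp <- motility_params()
  cfg <- sim_config(dt = 0.02, T = 120, n_agents = 800, seed = 44,
                    frame_dt = 1)
  tr <- simulate_tracks(cfg, default_uniform_env(), null_sensing(),
                        motility = mp)
  last <- tr[tr$t == max(tr$t), ]
  msd <- mean(last$x^2 + last$y^2 + last$z^2)
  D_emp <- msd / (6 * 120)
  # the ballistic transient shortens the apparent MSD by 1/(sigma T)
  D_th <- rt_diffusivity(mp) * (1 - 1 / (mp$sigma * 120))
  expect_lt(abs(D_emp - D_th) / D_th, 0.10)
})

test_that("homogeneous run times follow tau_r times the modulation", {
  mod <- run_time_modulation(c(1, 3000), c(1.0, 2.1), "serine")
  env <- rt_environment_uniform(list(serine = 100))
  m100 <- modulation_eval(mod, 100)   # log-linear between the anchors
  expect_equal(m100, 1.0 + 1.1 * log(100) / log(3000), tolerance = 1e-10)
  cfg <- sim_config(dt = 0.02, T = 250, n_agents = 80, seed = 5)
  tr <- simulate_tracks(cfg, env, null_sensing(), mod, record_runs = TRUE)
  runs <- attr(tr, "runs")$duration
  se <- sd(runs) / sqrt(length(runs))
  expect_lt(abs(mean(runs) - 1.15 * m100), 3 * se + 0.02)
})

test_that("the non-adapted steady state lengthens runs as 1/(1 - K0 A c)", {
  sens <- sensing_model(list(response_kernel(0.05, 1, 0.2)))  # Q_ss = 0.1
  env <- rt_environment_uniform(list(attr = 10))
  cfg <- sim_config(dt = 0.02, T = 250, n_agents = 80, seed = 6)
  tr <- simulate_tracks(cfg, env, sens, record_runs = TRUE)
  runs <- attr(tr, "runs")$duration
  se <- sd(runs) / sqrt(length(runs))
  expect_lt(abs(mean(runs) - 1.15 / 0.9), 3 * se + 0.02)
  # with steady-component compensation the baseline is restored exactly
  sens_c <- sensing_model(list(response_kernel(0.05, 1, 0.2)), dc_comp = TRUE)
  tr2 <- simulate_tracks(cfg, env, sens_c, record_runs = TRUE)
  runs2 <- attr(tr2, "runs")$duration
  se2 <- sd(runs2) / sqrt(length(runs2))
  expect_lt(abs(mean(runs2) - 1.15), 3 * se2 + 0.02)
})

test_that("drift measurement is exact on constant-velocity tracks", {
  tr <- rbind(transform(straight_track(40, u = 12), track_id = 1L),
              transform(straight_track(40, u = 12), track_id = 2L))
  dv <- measure_drift_velocity(tr)
  expect_equal(dv$v, 12, tolerance = 1e-9)
  expect_equal(dv$se, 0, tolerance = 1e-9)
})

test_that("Monte-Carlo drift in a shallow gradient is linear and matches theory", {
  mp <- motility_params()
  k <- response_kernel(1, 1, 0)
  v1 <- validate_against_theory(mp, k, gradient = 0.01, c0 = 5,
                                n_agents = 1500, T = 150, seed = 11)
  expect_lt(v1$z, 3)
  expect_null(v1$warning)
  # doubling the gradient doubles the drift within errors
  v2 <- validate_against_theory(mp, k, gradient = 0.02, c0 = 10,
                                n_agents = 1500, T = 150, seed = 12)
  expect_lt(abs(v2$v_mc - 2 * v1$v_mc),
            3 * sqrt(v2$se^2 + 4 * v1$se^2))
  # zero gradient: both predictions vanish
  v0 <- validate_against_theory(mp, k, gradient = 0, c0 = 5,
                                n_agents = 400, T = 60, seed = 13)
  expect_equal(v0$v_theory, 0)
  expect_lt(abs(v0$v_mc), 3 * v0$se)
})

test_that("race bookkeeping conserves agents and respects the geometry", {
  pre <- condition_preset("aspartate")
  cfg <- sim_config(dt = 0.02, T = 400, seed = 21, snapshot_dt = 100)
  ch <- channel_geometry()
  r <- simulate_race(cfg, ch, pre$env, pre$sensing, pre$modulation,
                     entry_density = 1e-5)
  cts <- attr(r, "counts")
  expect_equal(cts[["injected"]],
               cts[["absorbed"]] + cts[["returned"]] + cts[["remaining"]])
  expect_true(all(r$x >= 0 & r$x <= ch$L))
  expect_true(all(r$y >= 0 & r$y <= ch$width))
  # no injection: channel stays empty
  r0 <- simulate_race(cfg, ch, pre$env, pre$sensing, pre$modulation,
                      entry_density = 0)
  expect_equal(nrow(r0), 0)
  # determinism
  r2 <- simulate_race(cfg, ch, pre$env, pre$sensing, pre$modulation,
                      entry_density = 1e-5)
  expect_identical(r$x, r2$x)
})

test_that("configuration guards reject unstable steps and bad drivers", {
  expect_error(
    simulate_tracks(sim_config(dt = 0.1, T = 1, n_agents = 1, seed = 1),
                    default_uniform_env(), null_sensing()),
    "stability")
  mod <- run_time_modulation(c(1, 10), c(1, 2), "nope")
  expect_error(
    simulate_tracks(sim_config(dt = 0.02, T = 1, n_agents = 1, seed = 1),
                    default_uniform_env(), null_sensing(), mod),
    "driver")
})
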