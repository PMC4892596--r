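test_that("kernel evaluates to the bilobed form and rejects negative times", {
  k <- response_kernel(1, 1, 0)
  expect_equal(kernel_eval(k, 0), 0)
  expect_equal(kernel_eval(k, 1), exp(-1) * 0.5, tolerance = 1e-12)
  # single positive lobe when A = 1
  k1 <- response_kernel(1, 1, 1)
  expect_true(all(kernel_eval(k1, seq(0, 20, by = 0.05)) >= 0))
  expect_error(kernel_eval(k, -0.1), "non-negative")
})

test_that("kernel integral equals K0 * A by quadrature over a parameter grid", {
  grid <- expand.grid(K0 = c(0.5, 1, 2), lam = c(0.3, 1, 5),
                      A = c(0, 0.03, 0.5))
  for (i in seq_len(nrow(grid))) {
    k <- response_kernel(grid$K0[i], grid$lam[i], grid$A[i])
    if (k$A == 0) expect_lt(abs(kernel_integral(k)), 1e-12)
    else expect_equal(kernel_integral(k), k$K0 * k$A, tolerance = 1e-6)
  }
})

test_that("closed-form chemotactic coefficient matches the Laplace quadrature", {
  set.seed(42)
  for (i in 1:100) {
    mp <- motility_params(u = runif(1, 5, 30), tau_r = runif(1, 0.3, 3),
                          D_rot = runif(1, 0, 0.5),
                          mean_cos_phi = runif(1, -0.5, 0.9))
    k <- response_kernel(runif(1, 0.1, 3), runif(1, 0.2, 4), runif(1, 0, 0.5))
    chi_c <- chemotactic_coefficient_closed(mp, k)
    chi_i <- chemotactic_coefficient_integral(
      mp, function(t) kernel_eval(k, t), lambda_hint = k$lam)
    expect_equal(chi_i, chi_c, tolerance = 1e-8)
  }
})

test_that("chemotactic coefficient matches hand-computed reference values", {
  mp <- motility_params(u = 15, tau_r = 1.15, D_rot = 0.1, mean_cos_phi = 0.3)
  expect_equal(mp$alpha, 0.7 / 1.15, tolerance = 1e-12)
  expect_equal(mp$sigma, 0.2 + 0.7 / 1.15, tolerance = 1e-12)
  k <- response_kernel(1, 1, 0)
  # independent oracle: direct quadrature of exp(-sigma t) K(t)
  lap <- integrate(function(t) exp(-mp$sigma * t) * kernel_eval(k, t),
                   0, 60, rel.tol = 1e-12)$value
  oracle <- mp$alpha * mp$u^2 / (3 * mp$sigma^2) * lap
  expect_equal(chemotactic_coefficient_closed(mp, k), oracle,
               tolerance = 1e-9)
  expect_equal(oracle, 9.5407, tolerance = 1e-4)
  # linear in K0
  expect_equal(chemotactic_coefficient_closed(mp, response_kernel(0, 1, 0)), 0)
  # zero kernel through the quadrature path
  expect_equal(chemotactic_coefficient_integral(mp, function(t) 0 * t), 0)
})

test_that("a narrow unit-area pulse recovers the analytic Laplace limit", {
  mp <- motility_params()
  w <- 0.05  # pulse width; exp(-sigma t) deviates from 1 by ~sigma*w/2
  chi <- chemotactic_coefficient_integral(
    mp, function(t) ifelse(t < w, 1 / w, 0), lambda_hint = 1 / w)
  expect_equal(chi, mp$alpha * mp$u^2 / (3 * mp$sigma^2), tolerance = 0.03)
})

test_that("optimal memory rate matches a dense grid search and has a pole", {
  expect_equal(optimal_memory_rate(0, 0.8), 1.6, tolerance = 1e-12)
  g <- function(l, A, s) l^2 * (s + A * l) / (s + l)^3
  for (A in c(0, 0.1, 0.2, 0.3)) {
    for (s in c(0.5, 1)) {
      lam_grid <- seq(0.05, 60, by = 0.005)
      l_grid <- lam_grid[which.max(g(lam_grid, A, s))]
      expect_equal(optimal_memory_rate(A, s), l_grid, tolerance = 0.01)
    }
  }
  expect_error(optimal_memory_rate(1 / 3, 1), "A < 1/3")
  expect_error(optimal_memory_rate(0.4, 1), "A < 1/3")
})

test_that("adaptation velocity gain is sigma-invariant, unity at A = 0, increasing", {
  expect_equal(adaptation_velocity_gain(0), 1, tolerance = 1e-14)
  expect_equal(adaptation_velocity_gain(0.03, sigma = 1),
               adaptation_velocity_gain(0.03, sigma = 7.3), tolerance = 1e-12)
  # the percentage excess at the serine-like defect, frozen from the
  # closed-form bracket ratio
  expect_equal(100 * (adaptation_velocity_gain(0.03) - 1), 6.2812,
               tolerance = 1e-3)
  gains <- sapply(seq(0, 0.3, by = 0.02), adaptation_velocity_gain)
  expect_true(all(diff(gains) > 0))
  expect_error(adaptation_velocity_gain(0.34), "1/3")
})

test_that("motor responses are sigmoidal with exact derivatives", {
  hill <- motor_hill(H = 10, y0 = 0.35)
  expect_equal(motor_response(hill, 0.35)$h, 0.5, tolerance = 1e-12)
  allo <- motor_allosteric(C = 4, n = 6, K1 = 0.5, K2 = 0.1)
  # algebraic limit at saturating CheY-P
  expect_equal(motor_response(allo, 1e6)$h,
               1 / (1 + 4 * (0.1 / 0.5)^6), tolerance = 1e-3)
  # allosteric bias positive at y = 0, Hill bias vanishes
  expect_gt(motor_response(allo, 0)$h, 0)
  expect_equal(motor_response(hill, 0)$h, 0)
  # monotone increasing, in (0, 1)
  y <- seq(0.01, 0.99, by = 0.01)
  for (m in list(hill, allo)) {
    h <- motor_response(m, y)$h
    expect_true(all(h > 0 & h < 1))
    expect_true(all(diff(h) > 0))
    # derivative vs central finite differences
    eps <- 1e-6
    fd <- (motor_response(m, y + eps)$h - motor_response(m, y - eps)$h) /
      (2 * eps)
    expect_equal(motor_response(m, y)$dh, fd, tolerance = 1e-6)
  }
  expect_error(motor_allosteric(K1 = 0.1, K2 = 0.5), "K1 > K2")
})

test_that("response amplitude collapses to H K (1 - a) for the Hill motor", {
  hill <- motor_hill(H = 8, y0 = 0.3)
  K <- 0.3
  a <- seq(0.01, 0.99, by = 0.01)
  amp <- response_amplitude(pathway_state(a, K), hill)
  # generic formula evaluated independently through motor_response
  y <- a / (a + K)
  mr <- motor_response(hill, y)
  generic <- a * (1 - a) * mr$dh * (1 - y) / (mr$h * (1 - mr$h))
  expect_equal(amp, generic, tolerance = 1e-9)
  expect_equal(amp, 8 * K * (1 - a), tolerance = 1e-9)
  # ratio constant in a
  expect_lt(diff(range(amp / (8 * K * (1 - a)))), 1e-9)
  # vanishes at full activity
  expect_lt(response_amplitude(pathway_state(1, K), hill), 1e-6)
})

test_that("allosteric amplitude peaks at an interior activity below one half", {
  allo <- motor_allosteric()
  K <- 0.3
  f <- function(a) response_amplitude(pathway_state(a, K), allo)
  eps <- 1e-5
  expect_gt((f(2 * eps) - f(eps)) / eps, 0)   # increasing at a = 0+
  expect_lt((f(0.5 + eps) - f(0.5 - eps)) / (2 * eps), 0)  # decreasing at 1/2
  astar <- amplitude_argmax(allo, K)
  expect_gt(astar, 0)
  expect_lt(astar, 0.5)
  grid <- seq(0.001, 0.999, length.out = 4001)
  expect_lt(abs(astar - grid[which.max(f(grid))]), 5e-4)
  # Hill motor peaks at zero activity
  expect_lt(amplitude_argmax(motor_hill(), K), 1e-3)
})

test_that("chemotactic coefficient grows with run time up to about 3 s", {
  k <- response_kernel(1, 1, 0)
  taus <- seq(0.1, 3, by = 0.1)
  chi <- sapply(taus, function(tr)
    chemotactic_coefficient_closed(motility_params(tau_r = tr), k))
  expect_true(all(diff(chi) > 0))
})

test_that("constructors validate their domains", {
  expect_error(motility_params(u = -1))
  expect_error(motility_params(mean_cos_phi = 1.2))
  expect_error(response_kernel(1, -1, 0))
  expect_error(pathway_state(1.5))
  expect_silent(pathway_state(c(0, 0.5, 1)))
})
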