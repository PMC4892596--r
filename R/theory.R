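#' Swimming and tumbling parameters of a run-and-tumble bacterium
#'
#' Bundles the motility parameters entering the chemotactic-velocity theory:
#' the running speed, the baseline mean run time, the rotational diffusivity
#' and the mean cosine of the tumble scattering angle. Two decorrelation rates
#' are derived: `alpha = (1 - mean_cos_phi) / tau_r`, the tumbling contribution
#' to directional decorrelation, and `sigma = 2 * D_rot + alpha`, the total
#' decorrelation rate of the swimming direction in three dimensions.
#'
#' @param u Running speed (um/s). Default 15, typical of E. coli.
#' @param tau_r Baseline mean run time (s). Default 1.15, the population mean
#'   in the absence of attractant.
#' @param D_rot Rotational diffusivity (rad^2/s). Default 0.1.
#' @param mean_cos_phi Mean cosine of the tumble scattering angle
#'   (dimensionless, in (-1, 1)). Default 0.3.
#'
#' @return An object of class `motility_params`: a list with the four inputs
#'   plus derived rates `alpha` and `sigma` (1/s).
#' @examples
#' mp <- motility_params()
#' mp$alpha  # (1 - 0.3) / 1.15
#' @export
motility_params <- function(u = 15, tau_r = 1.15, D_rot = 0.1,
                            mean_cos_phi = 0.3) {
  stopifnot(u > 0, tau_r > 0, D_rot >= 0,
            mean_cos_phi > -1, mean_cos_phi < 1)
  alpha <- (1 - mean_cos_phi) / tau_r
  structure(list(u = u, tau_r = tau_r, D_rot = D_rot,
                 mean_cos_phi = mean_cos_phi,
                 alpha = alpha, sigma = 2 * D_rot + alpha),
            class = "motility_params")
}

#' @export
print.motility_params <- function(x, ...) {
  cat("Run-and-tumble motility parameters\n")
  cat(sprintf("  u = %g um/s, tau_r = %g s, D_rot = %g rad^2/s, <cos phi> = %g\n",
              x$u, x$tau_r, x$D_rot, x$mean_cos_phi))
  cat(sprintf("  alpha = %.5g 1/s, sigma = %.5g 1/s\n", x$alpha, x$sigma))
  invisible(x)
}

#' Bilobed chemotactic impulse-response kernel
#'
#' The linear impulse response of the tumbling machinery to a unit
#' concentration impulse,
#' \deqn{K(t) = K_0 \lambda e^{-\lambda t}\left[\lambda t -
#'   \frac{1-A}{2}(\lambda t)^2\right],}
#' a positive lobe followed by a negative one. The adaptation-defect parameter
#' `A` controls the imbalance of the two lobes: the time integral of the
#' kernel equals `K0 * A`, so `A = 0` corresponds to precise adaptation
#' (vanishing integral) and `A > 0` to a net steady-state lengthening of runs
#' with concentration, as observed for serine.
#'
#' @param K0 Amplitude (1/(uM*s)); sets sensitivity and dynamic range.
#' @param lam Memory rate lambda (1/s); `1/lam` is the memory timescale of
#'   past concentration detections.
#' @param A Adaptation-defect parameter (dimensionless). `A = 0`: precise
#'   adaptation; serine-like responses have `A` of order 0.03.
#'
#' @return An object of class `response_kernel`.
#' @export
response_kernel <- function(K0 = 1, lam = 1, A = 0) {
  stopifnot(is.finite(K0), lam > 0, is.finite(A))
  structure(list(K0 = K0, lam = lam, A = A), class = "response_kernel")
}

#' @export
print.response_kernel <- function(x, ...) {
  cat(sprintf("Bilobed response kernel: K0 = %g 1/(uM s), lambda = %g 1/s, A = %g\n",
              x$K0, x$lam, x$A))
  cat(sprintf("  integral K0*A = %g 1/uM (%s)\n", x$K0 * x$A,
              if (x$A == 0) "precise adaptation" else "imprecise adaptation"))
  invisible(x)
}

#' Evaluate the impulse-response kernel
#'
#' @param kernel A [response_kernel()].
#' @param t Times (s), non-negative.
#' @return Response density at `t` (1/(uM*s)).
#' @examples
#' k <- response_kernel(1, 1, 0)
#' kernel_eval(k, 1)  # exp(-1) * 0.5
#' @export
kernel_eval <- function(kernel, t) {
  stopifnot(inherits(kernel, "response_kernel"))
  if (any(t < 0)) stop("kernel_eval: t must be non-negative")
  lt <- kernel$lam * t
  kernel$K0 * kernel$lam * exp(-lt) * (lt - (1 - kernel$A) / 2 * lt^2)
}

#' Time integral of the impulse-response kernel
#'
#' Evaluates \eqn{\int_0^\infty K(t)\,dt} by adaptive quadrature on
#' `[0, 40/lambda]` (the kernel is negligible beyond). For the bilobed kernel
#' this integral equals `K0 * A` analytically; the quadrature path is kept so
#' that arbitrary kernels can be checked against the precise-adaptation
#' criterion.
#'
#' @param kernel A [response_kernel()].
#' @return The integral (1/uM).
#' @export
kernel_integral <- function(kernel) {
  stopifnot(inherits(kernel, "response_kernel"))
  q <- integrate(function(t) kernel_eval(kernel, t),
                 lower = 0, upper = 40 / kernel$lam,
                 rel.tol = 1e-10, abs.tol = 1e-12, subdivisions = 400L)
  q$value
}

#' Chemotactic coefficient: closed form
#'
#' The proportionality constant between the drift velocity up-gradient and the
#' concentration gradient, `v = chi * dc/dx`, for the bilobed kernel:
#' \deqn{\chi = \frac{K_0 u^2 \alpha}{3\sigma^2}\,
#'   \frac{\lambda^2(\sigma + A\lambda)}{(\sigma+\lambda)^3}.}
#' The `1/3` is the three-dimensional projection factor and
#' `sigma = 2 D_rot + alpha` the directional decorrelation rate.
#'
#' @param motility A [motility_params()].
#' @param kernel A [response_kernel()].
#' @return chi (um^2/(s*uM)).
#' @examples
#' chemotactic_coefficient_closed(motility_params(), response_kernel(1, 1, 0))
#' @export
chemotactic_coefficient_closed <- function(motility, kernel) {
  stopifnot(inherits(motility, "motility_params"),
            inherits(kernel, "response_kernel"))
  s <- motility$sigma
  l <- kernel$lam
  kernel$K0 * motility$u^2 * motility$alpha / (3 * s^2) *
    l^2 * (s + kernel$A * l) / (s + l)^3
}

#' Chemotactic coefficient: quadrature form
#'
#' Evaluates \eqn{\chi = \frac{\alpha u^2}{3\sigma^2}\int_0^\infty
#' e^{-\sigma t} K(t)\,dt} by adaptive quadrature, for an arbitrary
#' user-supplied kernel function (not only the bilobed form). The upper limit
#' is `40 / min(lambda_hint, sigma)`; `lambda_hint` lets callers with
#' slowly-decaying kernels extend the integration window.
#'
#' @param motility A [motility_params()].
#' @param kernel_fn Function of time (s) returning response density
#'   (1/(uM*s)); must be integrable against `exp(-sigma * t)`.
#' @param lambda_hint Decay-rate hint (1/s) used to set the quadrature window.
#' @return chi (um^2/(s*uM)).
#' @export
chemotactic_coefficient_integral <- function(motility, kernel_fn,
                                             lambda_hint = 1) {
  stopifnot(inherits(motility, "motility_params"), is.function(kernel_fn))
  s <- motility$sigma
  upper <- 40 / min(lambda_hint, s)
  split <- min(1 / lambda_hint, upper / 2)  # resolves short-memory kernels
  f <- function(t) exp(-s * t) * kernel_fn(t)
  q <- tryCatch(
    integrate(f, 0, split, rel.tol = 1e-11, abs.tol = 1e-13,
              subdivisions = 800L)$value +
    integrate(f, split, upper, rel.tol = 1e-11, abs.tol = 1e-13,
              subdivisions = 800L)$value,
    error = function(e) stop("chemotactic_coefficient_integral: quadrature failed (",
                             conditionMessage(e), ")"))
  motility$alpha * motility$u^2 / (3 * s^2) * q
}

#' Memory rate maximizing the chemotactic coefficient
#'
#' With all other parameters fixed, the bracket
#' \eqn{\lambda^2(\sigma+A\lambda)/(\sigma+\lambda)^3} of the closed-form
#' chemotactic coefficient is maximized at
#' \deqn{\lambda^* = \frac{2\sigma}{1 - 3A},}
#' valid for `A < 1/3` (the optimum runs away to infinite memory rate at the
#' pole).
#'
#' @param A Adaptation-defect parameter, `A < 1/3`.
#' @param sigma Directional decorrelation rate (1/s).
#' @return lambda* (1/s).
#' @export
optimal_memory_rate <- function(A, sigma) {
  stopifnot(sigma > 0)
  if (any(A >= 1 / 3))
    stop("optimal_memory_rate: requires A < 1/3 (pole of the formula)")
  2 * sigma / (1 - 3 * A)
}

#' Velocity gain from imprecise adaptation
#'
#' Ratio of the lambda-maximized chemotactic coefficient at adaptation defect
#' `A` to its value under precise adaptation (`A = 0`), each evaluated at its
#' own optimal memory rate:
#' \deqn{G(A) = \frac{g(\lambda^*(A); A)}{g(\lambda^*(0); 0)},\qquad
#'   g(\lambda; A) = \frac{\lambda^2(\sigma + A\lambda)}{(\sigma+\lambda)^3}.}
#' The ratio is independent of `sigma` (both brackets scale as `1/sigma`), so
#' `sigma` only needs to be any positive value; the default 1 is used unless
#' a caller wants to verify the scale invariance.
#'
#' @param A Adaptation-defect parameter in `[0, 1/3)`.
#' @param sigma Decorrelation rate (1/s); the result does not depend on it.
#' @return Gain ratio (dimensionless, 1 at `A = 0`).
#' @examples
#' 100 * (adaptation_velocity_gain(0.03) - 1)  # percent excess, about 6.3
#' @export
adaptation_velocity_gain <- function(A, sigma = 1) {
  stopifnot(sigma > 0)
  if (any(A < 0) || any(A >= 1 / 3))
    stop("adaptation_velocity_gain: requires 0 <= A < 1/3")
  g <- function(l, A) l^2 * (sigma + A * l) / (sigma + l)^3
  g(optimal_memory_rate(A, sigma), A) / g(2 * sigma, 0)
}

#' Motor response curves: Hill and allosteric
#'
#' The clockwise-bias response `h(y)` of the flagellar motor to the fractional
#' CheY-P level `y`. Two sigmoidal variants are supported:
#' * Hill: `h(y) = [1 + (y/y0)^(-H)]^(-1)`, which vanishes at `y = 0`;
#' * allosteric (conformation-spread flavour):
#'   `h(y) = 1 / [1 + C ((1 + y/K1)/(1 + y/K2))^n]` with `K1 > K2`, which
#'   stays positive at `y = 0` because the motor switches between its two
#'   conformations at a basal rate even without CheY-P.
#'
#' @param H Hill coefficient (> 0).
#' @param y0 Half-maximum CheY-P fraction (0 < y0 < 1).
#' @return An object of class `motor_model`.
#' @export
motor_hill <- function(H = 10, y0 = 0.35) {
  stopifnot(H > 0, y0 > 0, y0 < 1)
  structure(list(variant = "hill", H = H, y0 = y0), class = "motor_model")
}

#' @rdname motor_hill
#' @param C Basal conformational equilibrium constant (> 0).
#' @param n Number of conformational units (> 0).
#' @param K1,K2 Dissociation constants of CheY-P for the two motor
#'   conformations, `K1 > K2 > 0` (run-favouring conformation binds weaker).
#' @export
motor_allosteric <- function(C = 4, n = 6, K1 = 0.5, K2 = 0.1) {
  stopifnot(C > 0, n > 0)
  if (!(K1 > K2 && K2 > 0))
    stop("motor_allosteric: requires K1 > K2 > 0")
  structure(list(variant = "allosteric", C = C, n = n, K1 = K1, K2 = K2),
            class = "motor_model")
}

#' @export
print.motor_model <- function(x, ...) {
  if (x$variant == "hill")
    cat(sprintf("Hill motor response: H = %g, y0 = %g\n", x$H, x$y0))
  else
    cat(sprintf("Allosteric motor response: C = %g, n = %g, K1 = %g, K2 = %g\n",
                x$C, x$n, x$K1, x$K2))
  invisible(x)
}

#' Evaluate the motor bias and its slope
#'
#' Returns the clockwise bias `h(y)` and its exact derivative `h'(y)`.
#' Derivatives are analytic: for the Hill form `h' = (H/y) h (1 - h)`, and for
#' the allosteric form `h' = -C n R^(n-1) R' h^2` with
#' `R(y) = (1 + y/K1)/(1 + y/K2)` and `R' = (1/K1 - 1/K2)/(1 + y/K2)^2`.
#'
#' @param motor A [motor_hill()] or [motor_allosteric()].
#' @param y CheY-P fraction(s), `y >= 0`.
#' @return A list with vectors `h` (bias in (0,1)) and `dh` (slope).
#' @export
motor_response <- function(motor, y) {
  stopifnot(inherits(motor, "motor_model"))
  if (any(y < 0)) stop("motor_response: y must be non-negative")
  if (motor$variant == "hill") {
    H <- motor$H; y0 <- motor$y0
    # stable at both ends: express via (y/y0)^H
    r <- (y / y0)^H
    h <- r / (1 + r)
    dh <- ifelse(y > 0, (H / y) * h * (1 - h), if (H > 1) 0 else NA_real_)
    if (H == 1) dh[y == 0] <- 1 / y0
  } else {
    C <- motor$C; n <- motor$n; K1 <- motor$K1; K2 <- motor$K2
    R <- (1 + y / K1) / (1 + y / K2)
    h <- 1 / (1 + C * R^n)
    dR <- (1 / K1 - 1 / K2) / (1 + y / K2)^2
    dh <- -C * n * R^(n - 1) * dR * h^2
  }
  list(h = h, dh = dh)
}

#' Pathway state: CheA-P activity and the quasi-steady CheY-P level
#'
#' Maps the fractional CheA-P concentration `a` to the fractional CheY-P
#' level through the quasi-steady-state relation `y = a / (a + K)`.
#'
#' @param a Fractional CheA-P concentration in `[0, 1]`.
#' @param K_qss Quasi-steady constant (> 0).
#' @return An object of class `pathway_state` with fields `a`, `K_qss`, `y`.
#' @export
pathway_state <- function(a, K_qss = 0.3) {
  stopifnot(all(a >= 0), all(a <= 1), K_qss > 0)
  structure(list(a = a, K_qss = K_qss, y = a / (a + K_qss)),
            class = "pathway_state")
}

#' Linear-response amplitude of the chemotactic kernel
#'
#' The linear-regime amplitude of the response kernel as a function of the
#' pathway operating point,
#' \deqn{K_0 \propto \frac{a(1-a)\,h'(y)\,(1-y)}{h(y)\,(1-h(y))},\qquad
#'   y = \frac{a}{a+K},}
#' with the proportionality constant fixed to 1: the returned value is in
#' arbitrary units and is used only for shape and argmax statements, never
#' mixed with the uM-calibrated amplitude of [response_kernel()]. For the Hill
#' motor the expression collapses analytically to `H * K * (1 - a)` (maximal
#' at zero activity); for the allosteric motor it peaks at an interior
#' activity in `(0, 1/2)`.
#'
#' Endpoints `a = 0` and `a = 1` are handled by one-sided limits evaluated at
#' `a = 1e-9` and `1 - 1e-9`.
#'
#' @param state A [pathway_state()] (vector `a` allowed).
#' @param motor A motor model.
#' @return Amplitude(s), arbitrary units.
#' @export
response_amplitude <- function(state, motor) {
  stopifnot(inherits(state, "pathway_state"), inherits(motor, "motor_model"))
  eps <- 1e-9
  a <- pmin(pmax(state$a, eps), 1 - eps)
  K <- state$K_qss
  y <- a / (a + K)
  if (motor$variant == "hill") {
    # a(1-a) * (H/y) h(1-h) (1-y) / (h(1-h)) = a(1-a) H (1-y)/y = H K (1-a)
    return(motor$H * K * (1 - a))
  }
  mr <- motor_response(motor, y)
  denom <- mr$h * (1 - mr$h)
  if (any(denom == 0))
    stop("response_amplitude: motor bias saturated exactly at 0 or 1")
  a * (1 - a) * mr$dh * (1 - y) / denom
}

#' Activity maximizing the response amplitude
#'
#' Locates the fractional CheA-P activity `a*` at which the linear-response
#' amplitude peaks, by a dense-grid scan refined with golden-section search.
#' For a Hill motor the amplitude `H K (1 - a)` is decreasing, so `a* = 0`;
#' allosteric motors peak at an interior activity below one half.
#'
#' @param motor A motor model.
#' @param K_qss Quasi-steady constant of the CheA-P to CheY-P map.
#' @param n_grid Grid size of the initial scan.
#' @return `a*` in `[0, 1]`.
#' @export
amplitude_argmax <- function(motor, K_qss = 0.3, n_grid = 2001L) {
  stopifnot(inherits(motor, "motor_model"))
  f <- function(a) response_amplitude(pathway_state(a, K_qss), motor)
  grid <- seq(0, 1, length.out = n_grid)
  i <- which.max(f(grid))
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_grid, i + 1L)]
  if (i == 1L || i == n_grid) {
    # boundary maximum: refine against the adjacent cell only
    opt <- optimize(f, lower = lo, upper = hi, maximum = TRUE, tol = 1e-10)
    cand <- c(grid[i], opt$maximum)
    return(cand[which.max(f(cand))])
  }
  optimize(f, lower = lo, upper = hi, maximum = TRUE, tol = 1e-10)$maximum
}

#' Effective diffusivity of the run-and-tumble walk
#'
#' Long-time translational diffusivity `D = u^2 / (3 sigma)` of the
#' three-dimensional persistent random walk; the same coefficient enters the
#' continuum drift-diffusion description.
#'
#' @param motility A [motility_params()].
#' @return D (um^2/s).
#' @export
rt_diffusivity <- function(motility) {
  stopifnot(inherits(motility, "motility_params"))
  motility$u^2 / (3 * motility$sigma)
}
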