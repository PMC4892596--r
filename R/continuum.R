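#' Transport coefficients of the continuum channel model
#'
#' Drift-diffusion coefficients for the 1-D (cross-section homogenized)
#' description of the bacterial density along the channel axis:
#' `D(x) = u^2 / (3 sigma(x))` and `v(x) = chi(x) * dc/dx`. Both may vary
#' with position through the run-time modulation (`tau_r(c(x))` enters
#' `alpha` and `sigma`) and the Weber rescaling of the kernel amplitude.
#'
#' @param D Diffusivity: scalar or function of `x` (um^2/s), positive.
#' @param v Drift velocity: scalar or function of `x` (um/s).
#' @param L Channel length (um).
#' @return Object of class `transport_coeffs`.
#' @seealso [transport_from_theory()] to build the coefficients from a
#'   motility/kernel/gradient description.
#' @export
transport_coeffs <- function(D, v, L = 4000) {
  Df <- if (is.function(D)) D else function(x) rep(D, length(x))
  vf <- if (is.function(v)) v else function(x) rep(v, length(x))
  if (any(Df(seq(0, L, length.out = 101)) <= 0))
    stop("transport_coeffs: D must be positive everywhere")
  structure(list(D = Df, v = vf, L = L), class = "transport_coeffs")
}

#' Transport coefficients from the run-and-tumble theory
#'
#' Builds position-dependent `D(x)` and `v(x)` for a channel with a linear
#' attractant profile: the local run time is `tau_r * m(c(x))`, the local
#' decorrelation rates follow, `D = u^2/(3 sigma)`, and the drift is
#' `chi(x) * dc/dx` with the kernel amplitude optionally Weber-rescaled by
#' `c_ref / (c + c_eps)`.
#'
#' @param motility A [motility_params()] (baseline `tau_r`).
#' @param kernel A [response_kernel()].
#' @param env An [rt_environment()] with a single attractant.
#' @param modulation A [run_time_modulation()] or `NULL`.
#' @param weber Use the Weber amplitude rescaling.
#' @param c_ref,c_eps Weber parameters (uM).
#' @return A [transport_coeffs()].
#' @export
transport_from_theory <- function(motility, kernel, env, modulation = NULL,
                                  weber = TRUE, c_ref = 100, c_eps = 1) {
  stopifnot(inherits(env, "rt_environment"),
            length(env$attractants) == 1)
  a <- env$attractants[[1]]
  local_par <- function(x) {
    cc <- pmax(0, a$base + a$slope * x)
    m <- if (is.null(modulation)) rep(1, length(x)) else modulation_eval(modulation, cc)
    tau <- motility$tau_r * m
    alpha <- (1 - motility$mean_cos_phi) / tau
    sigma <- 2 * motility$D_rot + alpha
    list(c = cc, alpha = alpha, sigma = sigma)
  }
  Dfun <- function(x) {
    p <- local_par(x)
    motility$u^2 / (3 * p$sigma)
  }
  vfun <- function(x) {
    p <- local_par(x)
    K0e <- if (weber) kernel$K0 * c_ref / (p$c + c_eps) else kernel$K0
    l <- kernel$lam
    chi <- K0e * motility$u^2 * p$alpha / (3 * p$sigma^2) *
      l^2 * (p$sigma + kernel$A * l) / (p$sigma + l)^3
    chi * a$slope
  }
  transport_coeffs(Dfun, vfun, env$L)
}

#' Solve the 1-D drift-diffusion equation in the channel
#'
#' Integrates `dt rho = dx(D dx rho) - dx(v rho)` with a maintained source
#' density `rho(0) = rho0` (the injection channel) and an absorbing reservoir
#' `rho(L) = 0`, by a Crank-Nicolson finite-volume scheme on a uniform grid.
#' The grid is refined automatically (with a warning) until the cell Peclet
#' number `|v| dx / D` is below 2 everywhere, so the central flux averaging
#' stays oscillation-free. Face fluxes are bookkept so that the discrete mass
#' balance `d/dt integral(rho) = J_in - J_out` holds to round-off.
#'
#' @param coeffs A [transport_coeffs()].
#' @param rho0 Maintained density at the entry (bacteria per um of channel).
#' @param T Duration (s).
#' @param dx Target grid spacing (um).
#' @param dt Time step (s).
#' @param record_dt Interval between recorded profiles (s); default `dt`.
#' @param rho_init Initial profile: scalar or vector on the grid; default 0
#'   (empty channel).
#' @return Object of class `density_field`: list with `x`, `t`, `rho`
#'   (time-by-space matrix), `J_in`, `J_out` (bacteria/s), `mass`
#'   (bacteria), `D`, `v` (face values).
#' @export
solve_drift_diffusion <- function(coeffs, rho0, T, dx = 10, dt = 1,
                                  record_dt = NULL, rho_init = 0) {
  stopifnot(inherits(coeffs, "transport_coeffs"), rho0 >= 0, T > 0)
  L <- coeffs$L
  for (ref in 0:6) {
    N <- ceiling(L / dx)
    dx_use <- L / N
    xf <- (seq_len(N) - 0.5) * dx_use          # face centers
    Df <- coeffs$D(xf); vf <- coeffs$v(xf)
    pe <- max(abs(vf) * dx_use / Df)
    if (pe < 2) break
    dx <- dx / 2
    warning(sprintf("solve_drift_diffusion: cell Peclet %.2f >= 2, refining dx to %g um",
                    pe, dx))
  }
  if (pe >= 2) stop("solve_drift_diffusion: could not satisfy Peclet condition")
  x <- seq(0, L, by = dx_use)
  n_steps <- ceiling(T / dt)
  rec_stride <- if (is.null(record_dt)) 1L else stride_of(record_dt, dt, "record_dt")
  r0 <- if (length(rho_init) == 1) rep(rho_init, N + 1) else rho_init
  stopifnot(length(r0) == N + 1)
  sol <- .pde_cn_cpp(Df, vf, dx_use, dt, n_steps, rec_stride, rho0, r0)
  structure(list(x = x, t = sol$t, rho = sol$rho, J_in = sol$J_in,
                 J_out = sol$J_out, mass = sol$mass, D = Df, v = vf,
                 dx = dx_use, L = L, rho0 = rho0),
            class = "density_field")
}

#' Stationary density profile and flux
#'
#' The steady state of the drift-diffusion channel problem has a constant
#' flux `J = v rho - D rho'` with `rho(0) = rho0`, `rho(L) = 0`. In the
#' stable quadrature form
#' \deqn{\rho(x) = J \int_x^L \frac{e^{\Phi(x)-\Phi(s)}}{D(s)}\,ds,\qquad
#'   J = \rho_0 \Big/ \int_0^L \frac{e^{-\Phi(s)}}{D(s)}\,ds,\qquad
#'   \Phi(x)=\int_0^x \frac{v}{D}\,dx'.}
#' For constant coefficients this reduces to
#' `rho(x) = (J/v)(1 - exp(v (x - L)/D))` with
#' `J = v rho0 / (1 - exp(-v L / D))`.
#'
#' @param coeffs A [transport_coeffs()].
#' @param rho0 Entry density (bacteria/um).
#' @param n Quadrature grid size.
#' @return List with `x`, `rho` (stationary profile), `J` (flux,
#'   bacteria/s).
#' @export
stationary_profile <- function(coeffs, rho0, n = 2001L) {
  stopifnot(inherits(coeffs, "transport_coeffs"), rho0 >= 0)
  x <- seq(0, coeffs$L, length.out = n)
  D <- coeffs$D(x); v <- coeffs$v(x)
  h <- x[2] - x[1]
  phi <- cumsum(c(0, (v[-1] / D[-1] + v[-n] / D[-n]) / 2 * h))
  # I(x) = int_x^L exp(phi(x) - phi(s))/D(s) ds, computed by a backward
  # recursion so all exponents stay non-positive when v > 0
  g <- 1 / D
  I <- numeric(n)
  for (i in (n - 1):1) {
    w <- exp(phi[i] - phi[i + 1])
    I[i] <- w * I[i + 1] + h / 2 * (g[i] + w * g[i + 1])
  }
  J <- rho0 / I[1]
  list(x = x, rho = J * I, J = J)
}

#' Progression function from a density field
#'
#' `N(x, t) = integral_x^L rho(x', t) dx'`: the number of bacteria between
#' position `x` and the reservoir end, per recorded time.
#'
#' @param field A `density_field`.
#' @param x Positions (um) at which to evaluate; default the field grid.
#' @return Matrix `N` (times in rows, positions in columns) with attributes
#'   `x`, `t`.
#' @export
progression_from_density <- function(field, x = NULL) {
  stopifnot(inherits(field, "density_field"))
  xg <- field$x
  dxg <- field$dx
  # reverse cumulative trapezoid on the native grid, then interpolate
  Nmat <- t(apply(field$rho, 1, function(r) {
    seg <- (r[-1] + r[-length(r)]) / 2 * dxg
    rev(c(0, cumsum(rev(seg))))
  }))
  if (!is.null(x)) {
    Nmat <- t(apply(Nmat, 1, function(Nr) approx(xg, Nr, xout = x, rule = 2)$y))
    xg <- x
  }
  attr(Nmat, "x") <- xg
  attr(Nmat, "t") <- field$t
  Nmat
}

#' Rank-k front from a density field
#'
#' The position `x_k(t)` of the k-th most advanced bacterium in the continuum
#' description: the solution of `N(x_k, t) = k` where `N` is the progression
#' function. `NA` while the channel holds fewer than `k` bacteria; once the
#' density is stationary the front is constant (the saturation plateau), and
#' larger `k` plateaus farther back.
#'
#' @param field A `density_field`.
#' @param k Rank (count), > 0.
#' @return Data frame with `t` and `x_k` (um, `NA` when undefined).
#' @export
front_from_density <- function(field, k) {
  stopifnot(inherits(field, "density_field"), k > 0)
  Nmat <- progression_from_density(field)
  xg <- attr(Nmat, "x")
  xk <- apply(Nmat, 1, function(Nr) {
    if (Nr[1] < k) return(NA_real_)
    # N is non-increasing in x; find the crossing by monotone interpolation
    i <- max(which(Nr >= k))
    if (i == length(Nr)) return(xg[length(xg)])
    w <- (Nr[i] - k) / max(Nr[i] - Nr[i + 1], .Machine$double.eps)
    xg[i] + w * (xg[i + 1] - xg[i])
  })
  data.frame(t = field$t, x_k = xk)
}

#' Gradient distortion by attractant consumption
#'
#' Estimates how much bacterial uptake bends the linear attractant profile:
#' solves the steady reaction-diffusion balance
#' `D_attr c'' = q rho_b(x)` with the end concentrations fixed
#' (`c(0) = c_entry`, `c(L) = c_reservoir`) on a fine grid, and reports the
#' deviation from the undisturbed linear profile. For uniform `rho_b` the
#' deviation is the parabola `q rho_b x (L - x) / (2 D_attr)`, largest at the
#' midpoint where it equals `q rho_b L^2 / (8 D_attr)`; the headline scalar
#' `rel_mid` is that midpoint deviation relative to the midpoint linear
#' value (the entry-side ratio diverges as the linear profile goes to zero,
#' so it is not a useful summary).
#'
#' @param q Uptake rate per cell (uM um^3/s).
#' @param rho_b Cell density: scalar or function of `x` (cells/um^3).
#' @param D_attr Attractant diffusivity (um^2/s).
#' @param L Channel length (um).
#' @param c_entry,c_reservoir End concentrations (uM).
#' @param n Grid size.
#' @return List with `x`, `c`, `c_linear`, `deviation`
#'   (`c - c_linear`, <= 0), `rel_mid`, and `regime_violation` (TRUE when
#'   consumption drives `c` negative, i.e. the perturbative estimate is
#'   outside its regime).
#' @export
consumption_distortion <- function(q, rho_b, D_attr, L = 4000,
                                   c_entry = 0, c_reservoir = 1000,
                                   n = 801L) {
  stopifnot(q >= 0, D_attr > 0, L > 0)
  rb <- if (is.function(rho_b)) rho_b else function(x) rep(rho_b, length(x))
  x <- seq(0, L, length.out = n)
  h <- x[2] - x[1]
  src <- q * rb(x) / D_attr
  # tridiagonal Poisson solve: c'' = src, Dirichlet ends
  ni <- n - 2L
  d <- rep(-2, ni); rhs <- src[2:(n - 1)] * h^2
  rhs[1] <- rhs[1] - c_entry
  rhs[ni] <- rhs[ni] - c_reservoir
  # Thomas algorithm (sub/super diagonals are all 1)
  cp <- numeric(ni); dp <- numeric(ni)
  cp[1] <- 1 / d[1]; dp[1] <- rhs[1] / d[1]
  if (ni > 1) for (i in 2:ni) {
    m <- d[i] - cp[i - 1]
    cp[i] <- 1 / m
    dp[i] <- (rhs[i] - dp[i - 1]) / m
  }
  sol <- numeric(ni)
  sol[ni] <- dp[ni]
  if (ni > 1) for (i in (ni - 1):1) sol[i] <- dp[i] - cp[i] * sol[i + 1]
  cc <- c(c_entry, sol, c_reservoir)
  c_lin <- c_entry + (c_reservoir - c_entry) * x / L
  dev <- cc - c_lin
  mid <- which.min(abs(x - L / 2))
  rel_mid <- if (c_lin[mid] > 0) abs(dev[mid]) / c_lin[mid] else NA_real_
  list(x = x, c = cc, c_linear = c_lin, deviation = dev,
       rel_mid = rel_mid, regime_violation = any(cc < 0))
}
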