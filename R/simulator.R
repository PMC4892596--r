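#' Attractant environment of the lateral channel
#'
#' One or more attractants, each with a linear concentration profile
#' `c(x) = max(0, c_entry + (c_reservoir - c_entry) * x / L)` plus an optional
#' uniform background. The gradient is constant per attractant; concentrations
#' are clipped at zero outside the channel.
#'
#' @param attractants A list of attractant specs, each a list with `name`,
#'   `c_entry` (uM at x = 0), `c_reservoir` (uM at x = L), and optional
#'   `background` (uM, added uniformly).
#' @param L Channel length (um).
#' @return An object of class `rt_environment`.
#' @examples
#' env <- rt_environment(list(list(name = "serine", c_entry = 0,
#'                                 c_reservoir = 1000)), L = 4000)
#' @export
rt_environment <- function(attractants, L = 4000) {
  stopifnot(is.list(attractants), length(attractants) >= 1, L > 0)
  specs <- lapply(attractants, function(a) {
    bg <- if (is.null(a$background)) 0 else a$background
    list(name = a$name,
         base = a$c_entry + bg,
         slope = (a$c_reservoir - a$c_entry) / L)
  })
  structure(list(attractants = specs, L = L), class = "rt_environment")
}

#' Uniform-concentration environment (tracking assay)
#'
#' @param conc Named numeric vector of uniform concentrations (uM), one per
#'   attractant.
#' @return An `rt_environment` with zero gradients.
#' @export
rt_environment_uniform <- function(conc) {
  rt_environment(lapply(seq_along(conc), function(i)
    list(name = names(conc)[i] %||% paste0("attr", i),
         c_entry = conc[[i]], c_reservoir = conc[[i]])), L = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Concentration profile of an environment
#'
#' @param env An [rt_environment()].
#' @param x Positions (um).
#' @return Matrix of concentrations (uM), one column per attractant.
#' @export
env_concentration <- function(env, x) {
  stopifnot(inherits(env, "rt_environment"))
  sapply(env$attractants, function(a) pmax(0, a$base + a$slope * x))
}

#' Sensing model: per-attractant kernels and response scaling
#'
#' Attaches a bilobed [response_kernel()] to each attractant and selects how
#' the response amplitude depends on the background concentration:
#' * `"absolute"`: the filter input is the concentration itself and the
#'   amplitude is the kernel's `K0`;
#' * `"weber"`: the effective amplitude is rescaled by the local background,
#'   `K0_eff(c) = K0 * c_ref / (c + c_eps)`, the local linearization of a
#'   relative (Weber-type) response. Sensitivity then falls off as bacteria
#'   climb to higher concentrations.
#'
#' @param kernels A list of [response_kernel()], one per attractant of the
#'   environment (same order).
#' @param mode `"absolute"` or `"weber"`.
#' @param c_ref Weber reference concentration (uM).
#' @param c_eps Weber floor concentration (uM), keeps the gain finite at
#'   `c = 0`.
#' @param dc_comp Compensate the kernel's non-adapted steady component in the
#'   baseline run time: the local baseline is rescaled by
#'   `(1 - Q_ss(c))` with `Q_ss = K0_eff * A * c`, so that in a uniform
#'   medium the realized mean run time is exactly `tau_r * m(c)`. Use this
#'   whenever a [run_time_modulation()] encodes *measured* steady-state run
#'   times (which already include the kernel's steady component); keep it
#'   off when comparing raw-rate-law simulations against the closed-form
#'   chemotactic coefficient.
#' @return An object of class `sensing_model`.
#' @export
sensing_model <- function(kernels, mode = c("absolute", "weber"),
                          c_ref = 100, c_eps = 1, dc_comp = FALSE) {
  mode <- match.arg(mode)
  stopifnot(all(vapply(kernels, inherits, TRUE, "response_kernel")),
            c_ref > 0, c_eps > 0, is.logical(dc_comp))
  structure(list(kernels = kernels, mode = mode, c_ref = c_ref,
                 c_eps = c_eps, dc_comp = dc_comp), class = "sensing_model")
}

#' Concentration-dependent run-time modulation
#'
#' A piecewise log-linear curve `m(c)` of the normalized mean run time versus
#' the concentration of a driving attractant: the phenomenological signature
#' of imprecise adaptation (run times lengthen with background concentration,
#' as measured in homogeneous tracking assays). `m` is clamped at the end
#' anchors; `m = 1` everywhere corresponds to precise adaptation.
#'
#' @param conc Anchor concentrations (uM), strictly increasing, > 0.
#' @param m Normalized run times at the anchors (> 0).
#' @param driver Name of the driving attractant (matched against the
#'   environment), or `NA` for no modulation (`m == 1`).
#' @return An object of class `run_time_modulation`.
#' @examples
#' serine_mod <- run_time_modulation(c(1, 3000), c(1.0, 2.1), "serine")
#' modulation_eval(serine_mod, c(1, 30, 3000))
#' @export
run_time_modulation <- function(conc = 1, m = 1, driver = NA) {
  stopifnot(length(conc) == length(m), all(m > 0), all(conc > 0),
            !is.unsorted(conc, strictly = TRUE))
  structure(list(conc = conc, m = m, driver = driver),
            class = "run_time_modulation")
}

#' @rdname run_time_modulation
#' @param mod A `run_time_modulation`.
#' @param c_driver Concentrations of the driving attractant (uM).
#' @export
modulation_eval <- function(mod, c_driver) {
  stopifnot(inherits(mod, "run_time_modulation"))
  if (is.na(mod$driver)) return(rep(1, length(c_driver)))
  lc <- log(pmax(c_driver, .Machine$double.xmin))
  out <- approx(log(mod$conc), mod$m, xout = lc, rule = 2)$y
  out[c_driver <= 0] <- mod$m[1]
  out
}

#' Simulation configuration
#'
#' @param dt Time step (s). Must satisfy `dt <= 0.02 * min(tau_r, 1/lambda)`
#'   for all kernels (the exponential filter and the tumble draw assume the
#'   state barely changes per step).
#' @param T Duration (s).
#' @param n_agents Number of independent agents (tracking assays).
#' @param seed Integer seed; mandatory, simulations are bit-reproducible.
#' @param frame_dt Recording interval of track positions (s).
#' @param snapshot_dt Recording interval of race snapshots (s).
#' @param tumble_duration Tumble duration (s); 0 means instantaneous
#'   reorientation (the default; `alpha = (1 - <cos phi>)/tau_r` contains no
#'   tumble-time correction).
#' @param rate_cap Maximum tumble rate in units of `1/tau_loc`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.02, T = 60, n_agents = 100, seed = 1,
                       frame_dt = 0.1, snapshot_dt = 300,
                       tumble_duration = 0, rate_cap = 10) {
  stopifnot(dt > 0, T > 0, n_agents >= 0, frame_dt >= dt,
            snapshot_dt >= dt, tumble_duration >= 0, rate_cap > 0)
  structure(list(dt = dt, T = T, n_agents = as.integer(n_agents),
                 seed = as.integer(seed), frame_dt = frame_dt,
                 snapshot_dt = snapshot_dt,
                 tumble_duration = tumble_duration, rate_cap = rate_cap),
            class = "sim_config")
}

check_dt <- function(config, motility, sensing) {
  lam_min <- min(vapply(sensing$kernels, `[[`, 1, "lam"))
  lim <- 0.02 * min(motility$tau_r, 1 / lam_min)
  if (config$dt > lim + 1e-12)
    stop(sprintf("sim_config: dt = %g exceeds stability bound 0.02*min(tau_r, 1/lambda) = %g",
                 config$dt, lim))
  invisible(TRUE)
}

attr_matrix <- function(env, sensing) {
  na <- length(env$attractants)
  if (length(sensing$kernels) != na)
    stop("sensing_model: needs one kernel per attractant")
  m <- matrix(0, na, 8)
  for (i in seq_len(na)) {
    a <- env$attractants[[i]]
    k <- sensing$kernels[[i]]
    m[i, ] <- c(a$base, a$slope, k$K0, k$lam, k$A,
                as.numeric(sensing$mode == "weber"),
                sensing$c_ref, sensing$c_eps)
  }
  m
}

mod_list <- function(env, modulation) {
  if (is.null(modulation) || is.na(modulation$driver))
    return(list(driver = -1L, logc = 0, m = 1))
  nm <- vapply(env$attractants, `[[`, "", "name")
  i <- match(modulation$driver, nm)
  if (is.na(i))
    stop(sprintf("run_time_modulation: driver '%s' not among attractants (%s)",
                 modulation$driver, paste(nm, collapse = ", ")))
  list(driver = i - 1L, logc = log(modulation$conc), m = modulation$m)
}

stride_of <- function(interval, dt, what) {
  s <- round(interval / dt)
  if (abs(s * dt - interval) > 1e-9)
    stop(sprintf("%s (%g s) must be a multiple of dt (%g s)", what, interval, dt))
  as.integer(s)
}

#' Instantaneous tumble rate
#'
#' The rate law coupling the sensing state to the motor:
#' `rate = clip((1 - Q) / tau_loc, 0, cap / tau_loc)` where `Q` is the kernel
#' convolution state and `tau_loc = tau_r * m(c)` the locally modulated
#' baseline run time. A positive `Q` (recent up-gradient motion) lengthens
#' runs; the rate is clipped at zero and capped to prevent pathological
#' tumbling bursts.
#'
#' @param Q Convolution state (dimensionless).
#' @param tau_loc Local mean run time (s).
#' @param cap Cap in units of `1/tau_loc`.
#' @return Tumble rate (1/s).
#' @export
tumble_rate <- function(Q, tau_loc, cap = 10) {
  stopifnot(all(tau_loc > 0))
  pmin(pmax((1 - Q) / tau_loc, 0), cap / tau_loc)
}

#' Kernel convolution state for a concentration time series
#'
#' Runs the exact 3-state exponential-filter recursion used inside the
#' simulator on a piecewise-constant concentration series and returns
#' `Q(t) = K0 * integral K-hat(s) c(t - s) ds`. In a constant concentration
#' `c` the state converges to `K0 * A * c` (the kernel integral times the
#' concentration).
#'
#' @param kernel A [response_kernel()].
#' @param conc Concentration series (uM), one value per step.
#' @param dt Step (s).
#' @return Vector `Q` after each step.
#' @export
kernel_filter_response <- function(kernel, conc, dt) {
  stopifnot(inherits(kernel, "response_kernel"), dt > 0)
  .rt_filter_cpp(as.numeric(conc), dt, kernel$K0, kernel$lam, kernel$A)
}

#' Simulate free run-and-tumble trajectories
#'
#' Runs `n_agents` independent agents starting at the origin in an unbounded
#' medium with the given attractant environment, sensing model and run-time
#' modulation, and records positions at the configured frame rate. With
#' `record_runs = TRUE` the completed run durations (first, time-censored run
#' of each agent excluded) and the tumble-angle cosines are attached.
#'
#' @param config A [sim_config()].
#' @param env An [rt_environment()].
#' @param sensing A [sensing_model()].
#' @param modulation A [run_time_modulation()] or `NULL`.
#' @param motility A [motility_params()]. `mean_cos_phi` must be below 1/3
#'   (the linear-tilt tumble-angle density cannot produce a larger mean).
#' @param planar Confine swimming to the x-y plane (near-surface swimming as
#'   imaged by 2-D tracking assays): tumble angles follow the same cosine law
#'   with a random sign and the angular diffusion rate is set so the
#'   direction correlation decays at the same `exp(-2 D_rot t)` as in 3-D.
#' @param u_sd Population SD of the per-bacterium running speed (um/s);
#'   per-track speeds are drawn from `Normal(u, u_sd)` truncated at 2 um/s.
#'   0 (the default) keeps all agents at `u`.
#' @param record_runs Attach ground-truth run/tumble event logs.
#' @return A `data.frame` (class `track_table`) with columns `track_id`, `t`,
#'   `x`, `y`, `z`; attributes `meta` (frame interval, motility, seed) and,
#'   if requested, `runs` and `tumble_cos`.
#' @export
simulate_tracks <- function(config, env, sensing, modulation = NULL,
                            motility = motility_params(),
                            planar = FALSE, u_sd = 0, record_runs = FALSE) {
  stopifnot(inherits(config, "sim_config"), inherits(env, "rt_environment"),
            inherits(sensing, "sensing_model"),
            inherits(motility, "motility_params"))
  check_dt(config, motility, sensing)
  b <- 3 * motility$mean_cos_phi
  if (abs(b) > 1)
    stop("simulate_tracks: |mean_cos_phi| must be <= 1/3 for the linear-tilt tumble density")
  stride <- stride_of(config$frame_dt, config$dt, "frame_dt")
  set.seed(config$seed)
  raw <- .rt_tracks_cpp(config$n_agents, config$T, config$dt, stride,
                        motility$u, u_sd, motility$tau_r, motility$D_rot, b,
                        config$tumble_duration, config$rate_cap,
                        attr_matrix(env, sensing), mod_list(env, modulation),
                        isTRUE(sensing$dc_comp), planar, record_runs)
  out <- data.frame(track_id = raw$track_id, t = raw$t,
                    x = raw$x, y = raw$y, z = raw$z)
  attr(out, "meta") <- list(frame_dt = config$frame_dt, dt = config$dt,
                            seed = config$seed, motility = motility,
                            projected = FALSE, planar = planar, noise_sd = 0)
  attr(out, "agent_u") <- raw$agent_u
  if (record_runs) {
    attr(out, "runs") <- data.frame(track_id = raw$run_agent,
                                    duration = raw$run_durations)
    attr(out, "tumble_cos") <- raw$tumble_cos
  }
  class(out) <- c("track_table", "data.frame")
  out
}

#' Channel geometry of the race assay
#'
#' @param L Channel length (um); default 4000.
#' @param width Channel width (um); default 725.
#' @param height Channel height (um); default 300.
#' @return An object of class `channel_geometry`.
#' @export
channel_geometry <- function(L = 4000, width = 725, height = 300) {
  stopifnot(L > 0, width > 0, height > 0)
  structure(list(L = L, width = width, height = height),
            class = "channel_geometry")
}

#' Simulate a bacterial speed race in a gradient channel
#'
#' Agents are injected at the entry face (`x = 0`) by a Poisson source whose
#' rate is calibrated to the maintained density of the injection channel
#' (one-way kinetic flux `n0 * u / 4` through the entry cross-section), carry
#' the sensing filter initialized at the entry concentration, swim in the
#' channel with reflecting side walls, and are removed (and counted) when
#' they reach the reservoir (`x >= L`, absorbing on the experimental
#' timescale) or wander back into the injection channel (`x < 0`). In-channel
#' positions are recorded every `snapshot_dt`.
#'
#' @inheritParams simulate_tracks
#' @param channel A [channel_geometry()].
#' @param entry_density Maintained number density at the entry
#'   (bacteria/um^3); default `4e-5`, i.e. 4e7 bacteria/ml.
#' @param inject_rate Poisson injection rate (agents/s); overrides the
#'   kinetic-flux calibration if given.
#' @return A `data.frame` (class `snapshot_series`) with columns `t`, `x`,
#'   `y`; attributes `meta` (geometry, seed) and `counts` (injected,
#'   absorbed, returned, remaining; these conserve the total).
#' @export
simulate_race <- function(config, channel, env, sensing, modulation = NULL,
                          motility = motility_params(),
                          entry_density = 4e-5, inject_rate = NULL) {
  stopifnot(inherits(config, "sim_config"),
            inherits(channel, "channel_geometry"),
            inherits(env, "rt_environment"),
            inherits(sensing, "sensing_model"),
            inherits(motility, "motility_params"))
  check_dt(config, motility, sensing)
  b <- 3 * motility$mean_cos_phi
  if (abs(b) > 1)
    stop("simulate_race: |mean_cos_phi| must be <= 1/3 for the linear-tilt tumble density")
  stride <- stride_of(config$snapshot_dt, config$dt, "snapshot_dt")
  if (is.null(inject_rate))
    inject_rate <- entry_density * channel$width * channel$height *
      motility$u / 4
  set.seed(config$seed)
  raw <- .rt_race_cpp(config$T, config$dt, stride,
                      channel$L, channel$width, channel$height, inject_rate,
                      motility$u, motility$tau_r, motility$D_rot, b,
                      config$tumble_duration, config$rate_cap,
                      attr_matrix(env, sensing), mod_list(env, modulation),
                      isTRUE(sensing$dc_comp))
  out <- data.frame(t = raw$t, x = raw$x, y = raw$y)
  attr(out, "meta") <- list(channel = channel, seed = config$seed,
                            snapshot_dt = config$snapshot_dt,
                            inject_rate = inject_rate)
  attr(out, "counts") <- c(injected = raw$injected, absorbed = raw$absorbed,
                           returned = raw$returned, remaining = raw$remaining)
  class(out) <- c("snapshot_series", "data.frame")
  out
}

#' Mean drift velocity of an ensemble of tracks
#'
#' Per-track net displacement along `x` divided by the track duration,
#' averaged over tracks.
#'
#' @param tracks A `track_table`.
#' @return List with `v` (um/s), `se`, and `n`.
#' @export
measure_drift_velocity <- function(tracks) {
  stopifnot(is.data.frame(tracks), all(c("track_id", "t", "x") %in% names(tracks)))
  per <- vapply(split(tracks, tracks$track_id), function(d) {
    n <- nrow(d)
    (d$x[n] - d$x[1]) / (d$t[n] - d$t[1])
  }, numeric(1))
  list(v = mean(per), se = sd(per) / sqrt(length(per)), n = length(per))
}

#' Monte-Carlo drift versus linear-response theory
#'
#' Simulates an ensemble in a shallow linear gradient (absolute sensing, no
#' run-time modulation), measures the mean drift velocity and compares it to
#' the closed-form prediction `v = chi * dc/dx`. The gradient must be shallow
#' enough that the response stays linear; a rough linearity metric
#' `K0 * gradient * u / lambda` is reported and a warning is attached when it
#' exceeds 0.2.
#'
#' @param motility A [motility_params()].
#' @param kernel A [response_kernel()].
#' @param gradient Concentration gradient (uM/um).
#' @param c0 Concentration at the starting position (uM); keep it large
#'   enough that agents never see the clipped-at-zero region.
#' @param n_agents,T,seed Ensemble size, duration (s), seed.
#' @param dt Time step (s).
#' @return List with `v_mc`, `se`, `v_theory`, `z` (the discrepancy in
#'   standard errors), `linearity` and `warning`.
#' @export
validate_against_theory <- function(motility, kernel, gradient,
                                    c0 = 50, n_agents = 2000, T = 200,
                                    seed = 1, dt = NULL) {
  stopifnot(inherits(motility, "motility_params"),
            inherits(kernel, "response_kernel"))
  if (is.null(dt)) dt <- 0.02 * min(motility$tau_r, 1 / kernel$lam)
  env <- rt_environment(list(list(name = "attr", c_entry = c0,
                                  c_reservoir = c0 + gradient)), L = 1)
  sens <- sensing_model(list(kernel), mode = "absolute")
  cfg <- sim_config(dt = dt, T = T, n_agents = n_agents, seed = seed,
                    frame_dt = max(dt, round(T / 50 / dt) * dt))
  tr <- simulate_tracks(cfg, env, sens, modulation = NULL,
                        motility = motility)
  dv <- measure_drift_velocity(tr)
  v_th <- chemotactic_coefficient_closed(motility, kernel) * gradient
  lin <- max(abs(kernel$K0 * gradient * motility$u / kernel$lam),
             abs(kernel$K0 * kernel$A * c0))
  warn <- if (lin > 0.2)
    sprintf("linearity metric %.3g > 0.2: response too strong for linear theory", lin)
  else NULL
  z <- if (dv$se > 0) abs(dv$v - v_th) / dv$se else NA_real_
  list(v_mc = dv$v, se = dv$se, v_theory = v_th, z = z,
       linearity = lin, warning = warn)
}
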