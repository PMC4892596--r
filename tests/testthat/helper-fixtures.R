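# Constructed-track fixtures used across test files.

# A straight constant-velocity planar track.
straight_track <- function(n = 60, u = 15, dt = 0.1, angle = 0) {
  t <- seq(0, by = dt, length.out = n)
  data.frame(track_id = 1L, t = t,
             x = u * t * cos(angle), y = u * t * sin(angle))
}

# Alternating exponential runs and fixed-duration stops, sampled at frame_dt,
# with optional localization noise: the oracle generator for the run-time
# estimator (independent of the C++ simulator).
rt_oracle_track <- function(tau, u = 15, stop_dur = 0.3, T = 120,
                            frame_dt = 0.1, noise_sd = 0, track_id = 1L) {
  t <- 0; ang <- runif(1, 0, 2 * pi); pos <- c(0, 0)
  events <- list()  # (t_start, t_end, angle or NA for stop)
  while (t < T) {
    run <- rexp(1, 1 / tau)
    events[[length(events) + 1]] <- c(t, min(t + run, T), ang)
    t <- t + run
    if (t >= T) break
    events[[length(events) + 1]] <- c(t, min(t + stop_dur, T), NA)
    t <- t + stop_dur
    ang <- ang + sample(c(-1, 1), 1) * runif(1, pi / 3, pi)  # large turns
  }
  frames <- seq(0, T, by = frame_dt)
  xy <- matrix(0, length(frames), 2)
  pos <- c(0, 0); ei <- 1
  for (i in seq_along(frames)[-1]) {
    t0 <- frames[i - 1]; t1 <- frames[i]
    # advance through events overlapping [t0, t1]
    dtv <- c(0, 0)
    for (e in events) {
      ov <- max(0, min(e[2], t1) - max(e[1], t0))
      if (ov > 0 && !is.na(e[3]))
        dtv <- dtv + u * ov * c(cos(e[3]), sin(e[3]))
    }
    pos <- pos + dtv
    xy[i, ] <- pos
  }
  data.frame(track_id = track_id, t = frames,
             x = xy[, 1] + rnorm(length(frames), 0, noise_sd),
             y = xy[, 2] + rnorm(length(frames), 0, noise_sd))
}

default_uniform_env <- function(conc = 0) {
  rt_environment_uniform(list(attr = conc))
}

null_sensing <- function() sensing_model(list(response_kernel(0, 1, 0)))
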