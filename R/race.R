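#' Progression function of a snapshot
#'
#' `N(x, t)`: the number of in-channel bacteria located between position `x`
#' and the reservoir end, i.e. the survival-type cumulative count
#' `#{positions >= x}`, evaluated on a position grid for every snapshot time.
#'
#' @param snapshots A `snapshot_series` (columns `t`, `x`) or any data frame
#'   with those columns.
#' @param x_grid Position grid (um); default every 25 um over the channel.
#' @param L Channel length (um), used for the default grid.
#' @return A data frame (class `progression_curve`) in long format with
#'   columns `t`, `x`, `N`.
#' @export
progression_function <- function(snapshots, x_grid = NULL, L = 4000) {
  stopifnot(is.data.frame(snapshots), all(c("t", "x") %in% names(snapshots)))
  if (is.null(x_grid)) x_grid <- seq(0, L, by = 25)
  times <- sort(unique(snapshots$t))
  out <- do.call(rbind, c(list(
    data.frame(t = numeric(0), x = numeric(0), N = numeric(0))),
    lapply(times, function(tt) {
      pos <- snapshots$x[snapshots$t == tt]
      data.frame(t = tt, x = x_grid,
                 N = vapply(x_grid, function(g) sum(pos >= g), numeric(1)))
    })))
  rownames(out) <- NULL
  class(out) <- c("progression_curve", "data.frame")
  out
}

#' Position of the k-th most advanced bacterium
#'
#' The k-th largest position in a single snapshot. Ties share the value
#' (positions are sorted descending, stable; no jitter). `NA` when fewer
#' than `k` bacteria are present.
#'
#' @param positions Numeric vector of in-channel positions (um).
#' @param k Rank, a positive integer.
#' @return Position (um) or `NA`.
#' @examples
#' front_position(c(100, 400, 250), 1)  # 400
#' front_position(c(100, 400, 250), 3)  # 100
#' @export
front_position <- function(positions, k) {
  if (!(is.numeric(k) && length(k) == 1 && k >= 1 && k == round(k)))
    stop("front_position: k must be a positive integer")
  if (length(positions) < k) return(NA_real_)
  sort(positions, decreasing = TRUE)[k]
}

#' Rank-k front trajectory of a snapshot series
#'
#' Tracks the position of the k-th most advanced bacterium over time.
#' Undefined (NA) while the channel holds fewer than `k` bacteria; once
#' advanced bacteria are absorbed into the reservoir the rank window shifts
#' backward and the trajectory plateaus.
#'
#' @param snapshots A `snapshot_series`.
#' @param k Rank.
#' @return Data frame (class `front_trajectory`) with `t`, `k`, `x_k`.
#' @export
front_trajectory <- function(snapshots, k) {
  stopifnot(is.data.frame(snapshots), all(c("t", "x") %in% names(snapshots)))
  times <- sort(unique(snapshots$t))
  out <- data.frame(t = times, k = k,
                    x_k = vapply(times, function(tt)
                      front_position(snapshots$x[snapshots$t == tt], k),
                      numeric(1)))
  class(out) <- c("front_trajectory", "data.frame")
  out
}

#' Early-window slope of a front trajectory
#'
#' Ordinary least squares of `x_k` versus `t` restricted to the fit window
#' (default the first 30 minutes, where the progression is approximately
#' linear) and to times where the front is defined.
#'
#' @param traj A `front_trajectory` (or data frame with `t`, `x_k`).
#' @param window Two-element window `[t_min, t_max]` (s).
#' @return List with `slope` (um/s), `se`, `n` (points), `window`.
#' @export
fit_front_slope <- function(traj, window = c(0, 1800)) {
  stopifnot(all(c("t", "x_k") %in% names(traj)), length(window) == 2)
  d <- traj[traj$t >= window[1] & traj$t <= window[2] & !is.na(traj$x_k), ]
  if (nrow(d) < 2)
    return(list(slope = NA_real_, se = NA_real_, n = nrow(d), window = window))
  fit <- lm(x_k ~ t, data = d)
  s <- suppressWarnings(summary(fit))$coefficients
  se <- if (nrow(s) >= 2 && !is.nan(s["t", "Std. Error"])) s["t", "Std. Error"] else 0
  list(slope = unname(coef(fit)["t"]), se = unname(se), n = nrow(d),
       window = window)
}

#' Replicate mean with standard error
#'
#' Averages front trajectories (or progression curves) across replicate
#' experiments, per time (and grid) point; the error is the standard error
#' of the mean over replicates. `NA` values (undefined fronts) are dropped
#' pointwise; the SEM is `NA` when only one replicate contributes.
#'
#' @param reps A list of data frames with identical `t` (and `x`) columns
#'   and a value column (`x_k` or `N`).
#' @param value Name of the value column; guessed from the first element.
#' @return Data frame with the key columns plus `mean`, `sem`, `n_rep`.
#' @export
replicate_mean <- function(reps, value = NULL) {
  stopifnot(is.list(reps), length(reps) >= 1)
  if (is.null(value))
    value <- if ("x_k" %in% names(reps[[1]])) "x_k" else "N"
  keys <- intersect(c("t", "k", "x"), names(reps[[1]]))
  all <- do.call(rbind, lapply(seq_along(reps), function(i) {
    d <- reps[[i]][, c(keys, value)]
    d$`.rep` <- i
    d
  }))
  sp <- split(all, all[, keys, drop = FALSE], drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    v <- d[[value]][!is.na(d[[value]])]
    n <- length(v)
    cbind(d[1, keys, drop = FALSE],
          data.frame(mean = if (n) mean(v) else NA_real_,
                     sem = if (n > 1) sd(v) / sqrt(n) else NA_real_,
                     n_rep = n))
  }))
  out <- out[order(out$t), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect front saturation
#'
#' Compares the front slope in a late window to the early-window slope; the
#' trajectory is flagged saturated when the late slope falls below
#' `ratio_threshold` times the early one (absorption into the reservoir
#' balancing injection).
#'
#' @param traj A `front_trajectory`.
#' @param early_window,late_window Fit windows (s).
#' @param ratio_threshold Saturation threshold on the slope ratio.
#' @return List with `saturated` (flag), `ratio`, `early`, `late` (slope
#'   fits).
#' @export
saturation_check <- function(traj, early_window = c(0, 1800),
                             late_window = NULL, ratio_threshold = 0.2) {
  if (is.null(late_window)) {
    tmax <- max(traj$t)
    late_window <- c(tmax - (early_window[2] - early_window[1]), tmax)
  }
  early <- fit_front_slope(traj, early_window)
  late <- fit_front_slope(traj, late_window)
  ratio <- late$slope / early$slope
  list(saturated = isTRUE(ratio < ratio_threshold), ratio = ratio,
       early = early, late = late)
}
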