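# First-derivative-adaptation statistics on neural traces, pulse-derivative
# correlations, and trajectory analytics (angular deviation, reversals).

#' Mean activity before vs after the point of maximal first derivative
#'
#' Normalizes the trace to \[0, 1\], locates t* = argmax of the stimulus
#' first derivative, and averages activity over the `window` seconds before
#' and after t* (the midpoint sample itself is excluded from both windows).
#' A neuron that merely follows the instantaneous derivative gives equal
#' means for a symmetric sigmoid; adaptation to the derivative depresses the
#' "after" mean.
#'
#' @param trace A [calcium_trace()] sharing the stimulus time base.
#' @param stimulus A [stimulus_profile()] with `d1` available (filled with
#'   [finite_derivatives()] otherwise).
#' @param window Half-window in seconds (default 150, i.e. 2.5 min).
#' @return Named numeric vector `c(before = , after = )`.
#' @export
pre_post_midpoint_means <- function(trace, stimulus, window = 150) {
  d1 <- stimulus$d1
  if (is.null(d1)) d1 <- finite_derivatives(stimulus)$d1
  t_star <- stimulus$time_s[which.max(d1)]
  v <- normalize_trace(trace$values)
  tt <- trace$times
  before <- tt >= t_star - window & tt < t_star
  after <- tt > t_star & tt <= t_star + window
  expected <- window / trace_dt(trace)
  if (sum(before) < 0.5 * expected || sum(after) < 0.5 * expected)
    stop("window extends beyond the trace: <50% coverage on one side")
  if (sum(before) < 0.95 * expected || sum(after) < 0.95 * expected)
    warning("window truncated at the trace boundary")
  c(before = mean(v[before]), after = mean(v[after]))
}

#' Wilcoxon tests with a fixed exact-versus-approximate policy
#'
#' Thin wrapper around [stats::wilcox.test()] exposing the two designs used
#' here: the paired signed-rank test and the independent rank-sum test. The
#' exact null distribution is enumerated for small samples (n <= 25 effective
#' pairs, or both groups <= 25) when there are no ties; otherwise the normal
#' approximation with continuity correction is used. Zero differences are
#' dropped (Wilcoxon's convention); if all differences are zero the test is
#' undefined and an error is raised.
#'
#' @param a,b Numeric samples; equal length for the paired mode.
#' @param mode `"signed_rank_paired"` or `"rank_sum_independent"`.
#' @param side Alternative: `"two.sided"`, `"greater"` (a > b) or `"less"`.
#' @return List with `statistic`, `p_value`, `method`, `n_effective`.
#' @export
wilcoxon_test <- function(a, b,
                          mode = c("signed_rank_paired",
                                   "rank_sum_independent"),
                          side = c("two.sided", "greater", "less")) {
  mode <- match.arg(mode)
  side <- match.arg(side)
  if (mode == "signed_rank_paired") {
    if (length(a) != length(b)) stop("paired samples must have equal length")
    d <- a - b
    nz <- d[d != 0]
    if (!length(nz)) stop("all paired differences are zero; test undefined")
    exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, paired = TRUE, alternative = side,
                         exact = exact, correct = TRUE))
    n_eff <- length(nz)
  } else {
    exact <- length(a) <= 25 && length(b) <= 25 &&
      !any(duplicated(c(a, b)))
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = side,
                         exact = exact, correct = TRUE))
    n_eff <- length(a) + length(b)
  }
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = wt$method, n_effective = n_eff)
}

#' Correlation between pulse properties and the stimulus first derivative
#'
#' Pools per-worm normalized pulse amplitudes (or peak-to-peak intervals,
#' see [pulse_metrics()]) and correlates them with the stimulus first
#' derivative evaluated at each pulse peak time.
#'
#' @param pulses Pulse table (with `worm_id`, `peak_time_s`, `amplitude`,
#'   `interval_s`).
#' @param stimulus A [stimulus_profile()] with `d1`.
#' @param quantity `"amplitude"` or `"interval"`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `r`, `p_value`, `n`.
#' @export
pulse_derivative_correlation <- function(pulses, stimulus,
                                         quantity = c("amplitude", "interval"),
                                         method = c("pearson", "spearman")) {
  quantity <- match.arg(quantity)
  method <- match.arg(method)
  d1 <- stimulus$d1
  if (is.null(d1)) d1 <- finite_derivatives(stimulus)$d1
  m <- pulse_metrics(pulses)
  y <- if (quantity == "amplitude") m$norm_amplitude else m$norm_interval
  x <- stats::approx(stimulus$time_s, d1, xout = m$peak_time_s, rule = 2)$y
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("need at least 3 pulses with defined values")
  ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = method))
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Timestamped 2D trajectory with a target coordinate
#'
#' @param times Times in seconds, strictly increasing.
#' @param x,y Coordinates in mm (or simulation step-lengths).
#' @param target Length-2 target (source) coordinate.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(times, x, y, target) {
  stopifnot(length(times) == length(x), length(x) == length(y),
            length(target) == 2)
  if (any(!is.finite(c(x, y, times)))) stop("non-finite trajectory samples")
  if (any(diff(times) <= 0)) stop("duplicate or decreasing timestamps")
  structure(list(times = times, x = x, y = y,
                 target = as.numeric(target)),
            class = "trajectory")
}

#' Smooth a trajectory with a penalized regression spline
#'
#' Each coordinate is smoothed against time with a cubic smoothing spline
#' (least squares with a roughness penalty). `roughness = "auto"` selects the
#' penalty by generalized cross-validation; `roughness = 0` returns the
#' interpolating (unchanged) track; large values approach the straight
#' least-squares line.
#'
#' @param traj A [trajectory()] with at least 4 points.
#' @param roughness `"auto"`, or a non-negative spline penalty `lambda`.
#' @return The smoothed [trajectory()].
#' @export
smooth_track <- function(traj, roughness = "auto") {
  n <- length(traj$times)
  if (n < 4) stop("need at least 4 points to smooth")
  if (identical(roughness, 0)) return(traj)
  fit1 <- function(v) {
    if (identical(roughness, "auto"))
      sp <- stats::smooth.spline(traj$times, v, cv = FALSE)
    else
      sp <- stats::smooth.spline(traj$times, v, lambda = roughness)
    stats::predict(sp, traj$times)$y
  }
  trajectory(traj$times, fit1(traj$x), fit1(traj$y), traj$target)
}

#' Angular deviation between motion and the direct path to the target
#'
#' The angle, in degrees, between the (central-difference) velocity vector
#' and the unit vector from the current position to the target. 0 means the
#' animal heads straight at the target; ~180 means it moves directly away;
#' an abrupt increase marks a reversal.
#'
#' @param traj A (preferably smoothed) [trajectory()].
#' @return Data frame `time_s`, `deviation_deg` (NA where the velocity or the
#'   offset to the target vanishes), class `deviation_series`.
#' @export
angular_deviation <- function(traj) {
  n <- length(traj$times)
  stopifnot(n >= 2)
  tt <- traj$times
  vx <- c(traj$x[2] - traj$x[1],
          (traj$x[3:n] - traj$x[1:(n - 2)]),
          traj$x[n] - traj$x[n - 1]) /
    c(tt[2] - tt[1], tt[3:n] - tt[1:(n - 2)], tt[n] - tt[n - 1])
  vy <- c(traj$y[2] - traj$y[1],
          (traj$y[3:n] - traj$y[1:(n - 2)]),
          traj$y[n] - traj$y[n - 1]) /
    c(tt[2] - tt[1], tt[3:n] - tt[1:(n - 2)], tt[n] - tt[n - 1])
  dx <- traj$target[1] - traj$x
  dy <- traj$target[2] - traj$y
  nv <- sqrt(vx^2 + vy^2)
  nd <- sqrt(dx^2 + dy^2)
  cosang <- (vx * dx + vy * dy) / (nv * nd)
  dev <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  dev[nv == 0 | nd == 0] <- NA_real_
  out <- data.frame(time_s = tt, deviation_deg = dev)
  class(out) <- c("deviation_series", "data.frame")
  out
}

#' Detect reversal events as abrupt increases in angular deviation
#'
#' An event is declared at any sample whose deviation exceeds, by at least
#' `jump` degrees, some earlier sample within `horizon` seconds. Consecutive
#' event samples closer than `horizon` are merged into one event, timed at
#' the first sample of the cluster.
#'
#' @param dev A `deviation_series` from [angular_deviation()].
#' @param jump Minimum increase in degrees (default 90).
#' @param horizon Look-back window and merge distance in seconds (default 1).
#' @return Numeric vector of event times (possibly empty).
#' @export
detect_reversals <- function(dev, jump = 90, horizon = 1) {
  tt <- dev$time_s
  v <- dev$deviation_deg
  n <- length(v)
  hits <- logical(n)
  for (j in seq_len(n)) {
    if (is.na(v[j])) next
    back <- which(tt >= tt[j] - horizon & tt < tt[j])
    if (!length(back)) next
    prior <- v[back]
    prior <- prior[!is.na(prior)]
    if (length(prior) && v[j] - min(prior) >= jump) hits[j] <- TRUE
  }
  ev <- tt[hits]
  if (length(ev) < 2) return(ev)
  # merge chains: an event opens a cluster only if it is >= horizon after the
  # previously kept event
  out <- numeric(0)
  last <- -Inf
  for (e in ev) {
    if (e - last >= horizon) {
      out <- c(out, e)
      last <- e
    }
  }
  out
}

#' Relate reversal events to the phase of calcium pulses
#'
#' Splits each pulse at its peak and reports, per pulse, the maximal angular
#' deviation during the rising (first) and decaying (second) half, and, per
#' reversal event, which pulse and half it falls in (an event exactly at the
#' peak belongs to the second half) together with the activity level at the
#' event as a fraction of that pulse's peak. Events outside every pulse are
#' labeled `"between-pulse"`.
#'
#' @param trace A [calcium_trace()] aligned with the trajectory time base.
#' @param dev A `deviation_series` from [angular_deviation()].
#' @param events Reversal times from [detect_reversals()].
#' @param pulses Pulse table with `onset_time_s`, `peak_time_s`, `end_time_s`.
#' @return List with `halves` (per pulse: `max_dev_first`, `max_dev_second`)
#'   and `events` (per event: `time_s`, `pulse`, `phase`,
#'   `activity_fraction`).
#' @export
pulse_phase_of_reversals <- function(trace, dev, events, pulses) {
  v <- normalize_trace(trace$values)
  halves <- do.call(rbind, lapply(seq_len(nrow(pulses)), function(k) {
    on <- pulses$onset_time_s[k]
    pk <- pulses$peak_time_s[k]
    en <- pulses$end_time_s[k]
    in1 <- dev$time_s >= on & dev$time_s < pk
    in2 <- dev$time_s >= pk & dev$time_s <= en
    mx <- function(sel) {
      d <- dev$deviation_deg[sel]
      d <- d[!is.na(d)]
      if (length(d)) max(d) else NA_real_
    }
    data.frame(pulse = k, max_dev_first = mx(in1), max_dev_second = mx(in2))
  }))
  if (is.null(halves))
    halves <- data.frame(pulse = integer(0), max_dev_first = numeric(0),
                         max_dev_second = numeric(0))
  ne <- length(events)
  ev <- data.frame(time_s = as.numeric(events),
                   pulse = rep(NA_integer_, ne),
                   phase = rep("between-pulse", ne),
                   activity_fraction = rep(NA_real_, ne),
                   stringsAsFactors = FALSE)
  if (nrow(ev) && nrow(pulses)) {
    for (i in seq_len(nrow(ev))) {
      te <- ev$time_s[i]
      k <- which(pulses$onset_time_s <= te & te <= pulses$end_time_s)
      if (!length(k)) next
      k <- k[1]
      ev$pulse[i] <- k
      ev$phase[i] <- if (te >= pulses$peak_time_s[k]) "second" else "first"
      act <- stats::approx(trace$times, v, xout = te, rule = 2)$y
      peak_act <- stats::approx(trace$times, v,
                                xout = pulses$peak_time_s[k], rule = 2)$y
      ev$activity_fraction[i] <- if (peak_act > 0) act / peak_act else NA_real_
    }
  }
  list(halves = halves, events = ev)
}
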