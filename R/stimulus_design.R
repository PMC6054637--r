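# Smooth-gradient stimulus design: target profiles, the stirred mixing-chamber
# model, and inversion of the model into pump (stimulus-fraction) schedules.

#' Specification of the stirred mixing chamber
#'
#' Describes the well-stirred compartment that two syringe pumps feed: a
#' stimulus line at concentration `stim_conc` and a buffer line at
#' `buffer_conc`, mixed at constant total flow `total_flow` inside a chamber of
#' volume `volume`. The chamber dilutes its inflow with first-order kinetics
#' dC/dt = (Q/V) (C_in - C), which is what makes arbitrary smooth gradients
#' designable by modulating the stimulus fraction of the inflow.
#'
#' @param volume Chamber volume in microliters (typically 50 or 200).
#' @param total_flow Combined pump flow in microliters per minute.
#' @param stim_conc Stimulus-syringe concentration in micromolar.
#' @param buffer_conc Buffer-syringe concentration in micromolar
#'   (a small non-zero basal level is common; default 0).
#' @return An object of class `chamber_spec`.
#' @examples
#' chamber_spec(volume = 50, total_flow = 500, stim_conc = 1150, buffer_conc = 0.12)
#' @export
chamber_spec <- function(volume, total_flow, stim_conc, buffer_conc = 0) {
  stopifnot(is.numeric(volume), is.numeric(total_flow),
            is.numeric(stim_conc), is.numeric(buffer_conc))
  if (volume <= 0) stop("`volume` must be positive")
  if (total_flow <= 0) stop("`total_flow` must be positive")
  if (buffer_conc < 0) stop("`buffer_conc` must be non-negative")
  if (stim_conc <= buffer_conc) stop("`stim_conc` must exceed `buffer_conc`")
  structure(list(volume = volume, total_flow = total_flow,
                 stim_conc = stim_conc, buffer_conc = buffer_conc),
            class = "chamber_spec")
}

# Dilution rate constant in 1/s (flow is per minute, times are in seconds).
chamber_rate <- function(chamber) chamber$total_flow / chamber$volume / 60

check_uniform_grid <- function(times, what = "times") {
  if (length(times) < 2) stop("`", what, "` needs at least two samples")
  dt <- diff(times)
  if (any(dt <= 0)) stop("`", what, "` must be strictly increasing")
  if (any(abs(dt - dt[1]) > 1e-6 * dt[1]))
    stop("`", what, "` must lie on a uniform grid")
  dt[1]
}

#' Time course of a sensed concentration and its derivatives
#'
#' @param times Time grid in seconds; strictly increasing, uniform step.
#' @param conc Concentration in micromolar at each time point; non-negative.
#' @param d1,d2 Optional first/second temporal derivatives (uM/s, uM/s^2).
#' @return A data frame with columns `time_s`, `conc_uM` and optionally
#'   `d1`, `d2`, of class `stimulus_profile`.
#' @export
stimulus_profile <- function(times, conc, d1 = NULL, d2 = NULL) {
  stopifnot(is.numeric(times), is.numeric(conc))
  if (length(times) != length(conc))
    stop("`times` and `conc` must have equal length")
  check_uniform_grid(times)
  if (any(!is.finite(conc))) stop("`conc` must be finite")
  if (any(conc < -1e-9 * max(abs(conc), 1)))
    stop("concentrations must be non-negative everywhere")
  out <- data.frame(time_s = times, conc_uM = pmax(conc, 0))
  if (!is.null(d1)) {
    stopifnot(length(d1) == length(times))
    out$d1 <- d1
  }
  if (!is.null(d2)) {
    stopifnot(length(d2) == length(times))
    out$d2 <- d2
  }
  class(out) <- c("stimulus_profile", "data.frame")
  out
}

profile_dt <- function(profile) check_uniform_grid(profile$time_s)

pget <- function(params, name, default = NULL) {
  if (!is.null(params[[name]])) return(params[[name]])
  if (is.null(default)) stop("missing required parameter `", name, "`")
  default
}

#' Generate an analytic stimulus profile
#'
#' Builds the gradient shapes used throughout: on-steps, linear ramps,
#' hyperbolic-tangent sigmoids, sinusoids, and a ramp whose first derivative
#' grows exponentially. Analytic first and second derivatives are attached.
#'
#' Shape parameters by `kind` (all concentrations uM, times s):
#' * `step`: `baseline` (default 0), `height`, `t0`.
#' * `linear`: `baseline` (default 0), `slope` (uM/s).
#' * `tanh`: `baseline` (default 0), `amplitude`, `midpoint`, `steepness`
#'   (1/s): conc = baseline + amplitude (1 + tanh(k (t - t_m))) / 2.
#' * `sinusoid`: `baseline`, `amplitude`, `period`, `phase` (default 0);
#'   requires baseline >= amplitude so concentrations stay non-negative.
#' * `exp_derivative`: `baseline` (default 0), `C0`, `tau_growth`:
#'   conc = baseline + C0 (exp(t/tau_growth) - 1), so d1 grows exponentially.
#'
#' @param kind One of `"step"`, `"linear"`, `"tanh"`, `"sinusoid"`,
#'   `"exp_derivative"`.
#' @param params Named list of shape parameters, see Details.
#' @param times Uniform time grid in seconds.
#' @return A [stimulus_profile()] with `d1` and `d2` filled analytically.
#' @examples
#' p <- generate_profile("tanh",
#'   list(amplitude = 100, midpoint = 600, steepness = 0.01),
#'   times = seq(0, 1200, by = 1))
#' p$time_s[which.max(p$d1)]  # 600: steepest point at the midpoint
#' @export
generate_profile <- function(kind = c("step", "linear", "tanh", "sinusoid",
                                      "exp_derivative"),
                             params = list(), times) {
  kind <- match.arg(kind)
  check_uniform_grid(times)
  t <- times
  prof <- switch(kind,
    step = {
      b <- pget(params, "baseline", 0)
      h <- pget(params, "height")
      t0 <- pget(params, "t0")
      conc <- b + h * (t >= t0)
      list(conc = conc, d1 = rep(0, length(t)), d2 = rep(0, length(t)))
    },
    linear = {
      b <- pget(params, "baseline", 0)
      s <- pget(params, "slope")
      list(conc = b + s * (t - t[1]),
           d1 = rep(s, length(t)), d2 = rep(0, length(t)))
    },
    tanh = {
      b <- pget(params, "baseline", 0)
      a <- pget(params, "amplitude")
      tm <- pget(params, "midpoint")
      k <- pget(params, "steepness")
      th <- tanh(k * (t - tm))
      sech2 <- 1 - th^2
      list(conc = b + a * (1 + th) / 2,
           d1 = a * k * sech2 / 2,
           d2 = -a * k^2 * sech2 * th)
    },
    sinusoid = {
      b <- pget(params, "baseline")
      a <- pget(params, "amplitude")
      Tp <- pget(params, "period")
      ph <- pget(params, "phase", 0)
      if (b < a)
        stop("sinusoid requires `baseline` >= `amplitude` to keep conc >= 0")
      w <- 2 * pi / Tp
      list(conc = b + a * sin(w * t + ph),
           d1 = a * w * cos(w * t + ph),
           d2 = -a * w^2 * sin(w * t + ph))
    },
    exp_derivative = {
      b <- pget(params, "baseline", 0)
      C0 <- pget(params, "C0")
      tg <- pget(params, "tau_growth")
      e <- exp((t - t[1]) / tg)
      list(conc = b + C0 * (e - 1), d1 = C0 * e / tg, d2 = C0 * e / tg^2)
    })
  if (any(prof$conc < -1e-12))
    stop("parameters produce negative concentrations")
  stimulus_profile(times, prof$conc, d1 = prof$d1, d2 = prof$d2)
}

#' Concentration at the chamber exit for a given inflow
#'
#' Integrates the well-stirred dilution model dC/dt = (Q/V) (C_in - C) along
#' the inflow profile. The update is an exact exponential integrator assuming
#' the inflow is piecewise linear between samples, so constant and step
#' inflows are integrated exactly and smooth inflows to high order.
#'
#' @param inflow A [stimulus_profile()] giving C_in(t) at the chamber inlet.
#' @param chamber A [chamber_spec()].
#' @param c0 Initial chamber concentration (uM); defaults to the first inflow
#'   sample.
#' @return A [stimulus_profile()] of the outflow concentration on the same
#'   grid.
#' @export
chamber_output <- function(inflow, chamber, c0 = inflow$conc_uM[1]) {
  stopifnot(inherits(chamber, "chamber_spec"))
  if (c0 < 0) stop("`c0` must be non-negative")
  dt <- profile_dt(inflow)
  k <- chamber_rate(chamber)
  cin <- inflow$conc_uM
  n <- length(cin)
  out <- numeric(n)
  out[1] <- c0
  ekh <- exp(-k * dt)
  for (i in seq_len(n - 1)) {
    a <- cin[i]
    b <- (cin[i + 1] - cin[i]) / dt
    # exact solution over one step with linear inflow a + b (t - t_i)
    out[i + 1] <- (out[i] - a + b / k) * ekh + a + b * dt - b / k
  }
  stimulus_profile(inflow$time_s, pmax(out, 0))
}

#' Invert the chamber model into a stimulus-fraction schedule
#'
#' Solves the dilution model for the inflow needed to realize a target
#' outflow profile, and expresses it as the fraction f(t) of total flow that
#' the stimulus pump must contribute:
#' f(t) = ((V/Q) dC/dt + C - C_buf) / (C_stim - C_buf).
#' A target is feasible only if f stays within \[0, 1\]; gradients steeper
#' than the chamber can follow are rejected with the first violating time.
#'
#' @param target A [stimulus_profile()]; analytic `d1` is used when present,
#'   otherwise central finite differences are taken.
#' @param chamber A [chamber_spec()].
#' @return Data frame with columns `time_s`, `stim_fraction`, of class
#'   `mixing_schedule`.
#' @seealso [schedule_to_inflow()] to map the schedule back to an inflow
#'   profile and close the design loop through [chamber_output()].
#' @export
design_mixing_schedule <- function(target, chamber) {
  stopifnot(inherits(chamber, "chamber_spec"))
  d1 <- target$d1
  if (is.null(d1)) d1 <- finite_derivatives(target)$d1
  k <- chamber_rate(chamber)
  f <- (d1 / k + target$conc_uM - chamber$buffer_conc) /
    (chamber$stim_conc - chamber$buffer_conc)
  tol <- 1e-9
  bad <- which(f < -tol | f > 1 + tol)
  if (length(bad))
    stop(sprintf(
      "target gradient infeasible for this chamber: stimulus fraction %.4f at t = %g s",
      f[bad[1]], target$time_s[bad[1]]))
  out <- data.frame(time_s = target$time_s,
                    stim_fraction = pmin(pmax(f, 0), 1))
  class(out) <- c("mixing_schedule", "data.frame")
  out
}

#' Inflow concentration realized by a stimulus-fraction schedule
#'
#' @param schedule A `mixing_schedule` from [design_mixing_schedule()].
#' @param chamber A [chamber_spec()].
#' @return A [stimulus_profile()] of the mixed inflow concentration.
#' @export
schedule_to_inflow <- function(schedule, chamber) {
  stopifnot(inherits(chamber, "chamber_spec"))
  conc <- chamber$buffer_conc +
    schedule$stim_fraction * (chamber$stim_conc - chamber$buffer_conc)
  stimulus_profile(schedule$time_s, conc)
}

#' Fill first and second derivatives by finite differences
#'
#' Central differences on the uniform grid (one-sided at the endpoints),
#' optionally after smoothing the concentration with a centered moving
#' average of `window` samples.
#'
#' @param profile A [stimulus_profile()].
#' @param window Odd number of samples for the moving-average pre-smoother;
#'   1 means no smoothing.
#' @return The profile with `d1` and `d2` columns replaced.
#' @export
finite_derivatives <- function(profile, window = 1) {
  n <- nrow(profile)
  if (n < 3) stop("need at least 3 samples to differentiate")
  if (window > n) stop("`window` larger than the series")
  if (window %% 2 == 0) stop("`window` must be odd")
  dt <- profile_dt(profile)
  x <- profile$conc_uM
  if (window > 1) {
    sm <- stats::filter(x, rep(1 / window, window), sides = 2)
    x <- as.numeric(sm)
    # moving average is undefined at the edges; fall back to the raw samples
    x[is.na(x)] <- profile$conc_uM[is.na(x)]
  }
  d1 <- c(x[2] - x[1],
          (x[3:n] - x[1:(n - 2)]) / 2,
          x[n] - x[n - 1]) / dt
  d2 <- c(x[3] - 2 * x[2] + x[1],
          x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)],
          x[n] - 2 * x[n - 1] + x[n - 2]) / dt^2
  out <- profile
  out$d1 <- d1
  out$d2 <- d2
  out
}
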