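# Calcium-trace handling: normalization, pulse detection, exponential-decay
# fitting, and per-worm pulse metrics.

#' Single-neuron calcium trace
#'
#' @param worm_id Identifier of the animal.
#' @param neuron Neuron label, e.g. `"AWA"`, `"AWCON"`, `"AIY"`.
#' @param times Sample times in seconds. A uniform grid is expected (imaging
#'   at a nominal 1.4 frames/s); non-uniform input is resampled to the median
#'   interval by linear interpolation, with a warning.
#' @param values Fluorescence values (a.u.), finite and non-negative.
#' @return An object of class `calcium_trace`.
#' @export
calcium_trace <- function(worm_id, neuron, times, values) {
  stopifnot(is.numeric(times), is.numeric(values))
  if (length(times) != length(values))
    stop("`times` and `values` must have equal length")
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("trace contains non-finite samples")
  ord <- order(times)
  times <- times[ord]
  values <- values[ord]
  dt <- diff(times)
  if (any(dt <= 0)) stop("duplicate timestamps in trace")
  if (length(dt) && any(abs(dt - dt[1]) > 1e-6 * dt[1])) {
    warning("non-uniform sampling; resampling to the median interval")
    step <- stats::median(dt)
    grid <- seq(times[1], times[length(times)], by = step)
    values <- stats::approx(times, values, xout = grid)$y
    times <- grid
  }
  structure(list(worm_id = worm_id, neuron = neuron,
                 times = times, values = values),
            class = "calcium_trace")
}

trace_dt <- function(trace) trace$times[2] - trace$times[1]

#' Min-max normalize a trace to \[0, 1\]
#'
#' The per-neuron normalization used for raster displays:
#' (val - min(val)) / (max(val) - min(val)).
#'
#' @param x Numeric vector or a [calcium_trace()].
#' @return Numeric vector in \[0, 1\] (or the trace with normalized values).
#' @export
normalize_trace <- function(x) {
  if (inherits(x, "calcium_trace")) {
    x$values <- normalize_trace(x$values)
    return(x)
  }
  if (!length(x)) stop("empty series")
  r <- range(x)
  if (r[1] == r[2]) stop("degenerate trace: constant values cannot be normalized")
  (x - r[1]) / (r[2] - r[1])
}

# Topographic prominence of local maxima: height above the higher of the two
# minima separating the peak from the nearest larger values (or the edges).
peak_prominences <- function(x, peaks) {
  vapply(peaks, function(i) {
    h <- x[i]
    lmin <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) {
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1L
    }
    rmin <- h
    j <- i + 1L
    while (j <= length(x) && x[j] <= h) {
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Detect calcium pulses as prominent local maxima
#'
#' Local maxima (plateau ties broken toward the earlier sample) are kept when
#' their topographic prominence reaches `min_prominence` of the trace range,
#' then thinned greedily from the highest peak down so that retained peaks are
#' at least `min_separation` seconds apart.
#'
#' @param trace A [calcium_trace()].
#' @param min_prominence Fraction of the trace range (default 0.2).
#' @param min_separation Minimum peak spacing in seconds (default 10; pulses
#'   typically last tens of seconds).
#' @return Integer vector of peak sample indices (possibly empty), ascending.
#' @export
detect_pulses <- function(trace, min_prominence = 0.2, min_separation = 10) {
  stopifnot(min_prominence > 0, min_separation > 0)
  x <- trace$values
  n <- length(x)
  if (n < 3) return(integer(0))
  rng <- diff(range(x))
  if (rng == 0) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  prom <- peak_prominences(x, cand)
  cand <- cand[prom >= min_prominence * rng]
  if (!length(cand)) return(integer(0))
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) ||
        all(abs(trace$times[i] - trace$times[kept]) >= min_separation))
      kept <- c(kept, i)
  }
  sort(kept)
}

#' Fit an exponential decay A exp(-t/tau) to a pulse tail
#'
#' Fits the decaying flank from the peak by nonlinear least squares
#' (Levenberg-Marquardt), initialized from a log-linear regression on the
#' positive samples. Times are measured from the peak. With `offset = TRUE`
#' a residual constant is co-estimated (A exp(-t/tau) + c), which makes the
#' fit robust to small errors in the subtracted baseline when the window
#' includes enough of the flat tail.
#'
#' @param trace A [calcium_trace()].
#' @param peak_index Sample index of the pulse peak.
#' @param fit_end Last sample index of the fit window.
#' @param baseline Baseline (a.u.) subtracted from the window before fitting.
#' @param offset Co-estimate a residual baseline offset (default `FALSE`).
#' @return List with `A`, `tau` (s), `offset`, `rmse`, and `converged`. The
#'   window must hold at least 4 samples with positive baseline-subtracted
#'   values at its head; in the pure-exponential mode, trailing non-positive
#'   samples (possible under noise) are trimmed before fitting.
#' @export
fit_pulse_decay <- function(trace, peak_index, fit_end, baseline = 0,
                            offset = FALSE) {
  if (fit_end <= peak_index) stop("`fit_end` must follow `peak_index`")
  y <- trace$values[peak_index:fit_end] - baseline
  t <- trace$times[peak_index:fit_end] - trace$times[peak_index]
  if (y[1] <= 0) stop("non-positive values at the start of the fit window")
  if (!offset) {
    npos <- which(y <= 0)
    if (length(npos)) {
      y <- y[seq_len(npos[1] - 1L)]
      t <- t[seq_len(npos[1] - 1L)]
    }
  }
  if (length(y) < 4) stop("fit window needs at least 4 positive samples")
  pos <- y > 0
  init <- stats::lm(log(y[pos]) ~ t[pos])
  slope <- stats::coef(init)[[2]]
  tau0 <- if (is.finite(slope) && slope < 0) -1 / slope else diff(range(t))
  A0 <- exp(stats::coef(init)[[1]])
  fit <- tryCatch(
    if (offset)
      minpack.lm::nlsLM(y ~ A * exp(-t / tau) + c0,
                        start = list(A = A0, tau = tau0, c0 = 0),
                        lower = c(A = 1e-12, tau = 1e-12, c0 = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(y ~ A * exp(-t / tau),
                        start = list(A = A0, tau = tau0),
                        lower = c(A = 1e-12, tau = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(A = A0, tau = tau0, offset = 0,
                rmse = sqrt(mean((y - A0 * exp(-t / tau0))^2)),
                converged = FALSE))
  }
  cf <- stats::coef(fit)
  list(A = unname(cf["A"]), tau = unname(cf["tau"]),
       offset = if (offset) unname(cf["c0"]) else 0,
       rmse = sqrt(mean(stats::resid(fit)^2)), converged = TRUE)
}

#' Detect and fit all pulses of a trace
#'
#' Runs [detect_pulses()] and, for each peak, determines the pulse onset (the
#' trace minimum between the previous peak and this one), a local baseline
#' (median of up to `baseline_window` samples preceding the onset), and fits
#' [fit_pulse_decay()] on the decaying flank. The fit is anchored at the
#' rise-completion sample -- the first sample between onset and argmax that
#' reaches 80% of the peak prominence -- rather than at the raw argmax,
#' whose position and value are noise-selected; for sharp-rise pulses this
#' anchor is the moment the pulse attains its amplitude. With `fit_offset =
#' TRUE` (default) the window runs to the next pulse onset (or trace end)
#' and a residual baseline constant is co-estimated, so the flat tail pins
#' the baseline; with `fit_offset = FALSE` the window is cut at the first
#' pair of consecutive samples below `decay_frac` of the amplitude and a
#' pure exponential is fitted.
#'
#' @param trace A [calcium_trace()].
#' @inheritParams detect_pulses
#' @param decay_frac Fraction of the amplitude at which the fit window ends
#'   in the pure-exponential mode (default 0.1), keeping later pulses out of
#'   the fit.
#' @param baseline_window Number of pre-onset samples whose median defines the
#'   local baseline (default 5).
#' @param fit_offset Co-estimate a residual baseline in the decay fit over
#'   the full inter-pulse window (default `TRUE`).
#' @return A pulse table: data frame with columns `worm_id`, `neuron`,
#'   `peak_index`, `peak_time_s`, `onset_time_s`, `end_time_s`, `amplitude`
#'   (the fitted A, above the local baseline -- more robust to sampling
#'   noise than the raw peak sample), `tau_s`, `rmse`, `interval_s`
#'   (peak-to-peak time to the next pulse, NA for the last), `converged`.
#' @export
extract_pulses <- function(trace, min_prominence = 0.2, min_separation = 10,
                           decay_frac = 0.1, baseline_window = 5,
                           fit_offset = TRUE) {
  peaks <- detect_pulses(trace, min_prominence, min_separation)
  empty <- data.frame(worm_id = character(0), neuron = character(0),
                      peak_index = integer(0), peak_time_s = numeric(0),
                      onset_time_s = numeric(0), end_time_s = numeric(0),
                      amplitude = numeric(0), tau_s = numeric(0),
                      rmse = numeric(0), interval_s = numeric(0),
                      converged = logical(0))
  if (!length(peaks)) return(empty)
  x <- trace$values
  n <- length(x)
  onsets <- vapply(seq_along(peaks), function(k) {
    lo <- if (k == 1) 1L else peaks[k - 1]
    w <- lo:peaks[k]
    # last index attaining the minimum, i.e. the foot closest to the peak
    w[max(which(x[w] == min(x[w])))]
  }, integer(1))
  rows <- lapply(seq_along(peaks), function(k) {
    pk <- peaks[k]
    on <- onsets[k]
    pre <- seq(max(1L, on - baseline_window), max(1L, on - 1L))
    base <- if (on == 1L) x[1] else stats::median(x[pre])
    amp_raw <- x[pk] - base
    if (amp_raw <= 0) return(NULL)
    # anchor the decay fit where the rise is complete, not at the
    # noise-selected argmax
    anchor <- on + which(x[on:pk] - base >= 0.8 * amp_raw)[1] - 1L
    lim <- if (k < length(peaks)) onsets[k + 1] - 1L else n
    if (!fit_offset) {
      # end the window where the decay has genuinely reached decay_frac of
      # the amplitude: two consecutive sub-threshold samples, so a single
      # noise dip does not truncate the fit
      below <- which(x[(anchor + 1):n] - base < decay_frac * amp_raw)
      if (length(below) > 1) {
        runs <- which(diff(below) == 1L)
        if (length(runs)) lim <- min(lim, anchor + below[runs[1]])
      } else if (length(below) == 1 && below == n - anchor) {
        lim <- min(lim, anchor + below)
      }
    }
    if (lim - anchor < 3L) return(NULL)  # too short to fit
    fit <- tryCatch(fit_pulse_decay(trace, anchor, lim, baseline = base,
                                    offset = fit_offset),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    data.frame(worm_id = trace$worm_id, neuron = trace$neuron,
               peak_index = pk, peak_time_s = trace$times[pk],
               onset_time_s = trace$times[on], end_time_s = trace$times[lim],
               amplitude = fit$A, tau_s = fit$tau, rmse = fit$rmse,
               interval_s = NA_real_, converged = fit$converged)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  if (nrow(out) > 1)
    out$interval_s <- c(diff(out$peak_time_s), NA_real_)
  out
}

#' Half-decay time of an exponential pulse
#'
#' @param tau Decay constant in seconds.
#' @return tau * ln(2), the analytic time to fall to half the peak.
#' @seealso [empirical_half_decay()] for the grid-crossing variant.
#' @export
half_decay_time <- function(tau) {
  stopifnot(all(tau > 0))
  tau * log(2)
}

#' Empirical half-decay time of a detected pulse
#'
#' Time from the peak to the first sample at or below half the
#' baseline-subtracted peak value.
#'
#' @param trace A [calcium_trace()].
#' @param peak_index Peak sample index.
#' @param baseline Baseline subtracted before halving (default 0).
#' @return Time in seconds, or NA if the trace never crosses half-peak.
#' @export
empirical_half_decay <- function(trace, peak_index, baseline = 0) {
  y <- trace$values - baseline
  half <- y[peak_index] / 2
  later <- seq(peak_index + 1L, length(y))
  hit <- later[which(y[later] <= half)[1]]
  if (is.na(hit)) return(NA_real_)
  trace$times[hit] - trace$times[peak_index]
}

#' Per-worm normalized pulse metrics
#'
#' Applies, within each worm, the normalization
#' (amplitude - min(amplitude)) / max(amplitude) -- note the denominator is
#' the maximum, not the range, so the largest pulse maps to
#' 1 - min/max rather than 1. Peak-to-peak intervals are normalized the same
#' way.
#'
#' @param pulses A pulse table (see [extract_pulses()]) with at least
#'   `worm_id`, `amplitude` and optionally `interval_s`.
#' @return The table with added columns `norm_amplitude` and `norm_interval`
#'   (NA where the interval is undefined).
#' @export
pulse_metrics <- function(pulses) {
  stopifnot(nrow(pulses) >= 1)
  norm_one <- function(v) {
    ok <- !is.na(v)
    if (!any(ok)) return(v)
    if (max(v[ok]) == 0) stop("maximum amplitude is zero; cannot normalize")
    out <- rep(NA_real_, length(v))
    out[ok] <- (v[ok] - min(v[ok])) / max(v[ok])
    out
  }
  pulses$norm_amplitude <- stats::ave(pulses$amplitude, pulses$worm_id,
                                      FUN = norm_one)
  pulses$norm_interval <- if ("interval_s" %in% names(pulses)) {
    stats::ave(pulses$interval_s, pulses$worm_id, FUN = function(v) {
      ok <- !is.na(v)
      out <- rep(NA_real_, length(v))
      if (any(ok)) {
        if (max(v[ok]) == 0) stop("maximum interval is zero; cannot normalize")
        out[ok] <- (v[ok] - min(v[ok])) / max(v[ok])
      }
      out
    })
  } else NA_real_
  pulses
}
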