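# Seeded generators that emulate the statistical structure the analyses
# assume: worm-specific pulsatile signatures, derivative-driven (optionally
# adapting) pulse processes, graded off-responses, and pulse-gated walkers.

#' Synthetic cohort of pulsatile calcium traces with known ground truth
#'
#' Emulates a cohort of worms responding to a rising gradient with trains of
#' instant-rise / exponential-decay calcium pulses. In `"individual"` mode
#' each worm first draws a private signature (mean amplitude and mean decay
#' time) from between-worm lognormal distributions and then draws its pulses
#' around that signature with a smaller within-worm spread, reproducing the
#' situation where pulses of one animal cluster together in
#' (amplitude, tau) space. In `"pooled"` mode all pulses are i.i.d. from the
#' population distribution, which is the exchangeable null of the
#' individuality shuffle test.
#'
#' @param n_worms Number of worms (default 10).
#' @param pulses_per_worm Pulses per worm; a single count, a vector (one per
#'   worm), or `NULL` to draw Poisson counts with mean 9.2 (at least 2),
#'   giving cohorts of roughly 92 pulses at the default 10 worms.
#' @param mode `"individual"` or `"pooled"`.
#' @param hyper Named list of hyperparameters overriding the defaults:
#'   `amp_mean` (2 a.u.), `tau_mean` (10 s), `between_cv` (0.45),
#'   `within_cv` (0.1), `gap_mean` (mean extra inter-pulse gap beyond the
#'   refractory decay, 15 s), `noise_sd` (trace noise, a.u., 0),
#'   `dt` (1/1.4 s).
#' @param seed Integer seed.
#' @return List with `traces` (list of [calcium_trace()]), `pulses` (ground
#'   truth pulse table: `worm_id`, `peak_time_s`, `amplitude`, `tau_s`,
#'   `interval_s`), and `signatures` (per-worm mean amplitude/tau).
#' @export
synth_pulse_cohort <- function(n_worms = 10, pulses_per_worm = NULL,
                               mode = c("individual", "pooled"),
                               hyper = list(), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_worms >= 1)
  h <- utils::modifyList(list(amp_mean = 2, tau_mean = 10, between_cv = 0.45,
                              within_cv = 0.1, gap_mean = 15, noise_sd = 0,
                              dt = 1 / 1.4), hyper)
  if (any(unlist(h[c("amp_mean", "tau_mean", "between_cv", "within_cv",
                     "gap_mean", "dt")]) <= 0) || h$noise_sd < 0)
    stop("invalid hyperparameters")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  counts <- if (is.null(pulses_per_worm)) {
    pmax(2L, stats::rpois(n_worms, 9.2))
  } else {
    rep_len(as.integer(pulses_per_worm), n_worms)
  }
  stopifnot(all(counts >= 1))
  sd_b <- sqrt(log(1 + h$between_cv^2))
  sd_w <- sqrt(log(1 + h$within_cv^2))
  sd_pool <- sqrt(sd_b^2 + sd_w^2)
  sig <- data.frame(worm_id = sprintf("worm%02d", seq_len(n_worms)),
                    mean_amplitude = NA_real_, mean_tau = NA_real_)
  traces <- vector("list", n_worms)
  rows <- vector("list", n_worms)
  for (w in seq_len(n_worms)) {
    nk <- counts[w]
    if (mode == "individual") {
      ma <- stats::rlnorm(1, log(h$amp_mean), sd_b)
      mt <- stats::rlnorm(1, log(h$tau_mean), sd_b)
      amps <- stats::rlnorm(nk, log(ma), sd_w)
      taus <- stats::rlnorm(nk, log(mt), sd_w)
    } else {
      ma <- h$amp_mean
      mt <- h$tau_mean
      amps <- stats::rlnorm(nk, log(h$amp_mean), sd_pool)
      taus <- stats::rlnorm(nk, log(h$tau_mean), sd_pool)
    }
    sig$mean_amplitude[w] <- ma
    sig$mean_tau[w] <- mt
    # refractory spacing: each pulse decays to 10% before the next may start
    gaps <- taus * log(10) + stats::rgamma(nk, shape = 4,
                                           scale = h$gap_mean / 4)
    onsets <- 30 + cumsum(c(0, gaps[-nk]))
    span <- onsets[nk] + taus[nk] * log(10) + 4 * h$gap_mean
    times <- seq(0, span, by = h$dt)
    # snap onsets to the grid so the peak sample carries the full amplitude
    onsets <- times[findInterval(onsets, times)]
    v <- numeric(length(times))
    for (k in seq_len(nk)) {
      after <- times >= onsets[k]
      v[after] <- v[after] + amps[k] * exp(-(times[after] - onsets[k]) / taus[k])
    }
    if (h$noise_sd > 0) v <- pmax(v + stats::rnorm(length(v), 0, h$noise_sd), 0)
    traces[[w]] <- calcium_trace(sig$worm_id[w], "AWA", times, v)
    rows[[w]] <- data.frame(worm_id = sig$worm_id[w],
                            peak_time_s = onsets, amplitude = amps,
                            tau_s = taus,
                            interval_s = c(diff(onsets), NA_real_))
  }
  list(traces = traces, pulses = do.call(rbind, rows), signatures = sig)
}

# EMA of a sampled series with timescale `memory` seconds.
ema_series <- function(x, dt, memory) {
  a <- dt / memory
  out <- numeric(length(x))
  e <- 0
  for (i in seq_along(x)) {
    out[i] <- e
    e <- e + a * (x[i] - e)
  }
  out
}

#' Synthetic pulsatile trace driven by the stimulus first derivative
#'
#' Generates an inhomogeneous pulse process whose rate and amplitude follow
#' the positive part of a drive signal s(t): the raw first derivative of the
#' stimulus (`adapt = FALSE`) or the derivative minus its exponential moving
#' average (`adapt = TRUE`, first-derivative adaptation). Pulses rise
#' instantly and decay exponentially; a refractory period until the current
#' pulse has decayed to 10% keeps fitted decays non-overlapping.
#'
#' @param stimulus A [stimulus_profile()] with `d1` (filled by
#'   [finite_derivatives()] otherwise).
#' @param adapt Whether the drive adapts to the derivative.
#' @param memory EMA timescale in seconds (default 150).
#' @param gain Pulse rate per unit drive, in pulses/s per (uM/s)
#'   (default 0.1).
#' @param tau Pulse decay constant in seconds (default 10).
#' @param amp_gain Peak amplitude per unit drive (a.u. per uM/s, default 4).
#' @param noise_sd Additive trace noise (a.u., default 0.01).
#' @param worm_id,neuron Labels for the returned trace.
#' @param seed Integer seed.
#' @return A [calcium_trace()]; attribute `"pulses"` holds the ground-truth
#'   pulse onset times and amplitudes.
#' @export
synth_adaptive_trace <- function(stimulus, adapt = TRUE, memory = 150,
                                 gain = 0.1, tau = 10, amp_gain = 4,
                                 noise_sd = 0.01, worm_id = "worm01",
                                 neuron = "AWA", seed = 1) {
  d1 <- stimulus$d1
  if (is.null(d1)) d1 <- finite_derivatives(stimulus)$d1
  dt <- profile_dt(stimulus)
  drive <- if (adapt) d1 - ema_series(d1, dt, memory) else d1
  s_pos <- pmax(drive, 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(s_pos)
  v <- numeric(n)
  refractory_until <- -Inf
  onsets <- numeric(0)
  amps <- numeric(0)
  tt <- stimulus$time_s
  u <- stats::runif(n)
  for (i in seq_len(n)) {
    if (tt[i] >= refractory_until && u[i] < gain * s_pos[i] * dt) {
      a <- amp_gain * s_pos[i] * stats::rlnorm(1, 0, 0.1)
      onsets <- c(onsets, tt[i])
      amps <- c(amps, a)
      after <- i:n
      v[after] <- v[after] + a * exp(-(tt[after] - tt[i]) / tau)
      refractory_until <- tt[i] + tau * log(10)
    }
  }
  if (noise_sd > 0) v <- pmax(v + stats::rnorm(n, 0, noise_sd), 0)
  out <- calcium_trace(worm_id, neuron, tt, v)
  attr(out, "pulses") <- data.frame(peak_time_s = onsets, amplitude = amps,
                                    tau_s = rep(tau, length(onsets)))
  out
}

#' Synthetic graded off-response trace (AWC-like)
#'
#' A deterministic graded response that activates on decreasing
#' concentrations: g(t) = smooth(max(0, -gain * d1)) plus Gaussian noise,
#' so the trace anti-correlates with the stimulus first derivative.
#'
#' @param stimulus A [stimulus_profile()] with `d1`.
#' @param gain Response gain (a.u. per uM/s, default 1).
#' @param smoothing Moving-average smoothing window in seconds (default 5).
#' @param noise_sd Additive noise relative to the unit-normalized response
#'   (default 0.02).
#' @param worm_id,neuron Labels.
#' @param seed Integer seed.
#' @return A [calcium_trace()].
#' @export
synth_awc_trace <- function(stimulus, gain = 1, smoothing = 5,
                            noise_sd = 0.02, worm_id = "worm01",
                            neuron = "AWCON", seed = 1) {
  d1 <- stimulus$d1
  if (is.null(d1)) d1 <- finite_derivatives(stimulus)$d1
  dt <- profile_dt(stimulus)
  g <- pmax(0, -gain * d1)
  w <- max(1L, round(smoothing / dt))
  if (w %% 2 == 0) w <- w + 1L
  if (w > 1) {
    sm <- as.numeric(stats::filter(g, rep(1 / w, w), sides = 2))
    sm[is.na(sm)] <- g[is.na(sm)]
    g <- sm
  }
  if (max(g) > 0) g <- g / max(g)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  v <- g + stats::rnorm(length(g), 0, noise_sd)
  calcium_trace(worm_id, neuron, stimulus$time_s, pmax(v + 0.1, 0))
}

#' Synthetic pulse-gated walker: runs while active, reverses on pulse decay
#'
#' Emulates the coupling between pulsatile activity and locomotion: the
#' walker runs (heading held near the direction to the source) while the
#' current calcium pulse is above `turn_threshold` of its own peak; once the
#' pulse decays through the threshold the walker makes an about-face
#' (heading flipped plus jitter), and a fresh pulse starts after a short
#' gap, re-orienting the walker toward the source. Every emitted reversal
#' therefore falls in the decreasing phase of a pulse.
#'
#' @param field A [gradient_field()] supplying the source position.
#' @param signature List with `amp` (mean peak, a.u., default 1) and `tau`
#'   (decay s, default 5).
#' @param turn_threshold Fraction of the pulse peak below which the walker
#'   reverses (default 0.58); 0 disables reversals entirely.
#' @param n_steps Number of samples (default 400).
#' @param dt Sample interval in seconds (default 0.5).
#' @param speed Run speed in step-lengths/s (default 1).
#' @param rise_time Linear pulse rise time in seconds (default 1.5), so the
#'   pulse peak sits slightly after its onset.
#' @param gap Pause between threshold crossing and the next pulse (s,
#'   default 2).
#' @param jitter_sd SD of the reversal-angle jitter in degrees (default 15).
#' @param start Start position (default 120 step-lengths right of the
#'   source, far enough that the walker does not reach it within the
#'   default duration).
#' @param seed Integer seed.
#' @return List with `trajectory` ([trajectory()]), `trace`
#'   ([calcium_trace()]), `reversal_times`, and `pulses` (ground-truth table
#'   with `onset_time_s`, `peak_time_s`, `end_time_s`, `amplitude`,
#'   `tau_s`).
#' @export
synth_pulse_gated_trajectory <- function(field = gradient_field("gaussian"),
                                         signature = list(amp = 1, tau = 5),
                                         turn_threshold = 0.58,
                                         n_steps = 400, dt = 0.5, speed = 1,
                                         rise_time = 1.5, gap = 2,
                                         jitter_sd = 15,
                                         start = field$source + c(120, 0),
                                         seed = 1) {
  stopifnot(turn_threshold >= 0, turn_threshold < 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tt <- seq(0, by = dt, length.out = n_steps + 1)
  x <- numeric(n_steps + 1)
  y <- numeric(n_steps + 1)
  v <- numeric(n_steps + 1)
  x[1] <- start[1]
  y[1] <- start[2]
  to_source <- function(px, py) atan2(field$source[2] - py,
                                      field$source[1] - px)
  heading <- to_source(x[1], y[1]) + stats::rnorm(1, 0, 5 * pi / 180)
  mode <- "run"
  pulse_onset <- 0
  pulse_amp <- signature$amp * stats::rlnorm(1, 0, 0.1)
  next_pulse_at <- -Inf
  reversals <- numeric(0)
  pulses <- data.frame(onset_time_s = pulse_onset,
                       peak_time_s = pulse_onset + rise_time,
                       end_time_s = NA_real_,
                       amplitude = pulse_amp, tau_s = signature$tau)
  activity <- function(t) {
    el <- t - pulse_onset
    if (el < 0) return(0)
    if (el < rise_time) return(pulse_amp * el / rise_time)
    pulse_amp * exp(-(el - rise_time) / signature$tau)
  }
  in_pulse <- TRUE
  for (i in seq_len(n_steps + 1)) {
    t <- tt[i]
    if (!in_pulse && t >= next_pulse_at) {
      # a new pulse begins; the walker re-orients toward the source
      pulse_onset <- t
      pulse_amp <- signature$amp * stats::rlnorm(1, 0, 0.1)
      pulses <- rbind(pulses,
                      data.frame(onset_time_s = t,
                                 peak_time_s = t + rise_time,
                                 end_time_s = NA_real_,
                                 amplitude = pulse_amp,
                                 tau_s = signature$tau))
      pulses$end_time_s[nrow(pulses) - 1] <- t
      heading <- to_source(x[i], y[i]) + stats::rnorm(1, 0, 5 * pi / 180)
      in_pulse <- TRUE
      mode <- "run"
    }
    v[i] <- activity(t)
    decaying <- in_pulse && (t - pulse_onset) > rise_time
    if (turn_threshold > 0 && decaying && mode == "run" &&
        v[i] < turn_threshold * pulse_amp) {
      # reversal: about-face with jitter, during the decreasing pulse phase
      heading <- heading + pi + stats::rnorm(1, 0, jitter_sd * pi / 180)
      reversals <- c(reversals, t)
      mode <- "reversed"
      in_pulse <- FALSE
      next_pulse_at <- t + gap
    }
    if (i <= n_steps) {
      x[i + 1] <- x[i] + speed * dt * cos(heading)
      y[i + 1] <- y[i] + speed * dt * sin(heading)
    }
  }
  pulses$end_time_s[nrow(pulses)] <- tt[n_steps + 1]
  list(trajectory = trajectory(tt, x, y, field$source),
       trace = calcium_trace("worm01", "AWA", tt, v),
       reversal_times = reversals,
       pulses = pulses)
}
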