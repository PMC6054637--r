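# Shared fixtures, built in code.

# standard 20-minute hyperbolic-tangent gradient sampled at 1.4 Hz
tanh_profile <- function(amplitude = 100, midpoint = 600, steepness = 0.01,
                         baseline = 0.12, t_end = 1200, dt = 1 / 1.4) {
  generate_profile("tanh",
                   list(baseline = baseline, amplitude = amplitude,
                        midpoint = midpoint, steepness = steepness),
                   times = seq(0, t_end, by = dt))
}

# noiseless trace holding well-separated exponential pulses on the grid
two_pulse_trace <- function(A = c(2, 3), tau = c(10, 8), onset = c(50, 250),
                            t_end = 450, dt = 1 / 1.4, noise_sd = 0,
                            seed = NULL) {
  times <- seq(0, t_end, by = dt)
  onset <- times[findInterval(onset, times)]
  v <- numeric(length(times))
  for (k in seq_along(A)) {
    after <- times >= onset[k]
    v[after] <- v[after] + A[k] * exp(-(times[after] - onset[k]) / tau[k])
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + rnorm(length(v), 0, noise_sd)
  }
  list(trace = calcium_trace("w1", "AWA", times, v), onset = onset,
       A = A, tau = tau)
}

# small pulse table built by hand
toy_pulse_table <- function(values_by_worm, parameter = "amplitude") {
  df <- do.call(rbind, lapply(names(values_by_worm), function(w) {
    v <- values_by_worm[[w]]
    data.frame(worm_id = w, peak_time_s = seq_along(v) * 30,
               amplitude = v, tau_s = v, interval_s = c(diff(seq_along(v) * 30), NA))
  }))
  df
}
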