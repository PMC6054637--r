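# Gradient generation, the mixing-chamber model, and schedule inversion.

test_that("generate_profile produces the documented shapes with analytic derivatives", {
  # linear ramp: 20 uM/min for 10 min reaches 200 uM
  lin <- generate_profile("linear", list(slope = 20 / 60),
                          times = seq(0, 600, by = 1))
  expect_equal(lin$conc_uM[lin$time_s == 600], 200)
  expect_true(all(lin$d1 == 20 / 60))
  expect_true(all(lin$d2 == 0))

  # tanh: d1 maximal exactly at the midpoint, where d2 crosses zero
  th <- tanh_profile(midpoint = 600)
  i <- which.max(th$d1)
  expect_equal(th$time_s[i], th$time_s[which.min(abs(th$time_s - 600))])
  expect_lt(abs(th$d2[i]), 1e-3 * max(abs(th$d2)))

  # step: baseline before t0, baseline + height from t0 on
  st <- generate_profile("step", list(baseline = 1, height = 5, t0 = 10),
                         times = seq(0, 20, by = 0.5))
  expect_true(all(st$conc_uM[st$time_s < 10] == 1))
  expect_true(all(st$conc_uM[st$time_s >= 10] == 6))

  # sinusoid phase relation: d1 leads conc by a quarter period
  si <- generate_profile("sinusoid",
                         list(baseline = 10, amplitude = 5, period = 120),
                         times = seq(0, 600, by = 0.5))
  expect_equal(si$d1, 5 * (2 * pi / 120) * cos(2 * pi * si$time_s / 120))

  # exp_derivative: d1 grows exponentially
  ex <- generate_profile("exp_derivative", list(C0 = 1, tau_growth = 100),
                         times = seq(0, 500, by = 1))
  expect_equal(ex$d1[501] / ex$d1[1], exp(5), tolerance = 1e-10)
})

test_that("generate_profile rejects invalid parameters and kinds", {
  tms <- seq(0, 100, by = 1)
  expect_error(generate_profile("linear", list(slope = -1), times = tms),
               "negative")
  expect_error(generate_profile("sinusoid",
                                list(baseline = 1, amplitude = 2, period = 50),
                                times = tms), "baseline")
  expect_error(generate_profile("spiral", list(), times = tms))
  expect_error(stimulus_profile(c(0, 1, 3), c(1, 1, 1)), "uniform")
})

test_that("chamber_output holds constant inflow fixed and matches the step-response closed form", {
  ch <- chamber_spec(volume = 50, total_flow = 500, stim_conc = 1150,
                     buffer_conc = 0.12)
  tms <- seq(0, 120, by = 0.25)
  const <- stimulus_profile(tms, rep(7, length(tms)))
  expect_equal(chamber_output(const, ch, c0 = 7)$conc_uM,
               rep(7, length(tms)))

  # step 0 -> c at t = 0 with empty chamber: c (1 - exp(-Q t / V))
  cstep <- 100
  step <- stimulus_profile(tms, rep(cstep, length(tms)))
  out <- chamber_output(step, ch, c0 = 0)
  k <- ch$total_flow / ch$volume / 60
  analytic <- cstep * (1 - exp(-k * tms))
  expect_lt(max(abs(out$conc_uM - analytic)), 1e-6 * cstep)
  # at t = V/Q the output is c (1 - 1/e)
  tvq <- ch$volume / ch$total_flow * 60
  expect_equal(out$conc_uM[which.min(abs(tms - tvq))],
               cstep * (1 - exp(-1)), tolerance = 1e-6)
})

test_that("chamber_output respects inflow bounds, linearity, and the fast-mixing limit", {
  tms <- seq(0, 600, by = 1)
  si <- generate_profile("sinusoid",
                         list(baseline = 50, amplitude = 30, period = 200),
                         times = tms)
  ch <- chamber_spec(volume = 200, total_flow = 400, stim_conc = 200)
  out <- chamber_output(si, ch, c0 = 10)
  expect_true(all(out$conc_uM >= min(10, min(si$conc_uM)) - 1e-9))
  expect_true(all(out$conc_uM <= max(10, max(si$conc_uM)) + 1e-9))

  # linearity in (inflow, c0) for affine combinations a + b = 1
  li <- generate_profile("linear", list(baseline = 5, slope = 0.1),
                         times = tms)
  a <- 0.3
  mixed <- stimulus_profile(tms, a * si$conc_uM + (1 - a) * li$conc_uM)
  out_mixed <- chamber_output(mixed, ch, c0 = a * 10 + (1 - a) * 2)
  out_parts <- a * chamber_output(si, ch, c0 = 10)$conc_uM +
    (1 - a) * chamber_output(li, ch, c0 = 2)$conc_uM
  expect_equal(out_mixed$conc_uM, out_parts, tolerance = 1e-10)

  # Q/V large: output converges to the inflow
  fast <- chamber_spec(volume = 1, total_flow = 6e4, stim_conc = 200)
  out_fast <- chamber_output(si, fast, c0 = si$conc_uM[1])
  expect_lt(max(abs(out_fast$conc_uM - si$conc_uM)), 1e-3 * max(si$conc_uM))
})

test_that("design_mixing_schedule inverts the chamber and flags infeasible targets", {
  ch <- chamber_spec(volume = 50, total_flow = 500, stim_conc = 150,
                     buffer_conc = 0.12)
  tms <- seq(0, 1200, by = 1 / 1.4)
  # constant at buffer concentration -> all-buffer schedule
  buf <- stimulus_profile(tms, rep(ch$buffer_conc, length(tms)),
                          d1 = rep(0, length(tms)))
  expect_equal(design_mixing_schedule(buf, ch)$stim_fraction,
               rep(0, length(tms)))
  # constant at stimulus concentration -> all-stimulus schedule
  stim <- stimulus_profile(tms, rep(ch$stim_conc, length(tms)),
                           d1 = rep(0, length(tms)))
  expect_equal(design_mixing_schedule(stim, ch)$stim_fraction,
               rep(1, length(tms)))

  # round trip on a feasible tanh target
  target <- tanh_profile(amplitude = 100, baseline = 0.12)
  sched <- design_mixing_schedule(target, ch)
  back <- chamber_output(schedule_to_inflow(sched, ch), ch,
                         c0 = target$conc_uM[1])
  rng <- diff(range(target$conc_uM))
  expect_lt(max(abs(back$conc_uM - target$conc_uM)), 1e-4 * rng)

  # a gradient steeper than the chamber can follow is rejected with a time
  steep <- generate_profile("tanh",
                            list(amplitude = 149, midpoint = 60,
                                 steepness = 2, baseline = 0.5),
                            times = seq(0, 120, by = 0.1))
  expect_error(design_mixing_schedule(steep, ch), "infeasible.*t = ")
})

test_that("design-output round trip is identity across random feasible targets", {
  ch <- chamber_spec(volume = 50, total_flow = 500, stim_conc = 300,
                     buffer_conc = 0.12)
  set.seed(42)
  for (rep in 1:10) {
    tms <- seq(0, 1200, by = 1 / 1.4)
    prof <- if (rep %% 2 == 0) {
      generate_profile("tanh",
                       list(baseline = runif(1, 0.2, 5),
                            amplitude = runif(1, 20, 200),
                            midpoint = runif(1, 300, 900),
                            steepness = runif(1, 0.003, 0.02)),
                       times = tms)
    } else {
      b <- runif(1, 30, 100)
      generate_profile("sinusoid",
                       list(baseline = b, amplitude = runif(1, 5, b - 1),
                            period = runif(1, 200, 600)),
                       times = tms)
    }
    sched <- design_mixing_schedule(prof, ch)
    back <- chamber_output(schedule_to_inflow(sched, ch), ch,
                           c0 = prof$conc_uM[1])
    expect_lt(max(abs(back$conc_uM - prof$conc_uM)),
              1e-4 * diff(range(prof$conc_uM)))
  }
})

test_that("finite_derivatives recovers analytic derivatives on the grid", {
  tms <- seq(0, 600, by = 1)
  lin <- stimulus_profile(tms, 2 + 0.5 * tms)
  fd <- finite_derivatives(lin)
  expect_equal(fd$d1, rep(0.5, length(tms)), tolerance = 1e-10)
  expect_lt(max(abs(fd$d2)), 1e-10)

  th <- tanh_profile(dt = 1)
  fd_th <- finite_derivatives(stimulus_profile(th$time_s, th$conc_uM))
  # argmax of the numeric d1 within one sample of the analytic midpoint
  expect_lt(abs(fd_th$time_s[which.max(fd_th$d1)] -
                th$time_s[which.max(th$d1)]), 1 + 1e-9)

  expect_error(finite_derivatives(lin, window = 1e5), "larger")
})
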