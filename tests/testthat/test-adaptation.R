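# Pre/post-midpoint statistics, Wilcoxon wrapper, correlations, and
# trajectory analytics.

test_that("pre_post_midpoint_means splits symmetric activity evenly", {
  th <- tanh_profile()
  tms <- th$time_s
  # activity mirror-symmetric about the midpoint (t* = 600)
  sym <- calcium_trace("w", "AWA", tms, exp(-((tms - 600) / 100)^2))
  m <- pre_post_midpoint_means(sym, th)
  expect_equal(unname(m["before"]), unname(m["after"]), tolerance = 1e-6)

  # activity only before the midpoint
  pre_only <- calcium_trace("w", "AWA", tms,
                            ifelse(tms < 590, pmax(sin(tms / 20), 0), 0))
  m2 <- pre_post_midpoint_means(pre_only, th)
  expect_gt(m2["before"], 0)
  expect_equal(unname(m2["after"]), 0)

  # trace far too short on one side errors
  short <- calcium_trace("w", "AWA", tms[tms < 650],
                         seq_len(sum(tms < 650)))
  expect_error(suppressWarnings(pre_post_midpoint_means(short, th)),
               "coverage")
})

test_that("wilcoxon_test matches exact enumeration and flips under antisymmetry", {
  # 5 all-positive paired differences, one-sided: p = 1/2^5
  a <- c(2, 3, 4, 5, 6)
  b <- c(1, 2, 3, 4, 5) - c(0.1, 0.3, 0.2, 0.5, 0.4)
  w <- wilcoxon_test(a, b, "signed_rank_paired", side = "greater")
  expect_equal(w$p_value, 1 / 32)

  # enumeration oracle over all sign patterns for random inputs, n <= 10
  set.seed(9)
  for (n in c(6, 8, 10)) {
    d <- round(rnorm(n), 3)
    d <- d[d != 0]
    n_eff <- length(d)
    r <- rank(abs(d))
    W_obs <- sum(r[d > 0])
    signs <- expand.grid(rep(list(c(0, 1)), n_eff))
    W_null <- as.matrix(signs) %*% r
    p_enum <- mean(W_null >= W_obs)
    w2 <- wilcoxon_test(d, rep(0, n_eff), "signed_rank_paired",
                        side = "greater")
    expect_equal(w2$p_value, p_enum, tolerance = 1e-12)
    # antisymmetric swap: p(greater) of (a,b) + p(less) of (a,b) = 1 + P(W = W_obs)
    w_swap <- wilcoxon_test(rep(0, n_eff), d, "signed_rank_paired",
                            side = "greater")
    expect_equal(w_swap$p_value, mean(W_null <= W_obs), tolerance = 1e-12)
  }

  expect_error(wilcoxon_test(c(1, 2), c(1, 2), "signed_rank_paired"),
               "zero")
})

test_that("rank-sum mode is calibrated under the null", {
  set.seed(13)
  ps <- vapply(1:200, function(i) {
    x <- rnorm(8)
    y <- rnorm(8)
    wilcoxon_test(x, y, "rank_sum_independent")$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("pulse_derivative_correlation recovers constructed relationships", {
  th <- tanh_profile()
  tms <- seq(120, 1080, by = 60)
  d1 <- approx(th$time_s, th$d1, xout = tms)$y
  tab <- data.frame(worm_id = "w1", peak_time_s = tms,
                    amplitude = 3 * d1 + 1,
                    interval_s = c(1 / (d1[-1] + 0.01), NA))
  r_amp <- pulse_derivative_correlation(tab, th, "amplitude")
  expect_equal(r_amp$r, 1, tolerance = 1e-9)

  tab$interval_s <- c(2 / (d1[-length(d1)] + 0.02), NA)
  r_int <- pulse_derivative_correlation(tab, th, "interval")
  expect_lt(r_int$r, 0)

  # independent quantity: |r| small, p > 0.05 most of the time
  hits <- vapply(1:100, function(s) {
    set.seed(400 + s)
    tab$amplitude <- rlnorm(length(tms))
    pulse_derivative_correlation(tab, th, "amplitude")$p_value > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("smooth_track limits: interpolation at zero, straight line at high penalty", {
  set.seed(21)
  tms <- seq(0, 60, by = 0.5)
  true_x <- 2 + 0.5 * tms
  true_y <- 1 - 0.2 * tms
  sigma_j <- 0.4
  traj <- trajectory(tms, true_x + rnorm(length(tms), 0, sigma_j),
                     true_y + rnorm(length(tms), 0, sigma_j), c(100, -30))
  expect_identical(smooth_track(traj, roughness = 0), traj)

  # huge penalty: collinear output (matches the least-squares line)
  hard <- smooth_track(traj, roughness = 1e8)
  fit <- lm(hard$x ~ tms)
  expect_lt(max(abs(residuals(fit))), 1e-6 * diff(range(true_x)))

  # auto smoothing denoises a straight walk below the jitter level
  auto <- smooth_track(traj)
  rmse_x <- sqrt(mean((auto$x - true_x)^2))
  expect_lt(rmse_x, sigma_j)
  expect_error(trajectory(c(0, 1, 1, 2), 1:4, 1:4, c(0, 0)), "timestamps")
})

test_that("angular_deviation gives 0/180/90 for canonical motions and is rigid-motion invariant", {
  tms <- 0:20
  toward <- trajectory(tms, 21 - tms, rep(0, 21), c(0, 0))
  expect_equal(angular_deviation(toward)$deviation_deg, rep(0, 21),
               tolerance = 1e-9)
  away <- trajectory(tms, 21 + tms, rep(0, 21), c(0, 0))
  expect_equal(angular_deviation(away)$deviation_deg, rep(180, 21),
               tolerance = 1e-9)
  th <- seq(0, 2 * pi, length.out = 41)
  orbit <- trajectory(seq_along(th), 10 * cos(th), 10 * sin(th), c(0, 0))
  dev_orbit <- angular_deviation(orbit)$deviation_deg
  expect_true(all(abs(dev_orbit[2:40] - 90) < 1.5))

  # invariance under rotation + translation of track and target
  set.seed(3)
  x <- cumsum(rnorm(30))
  y <- cumsum(rnorm(30))
  base <- angular_deviation(trajectory(1:30, x, y, c(5, 5)))
  ang <- 0.7
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  P <- cbind(x, y) %*% t(R)
  tg <- as.numeric(R %*% c(5, 5)) + c(3, -2)
  moved <- angular_deviation(trajectory(1:30, P[, 1] + 3, P[, 2] - 2, tg))
  expect_equal(moved$deviation_deg, base$deviation_deg, tolerance = 1e-9)
})

test_that("detect_reversals finds constructed about-faces and merges within the horizon", {
  # straight toward the target, one 180-degree about-face at t = 30
  tms <- seq(0, 60, by = 0.5)
  x <- ifelse(tms <= 30, 100 - tms, 70 + (tms - 30))
  one <- trajectory(tms, x, rep(0, length(tms)), c(0, 0))
  ev <- detect_reversals(angular_deviation(one), jump = 90, horizon = 1)
  expect_length(ev, 1)
  expect_lt(abs(ev - 30), 1.01)

  # monotone approach: no events
  mono <- trajectory(tms, 100 - tms, rep(0, length(tms)), c(0, 0))
  expect_length(detect_reversals(angular_deviation(mono)), 0)

  # two toward->away about-faces 30 s apart -> two events
  x2 <- ifelse(tms <= 20, 100 - tms,                       # toward
        ifelse(tms <= 35, 80 + (tms - 20),                 # away (reversal 1)
        ifelse(tms <= 50, 95 - (tms - 35), 80 + (tms - 50))))  # toward, away (reversal 2)
  two <- trajectory(tms, x2, rep(0, length(tms)), c(0, 0))
  ev2 <- detect_reversals(angular_deviation(two), jump = 90, horizon = 1)
  expect_length(ev2, 2)
  expect_lt(abs(ev2[1] - 20), 1.01)
  expect_lt(abs(ev2[2] - 50), 1.01)
})

test_that("pulse_phase_of_reversals assigns halves with ties to the second half", {
  tms <- seq(0, 100, by = 0.5)
  v <- ifelse(tms < 40, tms / 40, exp(-(tms - 40) / 10))
  trace <- calcium_trace("w", "AWA", tms, v)
  pulses <- data.frame(onset_time_s = 0, peak_time_s = 40, end_time_s = 100)
  dev <- data.frame(time_s = tms,
                    deviation_deg = ifelse(tms < 40, 10, 120))
  class(dev) <- c("deviation_series", "data.frame")

  out <- pulse_phase_of_reversals(trace, dev, events = c(40, 20, 70), pulses)
  expect_equal(out$events$phase, c("second", "first", "second"))
  expect_equal(out$halves$max_dev_first, 10)
  expect_equal(out$halves$max_dev_second, 120)

  # no reversals: defined, empty event table
  empty <- pulse_phase_of_reversals(trace, dev, numeric(0), pulses)
  expect_equal(nrow(empty$events), 0)
  expect_equal(nrow(empty$halves), 1)

  # event outside every pulse is labeled between-pulse
  out2 <- pulse_phase_of_reversals(trace, dev, events = 20,
                                   pulses[pulses$onset_time_s > 50, ])
  expect_equal(out2$events$phase, "between-pulse")
})
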