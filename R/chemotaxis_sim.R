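# Agent-based chemotaxis simulator contrasting the classical biased random
# walk (turn probability set by the sign of the sensed concentration change)
# with a strategy that additionally adapts to the magnitude of that change.

#' Spatial attractant field
#'
#' @param kind `"gaussian"` (a single odor source with a Gaussian plume,
#'   C(x) = C0 exp(-|x - source|^2 / (2 sigma^2))) or `"linear"`
#'   (C(x) = max(0, c0 + g . x)).
#' @param source Source coordinate (step-length units), default the origin.
#' @param C0 Peak concentration (arbitrary units), Gaussian kind.
#' @param sigma Gaussian width in step-length units.
#' @param slope Length-2 gradient vector, linear kind.
#' @param c0 Offset concentration at the origin, linear kind.
#' @return An object of class `gradient_field`.
#' @export
gradient_field <- function(kind = c("gaussian", "linear"),
                           source = c(0, 0), C0 = 1, sigma = 50,
                           slope = c(1, 0), c0 = 0) {
  kind <- match.arg(kind)
  if (kind == "gaussian") {
    stopifnot(C0 > 0, sigma > 0)
  }
  structure(list(kind = kind, source = as.numeric(source), C0 = C0,
                 sigma = sigma, slope = as.numeric(slope), c0 = c0),
            class = "gradient_field")
}

#' Concentration of a field at one or more positions
#'
#' @param field A [gradient_field()].
#' @param pos Length-2 position or an n x 2 matrix of positions.
#' @return Concentration(s), non-negative.
#' @export
field_conc <- function(field, pos) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 2)
  if (field$kind == "gaussian") {
    r2 <- (pos[, 1] - field$source[1])^2 + (pos[, 2] - field$source[2])^2
    field$C0 * exp(-r2 / (2 * field$sigma^2))
  } else {
    pmax(0, field$c0 + pos[, 1] * field$slope[1] + pos[, 2] * field$slope[2])
  }
}

#' Turning-strategy parameters
#'
#' @param p_plus Per-step turn probability when the sensed signal is
#'   non-negative (a zero signal counts as non-negative).
#' @param p_minus Per-step turn probability when the signal is negative.
#' @param adapt If `FALSE`, the classical biased random walk: turn with
#'   `p_plus` on non-negative changes, `p_minus` on negative ones. If
#'   `TRUE`, first-derivative adaptation: the `p_minus` rule is kept, but
#'   the `p_plus` turning budget is spent only at moments when the change
#'   falls below its exponential moving average (the gradient flattens);
#'   while the change keeps rising the walker runs without turning.
#' @param memory Adaptation memory in steps (EMA window M >= 1); irrelevant
#'   when `adapt = FALSE`.
#' @param sense_noise_sd SD of additive Gaussian noise on each sensed
#'   concentration (concentration units).
#' @param step_length Distance advanced per step (1 unit).
#' @param n_steps Number of steps per run.
#' @param capture_radius Distance from the source at which the run is deemed
#'   complete; steps after capture are excluded from scoring.
#' @return An object of class `strategy_params`.
#' @export
strategy_params <- function(p_plus, p_minus, adapt = FALSE, memory = 20,
                            sense_noise_sd = 0, step_length = 1,
                            n_steps = 1000, capture_radius = 5) {
  stopifnot(p_plus >= 0, p_plus <= 1, p_minus >= 0, p_minus <= 1,
            memory >= 1, n_steps >= 1, sense_noise_sd >= 0)
  structure(list(p_plus = p_plus, p_minus = p_minus, adapt = adapt,
                 memory = memory, sense_noise_sd = sense_noise_sd,
                 step_length = step_length, n_steps = n_steps,
                 capture_radius = capture_radius),
            class = "strategy_params")
}

#' One step of first-derivative adaptation
#'
#' The adaptation state is an exponential moving average of past
#' concentration changes; the effective signal is the current change minus
#' the (pre-update) average, so a sustained constant change is adapted away
#' and only increases in the derivative keep driving the signal.
#'
#' @param ema Current EMA of concentration changes.
#' @param delta_c Concentration change sensed this step.
#' @param M Memory in steps; the EMA update is ema + (delta_c - ema)/M.
#'   As M grows the signal reduces to the raw change.
#' @return List with `ema` (updated) and `signal` (delta_c minus the
#'   pre-update ema). Vectorized over agents.
#' @export
update_adaptation <- function(ema, delta_c, M) {
  stopifnot(M >= 1)
  signal <- delta_c - ema
  list(ema = ema + (delta_c - ema) / M, signal = signal)
}

#' Agent state for the simulator
#'
#' All fields are vectors over agents: positions `x`, `y`, `heading`
#' (radians), previously sensed concentration `prev_c`, adaptation state
#' `ema`, and `active` (FALSE once captured). `proj` carries the projection
#' of the last executed step onto the direct line to the source.
#'
#' @param n Number of agents.
#' @param start Length-2 start position (all agents).
#' @param field A [gradient_field()] used to initialize `prev_c`.
#' @return A list state; headings are drawn uniformly on \[0, 2 pi).
#' @export
init_agents <- function(n, start, field) {
  x <- rep(start[1], n)
  y <- rep(start[2], n)
  list(x = x, y = y,
       heading = stats::runif(n, 0, 2 * pi),
       prev_c = field_conc(field, cbind(x, y)),
       ema = numeric(n),
       active = rep(TRUE, n),
       proj = rep(NA_real_, n))
}

#' Advance all agents by one step
#'
#' Each agent senses the local concentration (plus optional noise) and forms
#' the concentration change since the last step. The classical walker turns
#' to a fresh uniform heading with probability `p_plus` when the change is
#' non-negative and `p_minus` when it is negative. The adaptive walker keeps
#' the `p_minus` correction on negative changes but maintains, in addition,
#' an exponential moving average of past changes ([update_adaptation()]):
#' while the change stays at or above that average (the derivative keeps
#' rising) it runs without turning, and it spends its `p_plus` turns exactly
#' at the moments the adapted signal lapses below zero -- the gradient is
#' flattening and a steeper heading may exist. With `p_plus = 0` the two
#' strategies coincide. After the turn decision every agent advances one
#' step length. Captured agents (within the capture radius of the source)
#' stop moving.
#'
#' @param state State list from [init_agents()].
#' @param strategy A [strategy_params()].
#' @param field A [gradient_field()].
#' @return The updated state; `state$proj` holds each active agent's step
#'   projection onto the unit vector toward the source (NA once captured).
#' @export
step_agent <- function(state, strategy, field) {
  n <- length(state$x)
  cc <- field_conc(field, cbind(state$x, state$y))
  if (strategy$sense_noise_sd > 0)
    cc <- cc + stats::rnorm(n, 0, strategy$sense_noise_sd)
  delta <- cc - state$prev_c
  state$prev_c <- cc
  if (strategy$adapt) {
    ad <- update_adaptation(state$ema, delta, strategy$memory)
    state$ema <- ad$ema
    # down-gradient: the deterministic corrector turns at p_minus, as in the
    # classical walker. Up-gradient, the p_plus turning budget is repurposed:
    # while the adapted signal is non-negative (the derivative keeps rising
    # relative to its recent history) the walker runs without turning, and it
    # spends its p_plus turns exactly when the signal lapses (the gradient
    # flattens), searching for a steeper path.
    pturn <- ifelse(delta < 0, strategy$p_minus,
                    ifelse(ad$signal < 0, strategy$p_plus, 0))
  } else {
    pturn <- ifelse(delta >= 0, strategy$p_plus, strategy$p_minus)
  }
  turn <- stats::runif(n) < pturn
  if (any(turn))
    state$heading[turn] <- stats::runif(sum(turn), 0, 2 * pi)
  dx <- cos(state$heading)
  dy <- sin(state$heading)
  offx <- field$source[1] - state$x
  offy <- field$source[2] - state$y
  dist <- sqrt(offx^2 + offy^2)
  proj <- (dx * offx + dy * offy) / dist
  proj[dist == 0] <- NA_real_
  state$proj <- ifelse(state$active, proj, NA_real_)
  L <- strategy$step_length
  state$x <- state$x + ifelse(state$active, dx * L, 0)
  state$y <- state$y + ifelse(state$active, dy * L, 0)
  offx <- field$source[1] - state$x
  offy <- field$source[2] - state$y
  state$active <- state$active &
    sqrt(offx^2 + offy^2) > strategy$capture_radius
  state
}

#' Simulate a cohort of agents under one strategy
#'
#' @param n Number of independent runs (agents).
#' @param strategy A [strategy_params()].
#' @param field A [gradient_field()].
#' @param start Start position; default 100 step-lengths from the source.
#' @param seed Optional integer seed (set locally; the caller's RNG state is
#'   restored).
#' @param return_paths If `TRUE`, also return the full position arrays
#'   (n_steps+1 x n); memory-heavy, meant for plotting a few tracks.
#' @return List with `score` (per-agent chemotaxis score: mean step
#'   projection onto the direct line to the source over pre-capture steps),
#'   `captured` (logical), `steps_to_capture` (NA when censored), and
#'   optionally `x`, `y`.
#' @export
simulate_cohort <- function(n, strategy, field,
                            start = field$source + c(100, 0),
                            seed = NULL, return_paths = FALSE) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  state <- init_agents(n, start, field)
  sumproj <- numeric(n)
  nproj <- integer(n)
  steps_cap <- rep(NA_integer_, n)
  if (return_paths) {
    X <- matrix(NA_real_, strategy$n_steps + 1, n)
    Y <- matrix(NA_real_, strategy$n_steps + 1, n)
    X[1, ] <- state$x
    Y[1, ] <- state$y
  }
  for (s in seq_len(strategy$n_steps)) {
    was_active <- state$active
    state <- step_agent(state, strategy, field)
    ok <- was_active & !is.na(state$proj)
    sumproj[ok] <- sumproj[ok] + state$proj[ok]
    nproj[ok] <- nproj[ok] + 1L
    newly <- was_active & !state$active
    steps_cap[newly] <- s
    if (return_paths) {
      X[s + 1, ] <- state$x
      Y[s + 1, ] <- state$y
    }
  }
  out <- list(score = sumproj / pmax(nproj, 1L),
              captured = !state$active,
              steps_to_capture = steps_cap)
  if (return_paths) {
    out$x <- X
    out$y <- Y
  }
  out
}

#' Chemotaxis score of a recorded trajectory
#'
#' The mean, over steps, of the cosine between the step displacement and the
#' unit vector from the step's start position to the source -- i.e. the mean
#' projection of the (unit) velocity on the optimal direct path. Steps taken
#' after first entering `capture_radius`, and zero-length steps, are
#' excluded.
#'
#' @param traj A [trajectory()] or an n x 2 position matrix.
#' @param source Length-2 source position (defaults to the trajectory
#'   target).
#' @param capture_radius Exclusion radius (default 0: keep every step).
#' @return Score in \[-1, 1\].
#' @export
chemotaxis_score <- function(traj, source = NULL, capture_radius = 0) {
  if (inherits(traj, "trajectory")) {
    if (is.null(source)) source <- traj$target
    P <- cbind(traj$x, traj$y)
  } else {
    P <- traj
  }
  stopifnot(!is.null(source), nrow(P) >= 2)
  n <- nrow(P)
  sx <- P[-n, 1]; sy <- P[-n, 2]
  ex <- P[-1, 1]; ey <- P[-1, 2]
  dx <- ex - sx; dy <- ey - sy
  step_len <- sqrt(dx^2 + dy^2)
  offx <- source[1] - sx
  offy <- source[2] - sy
  dist <- sqrt(offx^2 + offy^2)
  cosang <- (dx * offx + dy * offy) / (step_len * dist)
  keep <- step_len > 0 & dist > 0
  if (capture_radius > 0) {
    hit <- which(dist <= capture_radius)[1]
    if (!is.na(hit)) keep[hit:length(keep)] <- FALSE
  }
  if (!any(keep)) stop("no scorable steps")
  mean(cosang[keep])
}

# Deterministic substream seed for a grid cell, derived from the cell's
# probability values so results are independent of evaluation order and of
# which other cells are in the grid.
derive_seed <- function(seed, p_plus, p_minus) {
  i <- round(p_plus * 1e6)
  j <- round(p_minus * 1e6)
  as.integer((as.numeric(seed) * 48271 + i * 2097169 + j * 7907) %%
               2147483629) + 1L
}

#' Sweep turning probabilities for both strategies over a grid
#'
#' Runs `reps` agents per (p_plus, p_minus) cell for each requested strategy
#' and records the per-cell mean chemotaxis score. Every cell draws from its
#' own RNG substream derived from the master seed, and the two strategies
#' share a cell's substream (matched random numbers), so results do not
#' depend on evaluation order and the two strategies coincide exactly where
#' they are the same process (the `p_plus = 0` column).
#'
#' @param p_plus_grid,p_minus_grid Probability grids in \[0, 1\] (default 25
#'   evenly spaced values each, i.e. 625 cells).
#' @param reps Runs per cell per strategy (the study-scale figure uses 800,
#'   giving 5e5 runs per strategy).
#' @param strategies Subset of `c("classical", "adaptive")`.
#' @param field A [gradient_field()]; default the standard Gaussian arena
#'   (source at the origin, sigma 50, start 100 step-lengths out).
#' @param base A [strategy_params()] template supplying memory, noise, steps,
#'   capture radius.
#' @param seed Master integer seed.
#' @return An object of class `sim_result`: list with `scores` (named list
#'   of p_plus x p_minus matrices of mean scores), `p_plus_grid`,
#'   `p_minus_grid`, `reps`, `seed`.
#' @export
run_grid <- function(p_plus_grid = seq(0, 1, length.out = 25),
                     p_minus_grid = seq(0, 1, length.out = 25),
                     reps = 800,
                     strategies = c("classical", "adaptive"),
                     field = gradient_field("gaussian"),
                     base = strategy_params(0, 0),
                     seed = 1) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  stopifnot(all(p_plus_grid >= 0 & p_plus_grid <= 1),
            all(p_minus_grid >= 0 & p_minus_grid <= 1), reps >= 1)
  scores <- lapply(strategies, function(s)
    matrix(NA_real_, length(p_plus_grid), length(p_minus_grid),
           dimnames = list(signif(p_plus_grid, 4), signif(p_minus_grid, 4))))
  names(scores) <- strategies
  for (i in seq_along(p_plus_grid)) {
    for (j in seq_along(p_minus_grid)) {
      cell_seed <- derive_seed(seed, p_plus_grid[i], p_minus_grid[j])
      for (s in strategies) {
        strat <- base
        strat$p_plus <- p_plus_grid[i]
        strat$p_minus <- p_minus_grid[j]
        strat$adapt <- (s == "adaptive")
        res <- simulate_cohort(reps, strat, field, seed = cell_seed)
        scores[[s]][i, j] <- mean(res$score)
      }
    }
  }
  structure(list(scores = scores, p_plus_grid = p_plus_grid,
                 p_minus_grid = p_minus_grid, reps = reps, seed = seed),
            class = "sim_result")
}

#' Percent fold-improvement of the adaptive over the classical strategy
#'
#' 100 (adaptive - classical) / classical per grid cell. Cells where the
#' classical score is within `eps` of zero are masked (NA): there the ratio
#' diverges because the classical walker no longer makes progress (the
#' neighborhood of the p_plus = p_minus diagonal).
#'
#' @param adapt_grid,classic_grid Equal-shape matrices of mean scores.
#' @param eps Mask threshold on `abs(classic_grid)` (default 0.05).
#' @return Matrix of percentages with NA in masked cells.
#' @export
fold_improvement <- function(adapt_grid, classic_grid, eps = 0.05) {
  if (!all(dim(adapt_grid) == dim(classic_grid)))
    stop("grids must have the same shape")
  out <- 100 * (adapt_grid - classic_grid) / classic_grid
  out[abs(classic_grid) <= eps] <- NA_real_
  out
}

#' Paired comparison of the two strategies over grid cells
#'
#' One-sided Wilcoxon signed-rank test that the adaptive strategy's per-cell
#' mean score exceeds the classical one's across all grid cells.
#'
#' @inheritParams fold_improvement
#' @return As [wilcoxon_test()].
#' @export
compare_strategies <- function(adapt_grid, classic_grid) {
  if (length(adapt_grid) < 6) stop("need at least 6 paired cells")
  wilcoxon_test(as.vector(adapt_grid), as.vector(classic_grid),
                mode = "signed_rank_paired", side = "greater")
}

#' Closed-form per-step drift of the classical walker in a linear gradient
#'
#' For the classical strategy in a noise-free linear field, the heading is a
#' Markov renewal process: a heading theta is held for a geometric number of
#' steps with mean 1/q(theta), where q = p_plus while moving up-gradient
#' (cos theta >= 0) and p_minus while moving down-gradient. Weighting a
#' uniform new-heading distribution by the holding time gives the stationary
#' per-step drift along the gradient
#' (2/pi) (p_minus - p_plus) / (p_minus + p_plus)
#' (0 when both probabilities vanish). With p_plus = 0, up-gradient headings
#' are absorbing and the same expression gives the limit 2/pi.
#'
#' @param p_plus,p_minus Turn probabilities.
#' @return Expected drift per step along the gradient direction, in step
#'   lengths.
#' @export
linear_drift_oracle <- function(p_plus, p_minus) {
  if (p_plus == 0 && p_minus == 0) return(0)
  (2 / pi) * (p_minus - p_plus) / (p_minus + p_plus)
}

#' Monte Carlo drift of the classical walker in a linear gradient
#'
#' Companion measurement to [linear_drift_oracle()]: simulates independent
#' classical walkers in a linear field and reports the mean per-step
#' displacement along the gradient with its standard error (over agents).
#'
#' @param p_plus,p_minus Turn probabilities.
#' @param n_agents Number of independent walkers.
#' @param n_steps Steps per walker.
#' @param seed Integer seed.
#' @return List with `drift`, `se`, `n_steps_total`.
#' @export
measure_linear_drift <- function(p_plus, p_minus, n_agents = 200,
                                 n_steps = 1000, seed = 1) {
  # large offset keeps concentrations positive however far a walker drifts
  field <- gradient_field("linear", slope = c(1, 0), c0 = 1e6,
                          source = c(1e9, 0))
  strat <- strategy_params(p_plus, p_minus, adapt = FALSE,
                           n_steps = n_steps, capture_radius = 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  state <- init_agents(n_agents, c(0, 0), field)
  x0 <- state$x
  for (s in seq_len(n_steps)) state <- step_agent(state, strat, field)
  per_agent <- (state$x - x0) / n_steps
  list(drift = mean(per_agent),
       se = stats::sd(per_agent) / sqrt(n_agents),
       n_steps_total = n_agents * n_steps)
}
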