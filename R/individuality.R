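# Pulse-individuality shuffle test: is the within-worm spread of pulse
# parameters smaller than expected if pulses were exchangeable across worms?

ind_param_column <- function(parameter) {
  switch(parameter,
         amplitude = "amplitude",
         tau = "tau_s",
         peak_to_peak = "interval_s",
         stop("unknown parameter `", parameter, "`"))
}

ind_extract <- function(pulses, parameter) {
  col <- ind_param_column(parameter)
  if (!col %in% names(pulses)) stop("pulse table lacks column `", col, "`")
  v <- pulses[[col]]
  g <- as.character(pulses$worm_id)
  ok <- !is.na(v)
  v <- v[ok]
  g <- g[ok]
  sizes <- table(g)
  keep <- names(sizes)[sizes >= 2]
  if (length(keep) < length(sizes))
    warning(sum(!(g %in% keep)), " pulse(s) from worms with <2 pulses excluded")
  if (length(keep) < 2) stop("need at least 2 worms with >= 2 pulses")
  sel <- g %in% keep
  list(values = v[sel], groups = factor(g[sel]))
}

grouped_mean_sd <- function(values, groups, sizes) {
  s1 <- rowsum(values, groups)
  s2 <- rowsum(values^2, groups)
  vr <- (s2 - s1^2 / sizes) / (sizes - 1)
  mean(sqrt(pmax(vr, 0)))
}

#' Mean within-worm standard deviation of a pulse parameter
#'
#' For each worm with at least two pulses, the sample standard deviation
#' (n - 1 denominator) of the chosen parameter is computed; the statistic is
#' the mean of these per-worm SDs. Worms with fewer than two pulses are
#' excluded with a warning.
#'
#' @param pulses Pulse table with columns `worm_id` and the parameter column
#'   (`amplitude`, `tau_s`, or `interval_s`).
#' @param parameter One of `"amplitude"`, `"tau"`, `"peak_to_peak"`.
#' @return The mean within-worm SD (same units as the parameter).
#' @export
mean_within_worm_sd <- function(pulses, parameter = c("amplitude", "tau",
                                                      "peak_to_peak")) {
  parameter <- match.arg(parameter)
  d <- ind_extract(pulses, parameter)
  sizes <- as.numeric(table(d$groups))
  grouped_mean_sd(d$values, d$groups, sizes)
}

#' Shuffle test for individuality of pulse parameters
#'
#' Tests whether pulses from the same worm are more alike than pulses drawn
#' at random from the pooled population. All pulses are shuffled between the
#' worms, preserving each worm's original pulse count; for each shuffle the
#' mean within-worm SD is recomputed, and the one-sided p-value asks how often
#' a shuffle is at least as *small* as the observed statistic (small observed
#' spread = individuality). The add-one correction
#' p = (1 + #\{null <= observed\}) / (n_shuffles + 1) keeps p strictly
#' positive.
#'
#' @inheritParams mean_within_worm_sd
#' @param n_shuffles Number of random shuffles (the study-scale analysis used
#'   1e6; 1e4 is ample for p-values down to ~1e-4).
#' @param seed Integer seed; results are reproducible given
#'   (data, n_shuffles, seed).
#' @return An object of class `shuffle_test`: list with `parameter`,
#'   `observed_mean_sd`, `null_mean_sds`, `p_value`, `n_shuffles`, `seed`,
#'   `n_pulses`, `n_worms`.
#' @export
shuffle_individuality_test <- function(pulses,
                                       parameter = c("amplitude", "tau",
                                                     "peak_to_peak"),
                                       n_shuffles = 10000, seed = 1) {
  parameter <- match.arg(parameter)
  stopifnot(n_shuffles >= 1)
  d <- ind_extract(pulses, parameter)
  v <- d$values
  g <- d$groups
  sizes <- as.numeric(table(g))
  observed <- grouped_mean_sd(v, g, sizes)
  null <- numeric(n_shuffles)
  N <- length(v)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (s in seq_len(n_shuffles))
    null[s] <- grouped_mean_sd(v[sample.int(N)], g, sizes)
  p <- (1 + sum(null <= observed)) / (n_shuffles + 1)
  structure(list(parameter = parameter, observed_mean_sd = observed,
                 null_mean_sds = null, p_value = p,
                 n_shuffles = n_shuffles, seed = seed,
                 n_pulses = N, n_worms = nlevels(g)),
            class = "shuffle_test")
}

#' @export
print.shuffle_test <- function(x, ...) {
  cat("Pulse-individuality shuffle test\n")
  cat(sprintf("  parameter: %s (%d pulses, %d worms)\n",
              x$parameter, x$n_pulses, x$n_worms))
  cat(sprintf("  observed mean within-worm SD: %.4g\n", x$observed_mean_sd))
  cat(sprintf("  null mean (SD): %.4g (%.4g), %d shuffles, seed %d\n",
              mean(x$null_mean_sds), stats::sd(x$null_mean_sds),
              x$n_shuffles, x$seed))
  cat(sprintf("  one-sided p (observed low): %.3g\n", x$p_value))
  invisible(x)
}

# Save/restore the global RNG state so seeded helpers do not disturb callers.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}
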