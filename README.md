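# pulsetaxis

Analysis of pulsatile chemosensory coding in smooth chemical gradients,
and simulation of the navigation strategy it supports.

*C. elegans* senses attractive odorants such as diacetyl through a pair of
complementary chemosensory neurons: AWA responds to rising concentrations
with discrete calcium pulses (sharp rise, exponential decay
A·e^(−t/τ)) whose rate and amplitude track — and adapt to — the magnitude
of the gradient's first derivative, while AWC^ON responds robustly and
gradedly to falling concentrations. `pulsetaxis` provides the
computational toolchain for studying this coding scheme end to end:

- **Stimulus design** — analytic gradient shapes (step, linear ramp,
  hyperbolic tangent, sinusoid, exponentially accelerating ramp), the
  stirred mixing-chamber model dC/dt = (Q/V)(C_in − C), and its inversion
  into feasible pump schedules (`generate_profile()`, `chamber_output()`,
  `design_mixing_schedule()`).
- **Pulse analytics** — prominence-based pulse detection and
  Levenberg–Marquardt fitting of A·e^(−t/τ) with a rise-completion anchor
  and a tail-pinned baseline (`detect_pulses()`, `extract_pulses()`,
  `half_decay_time()`, `pulse_metrics()`).
- **Individuality** — a shuffle test for whether pulses of one animal are
  more alike than pulses drawn from the pooled population, with the
  Phipson–Smyth add-one correction
  (`shuffle_individuality_test()`).
- **Adaptation & behavior** — mean activity before vs after the point of
  maximal stimulus derivative, pulse–derivative correlations, trajectory
  smoothing, angular deviation to a target, reversal detection and their
  phase within pulses (`pre_post_midpoint_means()`, `angular_deviation()`,
  `detect_reversals()`, `pulse_phase_of_reversals()`).
- **Chemotaxis simulation** — an agent-based contrast of the classical
  biased random walk (turn with probability P+ on rising, P− on falling
  concentration) with a first-derivative-adaptation strategy that keeps the
  P− correction but spends its P+ turns exactly when the sensed derivative
  lapses below its running average (`run_grid()`, `fold_improvement()`,
  `compare_strategies()`, `linear_drift_oracle()`).
- **Synthetic data** — seeded generators for worm-specific pulsatile
  signatures, adaptive/non-adaptive derivative-driven pulsers, graded
  off-responses, and pulse-gated walkers, each emitting its ground truth
  (`synth_pulse_cohort()`, `synth_adaptive_trace()`, `synth_awc_trace()`,
  `synth_pulse_gated_trajectory()`).

## Worked example

Generate a 10-worm cohort of pulsatile traces, recover every pulse, and
test for individuality:

```r
library(pulsetaxis)

cohort <- synth_pulse_cohort(n_worms = 10, seed = 1)
pulses <- do.call(rbind, lapply(cohort$traces, extract_pulses))
head(pulses[, c("worm_id", "peak_time_s", "amplitude", "tau_s")], 3)
#>   worm_id peak_time_s amplitude tau_s
#> 1  worm01        30.0      1.51  13.8
#> 2  worm01        80.7      1.53  12.3
#> 3  worm01       122.1      1.42  12.3

shuffle_individuality_test(pulses, "amplitude", n_shuffles = 10000, seed = 1)
#> Pulse-individuality shuffle test
#>   parameter: amplitude (97 pulses, 10 worms)
#>   observed mean within-worm SD: 0.2067
#>   null mean (SD): 1.029 (0.03772), 10000 shuffles, seed 1
#>   one-sided p (observed low): 0.0001
```

The observed within-worm spread (0.21 a.u.) is a fifth of what shuffling
pulses between worms produces (1.03 a.u.), and no shuffle in 10<sup>4</sup>
got that low: each animal keeps a private pulsatile signature.

Compare the two navigation strategies on a corner of the turning
probability grid (200 runs per cell; the full study-scale sweep uses
`run_grid()` defaults, 25 × 25 × 800):

```r
g <- run_grid(p_plus_grid = c(0.05, 0.2), p_minus_grid = c(0.5, 0.9),
              reps = 200, seed = 1)
round(g$scores$classical, 3)
#>        0.5   0.9
#> 0.05 0.462 0.524
#> 0.2  0.257 0.391
round(g$scores$adaptive, 3)
#>        0.5   0.9
#> 0.05 0.560 0.569
#> 0.2  0.535 0.606
round(fold_improvement(g$scores$adaptive, g$scores$classical), 1)
#>        0.5  0.9
#> 0.05  21.4  8.7
#> 0.2  108.0 55.0
```

The chemotaxis score is the mean projection of the step velocity on the
direct line to the source (+1 = beeline to the target). Repurposing the
P+ turning budget to the moments the gradient flattens improves the score
in every cell — most dramatically where indiscriminate turning on rising
gradients (P+ = 0.2) cripples the classical walker.

See the vignette (`vignettes/derivative-adaptation-chemotaxis.Rmd`) for
the models, parameter choices, and what the synthetic-data results do and
do not establish.

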