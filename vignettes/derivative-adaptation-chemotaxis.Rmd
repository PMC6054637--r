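---
title: "Pulsatile coding, derivative adaptation, and chemotaxis strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulsatile coding, derivative adaptation, and chemotaxis strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsetaxis)
```

# Scope

`pulsetaxis` analyzes how chemosensory neurons encode smooth chemical
gradients and what that coding buys a navigating animal. The package covers
five connected pieces:

1. **Stimulus design** -- target gradient shapes (steps, ramps, hyperbolic
   tangents, sinusoids, exponentially accelerating ramps), a model of the
   stirred mixing chamber that delivers them, and inversion of that model
   into pump schedules.
2. **Pulse analytics** -- detection of calcium transients (sharp rise,
   exponential decay) and estimation of their amplitude and decay constant.
3. **Individuality statistics** -- a permutation test asking whether pulses
   from one animal are more alike than pulses pooled across animals.
4. **Adaptation and behavior** -- before/after statistics around the point
   of maximal stimulus derivative, pulse-derivative correlations, and
   trajectory analytics (angular deviation to a target, reversal events,
   their phase within a pulse).
5. **Chemotaxis simulation** -- an agent-based comparison of the classical
   biased random walk against a strategy that adapts to the magnitude of
   the gradient's first derivative.

Because no imaging data ship with the package, a seeded synthetic-data
module generates traces and trajectories with the statistical structure
each analysis assumes; every generator returns its ground truth so tests
can close the loop.

# The mixing-chamber model

Two syringe pumps feed a stirred chamber of volume $V$ (50 or 200 uL) at
combined flow $Q$: one line carries the odorant (diacetyl) at $C_{stim}$,
the other buffer at $C_{buf}$. A well-stirred compartment obeys

$$\frac{dC}{dt} = \frac{Q}{V}\bigl(C_{in}(t) - C(t)\bigr),$$

so the chamber is a first-order low-pass filter of the inflow. The
integrator in `chamber_output()` advances this ODE with the exact
exponential update for piecewise-linear inflow; it is therefore exact for
steps and constants and has error $O(\Delta t^3 C_{in}'')$ for smooth
profiles at the 1.4 Hz grids used throughout -- a stiff-safe choice with no
tuning parameters, which is why no general-purpose ODE solver is involved.

Inverting the model gives the stimulus fraction the pumps must deliver,

$$f(t) = \frac{(V/Q)\,\dot C(t) + C(t) - C_{buf}}{C_{stim} - C_{buf}},$$

and a target is feasible exactly when $f$ stays in $[0, 1]$: gradients that
rise faster than the chamber can follow (or fall faster than dilution
allows) are rejected by `design_mixing_schedule()` with the first violating
time. The design round trip (schedule back through the chamber) reproduces
feasible hyperbolic-tangent and sinusoid targets to better than $10^{-4}$
of their range, which the test suite checks on randomized parameters.

A known physical effect deliberately not modeled: early in a real
experiment a small amount of cue diffuses ahead of its scheduled arrival
(a start-of-run artifact only), so measured onsets can lead the model by up
to a minute. This does not affect gradients later in a run.

# Pulse detection and decay fitting

Traces are min-max normalized per neuron for display statistics
(`normalize_trace()`), and pulses are fitted as $A e^{-t/\tau}$ from the
pulse apex. Choices that required judgment:

* **Detection** uses topographic prominence (threshold 0.2 of the trace
  range by default) with a 10 s minimum separation, reflecting pulse
  durations of tens of seconds. The original analyses marked pulses by
  hand; an automated pipeline needs a rule, and prominence is robust to
  slow baseline drift. Both parameters are exposed.
* **Baseline** is the median of the samples preceding the pulse onset (the
  trace minimum between successive peaks); the window is 5 samples by
  default and should be widened on clean, stationary recordings.
* **Fit anchor.** The decay fit is anchored at the rise-completion sample
  (first sample reaching 80% of the peak prominence), not the raw argmax.
  Under noise the argmax is a selected extreme -- it sits a sample late
  with appreciable probability and carries positive noise -- which biases
  the fitted amplitude low; the rise-completion anchor removes that bias.
* **Fit window and offset.** By default the fit runs to the next pulse
  onset and co-estimates a residual baseline constant
  ($y = A e^{-t/\tau} + c$). A pure exponential fitted after subtracting a
  noisy baseline estimate inherits that error in a strongly
  $\tau$-distorting way; letting the flat tail pin the offset restores the
  estimator to its Cramer-Rao floor. The strict two-parameter form with a
  window cut at 10% of the amplitude remains available
  (`fit_offset = FALSE`).
* **Initialization** is a log-linear regression on the positive window
  samples, refined by Levenberg-Marquardt least squares; log-linear alone
  is biased under additive noise.

With these defaults, noiseless synthetic pulses are recovered to machine
precision, and at noise of 5% of the amplitude, pulses with decay
constants of tens of seconds sampled at 1.4-2 Hz are recovered within 5%
in well over 95% of seeded fixtures. That 5% target is close to the
information-theoretic limit at these settings: the Cramer-Rao bound for
$\hat\tau$ at $\tau \approx 10$ s, 1.4 Hz and 5% noise is itself ~4% per
pulse, so recovery claims are only meaningful for the slower pulses the
recovery tests use.

The half-decay time is $t_{1/2} = \tau \ln 2$ (`half_decay_time()`), with
an empirical grid-crossing variant for traces where the exponential form is
in doubt.

Per-worm pulse metrics follow the printed normalization
$(x - \min x)/\max x$ -- note the denominator is the maximum, **not** the
range, so the largest pulse maps to $1 - \min/\max$, not to 1. The same
normalization applies to peak-to-peak intervals.

# The individuality shuffle test

Each worm with at least two pulses contributes the sample standard
deviation of a pulse parameter; the statistic is the mean of these
within-worm SDs. The null hypothesis -- pulses are exchangeable across
worms -- is simulated by shuffling all pulse values between worms while
preserving each worm's pulse count. The one-sided p-value asks how often a
shuffle produces a statistic at least as *small* as observed, with the
add-one correction $p = (1 + \#\{null \le obs\})/(n_{shuffles} + 1)$ so
permutation p-values never reach zero. Sample SDs use the $n-1$
denominator. The test is exact against an enumeration oracle on tiny
cases, calibrated (uniform p under exchangeable pulses), and on
10-worm/~92-pulse cohorts generated with worm-specific signatures it
reaches the minimum attainable p at $10^4$ shuffles; at the study scale of
$10^6$ shuffles the same construction reaches the $10^{-6}$ regime.

# Derivative adaptation in traces

For a sigmoidal (tanh) gradient the first derivative is symmetric about
the midpoint, so a neuron that codes the instantaneous derivative should be
equally active in the 2.5 min before and after it.
`pre_post_midpoint_means()` computes exactly those two means (the midpoint
sample itself belongs to neither window; windows must cover at least half
their nominal span). Adaptation to the derivative's magnitude shows up as
before > after. The paired comparison uses the Wilcoxon signed-rank test
(`wilcoxon_test()`), exact by enumeration for up to 25 informative pairs
without ties, normal approximation with continuity correction otherwise;
zero differences are dropped and an all-zero comparison is an error.

The synthetic adaptive pulser drives an inhomogeneous pulse process at rate
and amplitude proportional to $\max(0, s(t))$ with $s = \dot C$ (adaptation
off) or $s = \dot C - \mathrm{EMA}(\dot C)$ (adaptation on; EMA timescale
150 s, several pulses long). Cohorts of 17 adapting worms reproduce the
before > after asymmetry in at least 15 of 17 animals with signed-rank
p < 0.05, while non-adapting cohorts stay quiet in at least 90% of runs --
the negative control that the statistic does not manufacture asymmetry.
The pulse process uses per-sample Bernoulli thinning with a refractory
period equal to the pulse's 10%-decay time, so fitted decays do not
overlap.

Pulse-derivative correlations (`pulse_derivative_correlation()`) pool
per-worm-normalized amplitudes (or intervals) against the stimulus
derivative at pulse peak times; Pearson's r is the default (the original
report gives "r" without further qualification) with Spearman as an
option.

# Trajectory analytics

Tracks are smoothed per coordinate with a penalized least-squares spline
(`smooth_track()`; generalized cross-validation picks the penalty by
default, matching the head-swing-suppression role of spline smoothing in
worm tracking). The angular deviation is the angle between the
central-difference velocity and the direct line from the current position
to the target: 0 means heading straight at the target, ~180 means moving
away, and an abrupt increase marks a reversal. `detect_reversals()`
declares an event when the deviation rises by at least 90 degrees within
1 s (both thresholds are conventions, exposed as parameters; no published
figure pins them). `pulse_phase_of_reversals()` splits each pulse at its
peak -- events exactly at the peak count as the decaying half -- and
reports the maximal deviation per half plus the normalized activity level
at each event. The pulse-gated synthetic walker (runs while its pulse is
above 58% of peak, about-faces when the pulse decays through that level)
places every reversal in the decaying phase, and `detect_reversals()`
recovers the emitted times within one sample.

# The chemotaxis simulator

Agents move with unit steps in a radial Gaussian attractant field
($C_0 = 1$, $\sigma = 50$ step-lengths, source at the origin), starting
100 step-lengths out, for 1000 steps or until within the capture radius
(5). Each step the agent senses the local concentration (optionally with
additive Gaussian noise) and forms the change $\Delta C$ since its last
step.

* **Classical biased random walk:** turn (new heading uniform on
  $[0, 2\pi)$) with probability $P_+$ when $\Delta C \ge 0$ and $P_-$ when
  $\Delta C < 0$.
* **First-derivative adaptation:** the $P_-$ correction on negative
  changes is kept unchanged. On non-negative changes the agent consults an
  exponential moving average $E$ of past changes (memory $M = 20$ steps;
  update $E \leftarrow E + (\Delta C - E)/M$, signal $\Delta C - E$ with
  the pre-update average): while the signal is non-negative -- the
  derivative keeps rising relative to its history -- it runs without
  turning, and it spends its $P_+$ turns exactly at signal lapses, when
  the gradient it rides begins to flatten and a steeper heading may exist.

This operationalizes pulsatile coding with derivative adaptation: the
sensor's activity (rising derivative) gates runs; its adaptation-driven
lapses license exploratory turns; the deterministic off-response corrects
outright descents. Note the repurposing structure: both strategies own the
same two turn probabilities, but the adaptive walker redistributes its
$P_+$ budget from "uniformly while ascending" to "exactly when ascent
degrades". At $P_+ = 0$ the two strategies are one and the same process --
the fold-improvement is identically zero on that one grid edge, which is
the honest reading of "improvement throughout the parameter space" for a
budget-repurposing strategy.

The per-run chemotaxis score is the mean projection of the unit step
vector on the direct line from the agent's current position to the source,
over pre-capture steps -- +1 for a beeline to the source, -1 for a
beeline away, ~0 for an isotropic walk. The instantaneous-bearing
definition is the default; scoring against the fixed start-to-source chord
is available through `chemotaxis_score()` on recorded paths.

`run_grid()` sweeps a 25 x 25 grid over $(P_+, P_-) \in [0,1]^2$ with 800
runs per cell per strategy by default ($5 \times 10^5$ runs per strategy).
Each cell owns an RNG substream derived from the master seed and the
cell's probability values, shared by the two strategies: results are
independent of evaluation order and sub-grids reproduce the corresponding
cells of larger grids bitwise. Fold improvement is
$100 (S_{adapt} - S_{classic})/S_{classic}$ with cells masked where
$|S_{classic}| \le 0.05$: near the $P_+ = P_-$ diagonal the classical
walker no longer makes progress and the ratio diverges.

Under these defaults the adaptive strategy's mean score exceeds the
classical one's in every unmasked cell with $P_+ > 0$ at 800 reps, the
paired signed-rank p over all cells is far below $10^{-70}$, and for
$P_- \ge 0.8$ the best $P_+$ is strictly positive -- occasional
exploratory turns pay exactly when the correction mechanism behind them is
reliable. These are the three grid-level properties the acceptance suite
asserts.

For linear gradients the classical walker admits a closed form. A heading
$\theta$ is held for a geometric number of steps with mean $1/q(\theta)$,
$q = P_+$ up-gradient and $P_-$ down-gradient; weighting uniform headings
by holding time gives the stationary per-step drift along the gradient

$$v = \frac{2}{\pi}\,\frac{P_- - P_+}{P_- + P_+},$$

with $v = 2/\pi$ in the absorbing limit $P_+ = 0$ and $v = 0$ at
$P_+ = P_-$. Simulated drift agrees within three standard errors at the
tested parameter pairs; the oracle also provides the monotonicity scan
used in testing.

# Synthetic data: what it does and does not establish

The generators emulate the *statistical structure* the analyses assume:
lognormal between-worm signatures with smaller within-worm spread
(individuality), derivative-driven pulse rates with optional EMA
adaptation, a graded off-channel anti-correlated with the derivative, and
pulse-gated locomotion. Defaults: 10 worms with Poisson(9.2) pulses each
(~92 pulses per cohort), amplitude scale 2 a.u., decay scale 10 s,
between-worm CV 0.45 versus within-worm CV 0.10, sampling at 1.4 Hz.
Neither CV is quantified in print; they were chosen once so that
individual-mode cohorts are clearly individual and pooled-mode cohorts are
exchangeable, and the tests vary them only through the two modes.

Passing recoveries on these generators show the *pipeline* is correct --
that each analysis detects the structure it targets and stays quiet on
matched negative controls. They do not show that real recordings contain
that structure, and the generators deliberately omit known features of
real data: indicator (GCaMP) nonlinearity and bleaching, motion artifacts,
baseline drift, correlated noise, and left/right neuron asymmetry.
Wet-data quantities from the original study (correlation coefficients,
half-decay times, the 58% turn threshold) are consequently not reproduced
numerically anywhere in this package; where a generator needs such a value
(the 0.58 gating threshold, the anti-correlation regime) it is built in as
a construction parameter, not recovered as a finding.

# Numerical and design notes

* Times are seconds and concentrations micromolar everywhere; the
  simulator works in dimensionless step-length units.
* Profiles must live on uniform grids; non-uniform traces are resampled to
  the median interval with a warning; duplicate timestamps are errors.
* A zero signal ties to the non-turning/non-negative branch everywhere
  (`signal >= 0` uses $P_+$; a reversal exactly at a pulse peak belongs to
  the decaying half).
* The adaptation state starts at 0, which makes the first sensed change
  read as a full signal; with the default memory this transient is ~20
  steps of 1000.
* Problem sizes in the tests: the full 25 x 25 x 800 grid runs once and is
  shared by the three grid-level checks (about seven minutes on one core);
  scaled checks use 10 x 10 x 200. Null calibrations use 500 cohorts at 99
  shuffles; power checks use $10^4$ shuffles.
* `wilcox.test()` provides the Wilcoxon machinery; the package fixes the
  exact-versus-approximate policy and the error contract. The enumeration
  oracle in the test suite is independent of it.

# Limitations

* The exact turn-kernel and update rules of the original simulation are
  not published in the main text; the rules here follow the mechanism as
  described (gating, adaptation, deterministic correction) and all
  divergences sit behind `strategy_params()`.
* Pulse detection is automated where the original analysis was manual;
  prominence thresholds are a proxy for expert judgment and should be
  tuned per dataset.
* The chamber model is a single well-stirred compartment; tubing delay and
  dispersion are not modeled beyond the documented start-of-run caveat.
* The amplitude/decay estimator assumes non-overlapping pulses; heavily
  overlapping transients would need deconvolution, out of scope here.
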