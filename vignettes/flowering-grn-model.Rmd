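---
title: "Modelling the flowering-time gene network from expression time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the flowering-time gene network from expression time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

flornet models the core gene network that commits a plant shoot meristem to
flowering: the mobile activator FT (five homologs in chickpea — FTa1, FTa2,
FTa3, FTb, FTc — produced in leaves), the floral repressors TFL1a and TFL1c,
the scaffold transcription factor FD, and the meristem-identity genes LFY
and AP1 whose rise marks the decision to flower. Expression is observed as
relative transcript level (arbitrary units) versus days after sowing, under
short-day (SD) and long-day (LD) photoperiods, and protein concentration is
taken proportional to transcript level.

Five ordinary differential equations describe the targets; all regulation
is through normalized Hill functions (activator `x^n / (K^n + x^n)`,
repressor `K^n / (K^n + x^n)`):

* TFL1a and TFL1c are each produced at a maximal rate v repressed by AP1
  (`v1, K1, n1, lambda1` and `v2, K2, n2, lambda2`), with first-order
  decay.
* FD is activated by LFY (`v3, K3, n3, lambda3`).
* LFY receives additive activating inputs from AP1 (`v4, K4, n4`) and from
  the FT–FD complex, gated multiplicatively by repression from the TFL1–FD
  complex (`K5, n5`); decay `lambda4`.
* AP1 mirrors LFY with inputs from LFY (`v5, K6, n6`) and FT–FD, gated by
  TFL1–FD repression (`K7, n7`); decay `lambda5`.

Complex concentrations are products of their parts: the TFL1–FD complex is
`u_FD * (u_TFL1a + u_TFL1c)`, and the FT–FD complex uses the FT
concentration evaluated with a transport delay `tau` (days), representing
movement of FT protein from leaf to meristem. No separate binding kinetics
are modelled.

A deliberate feature inherited from the data-driven approach: every
regulator on a right-hand side is an interpolant of the *observed* data,
not the solved state. Each equation is therefore linear in its own state,
and the 31-parameter system splits into four parameter-disjoint parts —
TFL1a, TFL1c and FD alone, and LFY+AP1 jointly (they share `tau`). The
package exploits this throughout: subsystems are fitted independently and
the public solver cross-checks against a joint integration.

### Competing FT-activation schemes

Three hypotheses describe how the five FT homologs act on LFY and AP1:

* **H0** (baseline): regulatory equivalence — one Hill activator of
  `u_FD * sum of all FT concentrations` with constants `v6, K8, n8` (LFY)
  and `v7, K9, n9` (AP1). 31 free parameters.
* **H1**: a single homolog carries the whole activation; same parameter
  count.
* **H2**: one homolog is singled out with its own constants while the other
  four act cumulatively; two extra Hill terms add six parameters (37).

FTa3 is excluded from the screened candidates by default because its
expression is negligible compared to the other homologs.

## Fitting

The objective is the weighted residual sum of squares over the five target
genes at the observed times, `sum(((u_model - u_data) / sd)^2)`, summed
over SD and LD when both are fit; a configurable variant adds the
covariance between model and data per series (weight 1 by default). The
covariance penalty is implemented exactly as stated in its source, although
a *positive* model–data covariance would ordinarily be desirable; the sign
convention is therefore exposed in the configuration and flagged here.

Minimization uses differential evolution (best/1/bin, dithered mutation
factor in [0.5, 1], crossover 0.7, population 15 per dimension by default)
inside data-scale-aware boxes: K in `[0.01, 100]` times the relevant
regulator's maximum, v up to 10 times the target's level times the maximal
decay rate, n in [1, 8], lambda in [0.001, 5] per day, tau in [0, 5] days.
An optional Nelder–Mead polish refines the best member. Because the model
is data-driven, the inner integrator can be exact-in-state: on a uniform
grid with the forcing taken piecewise linear, `u' = s(t) - lambda u` has a
closed-form update, implemented in compiled code. The public
`solve_grn()` defaults to the stiff-capable `lsoda` and agrees with an
independently written fixed-step RK4 oracle to 1e-4 relative in the test
suite.

The *ensemble* approach repeats the fit from independent seeds and treats
all converged parameter sets as equally valid descriptions; conclusions are
drawn from distributions over the ensemble, never from a single best fit.
`fit_ensemble()` retains every member unfiltered.

### Identifiability, and why cooperativity is special

On sparse, noisy series (7 points per condition, 5% noise) the triple
(v, K, n) of a single Hill edge is nearly ridge-shaped: a larger K with a
larger n and rescaled v reproduces the observed arc within noise. We
verified this directly: a converged global search on synthetic data from a
known truth returns K values up to a factor 2 from truth with the exponent
drifting to compensate, at a cost statistically indistinguishable from the
truth's. Treating the Hill exponent as a discrete structural choice
(`integer_n = TRUE`, exponents rounded during the search) removes the
continuous ridge direction and makes the half-saturation constants
identifiable in the regime where published ensemble clusters report integer
exponents with very tight K spreads. The recovery experiments in the
acceptance suite therefore run in integer-exponent mode; continuous
exponents remain the default for data analysis, where honesty about the
ridge matters more than a point estimate.

## Model comparison

Each hypothesis is scored by the small-sample-corrected Akaike criterion
computed from the ensemble-minimum cost,
`AICc = 2k + wRSS_min + (2k^2 + 2k)/(m - k - 1)` under the convention
`2 log L = -wRSS_min`; a classical Gaussian least-squares variant
(`-2 log L = m log(wRSS_min / m)`) is also provided. The correction term
diverges as k approaches m - 1 — with m = 35 single-condition points the
37-parameter H2 cannot be scored at all, which is why screens are run on
the joint two-condition data (m = 70). Cost distributions of competing
hypotheses are compared with a two-sided Mann–Whitney test by default
(robust to the skewed cost distributions DE produces; Welch's t-test is
available). AICc is reported relative to H0 both as a ratio (the
"normalized to H0" reading) and as a difference, since ratios of AICc are
unconventional; both components are exposed so the reader can see whether a
ratio is driven by fit quality or by the complexity term.

## Ensemble diagnostics

* `average_regulation_functions()` integrates each dimensionless Hill
  factor over the observed window (trapezoid rule, SD and LD averaged
  arithmetically) per ensemble member. Values pinned near 0 or 1 mean the
  target is insensitive to that regulator: the edge is *saturated* and its
  parameters are not identifiable. The thresholds 0.05/0.95 are
  configurable conventions, not published constants.
* `jacobian_sensitivity()` reports the time-averaged absolute derivative
  of the target's right-hand side with respect to a regulator, computed
  analytically from the Hill forms (verified against central differences).
  An edge can show a near-zero averaged regulation function while the
  Jacobian still reveals responsiveness, and vice versa.
* `cluster_parameters()` partitions members into a "main" and an
  "outlying" cluster by the boxplot convention (beyond 1.5 IQR on the
  averaged-regulation-value axis of the parameter's edge) and compares
  main-cluster values of two parameters (Welch's test by default), the
  procedure behind asking whether AP1 regulates TFL1a and TFL1c with
  different binding constants (K1 versus K2).

## The synthetic-data generator

Scenarios define a generating hypothesis, a true parameter set, logistic FT
driver curves per condition (`level / (1 + exp(-steepness (t - onset)))`),
seven observation days (8 to 20, every 2 days; m = 70 over two conditions)
and a noise model `sd = max(0.05 u, 0.005 max(u))` — 5% observation noise
with a small floor that only guards near-zero values. LD driver levels
exceed SD levels (photoperiod induction), onsets sit at days 13–16 with
steepness 1.3/day so the targets sweep a wide dynamic range (AP1 rises
roughly 13-fold), placing every half-saturation constant mid-range — the
precondition for any recovery experiment to be informative. FTa3 is nearly
silent, mirroring its real expression.

Because regulators are read from interpolated data, a self-consistent
dataset must satisfy a fixed-point condition: the solution through traces
built from the knot values must reproduce those knot values. The generator
iterates this map (damped, from a generous positive state, since the
network also has a trivial all-off fixed point) to relative tolerance
1e-9; the generating parameters then attain numerically zero wRSS on the
noise-free dataset. Observations are drawn as `N(u, sd)` clamped at zero;
clamping (rather than resampling) is a documented choice, negligible at
the signal-to-noise of the default scenarios.

Four standard scenarios ship with the package: `h0_baseline` (recovery and
screen null), `h1_ftb` (FTb alone drives activation), `saturated_ap1_lfy`
(the AP1→LFY edge pinned near zero via a huge K4, reproducing a saturated,
non-identifiable edge), and `tfl1_contrast` (K1 = 561.14 vs K2 = 401.14
with identical exponents, for the clustering analysis). In `h1_ftb` the
non-FTb homologs deliberately get early, photoperiod-flat shapes: when all
homologs share FTb's time course, the cumulative pool is proportional to
the single driver and no finite dataset can distinguish the two
hypotheses — a screen fixture must make the generating signature
geometrically distinguishable before asking the statistics to find it.

What the generator does *not* emulate: autocorrelated biological noise,
condition-dependent parameter changes, digitization artifacts, or the
upstream photoperiod pathway shaping the FT curves. Passing recovery tests
on these scenarios demonstrates correctness of the pipeline under its own
assumptions, not that real chickpea data satisfy those assumptions.

## Numerical choices

* Interpolation of traces is piecewise linear by default: exact at knots
  and non-negative between them. The monotone-cubic option (Fritsch–
  Carlson) is clamped at zero because R's implementation can undershoot at
  slope sign changes. Before the first observation a trace holds its first
  value; TFL1a and TFL1c are instead interpolated back to zero at t = 0,
  consistent with their zero initial conditions. Delayed FT lookups use
  the same clamping.
* Integration starts at t = 0 with FD/LFY/AP1 at their first observed
  values (the clamped trace value); a config switch starts at the first
  observation day instead.
* `lsoda` runs at rtol 1e-6 / atol 1e-9; the exponential inner integrator
  uses a 0.1–0.2 day grid during optimization (its O(h^2) error is far
  below the noise floor) and 0.02 days for reported solutions.
* Standard deviations of zero are floored at
  `max(1e-6, 0.01 max(series mean))` on ingestion so weights stay finite.
* DE stops early when the population cost spread falls below a relative
  tolerance (1e-6 by default); reported fits recompute the cost from the
  assembled parameter vector so the stored value never depends on the
  optimizer's internal caching.

### Problem sizes in the shipped experiments

The acceptance suite runs the recovery ensemble at 100 restarts with a
population of 10 per dimension and 500 generations per subsystem, screens
at 2 restarts per hypothesis over 3 seeds, and the clustering fit at 30
restarts with the meristem subsystem frozen at truth; the acceptance
script uses 40, 2 and 20 restarts respectively. These sizes were chosen so
a full run completes on a single CPU in well under half an hour while
leaving the qualitative conclusions stable across seeds.

## Known limitations

* The data-driven formulation cannot extrapolate beyond the observed
  window and makes the fitted parameters conditional on the interpolation
  choice.
* Continuous Hill exponents leave (v, K, n) practically non-identifiable
  at the default noise level; see the identifiability section. Reported
  point estimates for K should always be read together with the ensemble
  spread and the saturation flags. A related ridge affects (v, lambda)
  when the observation window starts after the transient: within the
  window both large-lambda tracking and slow-decay solutions reproduce a
  quasi-steady trajectory, so synthesis and decay rates are constrained
  mainly through the lag between the target and its regulators. The
  recovery experiment in the test suite asserts the strict
  20%-median-recovery property for all unsaturated edges and is expected
  to fail for a subset of Hill constants at the default 5% noise — the
  failure is informative (it reproduces, on known ground truth, exactly
  the sloppiness that motivates the ensemble approach) and is asserted
  rather than hidden.
* The covariance penalty variant is implemented as documented but its sign
  convention is scientifically questionable; it is off by default.
* The Mann–Whitney and Welch tests treat ensemble members as independent
  draws, which holds across restarts but would not hold for members
  derived from a common optimization trajectory.
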