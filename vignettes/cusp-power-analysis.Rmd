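---
title: "Simulation-based power analysis for cusp catastrophe polynomial regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-based power analysis for cusp catastrophe polynomial regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

The cusp catastrophe model describes an outcome whose equilibrium surface
folds as two control variables vary: an *asymmetry* (normal) variable $x$
that drives gradual change, and a *bifurcation* (splitting) variable $y$
that governs whether change is smooth or sudden. Guastello's polynomial
regression operationalizes this for two-occasion behavioral data by
regressing the change score $\Delta z = z_2 - z_1$ — a numerical
approximation of the time derivative of the behavior $z$ — on a polynomial
design in the time-1 score and the controls:

$$\Delta z = \beta_0 + \beta_1 z_1^3 + \beta_2 z_1^2 + \beta_3\, y z_1 +
\beta_4 x + \beta_5 y + \varepsilon, \qquad
\varepsilon \sim N(0, \sigma^2).$$

The cubic term carries the folded structure of the equilibrium surface and
the $y z_1$ interaction the bifurcation effect; the quadratic term and the
main effect of $y$ absorb deviations of the observed data from the
equilibrium surface. All variables are assumed standardized before
analysis (`standardize()` is provided for observed data; the simulator
already draws on the standard-normal scale).

A cusp is *detected* when the fit provides joint evidence for the fold and
for at least one control pathway:

> $\beta_1$ significant **and** ($\beta_3$ significant **or** $\beta_4$
> significant),

each coefficient tested two-sided at level $\alpha$ with $n - 6$ residual
degrees of freedom (`detect_cusp()`, `cusp_rule()`). Significance is the
strict comparison $p < \alpha$, and the rule is sign-free: it uses only the
p-values, not the direction of the estimates. Both conventions are
documented limitations rather than modeling claims. No omnibus F gate is
layered on top of the three-coefficient rule.

As supporting evidence, the cusp fit is conventionally compared with four
linear models of the same variables — change-score models
$\Delta z \sim z_1 + x + y$ (without and with $y z_1$) and pre/post models
$z_2 \sim z_1 + x + y$ (without and with $y z_1$) — with a larger cusp
$R^2$ read as evidence of cusp dynamics (`compare_cusp_models()`). Note
that the cusp design does not nest the plain-$z_1$ models (it has no linear
$z_1$ column), so cusp dominance is an empirical pattern to check, not an
algebraic identity; only the with/without-interaction pairs are nested.

## The power question

For study planning one wants: at sample size $n$, with what probability
does the detection rule fire when the data really follow the cusp
polynomial with effect sizes $\beta$ and noise $\sigma$? The compound rule
(an AND of an OR of correlated t tests on a nonlinear design) has no
tractable closed-form power, so the package estimates it by direct
Monte-Carlo simulation:

1. Draw $x, y, z_1$ i.i.d. standard normal (other normal means/sds are
   supported via `cusp_design(means =, sds =)`), draw
   $\varepsilon \sim N(0, \sigma^2)$, and construct $\Delta z$ from the
   polynomial; set $z_2 = z_1 + \Delta z$.
2. Fit the cusp regression by ordinary least squares.
3. Apply the decision rule at level $\alpha$.
4. Repeat `replicates` times; the detection proportion estimates the power,
   with Monte-Carlo standard error $\sqrt{p(1-p)/\text{replicates}}$.

```{r}
library(cusppower)
des <- cusp_design(beta = rep(0.5, 6), sigma = 1, n = 100)
estimate_power(des, alpha = 0.05, replicates = 1000, seed = 1)
```

A *power curve* repeats this over a grid of sample sizes, and the required
sample size for a target power (0.85 is the conventional design value) is
read off by inverting the curve:

```{r}
res <- find_sample_size(cusp_design(rep(0.5, 6), sigma = 1),
                        target_power = 0.85, replicates = 1000, seed = 1)
res
plot(res$curve, target = 0.85)
```

`subsample_power()` provides the complementary *reverse verification*
device: instead of fresh simulated data, each replicate draws $m$
observations without replacement from one fixed dataset and applies the
same fit-and-detect pipeline. This estimates the power available at sample
size $m$ *conditional on that realization*; because all subsamples come
from the same data that also exhibit the signal, its realization-to-
realization spread is substantial, and single subsample-power numbers
should be read with that in mind.

## Tunable parameters

* `alpha` (default 0.05): per-coefficient significance level inside the
  decision rule. The conventional reading of "statistically significant";
  exposed so designs can be replicated at 0.01 or other levels.
* `replicates` (default 1000): Monte-Carlo replicates per power estimate.
  At 1000, the binomial standard error near $p = 0.85$ is about 0.011.
* `target_power` (default 0.85): the design power for back-calculation.
* `n_min` (default 10), `n_cap` (default 5000), `grid_size` (default 15):
  the sample-size grid for `find_sample_size()`.
* `pilot_replicates` (default `max(100, replicates/5)`): replicate count
  for the cheap bracketing probes (below).

## Numerical and design choices

**Curve smoothing and inversion.** Raw grid powers are smoothed by
isotonic (monotone non-decreasing) least squares (`stats::isoreg`) and the
required $n$ is the smallest integer where the piecewise-linear
interpolation of the smooth reaches the target. Isotonic regression
guarantees a well-defined inversion without imposing a parametric link on
the power function; linear interpolation between grid points keeps the
back-calculated $n$ resolution finer than the grid spacing.

**Grid construction.** `find_sample_size()` doubles an upper bound
(starting at 80) until a pilot power probe at that bound reaches the
target (or `n_cap` is hit), then lays `grid_size` evenly spaced integer
sample sizes from `n_min` to the bound and estimates the full-replicate
curve there. Probes run at the reduced pilot replicate count since they
only need to bracket the target, not locate it; the final curve uses the
full count. If the final smoothed curve still falls short of the target,
the bound is doubled and the curve re-estimated; failure below `n_cap` is
reported as an explicit `out_of_range` flag, never silently extrapolated.

**Seeding.** Every stochastic entry point takes a `seed` and restores the
caller's RNG state. Within one power estimate, replicates consume a single
sequential stream seeded once; across a grid, each point's seed is derived
deterministically from the master seed and the *sample size value* (not
the grid index), so inserting or appending grid points never perturbs the
estimates at existing sample sizes. Draws happen in the fixed order $x$,
$y$, $z_1$, $\varepsilon$, making every pipeline bit-reproducible under a
fixed master seed.

**Rank deficiency.** The public fitting functions test the design matrix's
relative singular values against $10^{-10}$ and fail with the offending
column names rather than silently pseudo-inverting. Inside the Monte-Carlo
loop, a faster Cholesky solve of the normal equations is used (its
agreement with the `lm()`-backed public fit is part of the test suite);
replicates whose subsample or draw is numerically rank deficient are
redrawn and counted separately — scoring them as non-detections would bias
power downward — with a hard cap of 100 × replicates attempts.

**Change-score discipline.** `dz` is always recomputed as `z2 - z1` when
both are available (on construction and on CSV load), with a warning when a
supplied `dz` disagrees beyond $10^{-8}$. `sigma = 0` designs are accepted
so exact-recovery behavior can be expressed directly.

## The four-scenario study design

`run_scenario_suite()` packages a complete planning study: four datasets at
noise levels $\sigma = 1, 2, 3, 4$ ($n = 100$, all $\beta = 0.5$), their
fitted summary table, per-scenario back-calculated sample sizes at 85%
power using each scenario's *fitted* coefficients and residual sd, and the
subsampling reverse verification of the first scenario.

The four scenarios share one realization of $(x, y, z_1)$ and of a
unit-variance residual vector $\varepsilon_0$; scenario $i$ observes the
same signal under residual $\sigma_i \varepsilon_0$. This is a deliberate
design choice: the suite's purpose is to isolate the effect of the noise
*level* on fit quality and required sample size. With fully independent
scenario draws, two sources of variation confound that comparison — the
sample variance of $z_1^3$ is extremely heavy-tailed (its population
kurtosis involves the twelfth normal moment), so realized signal strength
varies wildly between independent datasets, and the signal-by-noise cross
term in the total sum of squares adds further realization noise.
Conditioning on a shared base realization makes $R^2$ decrease and
$\hat\sigma$ increase essentially deterministically along the $\sigma$
grid, which is exactly the contrast the scenario study is meant to
display. Fitted coefficients then drift linearly in $\sigma$ across
scenarios (the estimate equals truth plus $\sigma$ times a shared
projection of $\varepsilon_0$), a recognizable signature of this design.
`estimate_power()` is unaffected: its replicates are always fully
independent draws.

## What the generator does and does not emulate

The simulator draws controls and the time-1 outcome as independent
(standard) normals and generates the change score exactly from the cusp
polynomial with homoscedastic Gaussian error. Real two-occasion behavioral
data differ in ways the power estimates do not capture: controls are
correlated with each other and with $z_1$; outcomes are often bounded
ordinal scales (sum scores, Likert-type indices) rather than continuous;
errors can be skewed or heteroscedastic; and data generated from a
polynomial regression are not the same as data generated from the cusp
equilibrium surface itself (no hysteresis, no genuinely bimodal sojourns).
Passing power targets under this generator therefore demonstrates the
engine's calibration under the stated design assumptions, not robustness
of the cusp regression to violations of them. Planning against published
estimates inherits their estimation error, too: the back-calculated $n$
treats the supplied $\beta$ and $\sigma$ as known truth.

## Problem sizes used in the tests

The test suite verifies the OLS path against a hand-rolled
normal-equations oracle on datasets of 7–60 rows; moment and closed-form
signal-to-noise checks run at $n = 10^5$–$10^6$ (the population $R^2$ of
the all-0.5, $\sigma = 1$ design is $5/(5+\sigma^2) = 5/6$, from the
normal moments $\mathrm{Var}(z^3) = 15$, $\mathrm{Var}(z^2) = 2$); power
properties use 100–2000 replicates; and the end-to-end back-calculation
checks run the published four-scenario and worked-example specifications
at the full 1000 replicates per grid point.

## Known limitations

* The decision rule ignores coefficient signs and applies no multiplicity
  or omnibus correction; it reproduces the classical procedure verbatim.
* One regressor per control variable; multi-regressor extensions of the
  cusp polynomial are out of scope.
* No maximum-likelihood stochastic cusp modeling (the alternative,
  SDE-based operationalization): that is a different estimation framework,
  and its power behavior is not interchangeable with this one.
* Subsample-based power (reverse verification) conditions on a single
  realization; prefer `estimate_power()` for planning numbers.
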