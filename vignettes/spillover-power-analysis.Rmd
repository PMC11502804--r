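---
title: "Designing and decomposing behavioral-spillover experiments"
author: "spillpower"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and decomposing behavioral-spillover experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spillpower)
```

## The problem

A randomized framing intervention (a "win-win" or a "doom-and-gloom"
narrative, say) tries to raise participation in a targeted
pro-environmental behavior, PEB1. The design question is whether — and
through which channel — that intervention also moves a second,
*non-targeted* behavior, PEB2. The total spillover effect of a treatment
T on PEB2 decomposes as

$$
\Delta_T \mathrm{PEB2}
  = \underbrace{\partial_T \mathrm{PEB1}\times\partial_{\mathrm{PEB1}}\mathrm{PEB2}}_{\text{indirect}}
  + \underbrace{\partial_T \mathrm{PEB2}}_{\text{direct}} .
$$

The indirect channel runs through actually *doing* the first behavior; the
direct channel is everything else (e.g., moral licensing after a
guilt-based appeal). Because the decision to do PEB1 is self-selected,
$\partial_{\mathrm{PEB1}}\mathrm{PEB2}$ cannot be read off a regression:
a randomized choice-architecture (salience) nudge that shifts PEB1 uptake
without touching the latent motivation serves as the instrument, and the
decomposition is estimated by two-stage least squares.

`spillpower` implements the full chain needed to design and analyse such
an experiment: the structural data-generating process, calibration of its
parameters to target effect sizes, simulation-based power analysis, and
the estimation pipeline with its bootstrap inference.

## The structural model

Latent "activation systems" U1 and U2 mediate all effects. With treatment
indicator $T$ and nudge indicator $IV$, both Bernoulli(0.5) and
independent:

* $U1 \sim N(\varphi_1 T,\ \sigma_{U1})$
* binary observation model (`version = "binary"`):
  $\mathrm{PEB1} \sim \mathrm{Bernoulli}\{\mathrm{logit}^{-1}(a_1 + \beta_{U1} U1 + \beta_{IV} IV)\}$
* $U2 \sim N(\varphi_{21} U1 + \varphi_{22}\,\mathrm{PEB1},\ \sigma_{U2})$,
  using the *realized* PEB1 draw
* $\mathrm{PEB2} \sim \mathrm{Bernoulli}\{\mathrm{logit}^{-1}(a_2 + \beta_{U2} U2)\}$

The continuous model (`version = "continuous"`) replaces the two
Bernoulli draws by Gaussian outcomes with SDs $\sigma_{PEB1}$,
$\sigma_{PEB2}$; there the path effects are exact products
(`closed_form_effects()`): the treatment effect on PEB1 is
$\beta_{U1}\varphi_1$, the behavior-on-behavior effect
$\beta_{U2}\varphi_{22}$, the direct effect
$\beta_{U2}\varphi_{21}\varphi_1$. No such closed form exists under the
logistic link, which is why the binary model is calibrated by simulation.

The intercepts $a_1, a_2$ are "attractiveness" parameters: $a = -1.5$
corresponds to a baseline participation probability of
$\mathrm{logit}^{-1}(-1.5) \approx 18.2\%$.

```{r dgp}
p <- generative_params("binary", phi1 = 0.5, beta_iv = 1, phi22 = 1)
s <- sample_dataset(p, n_total = 2000, seed = 1)
head(s[, c("T", "IV", "PEB1", "PEB2")], 3)
```

## Estimation

`decompose_spillover()` estimates, on a table with columns `T`, `IV`,
`PEB1`, `PEB2`:

* the total effect $\tau$ (OLS of PEB2 on T),
* the direct effect $\delta'$ and the behavior effect $\beta'$ (2SLS of
  PEB2 on PEB1 and T, PEB1 instrumented by the nudge),
* the indirect effect $\tau - \delta'$ with a **studentized bootstrap**
  confidence interval.

Robust standard errors are HC1 sandwiches; the 2SLS covariance uses the
residuals at the original (not fitted) endogenous values, and the
reported first-stage F is the robust Wald F of the excluded instrument.
The studentized pivot needs a standard error *per resample*: rather than
an inner bootstrap (which would make 10,000 resamples infeasible), the SE
of $\tau - \delta'$ comes from the analytic sandwich of the stacked
moment conditions of the two regressions sharing observations — the
OLS moments $x_i e_{3i}$ and the IV moments $z_i e_{2i}$ are stacked,
their joint covariance estimated from the data, and the delta-method
weight vector picks out $\tau - \delta'$. This captures the (strong)
correlation between $\hat\tau$ and $\hat\delta'$ exactly where a naive
variance sum would not. The stacked covariance uses HC0 scaling (the
pivot is scale-consistent; individual coefficient SEs remain HC1).

Degenerate bootstrap resamples (constant T, IV, or PEB1 column) are
redrawn up to 100 times each; the bootstrap fails with an error if fewer
than half the requested resamples are valid.

Supporting estimators round out the analysis plan: `fit_lpm()` (linear
probability models, HC1, normal reference), `fit_2sls()` (one or two
endogenous regressors, just- or over-identified), `fit_moderated_2sls()`
(endogenous PEB1 and PEB1-by-moderator with instruments IV and
IV-by-moderator; the `"domain"` contract adds the T-by-moderator
exogenous term whose coefficient is the difference in direct effects),
`fit_probit()` and `rivers_vuong_cf()` (control-function probit with the
first-stage-residual z-test as the endogeneity diagnostic), and
`bh_adjust()` (Benjamini–Hochberg step-up, one family per assembled
output table).

```{r decompose}
dec <- decompose_spillover(s, settings = bootstrap_settings(
  n_resamples = 499, seed = 2))
dec
```

## Calibration

A power scenario is a set of five Cohen's d targets (treatment on PEB1,
nudge on PEB1, total / direct / indirect spillover on PEB2). Three
built-in scenarios are provided:

```{r scenarios}
do.call(rbind, lapply(c("favorable", "middle", "adverse"), function(s) {
  as.data.frame(scenario_targets(s))
}))
```

`calibrate_scenario()` finds structural parameters whose *measured*
effect sizes — computed on a large simulated draw with the package's own
estimators — hit all five targets within ±0.01 jointly. Fixed,
non-intervened parameters are never touched: the attractiveness
intercepts (−1.5 binary / 0 continuous), the activation autocorrelation
$\varphi_{21}$ (0.6 binary / 0.7 continuous), and all noise SDs (1).

The search mirrors a three-step sweep: place the "exit" signal
$\beta_{U2}$ on the direct-spillover target, adjust $\varphi_1$ and
$\beta_{IV}$ for the two PEB1 targets, adjust $\varphi_{22}$ for the
total (hence indirect) target, and repeat until the joint criterion
holds. Design choices worth recording:

* **One redundant degree of freedom.** With the fixed parameters above,
  the five targets leave $\beta_{U1}$ redundant with $\varphi_1$ (both
  scale the treatment path into PEB1), so $\beta_{U1}$ is held at its 1.0
  starting value as a normalisation. Many parameter vectors yield
  identical effect sizes; calibration is therefore accepted on measured
  d's, never on raw parameters.
* **Common random numbers.** Every evaluation inside the search reuses
  one fixed set of exogenous noise draws, making each gap function
  deterministic and near-monotone so that plain one-dimensional
  root-finding (with bracket $(0, 5]$ and automatic upward extension) is
  reliable.
* **Two-stage draw sizes.** Inner iterations evaluate on 5×10⁵ units; the
  acceptance check — and polish sweeps, if any gap survives — use the
  full 5×10⁶-unit draw. The direct effect's d is the 2SLS $\delta'$
  scaled by the pooled SD of PEB2 across treatment groups; the indirect d
  is defined by the subtraction rule `total − direct`, so that identity
  holds exactly by construction.
* **Null targets.** A zero target is met structurally by switching the
  corresponding path off ($\varphi_1$, $\beta_{IV}$, or $\varphi_{22}$ set
  to 0). When $\varphi_1 = 0$, the direct effect is identically zero by
  construction while its Wald estimate under an irrelevant instrument is
  pure noise, so the structural zero is used for the convergence check.

```{r calibrate, eval = FALSE}
cal <- calibrate_scenario(scenario_targets("middle"),
                          calibration_settings(seed = 11), "binary")
attr(cal, "measured")   # all five within 0.01 of (0.58 0.40 0.37 0.20 0.17)
```

## Power analysis

`run_power_grid()` samples repeatedly from a calibrated scenario over a
per-arm grid (defaults 150–1250; total n is `2 * n_per_arm` with a
stochastic Bernoulli(0.5) split, matching the model's sampling equations
rather than forcing exact balance) and applies the study's decision rule
per estimand at $\alpha = 0.05$: robust regression p-values for the
PEB1, total, and direct effects; CI-excludes-zero from the studentized
bootstrap for the indirect effect. The inner bootstrap defaults to
B = 999 in the power loop — the CI quantiles are easily accurate enough
for a 5% decision — with B = 10,000 available for fidelity runs. Each
replicate draws its own seed from the root seed, so cells are
order-independent and reproducible.

At 300 replicates (Monte-Carlo SE of a power estimate near 0.8 is about
2.3 points) the shipped scripts and the acceptance suite reproduce the
design's sample-size conclusions for the binary model: the middle
scenario clears 80% power on both spillover effects at N = 1250 per
arm; the favorable scenario clears it already at N = 500; the adverse
scenario resolves the PEB1 and total effects at N = 500 but stays well
short of 80% for the direct/indirect split even at N = 1250.

Two sensitivity sweeps around the middle scenario are provided:
`sensitivity_iv_strength()` re-solves $\beta_{IV}$ for nudge effect sizes
d = 0.2–0.8 (power over the spillover estimands is very sensitive to
instrument strength), and `sensitivity_attractiveness()` fixes the PEB1
or PEB2 intercept at five levels corresponding to base probabilities
0.01–0.40.

**A limitation worth knowing.** With a genuinely irrelevant instrument
($\beta_{IV} = 0$) the direct/indirect split is unidentified; the 2SLS
ratio is not asymptotically normal and the bootstrap does not rescue it,
so the indirect decision neither holds its nominal size nor gains power
with n. The package's tests assert exactly that behavior. In design work
this is immaterial — the whole point of the sensitivity sweep is that
the instrument must be engineered to be strong (first-stage F well above
10 everywhere on the calibrated grids) — but the CI should not be
trusted on data where the first stage is weak.

## The synthetic experiment table

`generate_experiment()` emulates the three-study respondent table so the
pipeline (including the publication-style output tables assembled by
`render_results_table()`) can be exercised end to end without any
external data. The generator is explicitly synthetic: marginal rates are
anchored to the published sample facts — 50.3% task uptake without the
nudge plus a 38.9-point nudge effect (≈70% overall), 85% of takers
completing all 30 rounds, 27% signing the environmental petition and 38%
the health one — while all *injected* treatment and spillover effects
default to zero, matching the study's null findings. Outcomes are drawn
through the same binary latent-activation mechanism as the simulator,
with intercepts solved by Gauss–Hermite quadrature (and in-sample
root-finds for the second behavior) so that configured marginal effects
are what the estimators recover.

Choices the source material does not pin down are configuration, not
claims: rounds of non-completers follow a truncated geometric on 1–29
with the completion mass matched to the 85% share; per-round correctness
is Bernoulli with a difficulty-dependent rate (defaults 0.37 hard / 0.54
easy, consistent with the published performance regressions); covariate
marginals use the published bracket frequencies with no attempt to match
the real joint distribution; Study 3 carries the hard difficulty
condition forward by default.

```{r experiment}
d <- generate_experiment(experiment_design_config(n_study1 = 2000,
                                                  seed = 5), studies = 1)
c(uptake = mean(d$peb1_done), signing = mean(d$peb2_signed))
```

What passing tests on these tables shows — and what it does not: the
generator reproduces the *marginal* structure and the randomization of
the real design, so parameter-recovery tests validate the estimators,
not the behavioral realism of the joint distribution. Real respondent
data have covariate-outcome dependence, panel-provider artifacts, and
attention-check selection that the generator deliberately omits.

## Numerical notes

* Inverse logits go through `stats::plogis` (stable, branch-free);
  probabilities are never clamped — parameters in the calibrated ranges
  do not saturate.
* The fast decomposition statistic inside the bootstrap solves its 2×2
  and 3×3 systems in closed form with all cross-moments accumulated in
  double precision (integer accumulation overflows beyond n ≈ 2,500).
* Root seeds spawn per-task substreams through a small integer hash
  (`derive_seed()`), keeping every derived seed in [1, 2³¹ − 2] and
  making replicates order-independent.
* Problem sizes used by the shipped analysis scripts and tests:
  calibration at 5×10⁵ inner / 5×10⁶ final draws; power claims at 300
  replicates with B = 999; bootstrap coverage at N = 500 per arm, B = 999,
  200 replications; type-I error at 1000 null replicates; parameter recovery
  at n = 10,000. Full-fidelity settings (1000 replicates, B = 10,000, the
  eight-point grid) are one flag away in `analysis/02_power.R`.
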