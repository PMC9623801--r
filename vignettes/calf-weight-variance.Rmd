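---
title: "Partitioning variance in calf weight: model, generator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning variance in calf weight: model, generator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calfgrowth)
```

## The model

Weight recordings of dairy calves are nested: repeated weighings within
calves, calves within farms, farms within veterinary practices. The package
fits the three-level random-slope linear mixed model

$$y_{ijk} = \alpha + \beta_1 a_{ijk} + \beta_2 a_{ijk}^2 + v_k + u_{0jk} +
u_{1jk}\,a_{ijk} + e_{ijk},$$

where $a$ is calf age in days, $v_k \sim N(0, \sigma_v^2)$ is a
veterinary-practice intercept, $(u_{0jk}, u_{1jk}) \sim N_2(0, \Omega_u)$ is
a correlated farm intercept and growth-rate deviation, and
$e_{ijk} \sim N(0, \sigma_e^2)$ is the calf-level residual. Ages enter in raw
days (no centering), so $\alpha$ is interpretable as mean birth weight and
$\beta_1 + 2\beta_2 a$ as the instantaneous growth rate (kg/d) at age $a$.

Because the farm level carries a random age slope, the unexplained variance
at each level is a function of age:

$$\mathrm{var}_{\text{farm}}(a) = \sigma_{u0}^2 + 2a\,\sigma_{u01} +
a^2\sigma_{u1}^2,$$

while the practice and calf components are constant. The variance partition
coefficient (VPC) at a level is that level's share of the total at a given
age; with a random slope the partition shifts with age, which is the model's
central epidemiological output: it tells you at which level of the hierarchy
unexplained variation — and hence scope for intervention — resides for
calves of a given age.

## Estimation

The sampler (`run_mcmc()`) is a blocked Gibbs sampler with exact conjugate
conditional draws: the fixed-effect vector from its joint conditional
normal, each practice intercept from a univariate normal, each farm
(intercept, slope) pair from a bivariate normal, the practice and residual
precisions from Gamma conditionals, and the farm precision matrix from a
Wishart conditional with degrees of freedom equal to the prior degrees of
freedom plus the number of farms. The kernel is compiled (RcppArmadillo) and
consumes R's own RNG stream, so a seed fully determines a chain.

Priors follow the default-noninformative convention for multilevel models:
Gamma(0.001, 0.001) on the two scalar precisions and
$\Omega_u^{-1} \sim \mathrm{Wishart}_2\!\big(2,\, (2\hat S_u)^{-1}\big)$,
where $\hat S_u$ is a moment estimate of the farm-level covariance computed
by the initializer, so the prior expectation of the precision equals
$\hat S_u^{-1}$. The notation conventionally used for this prior is
typographically ambiguous about the degrees of freedom; we adopt df = 2
(the minimum for a 2×2 Wishart) and document rather than assert it.
Starting values come from OLS plus analysis-of-variance-style moment
estimators (floored at $10^{-6}$ kg² so degenerate inputs still yield a
valid state). An iterative GLS refinement would change nothing material:
with the long burn-in the chain forgets its start.

Two schedules are built in: the production profile (`"paper"`: 100,000
burn-in, 1,000,000 sweeps, thin 100, i.e. 10,000 stored draws) and a desk
profile (`"desk"`: 5,000 / 50,000 / 10, 5,000 stored draws) whose Monte
Carlo error is adequate for the derived summaries and which fits in seconds
to minutes on one CPU. Tests and the acceptance analyses use the desk
profile and populations of roughly 10 practices / 60 farms / 3,000 calves
(about 12,000 records); those sizes give posterior standard deviations small
enough to diagnose real calibration failures while keeping a full
multi-replicate recovery study in the minutes range.

## Diagnostics

`diagnose_chain()` reports, for the four variance parameters, the effective
sample size (autocorrelation-sum estimator truncated by the
initial-positive-sequence rule, capped at the draw count) and the
Raftery-Lewis run-length diagnostic at the conventional setting: probability
0.95 that the 0.025–0.975 quantile is accurate within 0.005, for which the
independence-chain minimum is 3,746 draws. Our Raftery-Lewis implementation
floors the required length at that minimum: the plug-in transition estimates
can dip a percent or two below it on near-independent chains, and a
required length below the independence bound is not meaningful. `dic()`
computes the conditional-on-random-effects DIC (the standard convention in
multilevel software); the marginal variant is out of scope.

## What the generator emulates — and what it does not

`simulate_population()` reproduces the features of a national
weight-recording service that matter to the pipeline: strict nesting
(every farm belongs to one practice), negative-binomial cluster sizes,
a shifted negative-binomial weighing count calibrated to a median of 3
weighings per calf (IQR 2–4, extreme tail ≈ 15), uniform follow-up ages on
1–138 d with optional linear attrition toward older ages, per-farm
calendars, a configurable fraction of confirmed birth weights, and four
defect classes: implausible ages (outside 1–138 d), estimate flags,
out-of-range weights (outside (30, 225] kg), and farms whose whole recording
history spans ≤ 365 d.

Three construction guarantees make selection testing exact. Non-short-window
farms pin their first and last calf birth dates to the ends of a 540-day
window, so a clean farm's recording span always exceeds a year; those two
anchor calves are exempt from record-level corruption; and the three
record-level defect classes are drawn on disjoint record sets. Each injected
defect is therefore removed by exactly one cascade rule, and the truth
object tallies them per rule.

One interaction is irreducible: with exactly Gaussian residuals at the
default variances (total day-0 variance 98.06 kg², sd ≈ 9.9 kg), about 12%
of true day-0 weights fall at or below the 30 kg bound, so the weight-range
filter removes some perfectly clean records. We deliberately keep clean
generation unbounded-Gaussian — truncation would bias the moment and
parameter-recovery checks the generator exists to support — and instead
tally `natural_out_of_range` in the truth object. Tests that require exact
stage counts use zero-variance configurations in which clean records sit
deterministically on the mean curve, inside every filter. Real
weight-recording data are of course not Gaussian in the tails, have
farm-specific weighing protocols rather than uniform ages, and exhibit
attrition through mortality and management rather than a linear thinning
rule; passing tests demonstrate correctness of the pipeline's logic and the
sampler's calibration under the model's own assumptions, not robustness to
violations of them.

The generator does not simulate calf mortality as a process (only its
observable footprint, attrition), nor breed/sex misclassification, and the
distributions of farms per practice and calves per farm are configurable
conventions, not estimates.

## The selection cascade

`run_selection()` applies, in order: the recording-age window (1–138 d; a
published tabulation also prints 139 in one header — we follow the
narrative methods value, configurably), the farm-activity filter
(span > 365 d), removal of estimate-flagged weights, injection of confirmed
birth weights as day-0 records for calves already present, and the weight
bounds (> 30, ≤ 225 kg) — applied last so injected birth weights are
themselves range-checked. Two details make the cascade idempotent:
previously injected day-0 records are spared by the age window on a rerun,
and injection skips calves that already carry a birth record. In the
original study's tabulated counts the calf total drops at the
birth-injection stage, implying calves without confirmed birth weights were
excluded there; the cascade here is append-only at that stage, as specified,
and the discrepancy is noted rather than imitated since the original counts
are not reproducible from proprietary data.

## Derived quantities

* `vpc_profile()` evaluates per-draw VPCs on an age grid (default 0–130 d,
  matching the range over which the partition is usually displayed) and
  reports both the posterior mean of the per-draw ratio and the plug-in
  ratio at the posterior means; for published point components the two
  coincide, and agreement at 2 decimals is the checkable surface.
* `growth_rate()` and `cumulative_growth_rate()` return
  $\beta_1 + 2\beta_2 a$ and the chord slope $\beta_1 + \beta_2 h$.
* `cluster_mean_coverage()` returns the 0.025–0.975 spread of practice-farm
  mean birth weight, by default from the model's own gaussian form
  $\alpha \pm z_q\sqrt{\sigma_v^2 + \sigma_{u0}^2}$ per draw. For the
  cumulative growth rate the gaussian form uses the farm slope only; the
  published rate coverage appears to have been computed from realized
  cluster estimates rather than this closed form, so an empirical method
  (quantiles of realized cluster means, requiring `store_ranef = TRUE`) is
  provided and the gaussian rate endpoints are not treated as a
  reproduction target.
* `posterior_predictive_weight()` mixes per-draw normal predictives, either
  for the median cluster (random effects at zero) or the population scope
  (adding the practice and age-dependent farm variance), yielding the
  probability a calf of a given age falls in a stated weight band — the
  quantity needed for proportion-based target setting.

## Numerical conventions

Variance floors ($10^{-6}$ kg²) guarantee valid starting states; conditional
covariance factorizations use symmetric-positive-definite solvers with no
jitter needed at these scales; predictive quantiles invert the draw-mixture
CDF by root finding to $10^{-8}$; VPC normalization (the three shares sum to
1) holds to machine precision by construction and is asserted exactly in
tests. Count distributions guarantee at least one farm per practice and two
calves per farm (the minimum for a span-pinned window). All randomness — in
the generator and the sampler — flows from a single seeded R RNG stream per
run, consumed in a fixed documented order, so every artefact is reproducible
byte for byte.

## Worked example

```{r, eval = FALSE}
library(calfgrowth)

cfg <- sim_config(n_practices = 10,
                  farms_per_practice = list(mean = 6, dispersion = 0),
                  calves_per_farm = list(mean = 50, dispersion = 0),
                  weighings_per_calf = list(mean = 3, dispersion = 0),
                  birth_weight_rate = 1, seed = 11)
sim <- simulate_population(cfg)
sel <- run_selection(sim$records, sim$birth_weights)
design <- build_design(sel$records)
chain <- run_mcmc(design, settings = mcmc_settings("desk", seed = 2))
tidy(chain)
vpc_profile(chain, ages = c(0, 66, 130))
autoplot(vpc_profile(chain))
```

## Known limitations

Calendar covariates (month/year of measurement) are not modelled; the
original analysis investigated and excluded them. Frequentist standard
errors are not provided. The empirical cluster-coverage method needs stored
random-effect draws and therefore more memory. The desk schedule's effective
sample size for the intercept can be modest (the intercept mixes slowly with
practice intercepts when practices are few); for publication-grade intervals
on $\alpha$, use the production schedule.
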