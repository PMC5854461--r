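---
title: "Model and methods behind fpem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind fpem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fpem` estimates and projects family planning indicators for married or
in-union women aged 15–49 from sparse, heterogeneous survey series: the
modern contraceptive prevalence rate (mCPR), unmet need for modern
methods, and demand satisfied with modern methods. This vignette is the
package's own account of the model, its assumptions, the tunable
parameters, and the choices made where the design was genuinely open.

## The latent process

For each country the logit of total contraceptive prevalence
$\eta_{c,t}$ lives on an annual integer grid (default 1970–2030, set by
`fpem_config(grid = ...)`; a grid year $Y$ represents the calendar
interval $[Y, Y+1)$). Its backbone is a logistic growth curve

$$\Lambda_c(t) = \frac{\tilde p_c}{1 + e^{-\omega_c (t - \Omega_c)}},$$

which encodes the standard transition narrative: prevalence rises slowly
at first, accelerates around the midpoint year $\Omega_c$, and
saturates at an asymptote $\tilde p_c < 1$. Rather than distorting the
*level* of this curve, the model distorts its annual *rates of change*:
with expected logit increments
$d^*_{c,t} = \mathrm{logit}\,\Lambda_c(t{+}1) - \mathrm{logit}\,\Lambda_c(t)$,

$$\eta_{c,t+1} = \eta_{c,t} + d^*_{c,t} + \delta_{c,t}, \qquad
\delta_{c,\cdot} \sim \mathrm{AR}(1)(\rho, \tau),$$

with the stationary parameterisation $\delta_1 \sim N(0,\tau^2)$,
$\delta_{t+1}\mid\delta_t \sim N(\rho\delta_t, \tau^2(1-\rho^2))$.
Because the distortions act on increments, a recent acceleration or
slow-down propagates into projections (reverting toward the expected
pace at rate $\rho$) instead of being pulled back to the historical
curve — this is the behaviour that makes the model responsive to changes
between the two most recent surveys.

The modern-method share of total use follows its own logistic curve in
time with parameters $(\tilde r_c, \psi_c, \Xi_c)$. The functional form
of the share trend is not dictated by the substance of the problem; a
logistic mirroring the total-use trend is assumed because the share,
like prevalence itself, moves from traditional-method dominance toward a
modern-method plateau. Modern prevalence is
`total * share`, traditional prevalence is the remainder, so
`modern + traditional = total` holds exactly in every posterior draw.

Unmet need is modelled among non-users: with $u_{c,t}$ the logit of
unmet need for any method among women not using contraception,

$$u_{c,t} = \alpha_c + \beta\, \eta_{c,t} + \delta^{(u)}_{c,t},$$

where $\beta$ is a global slope linking unmet need to prevalence and
$\delta^{(u)}$ is a second, independent AR(1) series of *level*
distortions. The observable unmet-need proportion is
$(1 - \mathrm{expit}(\eta))\cdot\mathrm{expit}(u)$, which keeps
`total + unmet_any <= 1` by construction. Rate-of-change distortions
are used only for total prevalence; unmet need keeps level distortions
because its link to $\eta$ already transmits prevalence momentum.

### Hierarchy

Each of the seven trend parameters (logit asymptote, log rate and
midpoint for both curves, and $\alpha$) is shared down a
world → region → subregion → country hierarchy of normal distributions,
so a country with few or no surveys borrows strength from its
neighbours. Default priors (all overridable through `fpem_config()` or
a YAML file):

| parameter | world prior | notes |
|---|---|---|
| logit $\tilde p$ | $N(0.5, 1^2)$ | truncated so $\tilde p \in (0.1, 0.95)$ |
| $\log \omega$ | $N(\log 0.1, 0.5^2)$ | growth per year |
| $\Omega$ | $N(2000, 10^2)$ | midpoint year |
| logit $\tilde r$, $\log\psi$, $\Xi$ | as above | share curve |
| $\alpha$ | $N(-0.5, 1^2)$ | unmet intercept |
| level SDs | half-normal(0.5) | region, subregion, country |
| $\rho$ | Uniform(0, 0.95) | both AR series |
| $\tau$ | half-normal(0.1) | logit-increment scale |

## Measurement error

Surveys are noisy in two ways. Sampling variance: when a survey supplies
a proportion-scale standard error, the delta method maps it to the logit
modelling scale, $v = \mathrm{se}^2/(p(1-p))^2$. The mapping itself is a
design choice — the model lives on the logit scale and proportion-scale
SEs are what surveys report. Missing SEs are imputed with the median of
observed SEs for the same indicator and source type (falling back to
the indicator-wide pool, then to `error$default_se = 0.015`); the median
is robust and declares no more than the data support. Whether imputation
should further condition on sample size or country is unknowable from
the available description; the rule here is declared, not inferred.

Non-sampling error: each source type (DHS, MICS, PMA, RHS, NATIONAL,
OTHER) carries an estimated non-sampling SD with a half-normal(0.2)
prior, added in quadrature, and an additive logit-scale bias with a
$N(0, 0.2^2)$ prior. DHS is the reference source with bias fixed at 0 —
without a reference the biases and the level of the latent trajectory
are not jointly identifiable.

A survey's reference period matters: an observation informs the
*average* of the indicator (on the proportion scale, then logit) over
the grid years its fieldwork window overlaps, with weights proportional
to fractional-year overlap. Calendar years without explicit months are
placed mid-year ($Y + 0.5$), symmetric within the year.

Service statistics (EMU — estimated modern use from facility data) have
unknown level biases, so only their changes are used: first differences
of logit EMU are normal around first differences of logit modern
prevalence with variance `emu$variance` (default 0.01, i.e. an SD of
0.1 on annual logit differences); the level offset cancels by
differencing. A single EMU point carries no difference information and
is dropped with a warning.

## Inference

`joint_logposterior()` is the package's reference statement of the full
density: hierarchical priors, AR distortion densities, and all survey
and EMU likelihood terms. The MCMC engine is JAGS (via `rjags`), the
standard sampler for this model class; its program mirrors the same
density in the centered hierarchical parameterisation, and the R-side
density is validated term by term against an independent oracle in the
test suite. Defaults are 4 chains of 1000 warmup + 1000 retained
iterations for production and 2 × (500 + 500) for test-scale runs; runs
are bitwise reproducible given a seed (each chain receives a derived
RNG seed). Convergence is assessed by split R-hat (< 1.1) and effective
sample size on the monitored parameters; non-convergence is a warning,
not an error, because counterfactual pipelines need partial results.

A caveat worth stating: where surveys cover only the rising phase of
the curve, the asymptote and midpoint are weakly identified and their
chains mix slowly; split R-hat on those parameters can stay above 1.1
at test-scale iteration counts while the *trajectories* — the
quantities everything downstream consumes — are well calibrated.

Outlying observations can be screened against a projected trend with
`flag_outliers()`: an observation more than 2 projection SDs from the
projection mean (strict inequality — a value at exactly 2 SD is kept)
is flagged, the rule used for provisional state-level survey rounds.

## Indicators, aggregation, reporting

All reported indicators are computed per posterior draw and only then
summarised: unmet need for modern methods is `unmet_any + trad_cpr`,
demand satisfied is `mcpr / (mcpr + unmet_modern)`. The identity
`demand_satisfied * (mcpr + unmet_modern) = mcpr` therefore holds
exactly draw-wise, while the same identity applied to published medians
holds only approximately — that is expected, not an error. Aggregates
weight country prevalences by counts of married/in-union women (MWRA),
per draw, so users add exactly and uncertainty propagates; demand
satisfied is recomputed from the aggregated components. Additional
users between two years are draw-wise differences of user counts,
with deterministic population counts (no population uncertainty — the
population series is external and published without intervals).
Summaries are medians with 2.5/97.5 percentiles by linear interpolation
(quantile type 7; for $n$ draws the 2.5th percentile interpolates
between order statistics, e.g. draws 1..100 give a median of 50.5).
Report tables round half away from zero to one decimal on the
percentage scale; the rounding convention is declared here and applied
uniformly.

## The counterfactual analysis

`truncate_dataset()` removes every observation whose start date is
strictly greater than the cutoff (default 2012) — an observation
starting exactly in the cutoff year is retained, a literal reading of
the truncation rule. Refitting on the truncated data yields
counterfactual projections that embody pre-cutoff expectations. For
each country with data after the cutoff, the evaluation year is its
most recent observation year (the latest survey period end or EMU year,
floored to the grid). The attainment probability is the fraction of
counterfactual draws at or above the full-data estimate; the full-data
"estimate" is the posterior median — the point summary used for all
reporting. Countries are grouped at ≤ 25%, 26–74% and ≥ 75% attainment,
and progress is called positive only when the median gap is positive
*and* the attainment probability is strictly below 50%. When the cutoff
removes nothing, every country attains its own median with probability
one half up to Monte Carlo error — a self-consistency check the test
suite runs.

## The synthetic-data generator

`simulate_dataset()` draws a complete truth from the model's own priors
(hierarchy means, level SDs, country parameters, AR parameters and
distortion series) and then observes it the way the measurement model
assumes: sparse surveys with one- or two-year reference periods (0.7 /
0.3), a configurable source mix, source biases and non-sampling noise
on the logit scale, sampling SEs derived from an effective sample size
($\mathrm{se} = \sqrt{p(1-p)/n_\mathrm{eff}}$,
$n_\mathrm{eff} \sim U(2000, 15000)$ — the form survey SEs actually
take, and the reported SE is computed from the survey's own estimate,
as a real survey would), missing SEs outside DHS, and EMU series with a
persistent level offset that only differencing removes. Per-country
sub-streams derived from the master seed make generation independent of
iteration order.

The `fp2020_like` scenario is proportioned to the database the model
class was built for — 68 countries, roughly 730 prevalence rows (each
survey reports total and modern prevalence), unmet need on ~63% of
surveys, 13 countries with ~6–7 EMU points each. The `small` scenario
(2 regions × 2 subregions × 4 countries) is the calibration-study
workhorse; `tiny` (3 countries) drives smoke tests.

Because generator and model share one generative story, posterior
intervals are calibrated by construction: the test suite checks that
95% intervals cover true mCPR in at least 90% of observed country-years
on the `small` scenario (2 chains × 500 + 500, fixed seed, grid
1980–2025 — the problem sizes used throughout the tests and the
acceptance script). What passing these tests does *not* show: real
surveys have design effects, non-normal and correlated non-sampling
errors, definitional revisions, and countries whose transitions are not
logistic; calibration on synthetic data is a necessary, not sufficient,
condition for trustworthy real-data intervals.

## Numerical and edge-case conventions

* Proportions are validated strictly inside (0, 1); a missing sampling
  SE is an empty field, never 0 (a zero variance is legal-looking but
  wrong).
* Decimal years are restricted to [1960, 2030]; single-year surveys sit
  at mid-year.
* Fixture transcriptions keep middle-dot decimal separators and true
  minus signs verbatim; normalisation happens at parse time.
* `ar1_logdensity` is validated against a dense-covariance
  multivariate-normal oracle to 1e-8.
* Inside the sampler, proportions are clamped to
  [1e-12, 1 − 1e-12] before any logit, so that transient burn-in
  excursions of the growth-rate parameters (which can make the logistic
  curve underflow to exactly 0) never produce an infinite density; the
  clamp is inactive everywhere the posterior has appreciable mass.
* A counterfactual with an empty post-cutoff roster returns an empty,
  correctly-typed table.
* Attainment probabilities are reported rounded to whole percent in
  table output; group boundaries (≤ 25, ≥ 75) are applied to the
  percentage scale.

## Limitations

Estimates are for married/in-union women only; all-women denominators,
age or parity structure, method-specific sub-models and covariate
effects are out of scope. The sampler estimates source biases and
non-sampling SDs globally, not per country. The counterfactual analysis
quantifies departure from model-based expectations; it is not an impact
evaluation of any programme, and attainment probabilities inherit all
the model's assumptions about what "expected" means.
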