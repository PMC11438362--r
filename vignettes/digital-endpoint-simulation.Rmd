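---
title: "Simulating trials with wearable activity endpoints: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating trials with wearable activity endpoints: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvpasim)
```

## The problem

Trials that replace an in-clinic endpoint with a wearable-derived digital
outcome — here, daily minutes of moderate-to-vigorous physical activity
(MVPA) from a wrist accelerometer — gain a high-frequency, real-world
measurement, but inherit new nuisances: seasonal variation in activity,
an observer (Hawthorne) effect when participants know they are being
monitored, a choice of measurement-period length, and device-driven missing
data that can depend on the activity level itself. `mvpasim` quantifies how
each of these affects the bias and precision of the standard
baseline-adjusted treatment-effect estimator, by Monte Carlo simulation of
a two-arm phase II trial.

## The data-generating model

For participant $i$ and follow-up day $j$, daily MVPA $y_{ij}$ (min/day)
is log-normal with natural-scale mean $\mu_{ij}$ and natural-scale SD 46,
conditionally independent across days given the participant random effect:

$$
\mu_{ij} = \text{baseline}_i
 + \delta_1 \, \text{arm}_i
 + \delta_2 \, \text{winter}_i
 + \delta_3 \, \text{winter}_i \, \text{arm}_i
 + \delta_4 \, \text{week1}_j
 + \delta_5 \, \text{week1}_j \, \text{arm}_i
 + \alpha_i
$$

* $\text{baseline}_i$ is the participant's baseline MVPA, log-normal with
  natural-scale mean 77 and SD 52 min/day (daily MVPA is right-skewed);
* $\delta_1 = 12.5$ min/day is the treatment effect;
* $\delta_2$ is an additive seasonal effect applying to the fraction of
  the cohort recruited in winter (whose follow-up falls in summer);
* $\delta_4$ is an observer effect confined to week 1 (days 1–7);
* $\delta_3, \delta_5$ are the corresponding treatment interactions; the
  "with interaction" convention sets them to one tenth of the main effect;
* $\alpha_i \sim N(0, 4)$ is a participant random effect.

The default design is 44 participants, 2:1 treatment:control allocation
and 28 follow-up days; a 1:1 variant is available as a configuration
option.

### Parameterisation choices

All distributional constants are **natural-scale moments**: the effect
model is additive in minutes/day, so the log-normal is moment-matched —
$\sigma_{\log}^2 = \log(1 + (\text{sd}/\text{mean})^2)$,
$\mu_{\log} = \log(\text{mean}) - \sigma_{\log}^2/2$ — for every draw.
Because a tiny baseline draw combined with a negative $\alpha_i$ could push
$\mu_{ij} \le 0$, the mean is floored at 1 min/day before matching; the
event is rare and its count is recorded on the dataset (`n_floored`).

Counts are exact rather than binomial: allocation assigns exactly
$\operatorname{round}(44 \cdot 2/3) = 29$ participants to treatment
(half rounded away from zero — base R's `round()` is banker's rounding and
would give 4.4 → 4 but 29.5 → 30 inconsistently), and the winter fraction
and missingness proportions are enforced exactly, so scenario parameters
are controlled, not merely targeted in expectation. Random draws are
consumed in a fixed documented order (baselines, random effects, arms,
winter flags, then the daily matrix participant-by-participant), making a
seed a complete description of a dataset.

## Missingness and compliance

A "missing day" stands directly for a non-compliant day (below 600 min =
10 h of wear while awake); wear time is not simulated at the minute level
because the outcome model is day-level. Two mechanisms are provided:

* **MCAR** — a fraction of participants each lose a fixed fraction of
  their measurement-period days, chosen uniformly;
* **MNAR** — the same counts, but each affected participant loses the days
  with the *lowest* MVPA (earliest day on ties). This mimics devices left
  off on sedentary days, and makes missingness depend on the unobserved
  value itself.

A participant enters the analysis when at least 14 of the 28
measurement-period days are observed (inclusive threshold). For shorter
periods the threshold scales as half the period, rounded up; the built-in
grids never combine missingness with the 14-day period, keeping the
scenario families separate. The maximum grid proportion of missing days
(0.5) leaves affected participants exactly at the inclusion boundary, and
the boundary is deliberately inclusive and configurable.

## Estimand and analysis

The per-participant endpoint is the mean of observed daily MVPA over the
measurement period — an *average*, not a sum, so that the endpoint is not
confounded with how many days survived the compliance filter. The primary
analysis is the ANCOVA

$$ \bar{y}_{i\cdot} = \beta_0 + \beta_1\,\text{baseline}_i + \beta_2\,\text{treat}_i + \epsilon_i $$

fitted by OLS on complete cases; the estimand is $\beta_2$ (min/day) and
its model-based standard error. The real trial's stratification factors
are intentionally omitted. `fit_primary_model()` delegates the fit to
`stats::lm()`; the test suite cross-checks it against an explicit
normal-equations solve.

## Monte Carlo evaluation

`run_cell()` repeats simulate → apply missingness → summarise → fit
`nsim` times and reports the mean estimate, mean SE and their Monte Carlo
errors ($\mathrm{sd}/\sqrt{n_\text{sim}}$, the same formula for both —
plots show $1.96\times$ error bars). Per-replication seed pairs (one for
the trial, one for the missingness selection) come from a stream seeded by
the cell seed, so the missingness pattern is independent of the simulated
values; cell seeds are derived from the grid seed and cell index by a
fixed 31-bit linear mix, so results are reproducible and independent of
execution order. Replications with failed fits are counted and dropped; a
cell errors out above 1% failures.

The built-in grids use 5 evenly spaced effect values over 0–10 and
missing-day proportions 0.05–0.5 in steps of 0.05 with a complete-data
reference cell. These spacings are declared defaults (the figure structure
they reproduce does not pin down spacing) and are configurable.

Expected behaviour, verified by the test suite at production scale
(10,000 replications per cell; 2,000 for the 1:1 allocation variant,
where the $3\times$ Monte Carlo error bands widen correspondingly):

* seasonality and the observer effect without treatment interactions leave
  $\hat\beta_2$ unbiased (randomisation protects the contrast) but inflate
  its SE;
* with an interaction, bias appears and grows with both the effect size
  and the affected fraction;
* halving the measurement period inflates the SE;
* MCAR is unbiased but costs precision; MNAR biases $\hat\beta_2$ upward
  — deleting each participant's lowest days raises observed means, and
  does so differentially once an interaction or skewness is in play —
  with a further SE increase.

## Validation metrics

The validation module implements the statistics used to analytically and
clinically validate a digital endpoint, generically over per-subject
summaries:

* `icc_test_retest()` — split-period test–retest reliability as a one-way
  random-effects, single-measurement ICC(1,1). A split-half wearable
  summary has no rater structure, so the one-way model is the appropriate
  form; it is recorded in the result object.
* `convergent_correlation()` — Pearson or Spearman correlation against a
  traditional outcome.
* `known_groups()` — median comparison between a disease group and
  controls; medians only, no test attached, matching how such comparisons
  are reported in qualification dossiers.
* `stability_curve()` — precision of a summary versus measurement-period
  length, as the within-subject coefficient of variation (%) of the
  summary over day-resampled replicates, averaged across subjects.
  "Variability" is not given a formula in the validation literature this
  mirrors; the CV is the conventional choice, and for an iid signal with
  the mean as summary the curve decays like $1/\sqrt{L}$.

## What the generator does and does not emulate

The generator reproduces the features that drive the design questions:
right-skewed daily activity, between-participant heterogeneity, seasonal
and observer shifts, and value-dependent missingness. It does **not**
emulate within-day (epoch-level) signals, day-to-day autocorrelation
beyond the shared random effect, calendar-based recruitment (winter is a
binary flag), participant dropout over time, or device artefacts. Passing
tests therefore demonstrate properties of the estimator under this model,
not performance on any particular real accelerometer stream.

## Numerical and scale choices

Simulation sizes in the test suite were chosen to keep Monte Carlo error
well below the effects being detected: 10,000 replications for primary
property checks (Monte Carlo error of the mean estimate ≈ 0.03 min/day),
2,000 for the supplementary allocation variant, $10^6$ draws for
moment-matching checks (1% tolerance), and 200–400 bootstrap replicates
for stability curves. Oracle comparisons use a relative tolerance of
$10^{-8}$. Degenerate inputs error early with named messages: empty
analysable sets, single-arm analyses, collinear designs, zero-variance
ICCs and correlations.

## Known limitations

* The model treats the 46 min/day daily SD as constant across
  participants and days; real wearables show heteroscedasticity.
* Complete-case ANCOVA is the only analysis; imputation-based and
  day-level mixed-model analyses are out of scope by design.
* MNAR deletes the lowest days deterministically — the most extreme form
  of activity-dependent missingness; graded (probabilistic) MNAR would
  interpolate between the MCAR and MNAR results shown here.
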