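# mvpasim

Monte Carlo simulation of two-arm randomised trials whose primary endpoint
is a wearable-derived digital outcome measure: daily minutes of
moderate-to-vigorous physical activity (MVPA). The package is for trial
statisticians weighing a switch from an in-clinic endpoint to a digital
one, and quantifies how seasonal variation, observer (Hawthorne) effects,
measurement-period length and missing-data mechanisms affect the bias and
standard error of the standard baseline-adjusted estimator. It also ships
reusable validation statistics for digital endpoints (test-retest ICC,
convergent correlations, known-groups medians, stability curves).

## Model

Daily MVPA for participant $i$ on follow-up day $j$ is log-normal with
natural-scale SD 46 min/day around

$$
\mu_{ij} = \text{baseline}_i + \delta_1\,\text{arm}_i
 + \delta_2\,\text{winter}_i + \delta_3\,\text{winter}_i\,\text{arm}_i
 + \delta_4\,\text{week1}_j + \delta_5\,\text{week1}_j\,\text{arm}_i
 + \alpha_i,
$$

with log-normal baselines (mean 77, SD 52 min/day), treatment effect
$\delta_1 = 12.5$ min/day, $\alpha_i \sim N(0, 4)$, 44 participants, 2:1
allocation, 28 days. The per-participant endpoint is the mean of observed
(compliant) days; a participant is analysed when at least 14 of 28 days
are observed. The primary analysis is the ANCOVA
$\bar y_{i\cdot} = \beta_0 + \beta_1\,\text{baseline}_i + \beta_2\,\text{treat}_i + \epsilon_i$,
and the estimand is $\beta_2$ with its standard error. Day-level
missingness is MCAR (random days) or MNAR (each affected participant's
lowest-activity days).

## Worked example

```r
library(mvpasim)

# one simulated trial with a seasonal effect of 10 min/day on half the cohort
trial <- simulate_trial(trial_design(),
                        effect_scenario(delta2 = 10, prop_winter = 0.5),
                        seed = 7)
trial
#> Simulated trial: 44 participants x 28 follow-up days
#>   treated: 29 | winter-recruited: 22 | observed days: 1232 / 1232

fit_primary_model(summarize_followup(trial))
#> Primary ANCOVA fit (n = 44 analysed, 0 excluded)
#>   treatment effect: 14.878 min/day (SE 3.330)
#>   intercept 4.192 | baseline slope 0.9863 | residual var 107.91

# repeat under the null nuisance scenario: the estimator centres on 12.5
cell <- run_cell(scenario = effect_scenario(), nsim = 500, base_seed = 7)
round(cell[, c("mean_beta2", "mc_error_mean", "mean_se", "mc_error_se")], 4)
#>   mean_beta2 mc_error_mean mean_se mc_error_se
#> 1    12.4003        0.1302  2.8647      0.0167

# split-period test-retest reliability of the monthly summary
icc_test_retest(rowMeans(trial$daily[, 1:14]), rowMeans(trial$daily[, 15:28]))
#> ICC = 0.970 (one-way random effects, single measurement (ICC(1,1)); n = 44 subjects)
```

The single-trial fit estimates a 14.9 min/day treatment effect — one
draw's sampling noise around the true 12.5. The 500-replication cell shows
the estimator is centred on 12.5 (mean 12.40, Monte Carlo error 0.13) with
a mean standard error of 2.86 min/day. The high split-half ICC reflects
the strong between-participant spread of baseline activity relative to
day-to-day noise in a 14-day mean.

Scenario grids (`seasonality_cells()`, `observer_cells()`,
`missingness_cells()`) run through `run_grid()`; `run_from_config()`
drives a whole study from a YAML file, and `replicate_study_grids()` runs
the three built-in grids under 2:1 and 1:1 allocation, writing CSVs,
figures and a checksummed manifest. A thin command-line wrapper lives at
`inst/scripts/mvpasim.R`.

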