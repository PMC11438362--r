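test_that("moment matching maps natural moments to log-scale parameters", {
  # degenerate point mass
  p <- moment_match_lognormal(1, 0)
  expect_equal(p$meanlog, 0)
  expect_equal(p$sdlog, 0)

  # closed form at the baseline constants
  p <- moment_match_lognormal(77, 52)
  expect_equal(p$sdlog, sqrt(log(1 + (52 / 77)^2)), tolerance = 1e-12)
  expect_equal(p$meanlog, log(77) - p$sdlog^2 / 2, tolerance = 1e-12)

  # algebraic inverse on a parameter grid
  grid <- expand.grid(m = c(0.5, 10, 77, 300), s = c(0, 1, 46, 120))
  p <- moment_match_lognormal(grid$m, grid$s)
  expect_equal(exp(p$meanlog + p$sdlog^2 / 2), grid$m, tolerance = 1e-12)
  expect_equal(sqrt((exp(p$sdlog^2) - 1)) * grid$m, grid$s, tolerance = 1e-12)

  expect_error(moment_match_lognormal(0, 1), "positive")
  expect_error(moment_match_lognormal(-3, 1), "positive")
})

test_that("moment-matched draws reproduce the natural moments", {
  set.seed(42)
  for (ms in list(c(77, 52), c(46, 46), c(10, 2))) {
    p <- moment_match_lognormal(ms[1], ms[2])
    y <- rlnorm(1e6, p$meanlog, p$sdlog)
    expect_equal(mean(y), ms[1], tolerance = 0.01)
    expect_equal(sd(y), ms[2], tolerance = 0.01)
  }
})

test_that("allocation and winter flags hit exact counts on the study grid", {
  set.seed(7)
  expect_equal(sum(allocate_arms(44, c(2, 1))), 29)
  expect_equal(sum(allocate_arms(44, c(1, 1))), 22)
  expect_equal(sum(allocate_arms(3, c(2, 1))), 2)
  expect_error(allocate_arms(2, c(100, 1)), "empty")

  for (pw in c(0, 0.1, 0.2, 0.5, 1)) {
    expect_equal(sum(assign_winter(44, pw)), floor(44 * pw + 0.5))
  }
  expect_equal(sum(assign_winter(44, 0.1)), 4)  # round(4.4), half away from 0
  expect_equal(sum(assign_winter(44, 0)), 0)
})

test_that("participant/day mean adds the effect terms of the outcome model", {
  sc <- effect_scenario(delta1 = 12.5)
  expect_equal(daily_mean(77, 1, 0, 0, 10, sc), 89.5)
  expect_equal(daily_mean(77, 0, 0, 0, 10, sc), 77)

  sc_all <- effect_scenario(delta1 = 12.5, delta2 = 10, delta3 = 1,
                            delta4 = 10, delta5 = 1)
  expect_equal(daily_mean(77, 1, 1, 0, 3, sc_all), 111.5)
  # week-1 terms switch off from day 8
  expect_equal(daily_mean(77, 1, 1, 0, 8, sc_all), 100.5)
  # floor engages for pathological baselines
  expect_equal(daily_mean(0.2, 0, 0, -5, 10, sc), 1)
})

test_that("simulated trials have the declared shape and are reproducible", {
  trial <- simulate_trial(trial_design(), effect_scenario(), seed = 11)
  expect_equal(dim(trial$daily), c(44, 28))
  expect_true(all(trial$daily > 0))
  expect_true(all(trial$observed))
  expect_equal(sum(trial$participants$arm), 29)

  trial2 <- simulate_trial(trial_design(), effect_scenario(), seed = 11)
  expect_identical(trial, trial2)
  trial3 <- simulate_trial(trial_design(), effect_scenario(), seed = 12)
  expect_false(identical(trial$daily, trial3$daily))

  long <- as.data.frame(trial)
  expect_equal(nrow(long), 44 * 28)
  expect_equal(long$value[long$participant_id == 3 & long$day == 5],
               trial$daily[3, 5])
})

test_that("with no random effect the day-level mean matches expectation", {
  # grand mean over a large cohort approximates the mean baseline (all
  # deltas zero), within 3 standard errors of the grand mean
  design <- trial_design(n_participants = 400, n_followup_days = 28,
                         random_effect_var = 0)
  sc <- effect_scenario(delta1 = 0, measurement_period_days = 28)
  trial <- simulate_trial(design, sc, seed = 99)
  gm <- mean(trial$daily)
  se_gm <- sd(trial$daily) / sqrt(length(trial$daily))
  # daily values centre on each participant's baseline
  expect_lt(abs(gm - mean(trial$participants$baseline)), 3 * se_gm)

  # E[y_ij] = mu_ij at three (participant, day) configurations
  set.seed(5)
  for (cfg in list(c(77, 1, 10), c(77, 0, 3), c(40, 1, 3))) {
    sc2 <- effect_scenario(delta1 = 12.5, delta4 = 10, delta5 = 1)
    mu <- daily_mean(cfg[1], cfg[2], 0, 0, cfg[3], sc2)
    p <- moment_match_lognormal(mu, 46)
    draws <- rlnorm(2e5, p$meanlog, p$sdlog)
    expect_lt(abs(mean(draws) - mu), 3 * sd(draws) / sqrt(length(draws)))
  }
})
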