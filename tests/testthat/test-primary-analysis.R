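test_that("follow-up summary averages observed days within the period", {
  design <- trial_design(n_participants = 4, n_followup_days = 6)
  sc <- effect_scenario(measurement_period_days = 6)
  trial <- simulate_trial(design, sc, seed = 61)
  trial$daily[1, ] <- c(10, 20, 30, 100, 100, 100)
  trial$observed[1, 4:6] <- FALSE
  s <- summarize_followup(trial, compliance_rule(min_compliant_days = 3))
  expect_equal(s$ybar[s$participant_id == 1], 20)
  expect_equal(s$n_compliant_days[s$participant_id == 1], 3L)

  # constant series over any observed subset
  trial$daily[2, ] <- 7
  trial$observed[2, c(2, 5)] <- FALSE
  s <- summarize_followup(trial, compliance_rule(min_compliant_days = 3))
  expect_equal(s$ybar[s$participant_id == 2], 7)

  # window restriction: period shorter than follow-up
  trial$observed[] <- TRUE
  s14 <- summarize_followup(trial, period_days = 3)
  expect_equal(s14$ybar[s14$participant_id == 1], 20)  # mean of days 1-3

  # excluded participants are counted
  trial$observed[3, ] <- FALSE
  s <- summarize_followup(trial, compliance_rule(min_compliant_days = 3))
  expect_equal(attr(s, "n_excluded"), 1L)
  expect_false(3 %in% s$participant_id)
})

test_that("the ANCOVA recovers exact coefficients on noise-free data", {
  set.seed(71)
  d <- data.frame(baseline = runif(10, 50, 100),
                  arm = rep(0:1, each = 5))
  d$ybar <- 5 + 1 * d$baseline + 12.5 * d$arm
  fit <- suppressWarnings(fit_primary_model(d))  # exact fit warns in summary.lm
  expect_equal(fit$beta0, 5, tolerance = 1e-10)
  expect_equal(fit$beta1, 1, tolerance = 1e-10)
  expect_equal(fit$beta2, 12.5, tolerance = 1e-10)
  expect_equal(fit$residual_var, 0, tolerance = 1e-14)

  # identical outcomes across rows carry no treatment signal
  d$ybar <- 42
  fit0 <- suppressWarnings(fit_primary_model(d))
  expect_equal(fit0$beta2, 0, tolerance = 1e-10)

  expect_error(fit_primary_model(d[d$arm == 1, ]), "both arms")
  expect_error(fit_primary_model(d[1:3, ]), "at least 4")
  d$baseline <- d$arm  # collinear
  expect_error(fit_primary_model(d), "singular")
})

test_that("the fit matches an independent normal-equations solve", {
  set.seed(72)
  for (r in 1:25) {
    n <- sample(8:40, 1)
    d <- data.frame(baseline = rlnorm(n, 4.2, 0.6),
                    arm = sample(c(rep(1, ceiling(n / 2)),
                                   rep(0, floor(n / 2)))))
    d$ybar <- 3 + 0.9 * d$baseline + 12.5 * d$arm + rnorm(n, 0, 15)
    fit <- fit_primary_model(d)
    o <- ols_oracle(cbind(1, d$baseline, d$arm), d$ybar)
    expect_equal(fit$beta0, o$beta[1], tolerance = 1e-8)
    expect_equal(fit$beta1, o$beta[2], tolerance = 1e-8)
    expect_equal(fit$beta2, o$beta[3], tolerance = 1e-8)
    expect_equal(fit$se_beta2, o$se[3], tolerance = 1e-8)
    expect_equal(fit$residual_var, o$sigma2, tolerance = 1e-8)
  }
})

test_that("the fit is invariant to row order and equivariant to shifts", {
  set.seed(73)
  d <- data.frame(baseline = rlnorm(20, 4.2, 0.6),
                  arm = rep(0:1, 10))
  d$ybar <- 3 + d$baseline + 12.5 * d$arm + rnorm(20, 0, 10)

  f1 <- fit_primary_model(d)
  f2 <- fit_primary_model(d[sample(20), ])
  expect_equal(f1$beta2, f2$beta2, tolerance = 1e-10)
  expect_equal(f1$se_beta2, f2$se_beta2, tolerance = 1e-10)

  d3 <- d; d3$ybar <- d3$ybar + 100
  f3 <- fit_primary_model(d3)
  expect_equal(f3$beta0, f1$beta0 + 100, tolerance = 1e-8)
  expect_equal(f3$beta1, f1$beta1, tolerance = 1e-10)
  expect_equal(f3$beta2, f1$beta2, tolerance = 1e-10)
})
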