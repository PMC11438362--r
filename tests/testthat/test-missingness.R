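test_that("MCAR removes exact counts without touching values", {
  trial <- simulate_trial(seed = 21)
  out <- apply_missingness(trial, missingness_spec("MCAR", 0.5, 0.5),
                           seed = 22)
  expect_identical(out$daily, trial$daily)
  miss_per_p <- rowSums(!out$observed)
  expect_equal(sum(miss_per_p > 0), 22)
  expect_true(all(miss_per_p[miss_per_p > 0] == 14))

  # no-op cases leave the mask alone
  same <- apply_missingness(trial, missingness_spec("MCAR", 0, 0.5), seed = 1)
  expect_identical(same$observed, trial$observed)
  same2 <- apply_missingness(trial, missingness_spec("none"), seed = 1)
  expect_identical(same2$observed, trial$observed)
})

test_that("MCAR day selection is independent of the outcome values", {
  # over many seeds, removed and retained days have similar means
  trial <- simulate_trial(seed = 31)
  diffs <- vapply(1:200, function(s) {
    out <- apply_missingness(trial, missingness_spec("MCAR", 0.5, 0.5),
                             seed = s)
    aff <- rowSums(!out$observed) > 0
    y <- out$daily[aff, , drop = FALSE]
    m <- out$observed[aff, , drop = FALSE]
    mean(y[!m]) - mean(y[m])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("MNAR removes the lowest-activity days, earliest day on ties", {
  design <- trial_design(n_participants = 4, n_followup_days = 4)
  sc <- effect_scenario(measurement_period_days = 4)
  trial <- simulate_trial(design, sc, seed = 41)
  trial$daily[1, ] <- c(5, 1, 9, 3)
  trial$daily[2, ] <- c(2, 2, 2, 7)  # tie among days 1-3
  out <- apply_missingness(trial, missingness_spec("MNAR", 1, 0.5), seed = 42)
  expect_equal(which(!out$observed[1, ]), c(2, 4))   # values 1 and 3
  expect_equal(which(!out$observed[2, ]), c(1, 2))   # earliest tied days

  # removing minima can only raise each affected participant's observed mean
  trial2 <- simulate_trial(seed = 43)
  out2 <- apply_missingness(trial2, missingness_spec("MNAR", 0.5, 0.5),
                            seed = 44)
  for (i in which(rowSums(!out2$observed) > 0)) {
    expect_gte(mean(trial2$daily[i, out2$observed[i, ]]),
               mean(trial2$daily[i, ]))
  }
})

test_that("compliance filter applies the inclusive day threshold", {
  trial <- simulate_trial(seed = 51)
  expect_equal(compliance_filter(trial), 1:44)  # complete data: all included

  # exactly 14 of 28 observed -> included; 13 -> excluded
  trial$observed[1, 1:14] <- FALSE   # 14 left
  trial$observed[2, 1:15] <- FALSE   # 13 left
  ids <- compliance_filter(trial, compliance_rule(min_compliant_days = 14))
  expect_true(1 %in% ids)
  expect_false(2 %in% ids)

  # default threshold scales to ceil(period/2)
  ids14 <- compliance_filter(trial, period_days = 14)
  expect_false(1 %in% ids14)  # 0 observed in first 14 days
  expect_true(3 %in% ids14)

  trial$observed[] <- FALSE
  expect_error(compliance_filter(trial), "no participant")
})
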