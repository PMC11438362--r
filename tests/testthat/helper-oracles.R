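# Independent oracles kept separate from the implementation paths.

# OLS by explicit normal equations, with classical standard errors.
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% beta
  sigma2 <- sum(resid^2) / (nrow(X) - ncol(X))
  list(beta = drop(beta), se = sqrt(diag(sigma2 * solve(XtX))),
       sigma2 = sigma2)
}

# One-way ICC(1,1) via stats::aov mean squares (k repeats per subject).
icc_aov_oracle <- function(first, second) {
  d <- data.frame(value = c(first, second),
                  subject = factor(rep(seq_along(first), 2)))
  ms <- summary(stats::aov(value ~ subject, data = d))[[1]][["Mean Sq"]]
  (ms[1] - ms[2]) / (ms[1] + (2 - 1) * ms[2])
}

# small default design/scenario used across tests
tiny_design <- function(...) trial_design(n_participants = 12,
                                          n_followup_days = 8, ...)
tiny_scenario <- function(...) effect_scenario(measurement_period_days = 8, ...)
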