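#' Per-participant follow-up summary over compliant days
#'
#' For every participant passing the compliance filter, computes the mean
#' daily MVPA over the observed days within the first `period_days` of
#' follow-up — the endpoint carried into the primary analysis. Excluded
#' participants are counted in the `n_excluded` attribute.
#'
#' @param dataset A `trial_dataset`.
#' @param rule A [compliance_rule()].
#' @param period_days Measurement period; defaults to the scenario's.
#' @return Data frame with columns `participant_id`, `arm`, `winter`,
#'   `baseline`, `ybar`, `n_compliant_days`; attribute `n_excluded`.
#' @examples
#' trial <- simulate_trial(seed = 1)
#' head(summarize_followup(trial))
#' @export
summarize_followup <- function(dataset, rule = compliance_rule(),
                               period_days = NULL) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (is.null(period_days))
    period_days <- dataset$scenario$measurement_period_days
  ids <- compliance_filter(dataset, rule, period_days)
  keep <- dataset$participants$id %in% ids

  win <- seq_len(period_days)
  y <- dataset$daily[keep, win, drop = FALSE]
  m <- dataset$observed[keep, win, drop = FALSE]
  n_obs <- rowSums(m)
  ybar <- rowSums(y * m) / n_obs

  p <- dataset$participants[keep, , drop = FALSE]
  out <- data.frame(participant_id = p$id, arm = p$arm, winter = p$winter,
                    baseline = p$baseline, ybar = ybar,
                    n_compliant_days = as.integer(n_obs),
                    row.names = NULL)
  attr(out, "n_excluded") <- nrow(dataset$daily) - nrow(out)
  out
}

#' Fit the primary ANCOVA model
#'
#' Ordinary least squares of the follow-up mean on an intercept, the
#' baseline MVPA and the treatment indicator. The trial estimand is the
#' treatment coefficient (`beta2`, min/day) and its model-based standard
#' error.
#'
#' @param summaries Output of [summarize_followup()] (or any data frame with
#'   `ybar`, `baseline`, `arm`).
#' @return An object of class `primary_fit`: list with `beta0`, `beta1`,
#'   `beta2`, `se_beta2`, `residual_var`, `n_analysed`, `n_excluded`.
#' @examples
#' trial <- simulate_trial(seed = 1)
#' fit_primary_model(summarize_followup(trial))
#' @export
fit_primary_model <- function(summaries) {
  stopifnot(all(c("ybar", "baseline", "arm") %in% names(summaries)))
  if (nrow(summaries) < 4)
    stop("need at least 4 analysable participants", call. = FALSE)
  if (length(unique(summaries$arm)) < 2)
    stop("both arms must be represented among analysable participants",
         call. = FALSE)

  fit <- stats::lm(ybar ~ baseline + arm, data = summaries)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("singular design: baseline and arm are collinear", call. = FALSE)
  se <- sqrt(diag(stats::vcov(fit)))

  structure(
    list(beta0 = unname(cf["(Intercept)"]),
         beta1 = unname(cf["baseline"]),
         beta2 = unname(cf["arm"]),
         se_beta2 = unname(se["arm"]),
         residual_var = stats::sigma(fit)^2,
         n_analysed = nrow(summaries),
         n_excluded = attr(summaries, "n_excluded") %||% NA_integer_),
    class = "primary_fit")
}

#' @export
print.primary_fit <- function(x, ...) {
  cat("Primary ANCOVA fit (n =", x$n_analysed, "analysed,",
      x$n_excluded, "excluded)\n")
  cat(sprintf("  treatment effect: %.3f min/day (SE %.3f)\n",
              x$beta2, x$se_beta2))
  cat(sprintf("  intercept %.3f | baseline slope %.4f | residual var %.2f\n",
              x$beta0, x$beta1, x$residual_var))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
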