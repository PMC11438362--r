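#' Day-level missingness specification
#'
#' Describes which mechanism deletes follow-up days and how much:
#' `"none"`, `"MCAR"` (each affected participant loses a fixed proportion of
#' uniformly chosen days) or `"MNAR"` (each affected participant loses the
#' days with the lowest activity values — missingness depends on the
#' unobserved outcome itself).
#'
#' @param mechanism One of `"none"`, `"MCAR"`, `"MNAR"`.
#' @param prop_participants Fraction of participants affected, in \[0, 1\].
#' @param prop_days Fraction of each affected participant's measurement-period
#'   days deleted, in \[0, 1\].
#' @return An object of class `missingness_spec`.
#' @examples
#' missingness_spec("MCAR", prop_participants = 0.5, prop_days = 0.5)
#' @export
missingness_spec <- function(mechanism = c("none", "MCAR", "MNAR"),
                             prop_participants = 0,
                             prop_days = 0) {
  mechanism <- match.arg(mechanism)
  stopifnot(prop_participants >= 0, prop_participants <= 1,
            prop_days >= 0, prop_days <= 1)
  if (mechanism == "none" && (prop_participants > 0 || prop_days > 0))
    stop("mechanism \"none\" requires both proportions to be 0", call. = FALSE)
  structure(list(mechanism = mechanism,
                 prop_participants = prop_participants,
                 prop_days = prop_days),
            class = "missingness_spec")
}

#' Wear-time compliance rule
#'
#' A follow-up day counts as compliant when the device was worn at least
#' `min_wear_minutes` (600 min = 10 h while awake, by convention); here a
#' non-compliant day is represented directly as an unobserved day, so the
#' wear threshold is documentary. A participant's measurement period is
#' analysable when it contains at least `min_compliant_days` compliant days
#' (14 for a 28-day period; by default half the period, rounded up).
#'
#' @param min_wear_minutes Wear-time threshold defining a compliant day.
#' @param min_compliant_days Minimum compliant days for inclusion, or `NULL`
#'   to use `ceiling(period / 2)` at filter time.
#' @return An object of class `compliance_rule`.
#' @export
compliance_rule <- function(min_wear_minutes = 600,
                            min_compliant_days = NULL) {
  if (!is.null(min_compliant_days) && min_compliant_days < 1)
    stop("`min_compliant_days` must be >= 1", call. = FALSE)
  structure(list(min_wear_minutes = min_wear_minutes,
                 min_compliant_days = min_compliant_days),
            class = "compliance_rule")
}

threshold_days <- function(rule, period_days) {
  if (is.null(rule$min_compliant_days)) ceiling(period_days / 2)
  else rule$min_compliant_days
}

#' Apply day-level missingness to a simulated trial
#'
#' Selects exactly `round(prop_participants * n)` participants uniformly at
#' random and, within the first `period_days` of follow-up, marks exactly
#' `round(prop_days * period_days)` days per selected participant as
#' unobserved — uniformly at random under MCAR, or the days with the lowest
#' MVPA values (ties broken by earliest day) under MNAR. Values are never
#' modified; only the observation mask shrinks.
#'
#' @param dataset A `trial_dataset`.
#' @param spec A [missingness_spec()].
#' @param period_days Measurement period the proportions refer to; defaults
#'   to the dataset's scenario period.
#' @param seed Optional integer seed for the participant/day selection.
#' @return The dataset with its `observed` mask updated.
#' @examples
#' trial <- simulate_trial(seed = 1)
#' spec <- missingness_spec("MNAR", 0.5, 0.5)
#' trial_miss <- apply_missingness(trial, spec, seed = 2)
#' sum(!trial_miss$observed)  # 22 participants x 14 days
#' @export
apply_missingness <- function(dataset, spec, period_days = NULL, seed = NULL) {
  stopifnot(inherits(dataset, "trial_dataset"),
            inherits(spec, "missingness_spec"))
  if (spec$mechanism == "none") return(dataset)
  if (is.null(period_days))
    period_days <- dataset$scenario$measurement_period_days
  stopifnot(period_days <= ncol(dataset$daily))
  if (!is.null(seed)) set.seed(seed)

  n <- nrow(dataset$daily)
  n_sel <- round_half_up(spec$prop_participants * n)
  n_days <- round_half_up(spec$prop_days * period_days)
  if (n_sel == 0L || n_days == 0L) return(dataset)
  chosen <- sample.int(n, n_sel)

  for (i in chosen) {
    if (spec$mechanism == "MCAR") {
      gone <- sample.int(period_days, n_days)
    } else {  # MNAR: lowest-activity days, earliest-day tie break
      y <- dataset$daily[i, seq_len(period_days)]
      gone <- order(y, seq_len(period_days))[seq_len(n_days)]
    }
    dataset$observed[i, gone] <- FALSE
  }
  dataset
}

#' Participants passing the compliance filter
#'
#' A participant is analysable when the number of observed (compliant) days
#' within the first `period_days` of follow-up meets the rule's threshold
#' (inclusive).
#'
#' @param dataset A `trial_dataset` (missingness already applied, if any).
#' @param rule A [compliance_rule()].
#' @param period_days Measurement period; defaults to the scenario's.
#' @return Integer vector of analysable participant ids.
#' @export
compliance_filter <- function(dataset, rule = compliance_rule(),
                              period_days = NULL) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (is.null(period_days))
    period_days <- dataset$scenario$measurement_period_days
  stopifnot(period_days <= ncol(dataset$daily))
  thr <- threshold_days(rule, period_days)
  n_obs <- rowSums(dataset$observed[, seq_len(period_days), drop = FALSE])
  ids <- dataset$participants$id[n_obs >= thr]
  if (length(ids) == 0L)
    stop("no participant meets the compliance threshold", call. = FALSE)
  ids
}
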