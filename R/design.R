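#' Trial design configuration
#'
#' Fixed parameters of the simulated two-arm trial: sample size, allocation
#' ratio, follow-up length and the distributional constants of the
#' day-level MVPA model. Defaults reproduce a 44-participant, 2:1,
#' 28-day phase II set-up with log-normal baselines (natural-scale mean 77,
#' SD 52 min/day), daily outcomes with natural-scale SD 46 min/day and a
#' participant random effect with variance 4 (min/day)^2.
#'
#' @param n_participants Number of participants (>= 2).
#' @param allocation_ratio Integer vector of length 2, treatment:control.
#' @param n_followup_days Length of the follow-up period in days.
#' @param baseline_mean,baseline_sd Natural-scale mean and SD (min/day) of the
#'   log-normal baseline MVPA distribution.
#' @param daily_sd Natural-scale SD (min/day) of the daily follow-up outcome
#'   around its participant/day mean.
#' @param random_effect_var Variance of the additive participant random
#'   effect, in (min/day)^2.
#' @param mean_floor Small positive floor (min/day) applied to the
#'   participant/day mean before moment matching, so the log-normal stays
#'   defined when a tiny baseline draw meets a negative random effect.
#' @return An object of class `trial_design`.
#' @examples
#' trial_design()
#' trial_design(allocation_ratio = c(1, 1))
#' @export
trial_design <- function(n_participants = 44,
                         allocation_ratio = c(2, 1),
                         n_followup_days = 28,
                         baseline_mean = 77,
                         baseline_sd = 52,
                         daily_sd = 46,
                         random_effect_var = 4,
                         mean_floor = 1) {
  if (length(n_participants) != 1L || n_participants < 2)
    stop("`n_participants` must be a single count >= 2", call. = FALSE)
  if (length(allocation_ratio) != 2L ||
      any(allocation_ratio != as.integer(allocation_ratio)) ||
      any(allocation_ratio < 1))
    stop("`allocation_ratio` must be two positive integers (treatment, control)",
         call. = FALSE)
  if (n_followup_days < 1)
    stop("`n_followup_days` must be >= 1", call. = FALSE)
  if (baseline_mean <= 0 || daily_sd <= 0 || baseline_sd < 0)
    stop("scale parameters must be positive", call. = FALSE)
  if (random_effect_var < 0)
    stop("`random_effect_var` must be non-negative", call. = FALSE)
  if (mean_floor <= 0)
    stop("`mean_floor` must be strictly positive", call. = FALSE)
  structure(
    list(n_participants = as.integer(n_participants),
         allocation_ratio = as.integer(allocation_ratio),
         n_followup_days = as.integer(n_followup_days),
         baseline_mean = baseline_mean,
         baseline_sd = baseline_sd,
         daily_sd = daily_sd,
         random_effect_var = random_effect_var,
         mean_floor = mean_floor),
    class = "trial_design")
}

#' Effect scenario for the data-generating mechanism
#'
#' The effect parameters of the day-level mean model. All effects are
#' additive on the minutes/day scale:
#' treatment (`delta1`), season for winter-recruited participants
#' (`delta2`), season-by-treatment interaction (`delta3`), first-week
#' observer (Hawthorne) effect (`delta4`) and observer-by-treatment
#' interaction (`delta5`).
#'
#' @param delta1 Treatment effect in min/day (default 12.5).
#' @param delta2 Seasonal effect (min/day) for winter-recruited participants.
#' @param delta3 Season-by-treatment interaction (min/day). When a scenario
#'   "with interaction" is wanted, the study convention is
#'   `delta3 = 0.1 * delta2`.
#' @param delta4 Observer effect (min/day) applied on follow-up days 1-7.
#' @param delta5 Observer-by-treatment interaction (min/day); the
#'   with-interaction convention is `delta5 = 0.1 * delta4`.
#' @param prop_winter Fraction of the cohort recruited in winter, in \[0, 1\].
#' @param measurement_period_days Length of the measurement period actually
#'   analysed (<= follow-up length); 14 or 28 in the built-in grids.
#' @return An object of class `effect_scenario`.
#' @examples
#' effect_scenario()                                 # null nuisance effects
#' effect_scenario(delta2 = 10, delta3 = 1, prop_winter = 0.5)
#' @export
effect_scenario <- function(delta1 = 12.5,
                            delta2 = 0,
                            delta3 = 0,
                            delta4 = 0,
                            delta5 = 0,
                            prop_winter = 0,
                            measurement_period_days = 28) {
  stopifnot(length(prop_winter) == 1L)
  if (prop_winter < 0 || prop_winter > 1)
    stop("`prop_winter` must lie in [0, 1]", call. = FALSE)
  if (measurement_period_days < 1)
    stop("`measurement_period_days` must be >= 1", call. = FALSE)
  if (any(c(delta2, delta3, delta4, delta5) < 0))
    warning("negative nuisance effects are unusual for these scenario grids",
            call. = FALSE)
  structure(
    list(delta1 = delta1, delta2 = delta2, delta3 = delta3,
         delta4 = delta4, delta5 = delta5,
         prop_winter = prop_winter,
         measurement_period_days = as.integer(measurement_period_days)),
    class = "effect_scenario")
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Trial design:", x$n_participants, "participants,",
      paste0(x$allocation_ratio, collapse = ":"), "allocation,",
      x$n_followup_days, "follow-up days\n")
  cat("  baseline ~ logN(mean ", x$baseline_mean, ", sd ", x$baseline_sd,
      ") min/day; daily sd ", x$daily_sd,
      "; random-effect var ", x$random_effect_var, "\n", sep = "")
  invisible(x)
}

#' @export
print.effect_scenario <- function(x, ...) {
  cat("Effect scenario (min/day): treatment", x$delta1,
      "| season", x$delta2, "(x trt", paste0(x$delta3, ")"),
      "| observer", x$delta4, "(x trt", paste0(x$delta5, ")"), "\n")
  cat("  winter proportion ", x$prop_winter,
      "; measurement period ", x$measurement_period_days, " days\n", sep = "")
  invisible(x)
}

# round half away from zero; base round() rounds half to even
round_half_up <- function(x) floor(x + 0.5)
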