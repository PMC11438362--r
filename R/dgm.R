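#' Moment-match a log-normal to natural-scale mean and SD
#'
#' Converts a natural-scale mean and standard deviation into the log-scale
#' parameters (`meanlog`, `sdlog`) of the log-normal distribution with those
#' moments: `sdlog^2 = log(1 + (sd/mean)^2)` and
#' `meanlog = log(mean) - sdlog^2 / 2`. Vectorised over both arguments.
#'
#' The day-level outcome model is additive on the minutes/day scale, so all
#' distributional constants are natural-scale moments and every draw goes
#' through this mapping.
#'
#' @param mean Natural-scale mean (> 0). May be a vector or matrix.
#' @param sd Natural-scale standard deviation (>= 0), recycled against `mean`.
#' @return A list with components `meanlog` and `sdlog`, shaped like the
#'   broadcast of the inputs.
#' @examples
#' moment_match_lognormal(77, 52)
#' p <- moment_match_lognormal(77, 52)
#' exp(p$meanlog + p$sdlog^2 / 2)  # recovers 77
#' @export
moment_match_lognormal <- function(mean, sd) {
  if (any(!is.finite(mean)) || any(mean <= 0))
    stop("`mean` must be strictly positive and finite", call. = FALSE)
  if (any(sd < 0))
    stop("`sd` must be non-negative", call. = FALSE)
  sdlog2 <- log1p((sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Randomise participants to arms in a fixed ratio
#'
#' Exactly `round(n * r_t / (r_t + r_c))` participants (half rounded away
#' from zero) receive treatment; assignment order is uniformly random.
#'
#' @param n Number of participants.
#' @param ratio Integer pair, treatment:control.
#' @return Integer vector of 0 (control) / 1 (treatment) of length `n`.
#' @examples
#' set.seed(1); table(allocate_arms(44, c(2, 1)))  # 15 control, 29 treated
#' @export
allocate_arms <- function(n, ratio = c(2, 1)) {
  stopifnot(n >= 2, length(ratio) == 2L, all(ratio >= 1))
  n_trt <- round_half_up(n * ratio[1] / sum(ratio))
  if (n_trt == 0L || n_trt == n)
    stop("allocation leaves an arm empty; adjust n or ratio", call. = FALSE)
  arms <- integer(n)
  arms[sample.int(n, n_trt)] <- 1L
  arms
}

#' Flag the winter-recruited fraction of the cohort
#'
#' Exactly `round(n * prop_winter)` participants (half rounded away from
#' zero) are flagged, chosen uniformly at random and independently of arm.
#'
#' @param n Number of participants.
#' @param prop_winter Fraction in \[0, 1\].
#' @return Integer vector of 0/1 winter flags of length `n`.
#' @export
assign_winter <- function(n, prop_winter) {
  stopifnot(prop_winter >= 0, prop_winter <= 1)
  n_winter <- round_half_up(n * prop_winter)
  flags <- integer(n)
  if (n_winter > 0) flags[sample.int(n, n_winter)] <- 1L
  flags
}

#' Participant/day mean of the outcome model
#'
#' The natural-scale mean for participant `i` on follow-up day `j`:
#' baseline, plus the treatment effect for the treated arm, the seasonal
#' effect (and its treatment interaction) for winter-recruited participants,
#' the observer effect (and its treatment interaction) during week 1
#' (days 1-7), plus the participant random effect; floored at the design's
#' `mean_floor`.
#'
#' @param baseline Baseline MVPA (min/day).
#' @param arm 0/1 treatment indicator.
#' @param winter 0/1 winter-recruitment indicator.
#' @param random_effect Participant random effect (min/day).
#' @param day Follow-up day index, 1-based.
#' @param scenario An [effect_scenario()].
#' @param mean_floor Positive floor applied to the result.
#' @return The mean in min/day (vectorised over `day`).
#' @examples
#' sc <- effect_scenario(delta1 = 12.5)
#' daily_mean(77, arm = 1, winter = 0, random_effect = 0, day = 10, scenario = sc)
#' @export
daily_mean <- function(baseline, arm, winter, random_effect, day, scenario,
                       mean_floor = 1) {
  week1 <- as.integer(day >= 1 & day <= 7)
  mu <- baseline +
    scenario$delta1 * arm +
    scenario$delta2 * winter +
    scenario$delta3 * winter * arm +
    scenario$delta4 * week1 +
    scenario$delta5 * week1 * arm +
    random_effect
  pmax(mu, mean_floor)
}

#' Simulate one trial from the day-level outcome model
#'
#' Draws a complete trial: log-normal baselines, normal participant random
#' effects, randomised arms, winter flags, and the follow-up matrix of daily
#' MVPA values, each day drawn log-normally with natural-scale mean given by
#' [daily_mean()] and natural-scale SD `design$daily_sd`, conditionally
#' independent across days given the random effect.
#'
#' Random draws are consumed in a fixed order (baselines, random effects,
#' arms, winter flags, then the daily matrix row by row) so a seed fully
#' determines the dataset.
#'
#' @param design A [trial_design()].
#' @param scenario An [effect_scenario()].
#' @param seed Integer seed; if `NULL` the current RNG state is used.
#' @return An object of class `trial_dataset`: a list with `participants`
#'   (data frame: `id`, `arm`, `winter`, `baseline`, `random_effect`),
#'   `daily` (n x days matrix, min/day), `observed` (same-shape logical mask,
#'   all `TRUE` on generation), `design`, `scenario`, `seed`, `n_floored`
#'   (count of participant/day means clipped at the floor) and `rng_kind`.
#' @examples
#' trial <- simulate_trial(trial_design(), effect_scenario(), seed = 1)
#' dim(trial$daily)
#' @export
simulate_trial <- function(design = trial_design(),
                           scenario = effect_scenario(),
                           seed = NULL) {
  stopifnot(inherits(design, "trial_design"),
            inherits(scenario, "effect_scenario"))
  if (scenario$measurement_period_days > design$n_followup_days)
    stop("measurement period exceeds follow-up length", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  n <- design$n_participants
  d <- design$n_followup_days

  bl_par <- moment_match_lognormal(design$baseline_mean, design$baseline_sd)
  baseline <- stats::rlnorm(n, bl_par$meanlog, bl_par$sdlog)
  alpha <- stats::rnorm(n, 0, sqrt(design$random_effect_var))
  arm <- allocate_arms(n, design$allocation_ratio)
  winter <- assign_winter(n, scenario$prop_winter)

  mu <- matrix(0, n, d)
  for (j in seq_len(d)) {
    mu[, j] <- daily_mean(baseline, arm, winter, alpha, j, scenario,
                          mean_floor = design$mean_floor)
  }
  n_floored <- sum(mu == design$mean_floor)

  pars <- moment_match_lognormal(mu, design$daily_sd)
  # consume draws row-major so the documented draw order is participant-major
  y_vec <- stats::rlnorm(n * d,
                         meanlog = as.vector(t(pars$meanlog)),
                         sdlog = as.vector(t(pars$sdlog)))
  daily <- matrix(y_vec, nrow = n, byrow = TRUE)

  structure(
    list(participants = data.frame(id = seq_len(n), arm = arm, winter = winter,
                                   baseline = baseline, random_effect = alpha),
         daily = daily,
         observed = matrix(TRUE, n, d),
         design = design, scenario = scenario,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         n_floored = n_floored,
         rng_kind = RNGkind()[1]),
    class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("Simulated trial:", nrow(x$daily), "participants x",
      ncol(x$daily), "follow-up days\n")
  cat("  treated:", sum(x$participants$arm), "| winter-recruited:",
      sum(x$participants$winter), "| observed days:", sum(x$observed),
      "/", length(x$observed), "\n")
  invisible(x)
}

#' Long-format view of a simulated trial
#'
#' One row per participant-day with the observation mask, suitable for
#' writing to CSV.
#'
#' @param x A `trial_dataset`.
#' @param ... Unused.
#' @return A data frame with columns `participant_id`, `arm`, `winter`,
#'   `baseline`, `day`, `value`, `observed`.
#' @export
as.data.frame.trial_dataset <- function(x, ...) {
  n <- nrow(x$daily); d <- ncol(x$daily)
  p <- x$participants
  data.frame(
    participant_id = rep(p$id, each = d),
    arm = rep(p$arm, each = d),
    winter = rep(p$winter, each = d),
    baseline = rep(p$baseline, each = d),
    day = rep(seq_len(d), times = n),
    value = as.vector(t(x$daily)),
    observed = as.vector(t(x$observed)))
}
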