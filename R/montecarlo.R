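#' Monte Carlo standard error of a simulation summary
#'
#' Sample standard deviation of the replication draws divided by the square
#' root of the number of draws. Figures conventionally display
#' `1.96 * mc_error()` as error bars; the factor is applied at plot time.
#'
#' @param draws Numeric vector of at least 2 replication values.
#' @return The Monte Carlo error as a single number.
#' @examples
#' mc_error(c(1, 2, 3))  # sd 1 over sqrt(3)
#' @export
mc_error <- function(draws) {
  if (length(draws) < 2)
    stop("need at least 2 draws for a Monte Carlo error", call. = FALSE)
  stats::sd(draws) / sqrt(length(draws))
}

# deterministic 31-bit mix for deriving cell seeds from (base_seed, index)
derive_seed <- function(base_seed, index) {
  m <- 2147483647  # 2^31 - 1
  s <- (as.numeric(base_seed) %% m) * 48271 + as.numeric(index) * 8191
  as.integer(s %% (m - 1) + 1)
}

#' Run one scenario cell of the simulation study
#'
#' Repeats `nsim` times: simulate a trial, apply missingness, summarise the
#' follow-up period under the compliance rule, fit the primary ANCOVA; then
#' averages the treatment-effect estimates and their standard errors and
#' attaches Monte Carlo errors for both. Per-replication seeds (one for the
#' trial, one for the missingness selection) are drawn from a stream seeded
#' by `base_seed`, so results are reproducible and the missingness pattern
#' is independent of the simulated values.
#'
#' Replications whose fit fails (e.g. an empty analysable set) are dropped
#' and counted; the cell errors out if more than 1% fail.
#'
#' @param design A [trial_design()].
#' @param scenario An [effect_scenario()].
#' @param missing A [missingness_spec()].
#' @param nsim Number of replications (>= 2); 10,000 for production grids.
#' @param base_seed Integer seed for the cell.
#' @param rule A [compliance_rule()].
#' @param keep_draws If `TRUE`, attach the per-replication `beta2` and SE
#'   draws as attributes `"beta2"` and `"se"`.
#' @return One-row data frame: scenario/missingness parameters, `mean_beta2`,
#'   `mc_error_mean`, `mean_se`, `mc_error_se`, `nsim_effective`, `base_seed`.
#' @examples
#' run_cell(nsim = 50, base_seed = 1)
#' @export
run_cell <- function(design = trial_design(),
                     scenario = effect_scenario(),
                     missing = missingness_spec("none"),
                     nsim = 10000,
                     base_seed = 1,
                     rule = compliance_rule(),
                     keep_draws = FALSE) {
  stopifnot(nsim >= 2)
  set.seed(base_seed)
  seeds <- matrix(sample.int(2147483646L, 2 * nsim, replace = TRUE),
                  ncol = 2)

  beta2 <- se <- rep(NA_real_, nsim)
  n_fail <- 0L
  for (r in seq_len(nsim)) {
    res <- tryCatch({
      trial <- simulate_trial(design, scenario, seed = seeds[r, 1])
      trial <- apply_missingness(trial, missing, seed = seeds[r, 2])
      fit <- fit_primary_model(summarize_followup(trial, rule))
      c(fit$beta2, fit$se_beta2)
    }, error = function(e) NULL)
    if (is.null(res)) n_fail <- n_fail + 1L
    else { beta2[r] <- res[1]; se[r] <- res[2] }
  }
  ok <- !is.na(beta2)
  if (n_fail > 0.01 * nsim)
    stop(sprintf("cell failed: %d of %d replications errored", n_fail, nsim),
         call. = FALSE)

  out <- data.frame(
    delta1 = scenario$delta1, delta2 = scenario$delta2,
    delta3 = scenario$delta3, delta4 = scenario$delta4,
    delta5 = scenario$delta5, prop_winter = scenario$prop_winter,
    period_days = scenario$measurement_period_days,
    mechanism = missing$mechanism,
    prop_participants = missing$prop_participants,
    prop_days = missing$prop_days,
    allocation = paste0(design$allocation_ratio, collapse = ":"),
    mean_beta2 = mean(beta2[ok]),
    mc_error_mean = mc_error(beta2[ok]),
    mean_se = mean(se[ok]),
    mc_error_se = mc_error(se[ok]),
    nsim_effective = sum(ok),
    base_seed = base_seed)
  if (keep_draws) {
    attr(out, "beta2") <- beta2[ok]
    attr(out, "se") <- se[ok]
  }
  out
}

#' Run a grid of scenario cells
#'
#' Executes [run_cell()] for every row of a cell table (as produced by
#' [seasonality_cells()], [observer_cells()] or [missingness_cells()]),
#' deriving an independent seed per cell from `base_seed` and the cell
#' index, so results do not depend on execution order.
#'
#' @param cells Data frame with one row per cell; recognised columns:
#'   `delta2`, `delta3`, `delta4`, `delta5`, `prop_winter`, `period_days`,
#'   `mechanism`, `prop_participants`, `prop_days`. Missing columns default
#'   to the null scenario.
#' @param design A [trial_design()] shared by all cells.
#' @param nsim Replications per cell.
#' @param base_seed Integer seed for the whole grid.
#' @param rule A [compliance_rule()].
#' @param verbose Print one progress line per cell.
#' @return Data frame with one [run_cell()] row per input row.
#' @examples
#' run_grid(seasonality_cells(delta2 = c(0, 10), prop_winter = 0.5),
#'          nsim = 20, base_seed = 1)
#' @export
run_grid <- function(cells, design = trial_design(), nsim = 10000,
                     base_seed = 1, rule = compliance_rule(),
                     verbose = FALSE) {
  stopifnot(is.data.frame(cells), nrow(cells) >= 1)
  ids <- if ("cell_id" %in% names(cells)) cells$cell_id
         else do.call(paste, c(cells, sep = "|"))
  if (anyDuplicated(ids))
    stop("duplicate cells in grid", call. = FALSE)
  grab <- function(row, col, default) {
    if (col %in% names(cells)) cells[row, col] else default
  }
  out <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    scenario <- effect_scenario(
      delta1 = grab(k, "delta1", 12.5),
      delta2 = grab(k, "delta2", 0), delta3 = grab(k, "delta3", 0),
      delta4 = grab(k, "delta4", 0), delta5 = grab(k, "delta5", 0),
      prop_winter = grab(k, "prop_winter", 0),
      measurement_period_days = grab(k, "period_days",
                                     design$n_followup_days))
    missing <- missingness_spec(
      as.character(grab(k, "mechanism", "none")),
      grab(k, "prop_participants", 0), grab(k, "prop_days", 0))
    cell_seed <- derive_seed(base_seed, k)
    out[[k]] <- cbind(cell_id = ids[k],
                      run_cell(design, scenario, missing, nsim = nsim,
                               base_seed = cell_seed, rule = rule))
    if (verbose)
      message(sprintf("cell %d/%d: mean beta2 = %.3f (MC err %.3f)",
                      k, nrow(cells), out[[k]]$mean_beta2,
                      out[[k]]$mc_error_mean))
  }
  do.call(rbind, out)
}

#' Built-in scenario grids
#'
#' Cell tables matching the three families of the simulation study:
#' seasonality (seasonal effect by winter proportion, with and without a
#' season-by-treatment interaction at one tenth of the seasonal effect),
#' observer effect by measurement-period length, and day-level missingness
#' (MCAR/MNAR by proportion of affected participants and of missing days,
#' with a complete-data reference cell).
#'
#' @param delta2,delta4 Effect grids in min/day (defaults: 5 evenly spaced
#'   points over 0-10).
#' @param prop_winter,prop_participants Affected-fraction grids.
#' @param prop_days Missing-day-fraction grid (default 0.05-0.5 plus the
#'   complete-data reference 0).
#' @param interaction Logical values: `FALSE` sets the interaction to 0,
#'   `TRUE` sets it to one tenth of the main effect.
#' @param periods Measurement-period lengths in days.
#' @param mechanisms Missingness mechanisms to cross.
#' @return Data frame of cell parameters for [run_grid()].
#' @name scenario_grids
NULL

#' @rdname scenario_grids
#' @export
seasonality_cells <- function(delta2 = c(0, 2.5, 5, 7.5, 10),
                              prop_winter = c(0.1, 0.2, 0.5),
                              interaction = c(FALSE, TRUE)) {
  g <- expand.grid(delta2 = delta2, prop_winter = prop_winter,
                   interaction = interaction)
  data.frame(cell_id = sprintf("season_d2=%g_pw=%g_%s", g$delta2,
                               g$prop_winter,
                               ifelse(g$interaction, "int", "noint")),
             delta2 = g$delta2,
             delta3 = ifelse(g$interaction, 0.1 * g$delta2, 0),
             prop_winter = g$prop_winter)
}

#' @rdname scenario_grids
#' @export
observer_cells <- function(delta4 = c(0, 2.5, 5, 7.5, 10),
                           periods = c(28, 14),
                           interaction = c(FALSE, TRUE)) {
  g <- expand.grid(delta4 = delta4, period_days = periods,
                   interaction = interaction)
  data.frame(cell_id = sprintf("observer_d4=%g_p=%d_%s", g$delta4,
                               g$period_days,
                               ifelse(g$interaction, "int", "noint")),
             delta4 = g$delta4,
             delta5 = ifelse(g$interaction, 0.1 * g$delta4, 0),
             period_days = g$period_days)
}

#' @rdname scenario_grids
#' @export
missingness_cells <- function(mechanisms = c("MCAR", "MNAR"),
                              prop_participants = c(0.1, 0.2, 0.5),
                              prop_days = seq(0.05, 0.5, by = 0.05)) {
  g <- expand.grid(mechanism = mechanisms,
                   prop_participants = prop_participants,
                   prop_days = prop_days, stringsAsFactors = FALSE)
  g <- g[order(g$mechanism, g$prop_participants, g$prop_days), , drop = FALSE]
  out <- rbind(data.frame(mechanism = "none", prop_participants = 0,
                          prop_days = 0),
               g)
  out$cell_id <- sprintf("miss_%s_pp=%g_pd=%g", out$mechanism,
                         out$prop_participants, out$prop_days)
  out
}
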