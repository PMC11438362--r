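#' Run a simulation study from a configuration file
#'
#' Reads a YAML configuration declaring the trial design, scenario grids,
#' replication count, seed and output directory, executes every declared
#' grid via [run_grid()], writes one results CSV per grid and a JSON run
#' manifest with file checksums. Identical configuration and seed reproduce
#' byte-identical result CSVs.
#'
#' The configuration recognises the top-level keys `design`, `grids`,
#' `nsim`, `base_seed` and `output_dir`; any other key is rejected by name.
#' `design` accepts the arguments of [trial_design()]; `grids` may contain
#' `seasonality`, `observer` and `missingness` sections whose keys are
#' passed to the corresponding cell builders. An empty or absent `grids`
#' section runs the single baseline cell (all nuisance effects zero,
#' complete data).
#'
#' @param config_path Path to the YAML configuration.
#' @param output_dir Optional override of the configured output directory.
#' @return Invisibly, the run manifest (also written to `manifest.json`).
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines("nsim: 20\nbase_seed: 1", cfg)
#' man <- run_from_config(cfg, output_dir = tempfile())
#' man$files
#' @export
run_from_config <- function(config_path, output_dir = NULL) {
  if (!file.exists(config_path))
    stop("config file not found: ", config_path, call. = FALSE)
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg)) cfg <- list()

  allowed <- c("design", "grids", "nsim", "base_seed", "output_dir")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("unknown configuration key: ", paste(bad, collapse = ", "),
         call. = FALSE)
  allowed_grids <- c("seasonality", "observer", "missingness")
  bad_g <- setdiff(names(cfg$grids), allowed_grids)
  if (length(bad_g))
    stop("unknown grid section: ", paste(bad_g, collapse = ", "),
         call. = FALSE)

  design <- do.call(trial_design, as.list(cfg$design))
  nsim <- cfg$nsim %||% 10000
  base_seed <- cfg$base_seed %||% 1
  out_dir <- output_dir %||% cfg$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  builders <- list(seasonality = seasonality_cells,
                   observer = observer_cells,
                   missingness = missingness_cells)
  grids <- cfg$grids
  if (length(grids) == 0)
    grids <- list(baseline = NULL)

  files <- character(0)
  for (g in seq_along(grids)) {
    gname <- names(grids)[g]
    cells <- if (gname == "baseline") {
      data.frame(delta2 = 0)
    } else {
      args <- lapply(as.list(grids[[g]]), unlist)
      do.call(builders[[gname]], args)
    }
    res <- run_grid(cells, design = design, nsim = nsim,
                    base_seed = derive_seed(base_seed, g))
    res$grid <- gname
    res$version <- as.character(utils::packageVersion("mvpasim"))
    path <- file.path(out_dir, paste0("results_", gname, ".csv"))
    utils::write.csv(res, path, row.names = FALSE)
    files <- c(files, path)
  }

  write_manifest(out_dir, files, config = cfg, base_seed = base_seed)
}

write_manifest <- function(out_dir, files, config, base_seed) {
  manifest <- list(
    config = config,
    base_seed = base_seed,
    version = as.character(utils::packageVersion("mvpasim")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = data.frame(path = files,
                       md5 = unname(tools::md5sum(files)),
                       row.names = NULL))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run the built-in study grids
#'
#' Executes the three built-in scenario families — seasonality, observer
#' effect by measurement period, and missing data — under each requested
#' allocation ratio, writing one results CSV per grid and allocation plus
#' figure files and a manifest.
#'
#' @param nsim Replications per cell (10,000 for production; use a small
#'   value for smoke runs).
#' @param base_seed Integer seed.
#' @param output_dir Directory for CSVs, plots and the manifest.
#' @param allocations List of allocation ratios to run.
#' @param make_plots Write PNG figures per grid.
#' @return Invisibly, the run manifest.
#' @export
replicate_study_grids <- function(nsim = 10000, base_seed = 1,
                                  output_dir = "study_output",
                                  allocations = list(c(2, 1), c(1, 1)),
                                  make_plots = TRUE) {
  stopifnot(nsim >= 2)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  grids <- list(seasonality = seasonality_cells(),
                observer = observer_cells(),
                missingness = missingness_cells())
  files <- character(0)
  idx <- 0
  for (alloc in allocations) {
    tag <- paste0(alloc, collapse = "to")
    design <- trial_design(allocation_ratio = alloc)
    for (g in seq_along(grids)) {
      idx <- idx + 1
      res <- run_grid(grids[[g]], design = design, nsim = nsim,
                      base_seed = derive_seed(base_seed, idx))
      res$grid <- names(grids)[g]
      res$version <- as.character(utils::packageVersion("mvpasim"))
      path <- file.path(output_dir,
                        paste0("results_", names(grids)[g], "_", tag, ".csv"))
      utils::write.csv(res, path, row.names = FALSE)
      files <- c(files, path)
      if (make_plots) {
        xvar <- switch(names(grids)[g], seasonality = "delta2",
                       observer = "delta4", missingness = "prop_days")
        gvar <- switch(names(grids)[g], seasonality = "prop_winter",
                       observer = "period_days",
                       missingness = "prop_participants")
        p <- plot_performance(res, x = xvar, group = gvar)
        ppath <- file.path(output_dir,
                           paste0("fig_", names(grids)[g], "_", tag, ".png"))
        ggplot2::ggsave(ppath, p, width = 8, height = 6, dpi = 150)
        files <- c(files, ppath)
      }
    }
  }
  write_manifest(output_dir, files,
                 config = list(nsim = nsim, allocations = allocations),
                 base_seed = base_seed)
}

#' Plot estimator performance over a scenario grid
#'
#' Two panels — mean treatment-effect estimate and mean standard error —
#' against a scenario parameter, one line per level of a grouping
#' parameter, with error bars at 1.96 times the Monte Carlo error.
#'
#' @param results Output of [run_grid()].
#' @param x Name of the column for the horizontal axis.
#' @param group Name of the column distinguishing lines.
#' @return A ggplot object.
#' @export
plot_performance <- function(results, x, group) {
  stopifnot(all(c(x, group, "mean_beta2", "mean_se") %in% names(results)))
  long <- rbind(
    data.frame(x = results[[x]], group = factor(results[[group]]),
               panel = "Mean treatment-effect estimate",
               value = results$mean_beta2, mce = results$mc_error_mean),
    data.frame(x = results[[x]], group = factor(results[[group]]),
               panel = "Mean standard error",
               value = results$mean_se, mce = results$mc_error_se))
  ggplot2::ggplot(long, ggplot2::aes(x = x, y = value, colour = group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = value - 1.96 * mce,
                                        ymax = value + 1.96 * mce),
                           width = 0.15) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = x, colour = group, y = "min/day") +
    ggplot2::theme_minimal()
}
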