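#' Default configuration for an end-to-end SPT analysis run
#'
#' All tunables default to the standard acquisition/analysis settings:
#' 20-photon / 40-nm localization filter, 0.8 um linking gate, 20 ms
#' frame interval, jump histograms with 0.01 um bins up to 3 um over 5
#' timepoints with 4 jumps per trajectory, dZ = 0.9 um and
#' D_slow_min = 0.08 um^2/s, with 2- and 3-state candidate models
#' compared by AIC.
#'
#' @param input path to a localization CSV (header
#'   `frame,x,y,photons,precision`), or `NULL` when `simulate` is given.
#' @param simulate optional `sim_config` used instead of `input`.
#' @param outdir output directory.
#' @param seed integer seed for fitting (and simulation when no seed is
#'   set in `simulate`).
#' @param min_photons,max_precision localization filter thresholds.
#' @param max_jump_link linking gate, um.
#' @param frame_interval seconds.
#' @param n_timepoints,jumps_to_consider,bin_width,max_jump_hist
#'   jump-histogram parameters.
#' @param n_states_candidates models to fit and compare (default 2 and 3).
#' @param dZ axial detection depth, um.
#' @param d_slow_min lower bound of the intermediate state's D, um^2/s.
#' @return a named list (class `spt_run_config`).
#' @export
spt_run_config <- function(input = NULL, simulate = NULL, outdir = ".",
                           seed = 1L, min_photons = 20, max_precision = 40,
                           max_jump_link = 0.8, frame_interval = 0.02,
                           n_timepoints = 5, jumps_to_consider = 4,
                           bin_width = 0.01, max_jump_hist = 3.0,
                           n_states_candidates = c(2L, 3L), dZ = 0.9,
                           d_slow_min = 0.08) {
  if (is.null(input) && is.null(simulate))
    stop(errorCondition("config needs either an input CSV or a simulation",
                        class = c("sptkin_config_error", "error",
                                  "condition")))
  if (!is.null(input) && !file.exists(input))
    stop(errorCondition(sprintf("input file not found: %s", input),
                        class = c("sptkin_config_error", "error",
                                  "condition")))
  structure(as.list(environment()), class = "spt_run_config")
}

#' Run the full SPT analysis chain
#'
#' filter -> link -> jump-length dataset -> candidate model fits ->
#' AIC selection -> report.  Writes `report.json` (fit parameters,
#' AICs, bound fraction, the fully resolved configuration and all
#' counts; byte-identical across reruns with the same seed),
#' `cdf_curves.csv` (per-lag empirical and fitted CDF/PDF) and
#' `run.log` to the output directory.
#'
#' @param config an [spt_run_config()].
#' @return the report, invisibly, as a list.
#' @export
run_spt <- function(config) {
  stopifnot(inherits(config, "spt_run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$outdir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = log_path, append = TRUE)
  cat(sprintf("sptkin run %s\n", format(Sys.time())), file = log_path)

  if (!is.null(config$simulate)) {
    sim <- simulate_spt(config$simulate)
    locs <- sim$localizations
    logline("simulated %d localizations (%d molecules, seed %d)",
            nrow(locs), config$simulate$n_molecules, config$simulate$seed)
  } else {
    locs <- read_localizations_csv(config$input)
    logline("read %d localizations from %s", nrow(locs), config$input)
  }

  kept <- filter_localizations(locs, config$min_photons,
                               config$max_precision)
  logline("filter (photons >= %g, precision <= %g nm): %d -> %d",
          config$min_photons, config$max_precision, nrow(locs), nrow(kept))
  if (nrow(kept) == 0L)
    stop(errorCondition("no localizations pass the quality filter",
                        class = c("sptkin_empty_error", "error",
                                  "condition")))

  tracks <- link_trajectories(kept, config$max_jump_link)
  n_traj <- length(unique(tracks$trajectory))
  logline("linked into %d trajectories (gate %g um)", n_traj,
          config$max_jump_link)

  ds <- compute_jump_dataset(tracks, config$frame_interval,
                             config$n_timepoints,
                             config$jumps_to_consider, config$bin_width,
                             config$max_jump_hist)
  logline("jumps per lag: %s", paste(ds$n_jumps, collapse = ", "))

  fits <- lapply(config$n_states_candidates, function(k)
    fit_model(ds, k, dZ = config$dZ, d_slow_min = config$d_slow_min,
              seed = config$seed))
  names(fits) <- paste0("state", config$n_states_candidates)
  for (f in fits)
    logline("%d-state fit: RSS %.6g, AIC %.2f, F_bound %.4f",
            f$n_states, f$rss, f$aic, f_bound(f))

  selected <- fits[[1L]]
  if (length(fits) > 1L) {
    for (f in fits[-1L]) selected <- select_by_aic(selected, f)
  }
  logline("selected %d-state model by AIC", selected$n_states)

  report <- list(
    config = .serializable_config(config),
    counts = list(localizations_in = nrow(locs),
                  localizations_kept = nrow(kept),
                  trajectories = n_traj,
                  jumps_per_lag = as.integer(ds$n_jumps)),
    fits = lapply(fits, fit_report_list),
    selected_n_states = selected$n_states,
    delta_aic = attr(selected, "delta_aic"),
    f_bound = f_bound(selected))

  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_cdf_curves_csv(selected, ds,
                       file.path(config$outdir, "cdf_curves.csv"))
  invisible(report)
}

.serializable_config <- function(config) {
  out <- unclass(config)
  if (!is.null(out$simulate)) out$simulate <- unclass(out$simulate)
  out[!vapply(out, is.null, logical(1))]
}

#' Run a fluctuation analysis over a counts CSV
#'
#' Estimates a mutation rate per condition (see [estimate_rate()]) and,
#' optionally, fold changes between named condition pairs.  Writes
#' `fluctuation_report.json` to `outdir` and returns the report.
#'
#' @param path CSV with header
#'   `culture_id,condition,mutant_count,n_final,efficiency`.
#' @param pairs optional list of `c(numerator, denominator)` condition
#'   pairs for fold changes.
#' @param outdir output directory (`NULL` to skip writing).
#' @return report list with per-condition `rate_estimate`s and fold
#'   changes.
#' @export
run_fluctuation <- function(path, pairs = NULL, outdir = NULL) {
  experiments <- read_fluctuation_csv(path)
  rates <- lapply(experiments, estimate_rate)
  folds <- list()
  for (pr in pairs) {
    if (!all(pr %in% names(rates)))
      stop(errorCondition(
        sprintf("unknown condition pair: %s / %s", pr[1], pr[2]),
        class = c("sptkin_config_error", "error", "condition")))
    folds[[paste(pr[1], "vs", pr[2])]] <-
      fold_change(rates[[pr[1]]], rates[[pr[2]]])
  }
  report <- list(
    rates = lapply(rates, function(r)
      list(condition = r$condition, m_hat = r$m_hat, rate = r$rate,
           ci95_rate = r$ci95_rate, all_zero = r$all_zero,
           n_cultures = length(r$counts), n_final = r$n_final,
           efficiency = r$efficiency)),
    fold_changes = folds)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report,
                         file.path(outdir, "fluctuation_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
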