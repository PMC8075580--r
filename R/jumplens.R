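#' Build a lag-resolved jump-length dataset
#'
#' For each lag k = 1 .. n_timepoints - 1 (time lag k * frame_interval),
#' collects the Euclidean displacements |r_{i+k} - r_i| of every
#' trajectory, starting from its first point and taking at most
#' `jumps_to_consider` jumps per trajectory per lag (this mitigates the
#' over-representation of slow, long-lived molecules caused by
#' photobleaching).  Displacements above `max_jump` are discarded.  Each
#' lag gets a histogram on [0, max_jump] with the given bin width and an
#' empirical CDF evaluated on the histogram bin edges, so that model
#' fitting compares on a fixed abscissa.
#'
#' @param tracks an `spt_tracks` table (see [link_trajectories()]).
#' @param frame_interval frame interval in seconds (default 0.02).
#' @param n_timepoints number of timepoints; lags run 1 .. n_timepoints-1
#'   (default 5).
#' @param jumps_to_consider maximum jumps per trajectory per lag
#'   (default 4).
#' @param bin_width histogram bin width in micrometres (default 0.01).
#' @param max_jump maximum displacement retained, micrometres (default 3).
#' @return an object of class `jump_dataset`: a list with elements
#'   `lags` (seconds), `samples` (list of displacement vectors per lag),
#'   `edges`, `pdf`, `cdf` (per lag, on `edges`), `n_jumps`, and the
#'   generating parameters.
#' @export
compute_jump_dataset <- function(tracks, frame_interval = 0.02,
                                 n_timepoints = 5, jumps_to_consider = 4,
                                 bin_width = 0.01, max_jump = 3.0) {
  stopifnot(n_timepoints >= 2, jumps_to_consider >= 1,
            bin_width > 0, max_jump > 0, frame_interval > 0)
  if (nrow(tracks) == 0L)
    stop(errorCondition("no trajectories supplied",
                        class = c("sptkin_empty_error", "error", "condition")))

  ord <- order(tracks$trajectory, tracks$frame)
  traj <- tracks$trajectory[ord]
  x <- tracks$x[ord]
  y <- tracks$y[ord]
  n <- length(traj)
  # position of each localization within its trajectory (1-based)
  pos <- stats::ave(rep(1L, n), traj, FUN = seq_along)

  lags_k <- seq_len(n_timepoints - 1L)
  samples <- vector("list", length(lags_k))
  names(samples) <- as.character(lags_k)
  for (k in lags_k) {
    if (n > k) {
      i <- seq_len(n - k)
      ok <- traj[i] == traj[i + k] & pos[i] <= jumps_to_consider
      d <- sqrt((x[i + k] - x[i])^2 + (y[i + k] - y[i])^2)[ok]
      samples[[k]] <- d[d <= max_jump]
    } else {
      samples[[k]] <- numeric()
    }
  }
  if (all(vapply(samples, length, 1L) == 0L))
    stop(errorCondition("no trajectory of length >= 2: empty jump dataset",
                        class = c("sptkin_empty_error", "error", "condition")))

  .finalize_jump_dataset(samples, frame_interval, n_timepoints,
                         jumps_to_consider, bin_width, max_jump)
}

.finalize_jump_dataset <- function(samples, frame_interval, n_timepoints,
                                   jumps_to_consider, bin_width, max_jump) {
  edges <- seq(0, max_jump, by = bin_width)
  pdf <- lapply(samples, function(s) {
    if (length(s) == 0L) return(rep(NA_real_, length(edges) - 1L))
    h <- graphics::hist(s, breaks = edges, plot = FALSE)
    h$counts / (length(s) * bin_width)
  })
  cdf <- lapply(samples, function(s) {
    if (length(s) == 0L) return(rep(NA_real_, length(edges)))
    vapply(edges, function(e) mean(s <= e), numeric(1))
  })
  ds <- list(frame_interval = frame_interval,
             n_timepoints = n_timepoints,
             jumps_to_consider = jumps_to_consider,
             bin_width = bin_width, max_jump = max_jump,
             lags = as.numeric(names(samples)) * frame_interval,
             edges = edges, samples = samples, pdf = pdf, cdf = cdf,
             n_jumps = vapply(samples, length, 1L))
  class(ds) <- "jump_dataset"
  ds
}

#' @export
print.jump_dataset <- function(x, ...) {
  cat(sprintf("<jump_dataset> %d lags (dt = %g s), %s jumps\n",
              length(x$lags), x$frame_interval,
              paste(x$n_jumps, collapse = "/")))
  invisible(x)
}

#' Pool jump-length datasets from independent experiments
#'
#' Concatenates the per-lag displacement samples of datasets acquired
#' with identical frame interval and binning, then recomputes histogram
#' and empirical CDF from the pooled samples (so counts are additive).
#'
#' @param datasets a list of `jump_dataset` objects.
#' @return a pooled `jump_dataset`.
#' @export
pool_datasets <- function(datasets) {
  stopifnot(length(datasets) >= 1L)
  ref <- datasets[[1L]]
  for (d in datasets[-1L]) {
    same <- isTRUE(all.equal(d$frame_interval, ref$frame_interval)) &&
      d$n_timepoints == ref$n_timepoints &&
      isTRUE(all.equal(d$bin_width, ref$bin_width)) &&
      isTRUE(all.equal(d$max_jump, ref$max_jump))
    if (!same)
      stop(errorCondition("datasets have incompatible binning or lags",
                          class = c("sptkin_incompatible_error", "error",
                                    "condition")))
  }
  samples <- ref$samples
  for (d in datasets[-1L]) {
    for (k in names(samples)) samples[[k]] <- c(samples[[k]], d$samples[[k]])
  }
  .finalize_jump_dataset(samples, ref$frame_interval, ref$n_timepoints,
                         ref$jumps_to_consider, ref$bin_width, ref$max_jump)
}

#' Serialise a jump dataset
#'
#' `write_jump_csv` writes the flat per-jump table (`lag_s`,
#' `displacement_um`); `write_jump_summary_json` writes counts per lag
#' and the binning parameters.
#'
#' @param ds a `jump_dataset`.
#' @param path output file path.
#' @export
write_jump_csv <- function(ds, path) {
  lag_s <- rep(ds$lags, ds$n_jumps)
  utils::write.csv(data.frame(lag_s = lag_s,
                              displacement_um = unlist(ds$samples,
                                                       use.names = FALSE)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_jump_csv
#' @export
write_jump_summary_json <- function(ds, path) {
  jsonlite::write_json(
    list(frame_interval = ds$frame_interval,
         n_timepoints = ds$n_timepoints,
         jumps_to_consider = ds$jumps_to_consider,
         bin_width = ds$bin_width, max_jump = ds$max_jump,
         lags_s = ds$lags, n_jumps = as.integer(ds$n_jumps)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
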