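#' Read and write trajectory tables in the Spot-On CSV dialect
#'
#' The dialect has header `frame,t,trajectory,x,y`: `frame` is a 1-based
#' integer, `t` is time in seconds (`(frame - 1) * frame_interval`),
#' `trajectory` is an integer track id and `x`, `y` are in micrometres.
#' Reading and writing round-trips `(frame, trajectory, x, y)` exactly.
#'
#' @param path file path.
#' @return `read_spoton_csv` returns an `spt_tracks` table (see
#'   [link_trajectories()]) with the frame interval inferred from the `t`
#'   column stored in attribute `frame_interval` (NA if not inferable).
#' @export
read_spoton_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  req <- c("frame", "t", "trajectory", "x", "y")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0L) {
    stop(errorCondition(
      sprintf("Spot-On CSV lacks column(s): %s",
              paste(missing_cols, collapse = ", ")),
      class = c("sptkin_format_error", "error", "condition")))
  }
  num <- .parse_numeric_columns(raw[req], path)
  out <- data.frame(trajectory = as.integer(num$trajectory),
                    frame = as.integer(num$frame), x = num$x, y = num$y)
  out <- out[order(out$trajectory, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  dt <- NA_real_
  if (nrow(num) >= 2L) {
    steps <- diff(num$t[order(num$frame)]) / diff(sort(num$frame))
    steps <- steps[is.finite(steps) & steps > 0]
    if (length(steps) > 0L) dt <- stats::median(steps)
  }
  attr(out, "frame_interval") <- dt
  class(out) <- c("spt_tracks", "data.frame")
  out
}

#' @rdname read_spoton_csv
#' @param tracks an `spt_tracks` table.
#' @param frame_interval frame interval in seconds, used to populate the
#'   `t` column.
#' @export
write_spoton_csv <- function(tracks, frame_interval, path) {
  stopifnot(frame_interval > 0)
  req <- c("trajectory", "frame", "x", "y")
  if (!all(req %in% names(tracks))) {
    stop(errorCondition("track table needs columns trajectory, frame, x, y",
                        class = c("sptkin_format_error", "error", "condition")))
  }
  out <- data.frame(frame = as.integer(tracks$frame),
                    t = (as.integer(tracks$frame) - 1L) * frame_interval,
                    trajectory = as.integer(tracks$trajectory),
                    x = tracks$x, y = tracks$y)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
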