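#' Build a localization table
#'
#' A localization is one detected fluorophore appearance: the frame it was
#' detected in, its fitted position (in micrometres), the signal photon
#' count and the localisation precision (in nanometres).  Localization
#' tables are plain data frames with columns `frame`, `x`, `y`, `photons`,
#' `precision`; this constructor validates the invariants.
#'
#' @param frame integer vector of 1-based frame indices.
#' @param x,y numeric positions in micrometres.
#' @param photons numeric photon counts (>= 0).
#' @param precision numeric localisation precision in nanometres (> 0).
#' @return a validated `data.frame` with one row per localization.
#' @export
localization_table <- function(frame, x, y, photons, precision) {
  df <- data.frame(frame = as.integer(frame), x = as.numeric(x),
                   y = as.numeric(y), photons = as.numeric(photons),
                   precision = as.numeric(precision))
  validate_localizations(df)
}

#' Validate a localization table
#'
#' Checks column presence and the per-row invariants (frame >= 1, finite
#' positions, photons >= 0, precision > 0).
#'
#' @param locs a data frame of localizations.
#' @return the input, invisibly unchanged, for piping.
#' @export
validate_localizations <- function(locs) {
  req <- c("frame", "x", "y", "photons", "precision")
  missing_cols <- setdiff(req, names(locs))
  if (length(missing_cols) > 0L) {
    stop(errorCondition(
      sprintf("localization table lacks column(s): %s",
              paste(missing_cols, collapse = ", ")),
      class = c("sptkin_format_error", "error", "condition")))
  }
  if (nrow(locs) == 0L) return(locs)
  if (any(locs$frame < 1L) || any(locs$frame != round(locs$frame)))
    stop("frame indices must be integers >= 1")
  if (!all(is.finite(locs$x)) || !all(is.finite(locs$y)))
    stop("x and y must be finite")
  if (any(locs$photons < 0)) stop("photons must be >= 0")
  if (any(locs$precision <= 0)) stop("precision must be > 0")
  locs
}

#' Filter localizations on photon count and precision
#'
#' Retains localizations with at least `min_photons` photons that are
#' localised to a precision of `max_precision` nanometres or better.
#' Both thresholds are inclusive.  Order is preserved and the filter is
#' idempotent.
#'
#' @param locs localization table (see [localization_table()]).
#' @param min_photons minimum photon count retained (default 20).
#' @param max_precision worst precision retained, in nm (default 40).
#' @return the retained rows of `locs`.
#' @export
filter_localizations <- function(locs, min_photons = 20, max_precision = 40) {
  stopifnot(min_photons > 0, max_precision > 0)
  validate_localizations(locs)
  keep <- locs$photons >= min_photons & locs$precision <= max_precision
  out <- locs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write a localization CSV
#'
#' The on-disk dialect has header `frame,x,y,photons,precision` with x, y
#' in micrometres and precision in nanometres.
#'
#' @param path file path.
#' @return `read_localizations_csv` returns a validated localization table.
#' @export
read_localizations_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  req <- c("frame", "x", "y", "photons", "precision")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0L) {
    stop(errorCondition(
      sprintf("localization CSV lacks column(s): %s",
              paste(missing_cols, collapse = ", ")),
      class = c("sptkin_format_error", "error", "condition")))
  }
  num <- .parse_numeric_columns(raw[req], path)
  validate_localizations(num)
}

#' @rdname read_localizations_csv
#' @param locs localization table to write.
#' @export
write_localizations_csv <- function(locs, path) {
  validate_localizations(locs)
  utils::write.csv(locs[, c("frame", "x", "y", "photons", "precision")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Convert character columns to numeric, reporting the first offending row.
.parse_numeric_columns <- function(df, path) {
  out <- df
  for (nm in names(df)) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(is.na(v) & !(df[[nm]] %in% c("NA", "")))
    if (any(is.na(v))) {
      row <- if (length(bad) > 0L) bad[1L] else which(is.na(v))[1L]
      stop(errorCondition(
        sprintf("non-numeric value '%s' in column '%s', row %d of %s",
                df[[nm]][row], nm, row, path),
        class = c("sptkin_parse_error", "error", "condition")))
    }
    out[[nm]] <- v
  }
  if ("frame" %in% names(out)) out$frame <- as.integer(out$frame)
  out
}
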