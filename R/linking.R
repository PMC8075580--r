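#' Link localizations into trajectories
#'
#' Frame-to-frame greedy nearest-neighbour tracking.  For each pair of
#' consecutive frames, all localization pairs within `max_jump`
#' micrometres are candidate links; links are accepted in ascending
#' distance order (exact ties broken by lower row index), each
#' localization participating in at most one link.  Unlinked
#' localizations start or terminate trajectories.  There is no gap
#' closing: a molecule absent for one frame restarts as a new trajectory.
#'
#' @param locs localization table (columns `frame`, `x`, `y`; extra
#'   columns are ignored).  Duplicate `(frame, x, y)` rows are rejected.
#' @param max_jump linking gate in micrometres (default 0.8, i.e. 800 nm).
#' @return a track table: `data.frame` with columns `trajectory`, `frame`,
#'   `x`, `y`, ordered by trajectory then frame, of class `spt_tracks`.
#' @export
link_trajectories <- function(locs, max_jump = 0.8) {
  stopifnot(max_jump > 0)
  req <- c("frame", "x", "y")
  if (!all(req %in% names(locs))) {
    stop(errorCondition("localization table needs columns frame, x, y",
                        class = c("sptkin_format_error", "error", "condition")))
  }
  if (anyDuplicated(locs[, req]) > 0L) {
    stop(errorCondition("duplicate (frame, x, y) localization rows",
                        class = c("sptkin_validation_error", "error",
                                  "condition")))
  }
  n <- nrow(locs)
  if (n == 0L) {
    out <- data.frame(trajectory = integer(), frame = integer(),
                      x = numeric(), y = numeric())
    class(out) <- c("spt_tracks", "data.frame")
    return(out)
  }

  ord <- order(locs$frame, seq_len(n))
  frame <- as.integer(locs$frame[ord])
  x <- locs$x[ord]
  y <- locs$y[ord]

  traj <- integer(n)          # trajectory id per (sorted) localization
  next_id <- 1L
  by_frame <- split(seq_len(n), frame)
  frames <- as.integer(names(by_frame))

  # first frame: everyone starts a trajectory
  first <- by_frame[[1L]]
  traj[first] <- seq.int(next_id, length.out = length(first))
  next_id <- next_id + length(first)

  for (k in seq_along(frames)[-1L]) {
    cur <- by_frame[[k]]
    prev <- if (frames[k - 1L] == frames[k] - 1L) by_frame[[k - 1L]] else integer()
    linked_cur <- logical(length(cur))
    if (length(prev) > 0L) {
      dx <- outer(x[prev], x[cur], "-")
      dy <- outer(y[prev], y[cur], "-")
      d <- sqrt(dx * dx + dy * dy)
      cand <- which(d <= max_jump, arr.ind = TRUE)
      if (nrow(cand) > 0L) {
        dist <- d[cand]
        # ascending distance; ties by lower previous then current row index
        o <- order(dist, cand[, 1L], cand[, 2L])
        used_prev <- logical(length(prev))
        for (ci in o) {
          i <- cand[ci, 1L]; j <- cand[ci, 2L]
          if (!used_prev[i] && !linked_cur[j]) {
            used_prev[i] <- TRUE
            linked_cur[j] <- TRUE
            traj[cur[j]] <- traj[prev[i]]
          }
        }
      }
    }
    fresh <- cur[!linked_cur]
    if (length(fresh) > 0L) {
      traj[fresh] <- seq.int(next_id, length.out = length(fresh))
      next_id <- next_id + length(fresh)
    }
  }

  out <- data.frame(trajectory = traj, frame = frame, x = x, y = y)
  out <- out[order(out$trajectory, out$frame), , drop = FALSE]
  # renumber trajectories 1..n_traj in order of first appearance
  out$trajectory <- match(out$trajectory, unique(out$trajectory))
  rownames(out) <- NULL
  class(out) <- c("spt_tracks", "data.frame")
  out
}

#' @export
print.spt_tracks <- function(x, ...) {
  cat(sprintf("<spt_tracks> %d localizations in %d trajectories\n",
              nrow(x), length(unique(x$trajectory))))
  NextMethod()
}

#' Trajectory lengths of a track table
#'
#' @param tracks an `spt_tracks` table.
#' @return integer vector, one entry per trajectory.
#' @export
trajectory_lengths <- function(tracks) {
  as.integer(table(factor(tracks$trajectory, levels = unique(tracks$trajectory))))
}
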