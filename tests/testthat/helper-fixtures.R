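# Shared fixture builders for the test suite.  Everything is generated
# in code; no binary fixtures.

# a small localization table with known pass/fail filter rows
loc_fixture <- function() {
  localization_table(frame = c(1L, 1L, 2L, 2L, 3L),
                     x = c(0, 0.3, 0.1, 0.35, 0.12),
                     y = c(0, 0, 0, 0.02, 0.01),
                     photons = c(50, 19, 50, 50, 50),
                     precision = c(30, 30, 41, 39, 25))
}

# a deterministic track table: straight-line trajectory with constant step
straight_track <- function(n_points, step = 0.1, id = 1L, start_frame = 1L) {
  data.frame(trajectory = id,
             frame = seq.int(start_frame, length.out = n_points),
             x = step * (seq_len(n_points) - 1), y = 0)
}

as_tracks <- function(df) {
  class(df) <- c("spt_tracks", "data.frame")
  df
}

# tracks straight from simulation ground truth (perfect linking), using
# the observed (noisy) positions
truth_tracks <- function(sim) {
  as_tracks(data.frame(trajectory = sim$truth$molecule,
                       frame = sim$truth$frame,
                       x = sim$localizations$x,
                       y = sim$localizations$y))
}

# brute-force one-to-one assignment between two frames minimising total
# distance; returns NULL when the optimum is not unique.  Oracle for the
# greedy linker on small inputs.
exhaustive_min_matching <- function(xy1, xy2, max_jump) {
  n1 <- nrow(xy1); n2 <- nrow(xy2)
  d <- as.matrix(stats::dist(rbind(xy1, xy2)))[seq_len(n1),
                                               n1 + seq_len(n2),
                                               drop = FALSE]
  allowed <- d <= max_jump
  best <- NULL; best_cost <- Inf; best_links <- -1L; unique_best <- TRUE
  # enumerate all partial injective assignments of frame-1 points
  rec <- function(i, used2, links) {
    if (i > n1) {
      cost <- sum(d[cbind(which(links > 0), links[links > 0])])
      nlinks <- sum(links > 0)
      # maximise number of links, then minimise total distance
      if (nlinks > best_links ||
          (nlinks == best_links && cost < best_cost - 1e-12)) {
        best <<- links; best_cost <<- cost; best_links <<- nlinks
        unique_best <<- TRUE
      } else if (nlinks == best_links && abs(cost - best_cost) <= 1e-12 &&
                 !identical(links, best)) {
        unique_best <<- FALSE
      }
      return(invisible())
    }
    rec(i + 1L, used2, c(links, 0L))  # leave i unlinked
    for (j in seq_len(n2)) {
      if (!used2[j] && allowed[i, j]) {
        u <- used2; u[j] <- TRUE
        rec(i + 1L, u, c(links, j))
      }
    }
  }
  rec(1L, rep(FALSE, n2), integer())
  if (!unique_best) return(NULL)
  best
}
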