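#' Simulation configuration for sptPALM trajectory data
#'
#' Describes the forward model used to generate synthetic
#' single-molecule tracking data: a mixture of Brownian states confined
#' in a reflective spherical nucleus, observed through an axial
#' detection slab of depth dZ with Gaussian localisation error, with
#' geometric photobleaching lifetimes and uniform appearance times over
#' the acquisition.
#'
#' Molecules appear (are photoconverted and first detected) inside the
#' slab: the initial z is uniform on \[-dZ/2, dZ/2\] and x, y uniform on
#' the corresponding nuclear cross-section.  A molecule's track ends at
#' photobleaching or at its first axial exit from the slab, whichever
#' comes first; slab exits are detected in continuous time (a
#' Brownian-bridge crossing test between frames), matching the
#' absorbing-boundary assumption of [z_survival()].
#'
#' @param n_molecules number of molecules to simulate.
#' @param state_fractions occupancy fractions, summing to 1.
#' @param state_D diffusion coefficients, um^2/s, one per state.
#' @param switching `"off"` (default: molecules keep their state) or a
#'   square rate matrix in 1/s for Markov state switching.
#' @param nucleus_radius radius of the reflective nuclear sphere in um
#'   (default 1.0; `Inf` disables confinement).
#' @param n_nuclei number of nuclei in the field of view (default 50,
#'   emulating an acquisition over many cells).  Molecules are assigned
#'   to nuclei evenly; nuclei sit on a grid with 4 um spacing at a
#'   common focal plane, so molecules from different nuclei can never
#'   fall within a realistic linking gate of each other.
#' @param frame_interval frame interval in seconds (default 0.02).
#' @param sigma_loc localisation error (per-axis SD) in um (default 0.035).
#' @param bleach_mean_frames mean track length before photobleaching, in
#'   frames (geometric; default 10).
#' @param dZ axial detection depth in um (default 0.9; `Inf` disables
#'   defocalisation loss).
#' @param n_frames number of frames in the acquisition (default 20000).
#' @param seed integer seed (mandatory for reproducibility).
#' @param photon_meanlog,photon_sdlog log-normal photon-count parameters
#'   (defaults give a median of ~150 photons with a tail below the
#'   20-photon filter threshold).
#' @param precision_scale_nm localisation-precision scale: the reported
#'   precision is `precision_scale_nm / sqrt(photons)` times a
#'   log-normal excess factor, following the shot-noise law
#'   sigma = sigma_PSF / sqrt(N).  The default 130 nm gives ~29 nm at
#'   the 20-photon threshold, so dim localizations fail the photon and
#'   precision filters coherently.
#' @param precision_sdlog spread (sdlog) of the log-normal excess
#'   factor on the reported precision.
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(n_molecules = 3000L,
                              state_fractions = c(0.40, 0.20, 0.40),
                              state_D = c(0.01, 0.15, 1.0),
                              switching = "off",
                              nucleus_radius = 1.0,
                              n_nuclei = 50L,
                              frame_interval = 0.02,
                              sigma_loc = 0.035,
                              bleach_mean_frames = 10,
                              dZ = 0.9,
                              n_frames = 20000L,
                              seed = 1L,
                              photon_meanlog = log(150),
                              photon_sdlog = 0.9,
                              precision_scale_nm = 130,
                              precision_sdlog = 0.2) {
  if (length(state_fractions) != length(state_D))
    stop(errorCondition("state_fractions and state_D lengths differ",
                        class = c("sptkin_config_error", "error",
                                  "condition")))
  if (abs(sum(state_fractions) - 1) > 1e-8)
    stop("state_fractions must sum to 1")
  stopifnot(nucleus_radius > 0, frame_interval > 0, sigma_loc >= 0,
            bleach_mean_frames >= 1, dZ > 0, n_frames >= 1,
            all(state_D >= 0), n_nuclei >= 1)
  if (!identical(switching, "off")) {
    switching <- as.matrix(switching)
    if (nrow(switching) != length(state_D) ||
        ncol(switching) != length(state_D))
      stop("switching rate matrix must be n_states x n_states")
    if (any(switching[row(switching) != col(switching)] < 0))
      stop("switching rates must be >= 0")
  }
  structure(list(n_molecules = as.integer(n_molecules),
                 state_fractions = state_fractions, state_D = state_D,
                 switching = switching, nucleus_radius = nucleus_radius,
                 n_nuclei = as.integer(n_nuclei),
                 frame_interval = frame_interval, sigma_loc = sigma_loc,
                 bleach_mean_frames = bleach_mean_frames, dZ = dZ,
                 n_frames = as.integer(n_frames), seed = as.integer(seed),
                 photon_meanlog = photon_meanlog,
                 photon_sdlog = photon_sdlog,
                 precision_scale_nm = precision_scale_nm,
                 precision_sdlog = precision_sdlog),
            class = "sim_config")
}

#' Named fixture configurations
#'
#' Documented presets used throughout the test suite:
#' \describe{
#'   \item{`nse4-like`}{40/20/40 bound/slow/free mixture,
#'     D = 0.01/0.15/1.0 um^2/s — emulating a kleisin subunit with a
#'     bound fraction of 0.40.}
#'   \item{`cohesin-like`}{two states only (no intermediate), 60/40
#'     bound/free, D = 0.01/1.0 — a stably chromatin-bound complex.}
#'   \item{`free-only`}{a single freely diffusing state, D = 1.0.}
#'   \item{`bound-only`}{a single chromatin-bound state, D = 0.01.}
#' }
#' All presets use sigma = 0.035 um, a 20 ms frame interval and
#' dZ = 0.9 um.
#'
#' @param name one of `"nse4-like"`, `"cohesin-like"`, `"free-only"`,
#'   `"bound-only"`.
#' @param ... overrides passed on to [simulation_config()].
#' @return a `sim_config`.
#' @export
make_fixture <- function(name, ...) {
  presets <- list(
    "nse4-like" = list(state_fractions = c(0.40, 0.20, 0.40),
                       state_D = c(0.01, 0.15, 1.0)),
    "cohesin-like" = list(state_fractions = c(0.60, 0.40),
                          state_D = c(0.01, 1.0)),
    "free-only" = list(state_fractions = 1.0, state_D = 1.0),
    "bound-only" = list(state_fractions = 1.0, state_D = 0.01))
  if (!name %in% names(presets))
    stop(errorCondition(sprintf("unknown fixture preset '%s'", name),
                        class = c("sptkin_config_error", "error",
                                  "condition")))
  args <- utils::modifyList(presets[[name]], list(...))
  do.call(simulation_config, args)
}

#' Simulate an sptPALM acquisition
#'
#' Forward-simulates the configured mixture of Brownian molecules (see
#' [simulation_config()]) and returns both the observed localization
#' table (with localisation noise, photon counts and precision values)
#' and the underlying ground truth.
#'
#' @param config a `sim_config`.
#' @return a list with elements `localizations` (localization table:
#'   `frame`, `x`, `y`, `photons`, `precision`), `truth` (`data.frame`
#'   with `molecule`, `nucleus`, `frame`, `state`, and the true `x`,
#'   `y`, `z` of every emitted localization), `nucleus_centres` and
#'   `config`.
#' @export
simulate_spt <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_molecules
  n_states <- length(config$state_D)
  dt <- config$frame_interval
  R <- config$nucleus_radius
  half <- config$dZ / 2
  switching_on <- !identical(config$switching, "off")

  state <- sample.int(n_states, n, replace = TRUE,
                      prob = config$state_fractions)
  start_frame <- sample.int(config$n_frames, n, replace = TRUE)
  # nuclei on a 4 um grid at a common focal plane; molecules assigned
  # evenly.  Positions are tracked relative to the nucleus centre and
  # offset on emission.
  side <- ceiling(sqrt(config$n_nuclei))
  nuc <- rep_len(seq_len(config$n_nuclei), n)
  centre_x <- ((seq_len(config$n_nuclei) - 1L) %% side) * 4
  centre_y <- ((seq_len(config$n_nuclei) - 1L) %/% side) * 4
  # geometric number of frames with mean bleach_mean_frames
  bleach_len <- stats::rgeom(n, prob = 1 / config$bleach_mean_frames) + 1L
  max_len <- pmin(bleach_len, config$n_frames - start_frame + 1L)

  # initial position: a molecule appears when first detected, so its z
  # is uniform on the slab; x,y uniform on the nuclear cross-section
  if (is.finite(R) && (!is.finite(half) || half >= R)) {
    # slab covers the nucleus: uniform in the sphere
    g <- matrix(stats::rnorm(3L * n), ncol = 3L)
    g <- g / sqrt(rowSums(g^2)) * R * stats::runif(n)^(1 / 3)
    x <- g[, 1L]; y <- g[, 2L]; z <- g[, 3L]
  } else {
    z <- if (is.finite(half)) stats::runif(n, -half, half) else numeric(n)
    if (is.finite(R)) {
      # x,y uniform on the disc of radius sqrt(R^2 - z^2)
      rho <- sqrt(pmax(R^2 - z^2, 0)) * sqrt(stats::runif(n))
      phi <- stats::runif(n, 0, 2 * pi)
      x <- rho * cos(phi); y <- rho * sin(phi)
    } else {
      x <- numeric(n); y <- numeric(n)
    }
  }

  loc_rows <- vector("list", max(max_len))
  truth_rows <- vector("list", max(max_len))
  alive <- max_len >= 1L
  step_idx <- 0L
  cur_frame <- start_frame
  emit <- function(ids, step) {
    m <- length(ids)
    cx <- centre_x[nuc[ids]]; cy <- centre_y[nuc[ids]]
    obs_x <- x[ids] + cx + stats::rnorm(m, 0, config$sigma_loc)
    obs_y <- y[ids] + cy + stats::rnorm(m, 0, config$sigma_loc)
    photons <- round(stats::rlnorm(m, config$photon_meanlog,
                                   config$photon_sdlog))
    # shot-noise law: precision ~ sigma_PSF / sqrt(N), with excess noise
    precision <- config$precision_scale_nm / sqrt(pmax(photons, 1)) *
      stats::rlnorm(m, 0, config$precision_sdlog)
    loc_rows[[step]] <<- data.frame(frame = cur_frame[ids], x = obs_x,
                                    y = obs_y, photons = photons,
                                    precision = precision)
    truth_rows[[step]] <<- data.frame(molecule = ids, nucleus = nuc[ids],
                                      frame = cur_frame[ids],
                                      state = state[ids],
                                      x = x[ids] + cx, y = y[ids] + cy,
                                      z = z[ids])
  }

  ids <- which(alive)
  if (length(ids) > 0L) emit(ids, step_idx <- 1L)

  while (TRUE) {
    ids <- which(alive & max_len > step_idx)
    if (length(ids) == 0L) break
    m <- length(ids)
    D <- config$state_D[state[ids]]
    if (switching_on) {
      # one embedded-chain step per frame: transition probabilities from
      # the rate matrix via first-order approximation P = I + Q*dt
      P <- diag(n_states) + config$switching * dt
      P[P < 0] <- 0
      P <- P / rowSums(P)
      state[ids] <- vapply(ids, function(i)
        sample.int(n_states, 1L, prob = P[state[i], ]), integer(1))
      D <- config$state_D[state[ids]]
    }
    sd_step <- sqrt(2 * D * dt)
    zx <- x[ids] + stats::rnorm(m, 0, sd_step)
    zy <- y[ids] + stats::rnorm(m, 0, sd_step)
    zz_old <- z[ids]
    zz <- zz_old + stats::rnorm(m, 0, sd_step)

    if (is.finite(R)) {
      # radial reflection at the nuclear envelope
      rad <- sqrt(zx^2 + zy^2 + zz^2)
      out <- which(rad > R)
      if (length(out) > 0L) {
        fac <- (2 * R - rad[out]) / rad[out]
        fac[fac < 0] <- 0   # pathological huge step: clamp to centre side
        zx[out] <- zx[out] * fac
        zy[out] <- zy[out] * fac
        zz[out] <- zz[out] * fac
      }
    }

    x[ids] <- zx; y[ids] <- zy; z[ids] <- zz
    cur_frame[ids] <- cur_frame[ids] + 1L

    survive <- rep(TRUE, m)
    if (is.finite(half)) {
      survive <- abs(zz) <= half
      # continuous-time crossing inside the frame interval: Brownian
      # bridge boundary-crossing probability for each slab face
      pos <- which(survive & D > 0)
      if (length(pos) > 0L) {
        dd <- D[pos] * dt
        p_up <- exp(-(half - zz_old[pos]) * (half - zz[pos]) / dd)
        p_dn <- exp(-(half + zz_old[pos]) * (half + zz[pos]) / dd)
        p_cross <- pmin(1, p_up + p_dn)
        crossed <- stats::runif(length(pos)) < p_cross
        survive[pos[crossed]] <- FALSE
      }
    }
    alive[ids[!survive]] <- FALSE
    keep <- ids[survive]
    step_idx <- step_idx + 1L
    if (length(keep) > 0L) emit(keep, step_idx)
  }

  locs <- do.call(rbind, loc_rows[!vapply(loc_rows, is.null, logical(1))])
  truth <- do.call(rbind, truth_rows[!vapply(truth_rows, is.null,
                                             logical(1))])
  o <- order(truth$molecule, truth$frame)
  locs <- locs[o, , drop = FALSE]
  truth <- truth[o, , drop = FALSE]
  rownames(locs) <- rownames(truth) <- NULL
  list(localizations = locs, truth = truth,
       nucleus_centres = data.frame(nucleus = seq_len(config$n_nuclei),
                                    cx = centre_x, cy = centre_y),
       config = config)
}

#' Write the ground-truth table of a simulation
#'
#' @param sim result of [simulate_spt()].
#' @param path output CSV path.
#' @export
write_ground_truth_csv <- function(sim, path) {
  utils::write.csv(sim$truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
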