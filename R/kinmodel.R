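#' Diffusion mixture model
#'
#' A kinetic model of molecular motion as a mixture of Brownian states.
#' Each state i has an occupancy fraction F_i and a diffusion coefficient
#' D_i (um^2/s); all states share a single localisation error sigma (um),
#' which inflates apparent displacements.  Fast states are additionally
#' subject to defocalisation: molecules diffusing axially leave the
#' detection slab of depth dZ, so their contribution to the observed
#' displacement mixture shrinks with increasing lag time.  The
#' chromatin-bound state (lowest D) moves with chromatin and is exempt
#' from the correction.
#'
#' @param fractions state fractions, summing to 1.
#' @param D diffusion coefficients in um^2/s, one per state.
#' @param sigma localisation error in um (0.005 - 0.1).
#' @param dZ axial detection depth in um (default 0.9).
#' @param defocalised logical per state; default exempts the lowest-D
#'   (bound) state and corrects all others.
#' @return an object of class `diffusion_model`.
#' @export
diffusion_model <- function(fractions, D, sigma, dZ = 0.9,
                            defocalised = NULL) {
  if (length(fractions) != length(D))
    stop("fractions and D must have equal length")
  if (abs(sum(fractions) - 1) > 1e-8 || any(fractions < -1e-12) ||
      any(fractions > 1 + 1e-12))
    stop("fractions must lie in [0,1] and sum to 1")
  if (any(D < 0)) stop("diffusion coefficients must be >= 0")
  if (sigma < 0.005 || sigma > 0.1)
    stop("sigma must lie in [0.005, 0.1] um")
  if (dZ <= 0) stop("dZ must be > 0")
  o <- order(D)
  fractions <- pmin(pmax(fractions[o], 0), 1)
  D <- D[o]
  if (is.null(defocalised)) {
    defocalised <- rep(TRUE, length(D))
    defocalised[1L] <- FALSE
  } else {
    defocalised <- defocalised[o]
  }
  structure(list(fractions = fractions / sum(fractions), D = D,
                 sigma = sigma, dZ = dZ, defocalised = defocalised),
            class = "diffusion_model")
}

#' @export
print.diffusion_model <- function(x, ...) {
  cat(sprintf("<diffusion_model> %d state(s), sigma = %.4f um, dZ = %g um\n",
              length(x$D), x$sigma, x$dZ))
  for (i in seq_along(x$D))
    cat(sprintf("  state %d: F = %.3f, D = %.4g um^2/s%s\n", i,
                x$fractions[i], x$D[i],
                if (x$defocalised[i]) "" else " (no defocalisation)"))
  invisible(x)
}

#' Single-state jump-length CDF and PDF
#'
#' For 2-D Brownian motion with diffusion coefficient D observed at lag
#' dt with Gaussian localisation error sigma per axis, the jump length r
#' is Rayleigh distributed with scale sqrt(2 * (D*dt + sigma^2)):
#' CDF(r) = 1 - exp(-r^2 / (4*(D*dt + sigma^2))).
#'
#' @param r jump length(s) in um (>= 0).
#' @param D diffusion coefficient in um^2/s.
#' @param dt lag time in seconds (> 0).
#' @param sigma localisation error in um.
#' @return probabilities (CDF) or densities (PDF) at `r`.
#' @export
jump_cdf_single <- function(r, D, dt, sigma) {
  if (D < 0 || sigma < 0) stop("D and sigma must be >= 0")
  stopifnot(all(r >= 0), dt > 0)
  s2 <- D * dt + sigma^2
  1 - exp(-r^2 / (4 * s2))
}

#' @rdname jump_cdf_single
#' @export
jump_pdf_single <- function(r, D, dt, sigma) {
  if (D < 0 || sigma < 0) stop("D and sigma must be >= 0")
  stopifnot(all(r >= 0), dt > 0)
  s2 <- D * dt + sigma^2
  r / (2 * s2) * exp(-r^2 / (4 * s2))
}

#' Axial in-slab survival probability (defocalisation correction)
#'
#' Probability that a molecule with diffusion coefficient D, initially
#' uniformly distributed along z inside the detection slab
#' [-dZ/2, dZ/2], has not crossed either slab boundary after time dt
#' (boundaries absorbing).  Uses the absorbing-slab eigenfunction series
#' P = sum_{odd j} 8/(j^2 pi^2) exp(-j^2 pi^2 D dt / dZ^2); for very
#' small D*dt/dZ^2, where the eigenseries converges slowly, the exact
#' short-time image expansion 1 - 4 sqrt(alpha/pi) is used (its
#' remainder, of order exp(-1/(4*alpha)), is below 1e-9 in that regime).
#'
#' @param D diffusion coefficient in um^2/s.
#' @param dt time in seconds.
#' @param dZ slab depth in um (may be `Inf`, giving survival 1).
#' @param n_terms number of (odd) series terms (default 101).
#' @return survival probability in (0, 1].
#' @export
z_survival <- function(D, dt, dZ = 0.9, n_terms = 101L) {
  if (dZ <= 0) stop("dZ must be > 0")
  stopifnot(D >= 0, dt >= 0)
  if (D == 0 || dt == 0 || !is.finite(dZ)) return(1.0)
  alpha <- D * dt / dZ^2
  if (alpha < 0.01) {
    # short-time (image) expansion; remainder < exp(-1/(4*alpha)) < 1e-10
    return(max(0, 1 - 4 * sqrt(alpha / pi)))
  }
  j <- seq(1L, 2L * n_terms - 1L, by = 2L)
  terms <- 8 / (j^2 * pi^2) * exp(-j^2 * pi^2 * alpha)
  # truncation bound: 8/(pi^2 J) * exp(-J^2 pi^2 alpha)
  jmax <- j[length(j)] + 2
  if (8 / (pi^2 * jmax) * exp(-jmax^2 * pi^2 * alpha) > 1e-9)
    warning("z_survival series truncated before 1e-9 accuracy; increase n_terms")
  min(1, sum(terms))
}

#' Mixture jump-length CDF with defocalisation-corrected weights
#'
#' Evaluates the model CDF at a given lag: state weights are
#' w_i(dt) proportional to F_i * Z_i(dt), where Z_i = 1 for states
#' exempt from defocalisation (bound) and Z_i = [z_survival()] otherwise;
#' weights are renormalised to sum to one at each lag, and the CDF is
#' the weighted sum of single-state Rayleigh CDFs.
#'
#' With the default `n_jumps = 1`, Z_i is the survival over the lag
#' itself.  When displacement histograms are gathered from the first
#' `n_jumps` jumps of every trajectory (see [compute_jump_dataset()]),
#' a jump at lag k starting at track position i0 is observed only if
#' the molecule has remained in the slab for (i0 + k) frames since its
#' appearance, so the effective per-state weight is the average of
#' Z_i over the start offsets:
#' Z_i = mean over i0 = 0..n_jumps-1 of z_survival(D_i, dt + i0 *
#' base_dt, dZ).  Passing the dataset's `jumps_to_consider` and frame
#' interval here removes the state-composition bias that the
#' jump-collection protocol otherwise introduces; [fit_model()] does
#' this automatically.
#'
#' @param model a [diffusion_model()].
#' @param dt lag time in seconds.
#' @param r_grid ascending jump lengths in um.
#' @param n_jumps number of jump start offsets averaged in the
#'   defocalisation weights (default 1: plain per-lag survival).
#' @param base_dt frame interval in seconds used for the start offsets
#'   (defaults to `dt`; only used when `n_jumps > 1`).
#' @return vector of probabilities on `r_grid`.
#' @export
model_cdf <- function(model, dt, r_grid, n_jumps = 1L, base_dt = dt) {
  stopifnot(inherits(model, "diffusion_model"))
  if (is.unsorted(r_grid)) stop("r_grid must be ascending")
  w <- .defocal_weights(model, dt, n_jumps, base_dt)
  out <- numeric(length(r_grid))
  for (i in seq_along(model$D))
    out <- out + w[i] * jump_cdf_single(r_grid, model$D[i], dt, model$sigma)
  out
}

#' @rdname model_cdf
#' @export
model_pdf <- function(model, dt, r_grid, n_jumps = 1L, base_dt = dt) {
  stopifnot(inherits(model, "diffusion_model"))
  w <- .defocal_weights(model, dt, n_jumps, base_dt)
  out <- numeric(length(r_grid))
  for (i in seq_along(model$D))
    out <- out + w[i] * jump_pdf_single(r_grid, model$D[i], dt, model$sigma)
  out
}

.defocal_weights <- function(model, dt, n_jumps = 1L, base_dt = dt) {
  offsets <- (seq_len(n_jumps) - 1L) * base_dt
  z <- vapply(seq_along(model$D), function(i) {
    if (!model$defocalised[i]) return(1.0)
    mean(vapply(offsets, function(o)
      z_survival(model$D[i], dt + o, model$dZ), numeric(1)))
  }, numeric(1))
  w <- model$fractions * z
  w / sum(w)
}

# ---- fitting ---------------------------------------------------------------

# vectorised in-slab survival over a vector of D*t/dZ^2 values; same
# switch between eigenseries and short-time expansion as z_survival()
.z_surv_alpha <- function(alpha, n_terms = 101L) {
  out <- numeric(length(alpha))
  small <- alpha < 0.01
  out[small] <- pmax(0, 1 - 4 * sqrt(alpha[small] / pi))
  if (any(!small)) {
    j2p2 <- (seq(1L, 2L * n_terms - 1L, by = 2L))^2 * pi^2
    out[!small] <- pmin(1, colSums((8 / j2p2) *
                                     exp(-outer(j2p2, alpha[!small]))))
  }
  out
}

# Fast residual-sum-of-squares objective used by the optimiser: avoids
# per-iteration object construction/validation.  Numerically identical
# to summing [emp - model_cdf(...)]^2 over lags.
.make_fit_objective <- function(emp, edges, lags, n_states, dZ, jprot,
                                base_dt) {
  e2 <- edges^2
  # survival times needed per lag: lag + each jump-start offset
  times <- lapply(lags, function(L) L + (seq_len(jprot) - 1L) * base_dt)
  tu <- sort(unique(unlist(times)))
  t_idx <- lapply(times, function(tt) match(tt, tu))
  defocal <- is.finite(dZ)

  function(par) {
    if (n_states == 1L) {
      f <- 1
      D <- par[[1L]]
      sigma <- par[[2L]]
    } else if (n_states == 2L) {
      f <- c(par[[1L]], 1 - par[[1L]])
      D <- c(par[[2L]], par[[3L]])
      sigma <- par[[4L]]
    } else {
      v1 <- par[[1L]]; v2 <- par[[2L]]
      f <- c(v1, (1 - v1) * v2, (1 - v1) * (1 - v2))
      D <- c(par[[3L]], par[[4L]], par[[5L]])
      sigma <- par[[6L]]
    }
    # per-state survival at every needed time; state 1 (bound) exempt
    if (defocal && n_states > 1L) {
      surv <- rbind(1, do.call(rbind, lapply(D[-1L], function(d)
        .z_surv_alpha(d * tu / dZ^2))))
    } else {
      surv <- matrix(1, n_states, length(tu))
    }
    rss <- 0
    for (li in seq_along(lags)) {
      zbar <- rowMeans(surv[, t_idx[[li]], drop = FALSE])
      w <- f * zbar
      w <- w / sum(w)
      cdf <- 0
      for (i in seq_len(n_states))
        cdf <- cdf + w[i] * (1 - exp(-e2 / (4 * (D[i] * lags[li] +
                                                   sigma^2))))
      res <- emp[[li]] - cdf
      rss <- rss + sum(res * res)
    }
    rss
  }
}

# parameter boxes for the CDF fit (um^2/s and um)
.fit_bounds <- function(n_states, d_slow_min) {
  if (n_states == 1L) {
    list(lower = c(D1 = 5e-4, sigma = 0.01),
         upper = c(D1 = 25,  sigma = 0.075))
  } else if (n_states == 2L) {
    list(lower = c(f1 = 0, D1 = 5e-4, D2 = 0.15, sigma = 0.01),
         upper = c(f1 = 1, D1 = 0.08, D2 = 25,   sigma = 0.075))
  } else {
    list(lower = c(v1 = 0, v2 = 0, D1 = 5e-4, D2 = d_slow_min, D3 = 0.15,
                   sigma = 0.01),
         upper = c(v1 = 1, v2 = 1, D1 = 0.08, D2 = 1.0, D3 = 25,
                   sigma = 0.075))
  }
}

# map a bounded parameter vector to a diffusion_model; fractions are
# stick-breaking so they sum to one exactly
.par_to_model <- function(par, n_states, dZ) {
  if (n_states == 1L) {
    diffusion_model(1, par[["D1"]], par[["sigma"]], dZ,
                    defocalised = is.finite(dZ))
  } else if (n_states == 2L) {
    f1 <- par[["f1"]]
    diffusion_model(c(f1, 1 - f1), c(par[["D1"]], par[["D2"]]),
                    par[["sigma"]], dZ)
  } else {
    v1 <- par[["v1"]]; v2 <- par[["v2"]]
    f <- c(v1, (1 - v1) * v2, (1 - v1) * (1 - v2))
    diffusion_model(f, c(par[["D1"]], par[["D2"]], par[["D3"]]),
                    par[["sigma"]], dZ)
  }
}

#' Fit a diffusion mixture model to an empirical jump-length dataset
#'
#' Least-squares fit of the defocalisation-corrected mixture CDF to the
#' empirical per-lag CDFs, jointly across all lags on the histogram
#' bin-edge grid.  Free parameters: the state fractions (on the
#' simplex), the per-state diffusion coefficients (box-bounded:
#' D_bound in \[5e-4, 0.08\], D_slow in \[d_slow_min, 1\] for the 3-state
#' model, D_free in \[0.15, 25\]) and a single localisation error sigma
#' in \[0.01, 0.075\] um shared across lags and states.  Optimisation is
#' multi-start L-BFGS-B with `n_starts` starting points drawn uniformly
#' within bounds from `seed`; the best residual sum of squares wins.
#'
#' @param dataset a `jump_dataset` (see [compute_jump_dataset()]).
#' @param n_states 2 or 3 (1 also accepted, for single-state controls).
#' @param dZ axial detection depth in um (default 0.9).  `Inf` disables
#'   the defocalisation correction.
#' @param d_slow_min lower bound for the intermediate state's D
#'   (default 0.08 um^2/s; 3-state model only).
#' @param seed integer seed for the multi-start draws.
#' @param n_starts number of starting points (default 5).
#' @return an object of class `spt_fit`: list with elements `model`
#'   ([diffusion_model()]), `rss`, `n_points`, `k_params`, `aic`,
#'   `n_states`, `converged`, `seed` and per-start diagnostics.
#' @export
fit_model <- function(dataset, n_states, dZ = 0.9, d_slow_min = 0.08,
                      seed = 1L, n_starts = 5L) {
  stopifnot(inherits(dataset, "jump_dataset"), n_states %in% 1:3)
  keep <- dataset$n_jumps > 0L
  if (sum(keep) < 2L && n_states > 1L)
    warning("fewer than 2 lags with data; fit is poorly constrained")
  if (sum(dataset$n_jumps) < 100L)
    warning("fewer than 100 jumps in total; fit is poorly constrained")

  lags <- dataset$lags[keep]
  emp <- dataset$cdf[keep]
  edges <- dataset$edges
  b <- .fit_bounds(n_states, d_slow_min)
  npar <- length(b$lower)

  # defocalisation weights account for the jump-collection protocol
  # (first `jumps_to_consider` jumps per trajectory; see model_cdf)
  jprot <- dataset$jumps_to_consider
  base_dt <- dataset$frame_interval
  objective <- .make_fit_objective(emp, edges, lags, n_states, dZ, jprot,
                                   base_dt)
  # optimise with diffusion coefficients on the log10 scale: D spans
  # several decades and the landscape is far better conditioned there
  is_D <- grepl("^D", names(b$lower))
  lo <- b$lower; hi <- b$upper
  lo[is_D] <- log10(lo[is_D]); hi[is_D] <- log10(hi[is_D])
  obj_t <- function(p) {
    q <- p
    q[is_D] <- 10^p[is_D]
    objective(q)
  }

  set.seed(as.integer(seed))
  starts <- lapply(seq_len(n_starts), function(i)
    stats::runif(npar, lo, hi))

  fits <- lapply(starts, function(p0) {
    tryCatch(
      stats::optim(p0, obj_t, method = "L-BFGS-B",
                   lower = lo, upper = hi,
                   control = list(maxit = 500L, factr = 1e7)),
      error = function(e) list(value = Inf, convergence = 99L,
                               message = conditionMessage(e), par = p0))
  })
  values <- vapply(fits, function(f) f$value, numeric(1))
  conv <- vapply(fits, function(f) f$convergence == 0L, logical(1))
  if (!any(is.finite(values))) {
    stop(errorCondition(
      paste0("all optimisation starts failed: ",
             paste(vapply(fits, function(f)
               if (!is.null(f$message)) f$message else "?", ""),
               collapse = "; ")),
      class = c("sptkin_fit_error", "error", "condition")))
  }
  best <- which.min(values)
  par <- fits[[best]]$par
  par[is_D] <- 10^par[is_D]
  names(par) <- names(b$lower)
  model <- .par_to_model(par, n_states, dZ)

  n_points <- sum(lengths(emp))
  rss <- values[best]
  k <- 2L * as.integer(n_states)  # n D's + (n-1) fractions + sigma
  aic <- n_points * log(rss / n_points) + 2 * k

  structure(list(model = model, rss = rss, n_points = n_points,
                 k_params = k, aic = aic, n_states = as.integer(n_states),
                 converged = conv[best], seed = as.integer(seed),
                 jump_protocol = jprot, base_dt = base_dt,
                 start_values = values, start_converged = conv),
            class = "spt_fit")
}

#' @export
print.spt_fit <- function(x, ...) {
  cat(sprintf("<spt_fit> %d-state, RSS = %.5g, AIC = %.2f, F_bound = %.3f\n",
              x$n_states, x$rss, x$aic, f_bound(x)))
  print(x$model)
  invisible(x)
}

#' Select between two fits by the Akaike information criterion
#'
#' AIC for a least-squares fit uses the Gaussian-residual surrogate
#' n * ln(RSS/n) + 2k.  The fit with the lower AIC is returned, with the
#' AIC difference attached as attribute `delta_aic` (selected minus
#' rejected, always <= 0).
#'
#' @param fit2,fit3 `spt_fit` objects fitted to the same dataset.
#' @return the winning `spt_fit`.
#' @export
select_by_aic <- function(fit2, fit3) {
  stopifnot(inherits(fit2, "spt_fit"), inherits(fit3, "spt_fit"))
  if (fit2$n_points != fit3$n_points)
    stop(errorCondition("fits have different residual vector lengths",
                        class = c("sptkin_incompatible_error", "error",
                                  "condition")))
  win <- if (fit3$aic < fit2$aic) fit3 else fit2
  attr(win, "delta_aic") <- min(fit2$aic, fit3$aic) - max(fit2$aic, fit3$aic)
  attr(win, "aic_2state") <- fit2$aic
  attr(win, "aic_3state") <- fit3$aic
  win
}

#' Bound fraction of a fitted model
#'
#' Returns the occupancy fraction of the slowest (chromatin-bound)
#' state.
#'
#' @param fit an `spt_fit` or a `diffusion_model`.
#' @return the bound fraction in \[0, 1\].
#' @export
f_bound <- function(fit) {
  m <- if (inherits(fit, "spt_fit")) fit$model else fit
  stopifnot(inherits(m, "diffusion_model"))
  m$fractions[which.min(m$D)]
}

#' Serialise a fit report and plot-ready curves
#'
#' `write_fit_report_json` writes the fitted parameters, RSS, AIC and
#' bound fraction; `write_cdf_curves_csv` writes, for every lag, the
#' empirical and fitted CDF (and fitted PDF) on the bin-edge grid.
#'
#' @param fit an `spt_fit`.
#' @param path output path.
#' @export
write_fit_report_json <- function(fit, path) {
  jsonlite::write_json(fit_report_list(fit), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# report as a plain list (used by the pipeline too)
fit_report_list <- function(fit) {
  m <- fit$model
  list(n_states = fit$n_states,
       fractions = m$fractions, D_um2_s = m$D,
       sigma_um = m$sigma, dZ_um = m$dZ,
       f_bound = f_bound(fit),
       rss = fit$rss, n_points = fit$n_points,
       k_params = fit$k_params, aic = fit$aic,
       converged = fit$converged, seed = fit$seed)
}

#' @rdname write_fit_report_json
#' @param dataset the `jump_dataset` the fit was computed from.
#' @export
write_cdf_curves_csv <- function(fit, dataset, path) {
  jprot <- if (!is.null(fit$jump_protocol)) fit$jump_protocol else 1L
  base_dt <- if (!is.null(fit$base_dt)) fit$base_dt else dataset$frame_interval
  rows <- lapply(seq_along(dataset$lags), function(li) {
    if (dataset$n_jumps[li] == 0L) return(NULL)
    data.frame(lag_s = dataset$lags[li], r_um = dataset$edges,
               empirical_cdf = dataset$cdf[[li]],
               model_cdf = model_cdf(fit$model, dataset$lags[li],
                                     dataset$edges, jprot, base_dt),
               model_pdf = model_pdf(fit$model, dataset$lags[li],
                                     dataset$edges, jprot, base_dt))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
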