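#' Luria-Delbruck mutant-count distribution
#'
#' Probability mass function of the number of mutant colonies observed
#' in one culture when mutations arise at random during exponential
#' growth (expected number of mutation events m per culture) and a
#' fraction `efficiency` of the final culture is plated.
#'
#' With full plating the pmf follows the Ma-Sandri-Sarkar recursion
#' p_0 = exp(-m); p_n = (m/n) * sum_{k=0}^{n-1} p_k / (n - k + 1),
#' which is the compound-Poisson distribution with clone-size
#' probabilities q_j = 1/(j (j+1)).  With partial plating each of the j
#' cells of a clone is observed independently with probability epsilon
#' (binomial thinning of the clone-size distribution), and the pmf is
#' computed by the same compound-Poisson recursion applied to the
#' thinned clone distribution — the probability-generating-function
#' composition exp(m (h_eps(z) - 1)).
#'
#' @param m expected number of mutation events per culture (>= 0).
#' @param n_max largest count for which a probability is returned.
#' @param efficiency plating efficiency epsilon in (0, 1].
#' @return numeric vector `p[1..n_max+1]` giving P(count = 0..n_max),
#'   with the unreturned tail mass in attribute `tail_mass`.
#' @export
ld_pmf <- function(m, n_max, efficiency = 1) {
  if (efficiency <= 0 || efficiency > 1)
    stop("efficiency must lie in (0, 1]")
  stopifnot(m >= 0, n_max >= 0)
  if (m == 0) {
    p <- c(1, rep(0, n_max))
    attr(p, "tail_mass") <- 0
    return(p)
  }
  q <- .ld_clone_pmf(n_max, efficiency)   # q[k+1] = P(clone shows k colonies)
  # compound Poisson (Panjer) recursion on the thinned clone distribution
  p <- numeric(n_max + 1L)
  p[1L] <- exp(-m * (1 - q[1L]))
  if (n_max >= 1L) {
    kq <- seq_len(n_max) * q[-1L]         # k * q_k
    for (n in seq_len(n_max)) {
      k <- seq_len(n)
      p[n + 1L] <- (m / n) * sum(kq[k] * p[n - k + 1L])
    }
  }
  attr(p, "tail_mass") <- max(0, 1 - sum(p))
  p
}

# Thinned Lea-Coulson clone-size pmf: q~_k = sum_{j>=max(k,1)}
# 1/(j(j+1)) * dbinom(k, j, eps), truncated where the geometric factor
# (1-eps)^(j-k) makes the remainder negligible.  At eps = 1 this is
# exactly q_0 = 0, q_k = 1/(k(k+1)).
.ld_clone_pmf <- function(n_max, efficiency) {
  eps <- efficiency
  if (eps == 1) {
    k <- seq_len(n_max)
    return(c(0, 1 / (k * (k + 1))))
  }
  # truncation: terms for j > J are bounded by (1-eps)^(j - n_max)
  J <- n_max + ceiling(log(1e-13) / log1p(-eps)) + 10L
  J <- max(J, n_max + 10L)
  j <- seq_len(J)
  w <- 1 / (j * (j + 1))
  q <- numeric(n_max + 1L)
  for (k in 0:n_max) {
    jj <- j[j >= max(k, 1L)]
    q[k + 1L] <- sum(w[jj] * stats::dbinom(k, jj, eps))
  }
  q
}

#' Construct a fluctuation experiment
#'
#' @param counts integer mutant-colony counts, one per parallel culture
#'   (triplicate plates from one culture should be summed, with
#'   `efficiency` set to the total fraction of the culture plated).
#' @param n_final final number of cells per culture.
#' @param efficiency fraction of each culture plated, in (0, 1].
#' @param condition free-text condition label.
#' @return an object of class `fluctuation_experiment`.
#' @export
fluctuation_experiment <- function(counts, n_final, efficiency = 1,
                                   condition = "") {
  counts <- as.integer(counts)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (n_final <= 0) stop("n_final must be > 0")
  if (efficiency <= 0 || efficiency > 1)
    stop("efficiency must lie in (0, 1]")
  structure(list(counts = counts, n_final = n_final,
                 efficiency = efficiency, condition = condition),
            class = "fluctuation_experiment")
}

#' Maximum-likelihood mutation-rate estimate
#'
#' Maximises the Luria-Delbruck log-likelihood (with plating-efficiency
#' correction, see [ld_pmf()]) over the expected number of mutations per
#' culture m; the mutation rate is m / n_final (mutations per cell per
#' generation under deterministic growth).  The 95% confidence interval
#' comes from the profile likelihood at the chi-square(1) cutoff.
#'
#' Counts larger than `count_cap` are treated as right-censored at
#' `count_cap` (their likelihood contribution is the tail mass), which
#' bounds the cost of the O(n^2) pmf recursion in the presence of
#' jackpot cultures.
#'
#' If every count is zero the MLE is m = 0 and only the 95% upper bound
#' is reported (p0 method), flagged by `all_zero = TRUE`.
#'
#' @param experiment a [fluctuation_experiment()].
#' @param count_cap censoring cap for jackpot counts (default 1000).
#' @return an object of class `rate_estimate`: list with `m_hat`,
#'   `rate`, `ci95_m`, `ci95_rate`, `loglik`, `all_zero`, plus the
#'   inputs.
#' @export
estimate_rate <- function(experiment, count_cap = 1000L) {
  stopifnot(inherits(experiment, "fluctuation_experiment"))
  counts <- experiment$counts
  if (length(counts) < 2L)
    stop("need at least 2 parallel cultures")
  eps <- experiment$efficiency
  capped <- pmin(counts, count_cap)
  censored <- counts > count_cap
  n_max <- max(capped)

  if (all(counts == 0L)) {
    # p0 method upper bound: p_0(m)^C >= 0.05
    q0 <- .ld_clone_pmf(0L, eps)[1L]
    m_up <- -log(0.05) / (length(counts) * (1 - q0))
    est <- list(m_hat = 0, rate = 0,
                ci95_m = c(0, m_up),
                ci95_rate = c(0, m_up / experiment$n_final),
                loglik = 0, all_zero = TRUE,
                counts = counts, n_final = experiment$n_final,
                efficiency = eps, condition = experiment$condition)
    class(est) <- "rate_estimate"
    return(est)
  }

  loglik <- function(m) {
    if (m <= 0) return(-Inf)
    p <- ld_pmf(m, n_max, eps)
    p_obs <- p[capped + 1L]
    if (any(censored)) {
      tail_at_cap <- max(attr(p, "tail_mass"), .Machine$double.xmin)
      p_obs[censored] <- tail_at_cap
    }
    if (any(p_obs <= 0)) return(-Inf)
    sum(log(p_obs))
  }

  # bracket the optimum on a log grid, then refine
  grid <- exp(seq(log(1e-4), log(max(10, 5 * mean(capped) + 10)),
                  length.out = 60))
  ll <- vapply(grid, loglik, numeric(1))
  i0 <- which.max(ll)
  lo <- grid[max(1L, i0 - 1L)]; hi <- grid[min(length(grid), i0 + 1L)]
  opt <- stats::optimize(loglik, c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.4)
  m_hat <- opt$maximum
  ll_max <- opt$objective

  # profile-likelihood 95% CI
  cut <- ll_max - stats::qchisq(0.95, df = 1) / 2
  f <- function(m) loglik(m) - cut
  lo_ci <- tryCatch({
    if (f(1e-8) > 0) 0
    else stats::uniroot(f, c(1e-8, m_hat), tol = 1e-8)$root
  }, error = function(e) NA_real_)
  hi_ci <- tryCatch({
    up <- m_hat * 2
    while (f(up) > 0 && up < 1e6) up <- up * 2
    stats::uniroot(f, c(m_hat, up), tol = 1e-8)$root
  }, error = function(e) NA_real_)

  est <- list(m_hat = m_hat, rate = m_hat / experiment$n_final,
              ci95_m = c(lo_ci, hi_ci),
              ci95_rate = c(lo_ci, hi_ci) / experiment$n_final,
              loglik = ll_max, all_zero = FALSE,
              counts = counts, n_final = experiment$n_final,
              efficiency = eps, condition = experiment$condition)
  class(est) <- "rate_estimate"
  est
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<rate_estimate>%s m = %.4g (95%% CI %.4g-%.4g); rate = %.3g per cell per generation\n",
    if (nzchar(x$condition)) paste0(" [", x$condition, "]") else "",
    x$m_hat, x$ci95_m[1], x$ci95_m[2], x$rate))
  invisible(x)
}

#' Fold change between two mutation-rate estimates
#'
#' Ratio of rates (induced / uninduced) with an approximate 95% CI by
#' the delta method on the log scale, using standard errors implied by
#' each profile CI.
#'
#' @param on,off `rate_estimate` objects (numerator and denominator).
#' @return list with `ratio`, `ci95`, and the input rates.
#' @export
fold_change <- function(on, off) {
  stopifnot(inherits(on, "rate_estimate"), inherits(off, "rate_estimate"))
  if (off$rate <= 0) {
    stop(errorCondition(
      paste("denominator rate is 0; fold change undefined.",
            "Use the p0-method upper bound", format(off$ci95_rate[2]),
            "for a lower bound on the ratio."),
      class = c("sptkin_ratio_error", "error", "condition")))
  }
  ratio <- on$rate / off$rate
  se_log <- function(est) {
    ci <- est$ci95_m
    if (any(is.na(ci)) || any(ci <= 0)) return(NA_real_)
    (log(ci[2]) - log(ci[1])) / (2 * stats::qnorm(0.975))
  }
  s <- sqrt(se_log(on)^2 + se_log(off)^2)
  ci <- if (is.na(s)) c(NA_real_, NA_real_) else
    exp(log(ratio) + c(-1, 1) * stats::qnorm(0.975) * s)
  list(ratio = ratio, ci95 = ci, rate_on = on$rate, rate_off = off$rate)
}

#' Simulate a fluctuation experiment (deterministic clone growth)
#'
#' Brute-force forward simulation used as an independent check of
#' [ld_pmf()]: the number of mutation events per culture is
#' Poisson(m); each clone's final cell number is floor(1/U)
#' (P(size >= j) = 1/j, the deterministic-growth clone-size law); each
#' clone cell is plated with probability `efficiency`.
#'
#' @param n_cultures number of parallel cultures.
#' @param m expected mutations per culture.
#' @param efficiency plating efficiency in (0, 1].
#' @return integer vector of mutant-colony counts.
#' @export
simulate_fluctuation <- function(n_cultures, m, efficiency = 1) {
  stopifnot(n_cultures >= 1, m >= 0)
  k <- stats::rpois(n_cultures, m)
  total <- sum(k)
  if (total == 0L) return(integer(n_cultures))
  sizes <- floor(1 / stats::runif(total))
  shown <- if (efficiency < 1)
    stats::rbinom(total, size = pmin(sizes, .Machine$integer.max),
                  prob = efficiency)
  else sizes
  culture <- rep.int(seq_len(n_cultures), k)
  out <- integer(n_cultures)
  agg <- tapply(shown, culture, sum)
  out[as.integer(names(agg))] <- as.integer(agg)
  out
}

#' Read a fluctuation-experiment CSV
#'
#' Expected header: `culture_id,condition,mutant_count,n_final,efficiency`.
#' Returns one [fluctuation_experiment()] per condition (n_final and
#' efficiency must be constant within a condition).
#'
#' @param path CSV path.
#' @return named list of `fluctuation_experiment` objects.
#' @export
read_fluctuation_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  req <- c("culture_id", "condition", "mutant_count", "n_final",
           "efficiency")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0L)
    stop(errorCondition(
      sprintf("fluctuation CSV lacks column(s): %s",
              paste(missing_cols, collapse = ", ")),
      class = c("sptkin_format_error", "error", "condition")))
  num <- .parse_numeric_columns(raw[c("mutant_count", "n_final",
                                      "efficiency")], path)
  df <- data.frame(condition = raw$condition, num)
  lapply(split(df, df$condition), function(g) {
    if (length(unique(g$n_final)) != 1L ||
        length(unique(g$efficiency)) != 1L)
      stop("n_final and efficiency must be constant within a condition")
    fluctuation_experiment(g$mutant_count, g$n_final[1L],
                           g$efficiency[1L], g$condition[1L])
  })
}
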