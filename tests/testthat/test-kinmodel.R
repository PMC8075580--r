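test_that("single-state jump CDF has Rayleigh form", {
  expect_equal(jump_cdf_single(0, 0.5, 0.02, 0.035), 0)
  expect_equal(jump_cdf_single(1e6, 0.5, 0.02, 0.035), 1)

  # substituting r^2 = 4*(D*dt + sigma^2) gives 1 - 1/e
  r1 <- sqrt(4 * (0.5 * 0.02 + 0.035^2))
  expect_equal(jump_cdf_single(r1, 0.5, 0.02, 0.035), 1 - exp(-1))

  # CDF equals the numerically integrated density
  grid <- seq(0, 1.5, by = 1e-4)
  pdf <- jump_pdf_single(grid, 0.5, 0.02, 0.035)
  num_cdf <- cumsum(pdf) * 1e-4
  expect_equal(num_cdf[length(grid)],
               jump_cdf_single(1.5, 0.5, 0.02, 0.035), tolerance = 1e-3)

  # immobile molecule: density mode at sqrt(2)*sigma
  rg <- seq(0, 0.2, by = 1e-5)
  mode <- rg[which.max(jump_pdf_single(rg, 0, 0.02, 0.035))]
  expect_equal(mode, sqrt(2) * 0.035, tolerance = 1e-3)

  expect_error(jump_cdf_single(0.1, -1, 0.02, 0.035), "D and sigma")
  expect_error(jump_pdf_single(0.1, 0.5, 0.02, -0.01), "D and sigma")
})

test_that("z_survival has correct limits and monotonicity", {
  expect_equal(z_survival(0, 0.02, 0.9), 1.0)
  expect_equal(z_survival(5, 1, Inf), 1.0)
  expect_equal(z_survival(1, 0.02, 1e4), 1.0, tolerance = 1e-4)

  # strictly decreasing in D and dt, increasing in dZ
  Ds <- c(0.01, 0.1, 0.5, 1, 3, 10)
  s_D <- vapply(Ds, z_survival, numeric(1), dt = 0.02, dZ = 0.9)
  expect_true(all(diff(s_D) < 0))
  dts <- c(0.02, 0.04, 0.06, 0.08, 0.2)
  s_t <- vapply(dts, function(t) z_survival(1, t, 0.9), numeric(1))
  expect_true(all(diff(s_t) < 0))
  dZs <- c(0.5, 0.7, 0.9, 1.2, 2)
  s_z <- vapply(dZs, function(z) z_survival(1, 0.02, z), numeric(1))
  expect_true(all(diff(s_z) > 0))
  expect_true(all(s_D > 0 & s_D <= 1))

  # the short-time branch (alpha < 0.01) agrees with a directly summed
  # eigenseries oracle at the same alpha
  eigen_oracle <- function(alpha, n = 400L) {
    j <- seq(1L, 2L * n - 1L, by = 2L)
    sum(8 / (j^2 * pi^2) * exp(-j^2 * pi^2 * alpha))
  }
  for (alpha in c(0.002, 0.005, 0.009)) {
    dt <- alpha * 0.81  # D = 1, dZ = 0.9
    expect_equal(z_survival(1, dt, 0.9), eigen_oracle(alpha),
                 tolerance = 1e-6)
  }
})

test_that("z_survival matches an absorbing random-walk Monte Carlo", {
  # Brownian z-walk with bridge-corrected absorbing boundaries
  set.seed(17)
  mc_survival <- function(D, dt, dZ, n = 2e5, n_steps = 20L) {
    h <- dt / n_steps
    half <- dZ / 2
    z <- runif(n, -half, half)
    alive <- rep(TRUE, n)
    for (s in seq_len(n_steps)) {
      z_old <- z
      z <- z + rnorm(n, 0, sqrt(2 * D * h))
      exit <- abs(z) > half
      p_up <- exp(-(half - z_old) * (half - z) / (D * h))
      p_dn <- exp(-(half + z_old) * (half + z) / (D * h))
      crossed <- runif(n) < pmin(1, p_up + p_dn)
      alive <- alive & !exit & !crossed
    }
    mean(alive)
  }
  for (case in list(c(1.0, 0.02, 0.9), c(0.15, 0.08, 0.9))) {
    p_mc <- mc_survival(case[1], case[2], case[3])
    se <- sqrt(p_mc * (1 - p_mc) / 2e5)
    expect_lt(abs(p_mc - z_survival(case[1], case[2], case[3])), 3 * se)
  }
})

test_that("model_cdf mixes states with defocalisation-corrected weights", {
  # degenerate mixture equals the single-state CDF
  m1 <- diffusion_model(1, 0.5, 0.035)
  r <- seq(0, 2, by = 0.01)
  expect_equal(model_cdf(m1, 0.02, r),
               jump_cdf_single(r, 0.5, 0.02, 0.035))

  # equal D's: fractions are irrelevant by convexity
  m_eq <- diffusion_model(c(0.3, 0.7), c(0.4, 0.4), 0.035)
  expect_equal(model_cdf(m_eq, 0.02, r),
               jump_cdf_single(r, 0.4, 0.02, 0.035))

  # doubling dt increases the bound state's renormalised weight
  m2 <- diffusion_model(c(0.5, 0.5), c(0.01, 1.0), 0.035)
  w1 <- sptkin:::.defocal_weights(m2, 0.02)
  w2 <- sptkin:::.defocal_weights(m2, 0.04)
  expect_gt(w2[1], w1[1])

  # monotone non-decreasing and -> 1, over random valid models and lags
  set.seed(23)
  for (rep in 1:10) {
    k <- sample(2:3, 1)
    f <- diff(c(0, sort(runif(k - 1)), 1))
    m <- diffusion_model(f, sort(runif(k, 0.001, 5)),
                         runif(1, 0.01, 0.075))
    cdf <- model_cdf(m, sample(c(0.02, 0.04, 0.08), 1), r)
    expect_true(all(diff(cdf) >= -1e-12))
    expect_equal(model_cdf(m, 0.02, 50), 1, tolerance = 1e-9)
  }
})

test_that("fit_model is deterministic, bounded and recovers simple truths", {
  set.seed(31)
  sim <- simulate_spt(make_fixture("cohesin-like", n_molecules = 1200L,
                                   seed = 31L, n_frames = 8000L))
  ds <- compute_jump_dataset(truth_tracks(sim))

  f2a <- fit_model(ds, 2, seed = 5)
  f2b <- fit_model(ds, 2, seed = 5)
  expect_identical(f2a$model$fractions, f2b$model$fractions)
  expect_identical(f2a$rss, f2b$rss)

  # AIC bookkeeping
  expect_equal(f2a$aic,
               f2a$n_points * log(f2a$rss / f2a$n_points) +
                 2 * f2a$k_params)
  expect_identical(f2a$k_params, 4L)

  # 2-state truth (60% bound): recovery within a few points
  expect_equal(f_bound(f2a), 0.60, tolerance = 0.06)

  # 3-state fit never returns D_slow below the bound
  f3 <- fit_model(ds, 3, seed = 5)
  expect_gte(sort(f3$model$D)[2], 0.08)
  expect_identical(f3$k_params, 6L)
})

test_that("all-bound data fits to F_bound >= 0.95", {
  set.seed(37)
  sim <- simulate_spt(make_fixture("bound-only", n_molecules = 600L,
                                   seed = 37L, n_frames = 5000L))
  ds <- compute_jump_dataset(truth_tracks(sim))
  f2 <- fit_model(ds, 2, seed = 3)
  expect_gte(f_bound(f2), 0.95)
})

test_that("select_by_aic prefers parsimony at equal RSS", {
  mk_fit <- function(n_states, rss, n_points = 1204L) {
    k <- 2L * n_states
    structure(list(model = NULL, rss = rss, n_points = n_points,
                   k_params = k,
                   aic = n_points * log(rss / n_points) + 2 * k,
                   n_states = n_states, converged = TRUE, seed = 1L),
              class = "spt_fit")
  }
  f2 <- mk_fit(2L, 0.5); f3 <- mk_fit(3L, 0.5)
  expect_identical(select_by_aic(f2, f3)$n_states, 2L)
  expect_lte(attr(select_by_aic(f2, f3), "delta_aic"), 0)
  expect_error(select_by_aic(f2, mk_fit(3L, 0.5, n_points = 900L)),
               class = "sptkin_incompatible_error")
})

test_that("f_bound returns the lowest-D state's fraction", {
  m3 <- diffusion_model(c(0.4, 0.2, 0.4), c(0.005, 0.2, 1.5), 0.035)
  expect_equal(f_bound(m3), 0.4)
  m2 <- diffusion_model(c(0.7, 0.3), c(0.01, 1.0), 0.035)
  expect_equal(f_bound(m2), 0.7)
  # ordering is by D, not input order
  m_swap <- diffusion_model(c(0.3, 0.7), c(1.0, 0.01), 0.035)
  expect_equal(f_bound(m_swap), 0.7)
})
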