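test_that("erlang hit probabilities match the Poisson pmf oracle", {
  # closed-form spot values
  expect_equal(erlang_hit_probability(0, 0, 258), 1)
  expect_equal(erlang_hit_probability(258, 0, 258), exp(-1))
  expect_equal(erlang_hit_probability(516, 2, 258), 2^2 * exp(-2) / 2)

  # independent oracle: stats::dpois at mu = phi/lambda
  withr::with_seed(11, {
    for (i in 1:50) {
      phi <- stats::runif(1, 0, 5000)
      lam <- stats::runif(1, 50, 1000)
      k <- sample(0:12, 1)
      expect_equal(erlang_hit_probability(phi, k, lam),
                   stats::dpois(k, phi / lam), tolerance = 1e-12)
    }
  })

  # partial sums reach 1
  for (phi in c(0, 100, 258, 2000, 10000)) {
    kmax <- ceiling(50 * phi / 258 + 50)
    s <- sum(vapply(0:kmax, erlang_hit_probability, numeric(1),
                    phi = phi, lambda_gy = 258))
    expect_gte(s, 1 - 1e-10)
    expect_lte(s, 1 + 1e-10)
  }

  expect_error(erlang_hit_probability(-1, 0, 258), "phi")
  expect_error(erlang_hit_probability(1, 0, -5), "lambda")
  expect_error(erlang_hit_probability(1, 1.5, 258), "integer")
})

test_that("survival and release curves have the stated shape", {
  lam <- 258
  expect_equal(survival_curve(0, lam), 1)
  expect_equal(survival_curve(lam * log(10), lam), 0.1)
  expect_equal(survival_curve(lam, lam), exp(-1))
  phi <- seq(0, 5000, by = 5)
  expect_true(all(diff(survival_curve(phi, lam)) < 0))

  # release: baseline at zero dose, unique max b + A/e at phi = lambda
  expect_equal(release_curve(0, lam, 1, 0.2), 0.2)
  expect_equal(release_curve(lam, lam, 1, 0), exp(-1))
  y <- release_curve(phi, lam, 1, 0)
  imax <- which.max(y)
  expect_equal(phi[imax], lam, tolerance = 5 / lam)
  expect_true(all(diff(y[phi < lam]) > 0))
  expect_true(all(diff(y[phi > lam]) < 0))
})

test_that("survival fitting recovers lambda from exact and counted data", {
  # exact geometric data: closed-form log-linear recovery
  d <- dose_response("Fe", c(0, 258, 516), c(1, exp(-1), exp(-2)), "survival")
  f <- fit_survival(d)
  expect_equal(f$lambda_gy, 258, tolerance = 1e-10)
  expect_equal(f$k, 0L)

  # zero-noise curve at arbitrary lambda recovers exactly
  lam <- 412.7
  doses <- c(0, 100, 250, 500, 1000, 2000)
  d2 <- dose_response("Fe", doses, survival_curve(doses, lam), "survival")
  expect_equal(fit_survival(d2)$lambda_gy, lam, tolerance = 1e-10)

  # degenerate: flat responses are non-identifiable
  flat <- dose_response("Fe", doses, rep(1, 6), "survival")
  expect_error(fit_survival(flat), "non-identifiable")
  one <- dose_response("Fe", c(500, 500), c(0.5, 0.4), "survival")
  expect_error(fit_survival(one), "insufficient")

  # zero responses are excluded from the log fit and reported
  dz <- dose_response("Fe", doses, c(survival_curve(doses[-6], lam), 0),
                      "survival")
  fz <- fit_survival(dz)
  expect_equal(fz$diagnostics$dropped_zero_responses, 1)
  expect_equal(fz$lambda_gy, lam, tolerance = 1e-10)

  # Poisson count route agrees with the log-linear route on clean data
  sim <- simulate_survival(simulation_design(seed = 99))
  fl <- fit_survival(sim)
  fp <- fit_survival(sim, method = "poisson")
  expect_equal(fp$lambda_gy, fl$lambda_gy, tolerance = 1e-2)
})

test_that("survival fit is consistent on the equivalent-dose axis", {
  # fitting Ar data after Fe-equivalent conversion equals rescaling a
  # raw-dose fit by sigma_Ar/sigma_Fe
  ar <- ar_beam(); fe <- fe_beam()
  ratio <- normalized_sigma(ar, fe)
  doses <- c(0, 250, 500, 1000, 1500)
  resp <- survival_curve(doses * ratio, 258) # truth lives on the Fe axis
  d <- dose_response("Ar", doses, resp, "survival")
  f_eq <- fit_survival(d, beam = ar, reference = fe)
  f_raw <- fit_survival(d)
  expect_equal(f_eq$lambda_gy, f_raw$lambda_gy * ratio, tolerance = 1e-9)
  expect_equal(f_eq$lambda_gy, 258, tolerance = 1e-9)
})

test_that("release fitting recovers parameters and flags degenerate shapes", {
  # noiseless self-consistency at 6 doses
  doses <- c(0, 100, 250, 500, 1000, 2000)
  y <- release_curve(doses, 258, 1, 0.2)
  d <- dose_response("Fe", doses, y, "release_ratio")
  f <- fit_release(d)
  expect_equal(f$lambda_gy, 258, tolerance = 1e-6)
  expect_equal(f$amplitude, 1, tolerance = 1e-6)
  expect_equal(f$baseline, 0.2, tolerance = 1e-6)
  expect_equal(threshold_dose(f), f$lambda_gy)
  expect_false(f$diagnostics$lambda_at_lower_bound)

  # threshold agrees with a grid-search argmax of the fitted curve
  grid <- seq(1, 4000, by = 0.01)
  curve_vals <- release_curve(grid, f$lambda_gy, f$amplitude, f$baseline)
  expect_equal(grid[which.max(curve_vals)], threshold_dose(f),
               tolerance = 0.1 / 258)

  # data that drop immediately and stay flat have no interior maximum in
  # the sampled range: lambda is pushed to its lower bound and flagged
  ymono <- c(1, 0.3, 0.28, 0.3, 0.29, 0.3)
  dmono <- dose_response("Fe", doses, ymono, "release_ratio")
  fmono <- fit_release(dmono)
  expect_true(fmono$diagnostics$lambda_at_lower_bound)

  expect_error(threshold_dose(fit_survival(
    dose_response("Fe", doses, survival_curve(doses, 258), "survival"))),
    "invalid model")
  expect_error(fit_release(dose_response("Fe", c(0, 100), c(0.2, 0.3),
                                         "release_ratio")), "insufficient")
})

test_that("release fitting is robust over seeded noisy replicates", {
  lams <- vapply(1:60, function(i) {
    d <- simulate_release_series(simulation_design(noise_sd = 0.05,
                                                   seed = 5000 + i))
    fit_release(d)$lambda_gy
  }, numeric(1))
  expect_lt(abs(stats::median(lams) - 258) / 258, 0.05)
})

test_that("bootstrap interval is seeded, degenerate on exact data, and informative", {
  doses <- c(0, 100, 250, 500, 1000, 2000)
  # noiseless exact data: interval collapses onto the point estimate
  d0 <- dose_response("Fe", doses, survival_curve(doses, 258), "survival")
  ci0 <- bootstrap_ci(d0, fit_survival, n_boot = 200, seed = 1)
  expect_equal(ci0$lower, 258, tolerance = 1e-9)
  expect_equal(ci0$upper, 258, tolerance = 1e-9)

  sim <- simulate_survival(simulation_design(seed = 123))
  ci_a <- bootstrap_ci(sim, fit_survival, n_boot = 300, seed = 7)
  ci_b <- bootstrap_ci(sim, fit_survival, n_boot = 300, seed = 7)
  ci_c <- bootstrap_ci(sim, fit_survival, n_boot = 300, seed = 8)
  expect_identical(ci_a$lower, ci_b$lower)      # deterministic given seed
  expect_identical(ci_a$upper, ci_b$upper)
  expect_false(identical(ci_a$lower, ci_c$lower)) # seed change moves it
  # different seeds still overlap
  expect_lt(max(ci_a$lower, ci_c$lower), min(ci_a$upper, ci_c$upper))

  expect_error(bootstrap_ci(d0, n_boot = 50), "n_boot")
  expect_error(bootstrap_ci(dose_response("Fe", c(0, 500), c(1, 0.5),
                                          "survival"), n_boot = 200),
               "insufficient")
})
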