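# concave quadratic vanishing at the grid ends: non-negative, its lower
# convex hull is the zero chord, and order-2 Savitzky-Golay reproduces it
# exactly, so preprocessing reduces to vector normalization
quad_fixture <- function(lo = 950, hi = 1800, by = 2) {
  w <- seq(lo, hi, by = by)
  y <- (w - lo) * (hi - w)
  spectrum(w, y / sqrt(sum((y / max(y))^2)) / max(y))
}

test_that("preprocessing is a unit-norm projection with a smooth fixpoint", {
  s <- quad_fixture()
  expect_equal(sqrt(sum(s$intensities^2)), 1, tolerance = 1e-12)
  out <- preprocess_ir(s)
  expect_equal(out$intensities, s$intensities, tolerance = 1e-10)

  # unit Euclidean norm over the full (pre-cut) range
  w <- seq(900, 1900, by = 2)
  withr::with_seed(31, {
    bumpy <- spectrum(w, exp(-(w - 1650)^2 / 800) +
                        0.5 * exp(-(w - 1080)^2 / 600) +
                        0.3 + 1e-4 * w + stats::rnorm(length(w), sd = 0.005))
  })
  full <- preprocess_ir(bumpy, cut = NULL)
  expect_equal(sqrt(sum(full$intensities^2)), 1, tolerance = 1e-9)
  cutted <- preprocess_ir(bumpy)
  expect_true(all(cutted$wavenumbers >= 950 & cutted$wavenumbers <= 1800))
  expect_lte(sqrt(sum(cutted$intensities^2)), 1 + 1e-9)

  # Savitzky-Golay (15, order 2) reproduces quadratics exactly on the
  # interior; order-3 content needs sg_order = 3
  wq <- seq(0, 100, by = 1)
  cub <- 1 + wq + 0.01 * wq^2 + 1e-4 * wq^3
  sm3 <- preprocess_ir(spectrum(wq, cub), baseline = "none", sg_order = 3,
                       normalize = "none", cut = NULL)
  expect_equal(sm3$intensities, cub, tolerance = 1e-10)

  expect_error(preprocess_ir(spectrum(seq(1000, 1500, 2),
                                      rep(1, 251))), "coverage")
  short <- spectrum(seq(950, 1800, length.out = 18),
                    seq(950, 1800, length.out = 18) * 0 + 1)
  expect_error(preprocess_ir(short, sg_window = 31), "window")
})

test_that("band integrals are chord-based and affine-invariant", {
  bands <- default_ir_bands()
  protein <- bands[bands$name == "protein", ]
  w <- seq(950, 1800, by = 2)

  # any straight line integrates to zero
  line <- spectrum(w, 3 - 0.002 * w)
  expect_equal(as.numeric(band_integral(line, protein)), 0, tolerance = 1e-9)

  # unit triangle: base 100, apex 1 -> area 50
  tri_band <- band_definition("tri", 1500, 1700)
  apex <- 1600
  tri <- spectrum(w, pmax(0, 1 - abs(w - apex) / 50))
  expect_equal(as.numeric(band_integral(tri, tri_band)), 50,
               tolerance = 1e-9)

  # random affine perturbations never change the integral
  base <- spectrum(w, exp(-(w - 1600)^2 / 500))
  a0 <- as.numeric(band_integral(base, protein))
  withr::with_seed(17, {
    for (i in 1:20) {
      aa <- stats::rnorm(1, sd = 5); bb <- stats::rnorm(1, sd = 0.01)
      pert <- spectrum(w, base$intensities + aa + bb * w)
      expect_equal(as.numeric(band_integral(pert, protein)), a0,
                   tolerance = 1e-9)
    }
  })

  expect_error(band_integral(base, band_definition("x", 100, 200)),
               "coverage")
  expect_error(band_definition("bad", 1700, 1500), "lo_cm1 < hi_cm1")
})

test_that("band ratios report the constructed areas and scale invariance", {
  s <- synth_ir_spectrum(c(protein = 2, dpa = 1, carb = 4), noise_sd = 0)
  br <- band_ratios(s)
  expect_equal(br$protein_area, 2, tolerance = 1e-9)
  expect_equal(br$dpa_area, 1, tolerance = 1e-9)
  expect_equal(br$carb_area, 4, tolerance = 1e-9)
  expect_equal(br$dpa_over_protein, 0.5, tolerance = 1e-9)
  expect_equal(br$carb_over_protein, 2, tolerance = 1e-9)

  s7 <- spectrum(s$wavenumbers, 7 * s$intensities)
  br7 <- band_ratios(s7)
  expect_equal(br7$dpa_over_protein, br$dpa_over_protein, tolerance = 1e-12)
  expect_equal(br7$carb_over_protein, br$carb_over_protein,
               tolerance = 1e-12)

  # no DPA content: dpa_over_protein collapses to ~0
  s0 <- synth_ir_spectrum(c(protein = 2, dpa = 0, carb = 4), noise_sd = 0)
  expect_equal(band_ratios(s0)$dpa_over_protein, 0, tolerance = 1e-9)
})

test_that("PCA partitions variance as constructed and round-trips scores", {
  w <- seq(950, 1800, by = 5)
  base <- exp(-(w - 1400)^2 / 5000)
  dir1 <- sin(w / 40); dir1 <- dir1 / sqrt(sum(dir1^2))

  # rank-one data: PC1 explains everything
  specs1 <- lapply(c(-2, -1, 0.5, 2.5), function(a)
    spectrum(w, base + a * dir1))
  p1 <- fit_pca(specs1)
  expect_equal(p1$explained_variance_fraction[1], 1, tolerance = 1e-10)

  # two orthogonal sources with variance ratio 9:1
  dir2 <- cos(w / 23); dir2 <- dir2 - sum(dir2 * dir1) * dir1
  dir2 <- dir2 / sqrt(sum(dir2^2))
  n <- 60
  withr::with_seed(23, {
    a <- stats::rnorm(n, sd = 3); b <- stats::rnorm(n, sd = 1)
  })
  # remove sample covariance so the empirical variances split exactly
  b <- stats::residuals(stats::lm(b ~ a))
  a <- (a - mean(a)) / stats::sd(a) * 3
  b <- (b - mean(b)) / stats::sd(b)
  specs2 <- lapply(seq_len(n), function(i)
    spectrum(w, base + a[i] * dir1 + b[i] * dir2))
  p2 <- fit_pca(specs2, n_components = 2)
  expect_equal(p2$explained_variance_fraction, c(0.9, 0.1),
               tolerance = 1e-9)

  # loadings orthonormal; fractions non-increasing, sum <= 1
  gram <- crossprod(p2$loadings)
  expect_equal(gram, diag(2), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(p2$explained_variance_fraction) <= 1e-12))
  expect_lte(sum(p2$explained_variance_fraction), 1 + 1e-12)

  # round-trip: projecting a training spectrum returns its stored score
  sc <- project_spectrum(p2, specs2[[7]])
  expect_equal(unname(sc), unname(p2$scores[7, ]), tolerance = 1e-9)

  # independent cross-check against prcomp on the same matrix
  x <- t(vapply(specs2, `[[`, numeric(length(w)), "intensities"))
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  expect_equal(abs(p2$loadings[, 1]), abs(pr$rotation[, 1]),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(p2$explained_variance_fraction[1],
               pr$sdev[1]^2 / sum(pr$sdev^2), tolerance = 1e-10)

  # reconstruction error decreases as components are added
  recon_rmse <- vapply(1:3, function(k) {
    pk <- fit_pca(specs2, n_components = k)
    xr <- pk$scores %*% t(pk$loadings)
    xc <- sweep(x, 2, colMeans(x))
    sqrt(mean((xc - xr)^2))
  }, numeric(1))
  expect_true(all(diff(recon_rmse) < 1e-12))

  expect_error(fit_pca(specs2[1]), "insufficient")
})

test_that("confidence ellipses follow the chi-square geometry", {
  # isotropic unit-variance cloud: radius ~ sqrt(qchisq(.95, 2)) = 2.448
  n <- 20000
  pts <- withr::with_seed(41, matrix(stats::rnorm(2 * n), ncol = 2))
  e <- confidence_ellipse(pts, 0.95)
  expect_equal(e$radii, rep(sqrt(stats::qchisq(0.95, 2)), 2),
               tolerance = 0.03)
  expect_equal(unname(e$center), c(0, 0), tolerance = 0.05)
  expect_false(e$degenerate)

  # rotation equivariance: rotating the cloud rotates the ellipse
  aniso <- cbind(3 * pts[, 1], pts[, 2])
  th <- pi / 7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  e0 <- confidence_ellipse(aniso)
  e1 <- confidence_ellipse(aniso %*% t(rot))
  expect_equal(e1$radii, e0$radii, tolerance = 1e-6)
  ang <- (e1$angle_rad - e0$angle_rad - th) %% pi
  expect_lt(min(ang, pi - ang), 1e-6)

  # identical points: zero-area, flagged degenerate
  same <- matrix(rep(c(1, 2), each = 5), ncol = 2)
  ed <- confidence_ellipse(same)
  expect_true(ed$degenerate)
  expect_equal(unname(ed$radii), c(0, 0))
  expect_error(confidence_ellipse(pts[1:2, ]), "3 points|>= 3")
})

test_that("the IR pipeline tracks a prescribed dose profile end to end", {
  # DPA/protein follows the single-event release curve over the dose panel;
  # per-dose values are means over replicate spectra, emulating the many
  # spectra collected per treatment
  doses <- c(0, 250, 500, 1000, 1500, 2000)
  profile <- release_curve(doses, 258, 1.5, 0.4)
  run <- function(noise, reps) vapply(seq_along(doses), function(i) {
    mean(vapply(seq_len(reps), function(r) {
      s <- synth_ir_spectrum(c(protein = 2, dpa = 2 * profile[i], carb = 3),
                             noise_sd = noise, seed = 8000 + 100 * i + r)
      band_ratios(preprocess_ir(s))$dpa_over_protein
    }, numeric(1)))
  }, numeric(1))
  noiseless <- run(0, 1)
  expect_equal(stats::cor(noiseless, profile, method = "spearman"), 1)
  # noise at 2% of the clean spectrum peak-to-trough amplitude
  clean <- synth_ir_spectrum(c(protein = 2, dpa = 2 * profile[2], carb = 3),
                             noise_sd = 0)
  peak_amp <- max(clean$intensities) - min(clean$intensities)
  noisy <- run(0.02 * peak_amp, 10)
  expect_gte(stats::cor(noisy, profile, method = "spearman"), 0.9)
})
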