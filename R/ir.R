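#' IR band definitions
#'
#' A named integration band `[lo, hi]` (cm^-1). `default_ir_bands()` returns
#' the four bands used for spore fingerprinting: proteins (amide I + II)
#' 1480-1735, amide I 1700-1600, Ca2+-DPA 1330-1480 and carbohydrates
#' 950-1180 cm^-1.
#'
#' @param name Band label.
#' @param lo_cm1,hi_cm1 Band limits (cm^-1), `lo_cm1 < hi_cm1`.
#' @return `band_definition()`: a one-row data frame; `default_ir_bands()`:
#'   a four-row data frame.
#' @export
band_definition <- function(name, lo_cm1, hi_cm1) {
  if (!(lo_cm1 < hi_cm1))
    stop("band limits must satisfy lo_cm1 < hi_cm1", call. = FALSE)
  data.frame(name = name, lo_cm1 = lo_cm1, hi_cm1 = hi_cm1)
}

#' @rdname band_definition
#' @export
default_ir_bands <- function() {
  rbind(band_definition("protein", 1480, 1735),
        band_definition("amide_I", 1600, 1700),
        band_definition("dpa",     1330, 1480),
        band_definition("carb",     950, 1180))
}

# lower convex hull (Andrew monotone chain) evaluated on the full grid
rubberband_baseline <- function(w, y) {
  n <- length(w)
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2) {
      k <- length(hull)
      o <- hull[k - 1]; a <- hull[k]
      cross <- (w[a] - w[o]) * (y[i] - y[o]) - (y[a] - y[o]) * (w[i] - w[o])
      if (cross <= 0) hull <- hull[-k] else break
    }
    hull <- c(hull, i)
  }
  stats::approx(w[hull], y[hull], xout = w, method = "linear")$y
}

#' Preprocess an IR spectrum
#'
#' Applies, in order: baseline correction (rubberband convex-hull by
#' default, polynomial detrend or none as alternatives), Savitzky-Golay
#' smoothing (15-point window, order-2 polynomial by default), vector
#' normalization to unit Euclidean norm over the full available range, and
#' restriction to the analysis range 950-1800 cm^-1. Normalization precedes
#' the cut by default (`normalize = "before_cut"`), matching the listed
#' processing order; `"after_cut"` is available since workflows vary.
#'
#' @param spec A [spectrum()] whose grid covers the cut range.
#' @param baseline `"rubberband"`, `"polynomial"` or `"none"`.
#' @param poly_degree Degree for the polynomial baseline alternative.
#' @param sg_window Savitzky-Golay window length (odd); `NULL` skips
#'   smoothing.
#' @param sg_order Savitzky-Golay polynomial order (`< sg_window`).
#' @param normalize `"before_cut"`, `"after_cut"` or `"none"`.
#' @param cut `c(lo, hi)` analysis range (cm^-1), or `NULL` to keep all.
#' @return Preprocessed [spectrum()]; with `normalize = "before_cut"` the
#'   full-range norm is 1 before cutting.
#' @export
preprocess_ir <- function(spec, baseline = c("rubberband", "polynomial",
                                             "none"),
                          poly_degree = 2, sg_window = 15, sg_order = 2,
                          normalize = c("before_cut", "after_cut", "none"),
                          cut = c(950, 1800)) {
  stopifnot(inherits(spec, "spectrum"))
  baseline <- match.arg(baseline)
  normalize <- match.arg(normalize)
  w <- spec$wavenumbers; y <- spec$intensities
  if (!is.null(cut)) {
    if (min(w) > cut[1] || max(w) < cut[2])
      stop("coverage error: grid [", min(w), ", ", max(w),
           "] does not cover the cut range [", cut[1], ", ", cut[2], "]",
           call. = FALSE)
  }
  require_min_points(spec, 16L, "preprocess_ir")

  y <- switch(baseline,
    rubberband = y - rubberband_baseline(w, y),
    polynomial = stats::residuals(stats::lm(y ~ stats::poly(w, poly_degree))),
    none = y)

  if (!is.null(sg_window)) {
    if (sg_window > length(y))
      stop("invalid params: smoothing window longer than spectrum",
           call. = FALSE)
    y <- signal::sgolayfilt(y, p = sg_order, n = sg_window)
  }

  vecnorm <- function(v) {
    nrm <- sqrt(sum(v^2))
    if (nrm == 0) stop("cannot normalize an all-zero spectrum", call. = FALSE)
    v / nrm
  }
  if (normalize == "before_cut") y <- vecnorm(y)
  out <- spectrum(w, y, spec$meta)
  if (!is.null(cut)) out <- crop_spectrum(out, cut[1], cut[2])
  if (normalize == "after_cut")
    out <- spectrum(out$wavenumbers, vecnorm(out$intensities), out$meta)
  out
}

#' Linear-baseline band integral
#'
#' Trapezoidal integral of the spectrum minus the chord drawn between the
#' band extremes: the straight line joining the spectrum's values at the two
#' band limits is subtracted before integration, so any affine component of
#' the signal contributes nothing. Band limits falling between grid points
#' snap to the nearest grid point (recorded in the result attributes). The
#' value may be negative where the signal dips below its own chord.
#'
#' @param spec A [spectrum()] whose grid covers the band.
#' @param band A one-row band data frame (see [band_definition()]).
#' @return Band area (intensity x cm^-1) with attributes `lo_used`/`hi_used`
#'   giving the snapped anchor wavenumbers.
#' @export
band_integral <- function(spec, band) {
  stopifnot(inherits(spec, "spectrum"))
  w <- spec$wavenumbers; y <- spec$intensities
  if (band$lo_cm1 < min(w) || band$hi_cm1 > max(w))
    stop("coverage error: band ", band$name, " [", band$lo_cm1, ", ",
         band$hi_cm1, "] outside grid", call. = FALSE)
  i_lo <- which.min(abs(w - band$lo_cm1))
  i_hi <- which.min(abs(w - band$hi_cm1))
  idx <- i_lo:i_hi
  chord <- y[i_lo] + (y[i_hi] - y[i_lo]) *
    (w[idx] - w[i_lo]) / (w[i_hi] - w[i_lo])
  area <- pracma::trapz(w[idx], y[idx] - chord)
  attr(area, "lo_used") <- w[i_lo]
  attr(area, "hi_used") <- w[i_hi]
  area
}

#' Band-area ratios for spore IR spectra
#'
#' Linear-baseline band integrals over the standard bands and the two
#' summary ratios: Ca2+-DPA over proteins (area 1330-1480 over area
#' 1480-1735 cm^-1) and carbohydrates over proteins. Both are invariant
#' under uniform intensity rescaling of the spectrum.
#'
#' @param spec A (preprocessed) [spectrum()].
#' @param bands Band table; default [default_ir_bands()]. Must contain
#'   `protein`, `dpa`, `carb` and `amide_I` rows.
#' @return Named list: `dpa_over_protein`, `carb_over_protein`, `dpa_area`,
#'   `amideI_area`, `protein_area`, `carb_area`.
#' @export
band_ratios <- function(spec, bands = default_ir_bands()) {
  get_band <- function(nm) {
    row <- bands[bands$name == nm, , drop = FALSE]
    if (nrow(row) != 1L) stop("band table must contain one '", nm, "' row",
                              call. = FALSE)
    row
  }
  a_prot <- as.numeric(band_integral(spec, get_band("protein")))
  a_dpa <- as.numeric(band_integral(spec, get_band("dpa")))
  a_carb <- as.numeric(band_integral(spec, get_band("carb")))
  a_am1 <- as.numeric(band_integral(spec, get_band("amide_I")))
  if (a_prot == 0)
    stop("degenerate ratio: protein band area is zero", call. = FALSE)
  list(dpa_over_protein = a_dpa / a_prot,
       carb_over_protein = a_carb / a_prot,
       dpa_area = a_dpa, amideI_area = a_am1,
       protein_area = a_prot, carb_area = a_carb)
}

#' Principal component analysis of a spectra population
#'
#' Mean-centered PCA of spectra sharing one grid, computed via singular
#' value decomposition. Loadings follow a deterministic sign convention (the
#' largest-magnitude element of each loading is positive); explained
#' variance fractions refer to the total variance, so retained fractions
#' are non-increasing and sum to at most 1.
#'
#' @param specs List of `>= 3` preprocessed [spectrum()] objects on a common
#'   grid.
#' @param n_components Number of components to retain; default all
#'   (`min(n - 1, p)`).
#' @return Object of class `"pca_model"`: `mean_spectrum`, `loadings`
#'   (wavenumber x component), `scores` (spectrum x component),
#'   `explained_variance_fraction`, `wavenumbers`.
#' @export
fit_pca <- function(specs, n_components = NULL) {
  if (length(specs) < 2)
    stop("insufficient data: PCA needs at least 2 spectra", call. = FALSE)
  stopifnot(all(vapply(specs, inherits, logical(1), "spectrum")))
  grid <- specs[[1]]$wavenumbers
  for (s in specs)
    if (!isTRUE(all.equal(s$wavenumbers, grid)))
      stop("all spectra must share one grid (preprocess first)",
           call. = FALSE)
  x <- t(vapply(specs, `[[`, numeric(length(grid)), "intensities"))
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc)
  rank_max <- min(nrow(x) - 1L, ncol(x))
  if (is.null(n_components)) n_components <- rank_max
  n_components <- min(n_components, rank_max)
  d2 <- sv$d^2
  total <- sum(d2)
  keep <- seq_len(n_components)
  loadings <- sv$v[, keep, drop = FALSE]
  scores <- xc %*% loadings
  # sign convention: largest-|element| of each loading positive
  for (j in keep) {
    s <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (s < 0) { loadings[, j] <- -loadings[, j]; scores[, j] <- -scores[, j] }
  }
  colnames(loadings) <- colnames(scores) <- paste0("PC", keep)
  structure(list(mean_spectrum = mu, loadings = loadings, scores = scores,
                 explained_variance_fraction = d2[keep] / total,
                 wavenumbers = grid),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  ev <- round(100 * x$explained_variance_fraction, 1)
  cat(sprintf("<pca_model> %d spectra x %d wavenumbers, %d components (%s%%)\n",
              nrow(x$scores), length(x$wavenumbers), ncol(x$loadings),
              paste(ev, collapse = ", ")))
  invisible(x)
}

#' Project a spectrum onto a fitted PCA model
#'
#' @param model A `"pca_model"`.
#' @param spec A [spectrum()] on the model grid.
#' @return Numeric score vector (one value per retained component).
#' @export
project_spectrum <- function(model, spec) {
  stopifnot(inherits(model, "pca_model"), inherits(spec, "spectrum"))
  if (!isTRUE(all.equal(spec$wavenumbers, model$wavenumbers)))
    stop("spectrum grid does not match the model grid", call. = FALSE)
  drop((spec$intensities - model$mean_spectrum) %*% model$loadings)
}

#' Confidence ellipse of 2-d PCA scores
#'
#' Gaussian confidence ellipse from the 2-d sample covariance: semi-axes are
#' the square roots of the covariance eigenvalues scaled by the chi-square
#' quantile with 2 degrees of freedom at `level`.
#'
#' @param scores Matrix/data frame with `>= 3` rows and 2 columns.
#' @param level Coverage level, default 0.95.
#' @return List: `center`, `radii` (major, minor), `angle_rad` (orientation
#'   of the major axis), `degenerate` flag (rank-deficient covariance).
#' @export
confidence_ellipse <- function(scores, level = 0.95) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 3 || ncol(scores) != 2)
    stop("need >= 3 points in 2 dimensions", call. = FALSE)
  ctr <- colMeans(scores)
  s <- stats::cov(scores)
  eg <- eigen(s, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  degenerate <- vals[1] <= 0 || vals[2] / vals[1] < 1e-12
  q <- stats::qchisq(level, df = 2)
  list(center = ctr,
       radii = sqrt(vals * q),
       angle_rad = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
       degenerate = degenerate)
}
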