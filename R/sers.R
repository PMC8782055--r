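#' Lorentzian line shape
#'
#' Intensity of a single Lorentzian mode at wavenumber `nu`:
#' \eqn{h \gamma^2 / ((\nu - \nu_0)^2 + \gamma^2)} with \eqn{\gamma} the
#' half-width at half-maximum. Parameterized by peak height (not area)
#' because the downstream statistic is an intensity ratio.
#'
#' @param nu Wavenumber(s) (cm^-1), vectorized.
#' @param center_cm1 Mode position \eqn{\nu_0} (cm^-1).
#' @param hwhm_cm1 Half-width at half-maximum \eqn{\gamma} (cm^-1); `> 0`.
#' @param height Peak intensity at the center; `>= 0`.
#' @return Intensity value(s); equals `height` at the center, `height/2` at
#'   `center +/- hwhm`.
#' @export
lorentzian <- function(nu, center_cm1, hwhm_cm1, height) {
  if (hwhm_cm1 <= 0) stop("hwhm_cm1 must be positive", call. = FALSE)
  if (height < 0) stop("height must be >= 0", call. = FALSE)
  height * hwhm_cm1^2 / ((nu - center_cm1)^2 + hwhm_cm1^2)
}

#' Default SERS mode template for spore spectra
#'
#' Starting peaks for [fit_lorentzians()]: phenylalanine (~1000 cm^-1,
#' protein marker on the spore surface), Ca2+-DPA (~1024 cm^-1, released
#' calcium dipicolinate) and lipid CH2 (~1400 cm^-1).
#'
#' @param hwhm_cm1 Common starting half-width (cm^-1).
#' @return Data frame with columns `center_cm1`, `hwhm_cm1`, `height`.
#' @export
spore_sers_template <- function(hwhm_cm1 = 8) {
  data.frame(center_cm1 = c(1000, 1024, 1400),
             hwhm_cm1 = hwhm_cm1,
             height = 1)
}

#' Fit a sum of Lorentzians plus polynomial baseline
#'
#' Least-squares decomposition of a spectral window into Lorentzian modes on
#' a smooth polynomial background (Levenberg-Marquardt). Mode centers are
#' constrained to within +/- 10 cm^-1 of their initial guesses, widths to be
#' positive and heights non-negative, so modes keep their assignments.
#'
#' @param spec A [spectrum()].
#' @param initial Data frame of starting peaks (`center_cm1`, `hwhm_cm1`,
#'   `height`); heights may be `NA` to be seeded from the data.
#' @param window `c(lo, hi)` fit window (cm^-1); default spans the initial
#'   centers +/- 60 cm^-1.
#' @param baseline_degree Degree of the polynomial baseline inside the
#'   window; default 1 (linear).
#' @param center_tol_cm1 Half-width of the box constraint on centers.
#' @return List of class `"lorentzian_fit"` with `peaks` (data frame sorted
#'   by center), `baseline_coef`, `residual_ss`, `fitted`, `window` and
#'   `low_signal` flag (all heights indistinguishable from zero).
#' @export
fit_lorentzians <- function(spec, initial = spore_sers_template(),
                            window = NULL, baseline_degree = 1,
                            center_tol_cm1 = 10) {
  stopifnot(inherits(spec, "spectrum"))
  initial <- as.data.frame(initial)
  if (anyDuplicated(initial$center_cm1))
    stop("invalid initialization: duplicate initial centers", call. = FALSE)
  if (is.null(window))
    window <- c(min(initial$center_cm1) - 60, max(initial$center_cm1) + 60)
  sub <- crop_spectrum(spec, window[1], window[2])
  require_min_points(sub, max(16L, 3L * nrow(initial)), "fit_lorentzians")
  nu <- sub$wavenumbers; y <- sub$intensities
  npk <- nrow(initial)

  # seed missing heights from the (baseline-offset) data at each center
  h0 <- initial$height
  base0 <- stats::median(y)
  for (j in seq_len(npk)) {
    if (is.na(h0[j]))
      h0[j] <- max(y[which.min(abs(nu - initial$center_cm1[j]))] - base0, 1e-6)
  }
  g0 <- initial$hwhm_cm1

  # orthogonal-ish polynomial basis on a centered/scaled axis for stability
  nu_c <- (nu - mean(nu)) / max(diff(range(nu)) / 2, 1)
  pbasis <- sapply(0:baseline_degree, function(d) nu_c^d)
  pbasis <- matrix(pbasis, nrow = length(nu))

  model <- function(par) {
    cen <- par[seq_len(npk)]
    gam <- par[npk + seq_len(npk)]
    hgt <- par[2 * npk + seq_len(npk)]
    cf <- par[3 * npk + seq_len(baseline_degree + 1)]
    out <- drop(pbasis %*% cf)
    for (j in seq_len(npk))
      out <- out + hgt[j] * gam[j]^2 / ((nu - cen[j])^2 + gam[j]^2)
    out
  }
  resid_fn <- function(par) y - model(par)

  par0 <- c(initial$center_cm1, g0, h0,
            c(base0, rep(0, baseline_degree)))
  lower <- c(initial$center_cm1 - center_tol_cm1,
             rep(1e-3, npk), rep(0, npk),
             rep(-Inf, baseline_degree + 1))
  upper <- c(initial$center_cm1 + center_tol_cm1,
             rep(diff(window), npk), rep(Inf, npk),
             rep(Inf, baseline_degree + 1))

  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 400, ftol = 1e-14, ptol = 1e-14))
  if (fit$info == 0 || fit$info == 5)
    stop("fit failure: Levenberg-Marquardt did not converge (info = ",
         fit$info, ", rss = ", signif(fit$deviance, 6), ")", call. = FALSE)
  par <- fit$par
  peaks <- data.frame(center_cm1 = par[seq_len(npk)],
                      hwhm_cm1 = par[npk + seq_len(npk)],
                      height = par[2 * npk + seq_len(npk)])
  ord <- order(peaks$center_cm1)
  peaks <- peaks[ord, , drop = FALSE]
  rownames(peaks) <- NULL
  noise_scale <- stats::sd(resid_fn(par))
  structure(list(peaks = peaks,
                 baseline_coef = par[3 * npk + seq_len(baseline_degree + 1)],
                 residual_ss = fit$deviance,
                 fitted = model(par),
                 wavenumbers = nu,
                 window = window,
                 low_signal = all(peaks$height <=
                                    3 * noise_scale + 1e-6 * max(abs(y)))),
            class = "lorentzian_fit")
}

#' @export
print.lorentzian_fit <- function(x, ...) {
  cat(sprintf("<lorentzian_fit> %d modes in [%g, %g] cm^-1, rss = %.4g%s\n",
              nrow(x$peaks), x$window[1], x$window[2], x$residual_ss,
              if (x$low_signal) " [low signal]" else ""))
  print(x$peaks)
  invisible(x)
}

#' Ca2+-DPA / phenylalanine intensity ratio
#'
#' The release statistic \eqn{I_{1025}/I_{1000}}: fitted height of the
#' Ca2+-DPA mode (center within `dpa_window`, nominally 1024-1025 cm^-1)
#' over the phenylalanine mode (center within `phe_window`, ~1000 cm^-1).
#' Being a ratio of heights from the same spectrum it is invariant under
#' uniform intensity rescaling and under baseline shifts absorbed by the
#' fitted polynomial. Window half-widths (+/- 6 cm^-1) exceed the 4 cm^-1
#' instrumental resolution.
#'
#' @param peaks Fitted peaks: a `"lorentzian_fit"` or its `peaks` data frame.
#' @param dpa_window,phe_window Acceptance windows (cm^-1) for the two modes.
#' @return Dimensionless ratio `height(DPA) / height(Phe)`.
#' @export
dpa_phe_ratio <- function(peaks, dpa_window = c(1018, 1030),
                          phe_window = c(994, 1006)) {
  if (inherits(peaks, "lorentzian_fit")) peaks <- peaks$peaks
  pick <- function(win, label) {
    hit <- which(peaks$center_cm1 >= win[1] & peaks$center_cm1 <= win[2])
    if (!length(hit))
      stop("missing mode: no fitted peak in the ", label, " band [",
           win[1], ", ", win[2], "] cm^-1", call. = FALSE)
    hit[which.max(peaks$height[hit])]
  }
  i_dpa <- pick(dpa_window, "Ca2+-DPA")
  i_phe <- pick(phe_window, "phenylalanine")
  peaks$height[i_dpa] / peaks$height[i_phe]
}

#' Average spectra measured at different positions
#'
#' Pointwise mean of a list of spectra. Grids must agree exactly unless
#' `resample = TRUE`, in which case each spectrum is linearly interpolated
#' onto the grid of the first.
#'
#' @param specs Non-empty list of [spectrum()] objects.
#' @param resample Interpolate onto the first grid when grids differ.
#' @return A [spectrum()] on the common (first) grid.
#' @export
average_spectra <- function(specs, resample = FALSE) {
  if (!length(specs)) stop("empty spectrum list", call. = FALSE)
  stopifnot(all(vapply(specs, inherits, logical(1), "spectrum")))
  grid <- specs[[1]]$wavenumbers
  mat <- vapply(specs, function(s) {
    if (isTRUE(all.equal(s$wavenumbers, grid))) return(s$intensities)
    if (!resample)
      stop("grids differ; set resample = TRUE to interpolate", call. = FALSE)
    stats::approx(s$wavenumbers, s$intensities, xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  spectrum(grid, rowMeans(matrix(mat, nrow = length(grid))),
           meta = list(n_averaged = length(specs)))
}
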