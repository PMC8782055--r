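#' Simulation design
#'
#' Study-design parameters shared by the dose-response generators: the
#' delivered-dose panel (0 control plus 250-2000 Gy), the generating dose
#' scale lambda, the initial titre (1e8 CFU/mL), triplicate measurements and
#' an RNG seed. Defaults mirror the irradiation campaign the analysis
#' models.
#'
#' @param ion Beam label (must exist in `beams` when equivalent-dose
#'   conversion is requested by a generator).
#' @param doses Delivered doses (Gy).
#' @param lambda_gy Generating dose scale (Gy); default 258.
#' @param n0_cfu Initial titre (CFU/mL); default 1e8.
#' @param replicates Measurements per dose; default 3.
#' @param amplitude,baseline Release-curve scale and offset for the release
#'   generator.
#' @param noise_sd Gaussian noise SD for the release generator (response
#'   units).
#' @param seed Integer RNG seed; default 20220116.
#' @return List of class `"simulation_design"`.
#' @export
simulation_design <- function(ion = "Fe",
                              doses = c(0, 250, 500, 1000, 1500, 2000),
                              lambda_gy = 258, n0_cfu = 1e8, replicates = 3,
                              amplitude = 1, baseline = 0.2,
                              noise_sd = 0.05, seed = 20220116) {
  if (any(doses < 0)) stop("doses must be non-negative", call. = FALSE)
  if (n0_cfu <= 0) stop("n0_cfu must be positive", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (lambda_gy <= 0) stop("lambda_gy must be positive", call. = FALSE)
  structure(list(ion = ion, doses = doses, lambda_gy = lambda_gy,
                 n0_cfu = n0_cfu, replicates = as.integer(replicates),
                 amplitude = amplitude, baseline = baseline,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "simulation_design")
}

design_phi <- function(design, beams, reference) {
  if (is.null(beams) || design$ion == reference) return(design$doses)
  equivalent_dose(design$doses, beams[[design$ion]], beams[[reference]])
}

#' Simulate a CFU survival dose-response dataset
#'
#' For each dose and replicate, draws a plated count
#' \eqn{N \sim \mathrm{Poisson}(N_0 P_0(\Phi; \lambda))} around the
#' zero-event survival curve, with \eqn{\Phi} the reference-equivalent dose,
#' and returns counts plus N/N0 responses. Bit-reproducible for a fixed
#' seed; the generating parameters are stored in the dataset metadata.
#'
#' @param design A [simulation_design()].
#' @param beams Beam registry (named list of [ion_beam()]); default the
#'   bundled He/Ar/Fe registry. Used only when `design$ion != reference`.
#' @param reference Reference ion label for the equivalent-dose axis.
#' @return A [dose_response()] of kind `"survival"` with counts.
#' @export
simulate_survival <- function(design = simulation_design(),
                              beams = default_beams(), reference = "Fe") {
  stopifnot(inherits(design, "simulation_design"))
  phi <- design_phi(design, beams, reference)
  doses_rep <- rep(design$doses, each = design$replicates)
  phi_rep <- rep(phi, each = design$replicates)
  mu <- design$n0_cfu * survival_curve(phi_rep, design$lambda_gy)
  n <- withr::with_seed(design$seed, stats::rpois(length(mu), mu))
  dose_response(design$ion, doses_rep, n / design$n0_cfu, "survival",
                n = n, n0 = design$n0_cfu,
                meta = list(truth = list(lambda_gy = design$lambda_gy,
                                         n0_cfu = design$n0_cfu,
                                         reference = reference,
                                         phi = phi_rep),
                            seed = design$seed))
}

#' Simulate a Ca2+-DPA release dose series
#'
#' Responses are \eqn{b + A P_1(\Phi; \lambda)} plus additive Gaussian noise
#' of SD `design$noise_sd`; replicates share doses. Metadata records the
#' generating parameters.
#'
#' @inheritParams simulate_survival
#' @return A [dose_response()] of kind `"release_ratio"`.
#' @export
simulate_release_series <- function(design = simulation_design(),
                                    beams = default_beams(),
                                    reference = "Fe") {
  stopifnot(inherits(design, "simulation_design"))
  phi <- design_phi(design, beams, reference)
  doses_rep <- rep(design$doses, each = design$replicates)
  phi_rep <- rep(phi, each = design$replicates)
  mean_resp <- release_curve(phi_rep, design$lambda_gy, design$amplitude,
                             design$baseline)
  y <- withr::with_seed(design$seed,
                        mean_resp + stats::rnorm(length(mean_resp),
                                                 sd = design$noise_sd))
  dose_response(design$ion, doses_rep, y, "release_ratio",
                meta = list(truth = list(lambda_gy = design$lambda_gy,
                                         amplitude = design$amplitude,
                                         baseline = design$baseline,
                                         noise_sd = design$noise_sd,
                                         reference = reference,
                                         phi = phi_rep),
                            seed = design$seed))
}

#' Synthesize a SERS spore spectrum with a prescribed DPA/Phe ratio
#'
#' Sum of Lorentzian modes at the spore band positions — phenylalanine at
#' 1000 cm^-1 (height 1), Ca2+-DPA at 1024 cm^-1 (height = `ratio`) and a
#' lipid CH2 mode at 1400 cm^-1 — on a smooth cubic background with additive
#' Gaussian noise, sampled on an 870-1500 cm^-1 grid at 2 cm^-1 spacing.
#' The complete ground truth is stored in the metadata.
#'
#' @param ratio Target I(1024)/I(1000) height ratio; `>= 0`.
#' @param noise_sd Gaussian noise SD in units of the Phe height (0.005 =
#'   0.5\% of the strongest mode).
#' @param seed Integer RNG seed.
#' @param hwhm_cm1 Common mode half-width (cm^-1).
#' @return A [spectrum()] with `meta$truth`.
#' @export
synth_sers_spectrum <- function(ratio, noise_sd = 0.005, seed = 20220116,
                                hwhm_cm1 = 8) {
  if (ratio < 0) stop("ratio must be >= 0", call. = FALSE)
  nu <- seq(870, 1500, by = 2)
  peaks <- data.frame(center_cm1 = c(1000, 1024, 1400),
                      hwhm_cm1 = c(hwhm_cm1, hwhm_cm1, 10),
                      height = c(1, ratio, 0.6))
  y <- numeric(length(nu))
  for (j in seq_len(nrow(peaks)))
    y <- y + lorentzian(nu, peaks$center_cm1[j], peaks$hwhm_cm1[j],
                        peaks$height[j])
  u <- (nu - mean(nu)) / (diff(range(nu)) / 2)
  bg_coef <- c(0.08, 0.03, 0.02, -0.015)
  y <- y + bg_coef[1] + bg_coef[2] * u + bg_coef[3] * u^2 + bg_coef[4] * u^3
  if (noise_sd > 0)
    y <- y + withr::with_seed(seed, stats::rnorm(length(nu), sd = noise_sd))
  spectrum(nu, y, meta = list(truth = list(ratio = ratio, peaks = peaks,
                                           background_coef = bg_coef,
                                           noise_sd = noise_sd, seed = seed)))
}

#' Synthesize an IR spore spectrum with prescribed band areas
#'
#' Gaussian-mode composite on a 950-1800 cm^-1 grid (2 cm^-1 spacing) whose
#' linear-baseline band integrals over the protein (1480-1735), Ca2+-DPA
#' (1330-1480) and carbohydrate (950-1180 cm^-1) bands equal `band_targets`
#' exactly before noise: modes sit at the spore positions (amide I 1654,
#' amide II 1540; DPA doublet 1445/1395; carbohydrate peaks 1100, 1070,
#' 1020, 990 cm^-1) and the three group scales are obtained by solving the
#' 3x3 linear system of band-integral cross-talk, so Gaussian tail leakage
#' between adjacent bands is compensated rather than assumed negligible.
#' A linear baseline and Gaussian noise are added afterwards.
#'
#' @param band_targets Named numeric: target areas for `protein`, `dpa`,
#'   `carb` (intensity x cm^-1); `>= 0`.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param seed Integer RNG seed.
#' @return A [spectrum()] with `meta$truth` holding targets and group
#'   scales.
#' @export
synth_ir_spectrum <- function(band_targets = c(protein = 2, dpa = 1,
                                               carb = 4),
                              noise_sd = 0, seed = 20220116) {
  if (any(band_targets < 0)) stop("areas must be >= 0", call. = FALSE)
  need <- c("protein", "dpa", "carb")
  if (!all(need %in% names(band_targets)))
    stop("band_targets must name protein, dpa and carb", call. = FALSE)
  nu <- seq(950, 1800, by = 2)
  gauss <- function(c0, sd) exp(-(nu - c0)^2 / (2 * sd^2))
  groups <- list(
    protein = gauss(1654, 18) + 0.8 * gauss(1540, 18),
    dpa = gauss(1445, 12) + 0.9 * gauss(1395, 12),
    carb = gauss(1100, 14) + 0.9 * gauss(1070, 14) +
      0.8 * gauss(1020, 14) + 0.7 * gauss(990, 14))
  bands <- default_ir_bands()
  bands3 <- bands[match(need, bands$name), , drop = FALSE]
  xtalk <- sapply(groups, function(g) {
    sp <- spectrum(nu, g)
    vapply(seq_len(3), function(i)
      as.numeric(band_integral(sp, bands3[i, , drop = FALSE])), numeric(1))
  })
  scales <- solve(xtalk, as.numeric(band_targets[need]))
  names(scales) <- need
  y <- groups$protein * scales["protein"] + groups$dpa * scales["dpa"] +
    groups$carb * scales["carb"]
  y <- y + 0.2 + 1e-4 * (nu - 950)          # affine baseline, chord-invisible
  if (noise_sd > 0)
    y <- y + withr::with_seed(seed, stats::rnorm(length(nu), sd = noise_sd))
  spectrum(nu, y,
           meta = list(truth = list(band_targets = band_targets[need],
                                    group_scales = scales,
                                    noise_sd = noise_sd, seed = seed)))
}
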