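#!/usr/bin/env Rscript
# IR microspectroscopy pipeline: preprocesses every simulated spectrum
# (rubberband baseline, 15-point Savitzky-Golay, vector normalization, cut
# to 1800-950 cm^-1), computes linear-baseline band integrals and the
# DPA/protein and carbohydrate/protein ratios per dose, and runs a PCA of
# the spectra population with 95% score ellipses per dose group. Run
# analysis/02_simulate.R first.

suppressPackageStartupMessages(library(sporehit))
in_dir <- "results/simulated"
out_dir <- "results/ir"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

files <- list.files(in_dir, pattern = "^ir_\\d+_r\\d+\\.csv$",
                    full.names = TRUE)
dose_of <- as.numeric(sub("^ir_(\\d+)_r.*$", "\\1", basename(files)))
specs <- lapply(files, function(f) preprocess_ir(read_spectrum(f)))

rat <- t(vapply(specs, function(s) {
  b <- band_ratios(s)
  c(b$dpa_over_protein, b$carb_over_protein, b$dpa_area, b$amideI_area)
}, numeric(4)))
tab <- data.frame(dose_gy = dose_of, dpa_over_protein = rat[, 1],
                  carb_over_protein = rat[, 2], dpa_area = rat[, 3],
                  amideI_area = rat[, 4])
write.csv(tab, file.path(out_dir, "band_ratios.csv"), row.names = FALSE)

agg <- aggregate(cbind(dpa_over_protein, carb_over_protein) ~ dose_gy,
                 tab, function(x) c(mean = mean(x), sd = sd(x)))
cat("Band ratios by dose (mean over replicates):\n")
print(data.frame(dose_gy = agg$dose_gy,
                 dpa_over_protein = agg$dpa_over_protein[, "mean"],
                 carb_over_protein = agg$carb_over_protein[, "mean"]),
      row.names = FALSE, digits = 4)

# PCA of the preprocessed population
p <- fit_pca(specs, n_components = 4)
ev <- round(100 * p$explained_variance_fraction, 1)
cat(sprintf("\nPCA: PC1-PC4 explain %s%% of variance\n",
            paste(ev, collapse = "%, ")))
scores <- data.frame(dose_gy = dose_of, p$scores)
write.csv(scores, file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
write.csv(data.frame(wavenumber_cm1 = p$wavenumbers, p$loadings),
          file.path(out_dir, "pca_loadings.csv"), row.names = FALSE)

ell <- do.call(rbind, lapply(sort(unique(dose_of)), function(d) {
  e <- confidence_ellipse(p$scores[dose_of == d, 1:2, drop = FALSE])
  data.frame(dose_gy = d, center_pc1 = e$center[1], center_pc2 = e$center[2],
             major = e$radii[1], minor = e$radii[2],
             angle_rad = e$angle_rad, degenerate = e$degenerate)
}))
write.csv(ell, file.path(out_dir, "score_ellipses_95.csv"), row.names = FALSE)
cat("\n95% score ellipses (PC1/PC2) written per dose group\n")
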