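#!/usr/bin/env Rscript
# Ion physics of the exposure campaign: Fe-normalized Rutherford cross
# sections for the He/Ar/Fe beams, irradiation durations implied by the
# facility dose rates, and residence times in open space equivalent to the
# tolerated doses.

suppressPackageStartupMessages(library(sporehit))
out_dir <- "results/ion_physics"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

beams <- default_beams()
fe <- beams$Fe

xsec <- do.call(rbind, lapply(beams, function(b) data.frame(
  ion = b$name, mass_amu = b$mass_amu, atomic_number = b$atomic_number,
  energy_mev_per_nucleon = b$energy_mev_per_nucleon,
  normalized_sigma = normalized_sigma(b, fe))))
xsec$normalized_sigma_2dp <- round(xsec$normalized_sigma, 2)
write.csv(xsec, file.path(out_dir, "normalized_cross_sections.csv"),
          row.names = FALSE)
cat("Normalized cross sections (reference Fe):\n")
print(xsec[, c("ion", "normalized_sigma", "normalized_sigma_2dp")],
      row.names = FALSE)

dose_panel <- list(He = c(250, 1000),
                   Ar = c(250, 500, 1000, 1500),
                   Fe = c(250, 500, 1000, 1500, 2000))
dur <- do.call(rbind, lapply(names(dose_panel), function(ion) {
  d <- dose_panel[[ion]]
  data.frame(ion = ion, dose_gy = d,
             duration_min = round(exposure_duration(d, beams[[ion]]), 1),
             phi_fe_gy = round(equivalent_dose(d, beams[[ion]], fe), 1))
}))
write.csv(dur, file.path(out_dir, "exposure_durations.csv"),
          row.names = FALSE)
cat("\nDurations and Fe-equivalent doses:\n")
print(dur, row.names = FALSE)

# residence times at the 0.2-0.5 Gy/yr ambient flux for the tolerated doses
life <- do.call(rbind, lapply(c(500, 1500, 2000), function(d) {
  yrs <- space_exposure_years(d, 0.2, 0.5)
  data.frame(tolerated_dose_gy = d, min_years = yrs[["min_years"]],
             max_years = yrs[["max_years"]])
}))
write.csv(life, file.path(out_dir, "space_exposure_lifetimes.csv"),
          row.names = FALSE)
cat("\nEquivalent residence times in open space (0.2-0.5 Gy/yr):\n")
print(life, row.names = FALSE)
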