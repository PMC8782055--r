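#!/usr/bin/env Rscript
# Generates the synthetic study data every later stage consumes: CFU
# survival counts with Poisson plating noise around the zero-event curve
# (lambda = 258 Gy, N0 = 1e8 CFU/mL, triplicate) for Fe and Ar, a noisy
# single-event release series, and SERS/IR spectra whose ground truth
# follows the release curve. All generators are seeded; a manifest records
# the configuration.

suppressPackageStartupMessages(library(sporehit))
out_dir <- "results/simulated"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20220116

for (ion in c("Fe", "Ar")) {
  des <- simulation_design(ion = ion, seed = seed)
  surv <- simulate_survival(des)
  write_dose_response(surv, file.path(out_dir,
                                      paste0("survival_", ion, ".csv")))
  cat(sprintf("%s survival: %d points, min N/N0 = %.3g\n",
              ion, length(surv$doses), min(surv$responses)))
}

rel <- simulate_release_series(simulation_design(seed = seed,
                                                 noise_sd = 0.05))
write_dose_response(rel, file.path(out_dir, "release_Fe.csv"))
cat(sprintf("Release series: peak response %.3f at %g Gy\n",
            max(rel$responses), rel$doses[which.max(rel$responses)]))

# SERS spectra: one per dose, generator ratio follows the release curve
doses <- c(0, 250, 500, 1000, 1500, 2000)
truth_ratio <- release_curve(doses, 258, 1, 0.2)
for (i in seq_along(doses)) {
  s <- synth_sers_spectrum(truth_ratio[i], noise_sd = 0.005,
                           seed = seed + i)
  write_spectrum(s, file.path(out_dir, sprintf("sers_%04d.csv", doses[i])))
}
write.csv(data.frame(dose_gy = doses, true_ratio = truth_ratio),
          file.path(out_dir, "sers_truth.csv"), row.names = FALSE)

# IR spectra: 12 replicates per dose, DPA band area tracks the release
# curve while protein and carbohydrate content stay fixed
for (i in seq_along(doses)) for (r in 1:12) {
  s <- synth_ir_spectrum(c(protein = 2, dpa = 2 * truth_ratio[i], carb = 3),
                         noise_sd = 0.002, seed = seed + 100 * i + r)
  write_spectrum(s, file.path(out_dir,
                              sprintf("ir_%04d_r%02d.csv", doses[i], r)))
}
cat(sprintf("Wrote %d SERS and %d IR spectra\n",
            length(doses), 12 * length(doses)))

man <- run_manifest(config = list(lambda_gy = 258, n0_cfu = 1e8,
                                  replicates = 3, doses = doses,
                                  sers_noise = 0.005, ir_noise = 0.002,
                                  ir_replicates = 12),
                    seeds = c(base = seed))
jsonlite::write_json(unclass(man), file.path(out_dir, "manifest.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
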