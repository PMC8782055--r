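# sporehit

Target-hit dose–response modelling and spectral fingerprinting for heavy-ion
(HZE) irradiation experiments on extremophile spores.

Bacterial spores exposed to galactic-cosmic-ray-like ion beams (He, Ar, Fe at
150–500 MeV/n) show a two-regime response: below a threshold dose they release
their core calcium dipicolinate (Ca²⁺-DPA) as in the first stages of
germination; above it they are inactivated. `sporehit` implements the
quantitative chain that turns raw dose–response tables and vibrational spectra
into that picture, for radiation microbiologists and astrobiologists who need
each step reusable and testable:

- **Ion physics.** Rutherford single-collision cross sections
  σ ∝ M₁Z₁²Z₂²/(M₂E) · ∫dT/T², normalized to a reference ion (Fe), define an
  equivalent dose Φ = D·σ/σ_Fe that places different ions on one damage axis;
  plus exposure-duration and open-space residence-time arithmetic
  (0.2–0.5 Gy/yr ambient flux).
- **Hit model.** A Poisson/Erlang target-hit model
  Pₖ(Φ) = (Φ/λ)ᵏ e^(−Φ/λ)/k!: spore survival is the zero-event probability
  N/N₀ = e^(−Φ/λ); Ca²⁺-DPA release is the single-event response
  b + A·(Φ/λ)e^(−Φ/λ), maximal at the threshold dose Φ = λ. Closed-form
  log-linear fitting for k = 0, bounded multistart nonlinear least squares for
  k = 1, case-resampling bootstrap intervals for λ.
- **SERS analysis.** Lorentzian decomposition of surface-enhanced Raman
  spectra and the I₁₀₂₅/I₁₀₀₀ Ca²⁺-DPA/phenylalanine intensity ratio, the
  proxy for DPA leaked from the spore core.
- **IR pipeline.** Rubberband baseline, 15-point Savitzky–Golay smoothing,
  vector normalization, cut to 1800–950 cm⁻¹; linear-baseline band integrals
  over the protein (1480–1735), amide I (1600–1700), Ca²⁺-DPA (1330–1480) and
  carbohydrate (950–1180 cm⁻¹) bands; PCA with 95% score ellipses.
- **Synthetic data.** Seeded generators (Poisson CFU counts at N₀ = 10⁸
  CFU/mL, Lorentzian/Gaussian spectra with known ground truth) that emulate
  the study conditions so the whole pipeline is testable without raw
  measurements.

## Worked example

```r
library(sporehit)
beams <- default_beams()                    # He / Ar / Fe registry

normalized_sigma(beams$Ar, beams$Fe)
#> [1] 0.3429624                             # prints as 0.34 at 2 d.p.
round(exposure_duration(250, beams$He), 1)  # 250 Gy at 4.2 Gy/min
#> [1] 59.5
space_exposure_years(1500)                  # Gy tolerated -> years in space
#> min_years max_years
#>      3000      7500

# simulate triplicate CFU survival at the study design and refit lambda
d  <- simulate_survival(simulation_design(seed = 20220116))
f  <- fit_survival(d)
ci <- bootstrap_ci(d, fit_survival, n_boot = 1000, seed = 20220116)
c(lambda = f$lambda_gy, lo = ci$lower, hi = ci$upper)
#>   lambda       lo       hi
#> 258.0463 257.9748 258.1372

# single-event release fit: the threshold dose is the fitted lambda
r <- simulate_release_series(simulation_design(noise_sd = 0.05))
threshold_dose(fit_release(r))
#> [1] 224.7782                              # this seed; truth 258
```

The first three numbers are the campaign's derived quantities: the
Fe-normalized Ar cross section (0.34), the 59.5 min irradiation for 250 Gy of
He, and the 3000–7500 year open-space residence equivalent to 1500 Gy. The
fitted λ is the mean dose per hit event: e^(−Φ/λ) drops to 1/e at Φ = λ, and
the release curve peaks there, which is why λ is read as the release-threshold
dose.

The full analysis sequence lives in `analysis/01_ion_physics.R` …
`analysis/05_ir_pca.R`: each script narrates one stage (cross-section tables,
synthetic data, hit-model fits, SERS ratios, IR band ratios + PCA) and writes
its tables under `results/`.

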