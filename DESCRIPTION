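Package: sporehit
Title: Target-Hit Dose-Response Modelling and Spectral Fingerprinting of
    HZE-Irradiated Bacterial Spores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis pipeline for heavy-ion (HZE) irradiation
    experiments on extremophile spores. Converts delivered doses between ion
    species through Rutherford single-collision cross sections normalized to a
    reference ion (Fe), fits Erlang/Poisson target-hit dose-response models in
    which spore survival is the zero-event probability and calcium dipicolinate
    (Ca2+-DPA) release is the single-event probability, decomposes
    surface-enhanced Raman (SERS) spectra into Lorentzian modes to form the
    Ca2+-DPA/phenylalanine intensity ratio, and processes infrared
    microspectroscopy data (rubberband baseline, Savitzky-Golay smoothing,
    vector normalization, linear-baseline band integrals, principal component
    analysis). Seeded synthetic-data generators reproduce the statistical
    structure each stage assumes, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm,
    signal,
    pracma,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
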