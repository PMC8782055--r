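# Beam fixtures built in code: the He/Ar/Fe exposure parameters
# (mass, charge, MeV/n, LET, dose rate) used throughout the analyses.
he_beam <- function() ion_beam("He", 4, 2, 150, 2.2, 4.2)
ar_beam <- function() ion_beam("Ar", 40, 18, 500, 90, 6.8)
fe_beam <- function() ion_beam("Fe", 55.9, 26, 500, 200, 12.1)

random_beam <- function() {
  ion_beam("X",
           mass_amu = stats::runif(1, 1, 240),
           atomic_number = sample(1:92, 1),
           energy_mev_per_nucleon = stats::runif(1, 10, 1000))
}
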