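Package: cloudpolymer
Title: Thermochemical Feasibility of Carbon-Free Heteropolymers in Acidic
    Cloud Droplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline for condensed-phase quantum-chemistry
    thermochemistry aimed at feasibility analysis of polymer chemistry in
    concentrated sulfuric acid cloud droplets. Provides a validated species
    thermochemistry library format; standard-state and activity-corrected
    reaction Gibbs energies at low water activity; cyclic-oligomer insertion
    energetics, ring-strain and proxy selection; bond-dissociation and
    ionization-potential/electron-affinity summaries; Eyring-equation
    persistence timescales; droplet-scale feedstock concentration arithmetic;
    Lorentzian/Gaussian broadening of IR line lists and oscillator-strength
    weighted UV-Vis convolution with diagnostic-window and absorber-overlap
    analyses; and a seeded synthetic-data generator with embedded ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
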