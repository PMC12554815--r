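# shared helpers: tiny libraries and conditions built in code

unit_water_conditions <- function() {
  venus_conditions(activities = c(h2o = 1))
}

# a minimal two-species library for IO tests
tiny_library <- function() {
  species_library(list(
    species_record("h2o", -47895.23, formula = c(H = 2, O = 1),
                   phase_class = "fixed-activity",
                   frequencies = data.frame(wavenumber = c(1595, 3657, 3756),
                                            intensity = c(60, 5, 45),
                                            intensity_unit = "a.u.")),
    species_record("so3", -391205.7, formula = c(S = 1, O = 3),
                   charge = 0L, phase_class = "solute",
                   excitations = data.frame(energy_ev = c(5.1, 6.4),
                                            oscillator_strength = c(0.02, 0),
                                            multiplicity = c("singlet",
                                                             "triplet")))))
}

# random reaction network over a random all-solute library; used as the
# brute-force Hess oracle substrate
random_network <- function(n_species = 8, n_reactions = 5) {
  ids <- paste0("sp", seq_len(n_species))
  recs <- lapply(ids, function(id) {
    species_record(id, stats::rnorm(1, 0, 50), phase_class = "solute")
  })
  lib <- species_library(recs)
  rxns <- lapply(seq_len(n_reactions), function(i) {
    k <- sample(3:5, 1)
    who <- sample(ids, k)
    nu <- stats::setNames(sample(c(-2, -1, 1, 2), k, replace = TRUE), who)
    while (!any(nu < 0) || !any(nu > 0)) {
      nu <- stats::setNames(sample(c(-2, -1, 1, 2), k, replace = TRUE), who)
    }
    reaction(paste0("rxn", i), nu)
  })
  list(lib = lib, reactions = rxns)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "cloudpolymer", mustWork = TRUE)
}
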