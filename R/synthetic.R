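# run expr with a private RNG stream; the caller's global RNG state is
# untouched (the generator owns one documented pseudo-random source)
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specification for the synthetic-data generator
#'
#' Defines a family of synthetic species libraries with known ground truth:
#' a cyclic-oligomer free-energy series G(cyc_n) = n (u_inf + s/n^p) + noise
#' whose noiseless sequential-insertion free energy approaches a target
#' asymptote `g_inf`; monomer/water records back-solved to meet that target
#' under the stated conditions; vibrational line lists around stated band
#' centres; and an excitation list with a controllable absorbance maximum.
#'
#' @param seed Integer seed; the same spec yields bit-identical output.
#' @param u_inf Per-unit free energy of the strain-free chain, kcal/mol.
#' @param strain Strain amplitude s, kcal/mol (per-unit strain s/n^p).
#' @param strain_exponent p of the per-unit strain decay (default 2).
#' @param max_n Largest ring size generated (>= 3).
#' @param g_inf Target asymptotic insertion free energy under `conditions`,
#'   kcal/mol (default -1).
#' @param sigma Gaussian noise s.d. applied to every free energy, kcal/mol.
#' @param band_jitter Gaussian jitter s.d. on band positions, cm^-1.
#' @param unique_positions Wavenumbers of the planted diagnostic bands
#'   (default 845 and 861 cm^-1); may be empty.
#' @param peak_energy_ev Centre of the synthetic excitation manifold's
#'   absorbance maximum, eV (default 7.29, i.e. ~170 nm).
#' @param n_states Number of singlet states generated (default 50; an equal
#'   number of dark triplets is added).
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L, u_inf = -120, strain = 6,
                           strain_exponent = 2, max_n = 6L, g_inf = -1,
                           sigma = 0, band_jitter = 0,
                           unique_positions = c(845, 861),
                           peak_energy_ev = 7.29, n_states = 50L) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (max_n < 3L) stop("max_n must be >= 3", call. = FALSE)
  structure(list(seed = as.integer(seed), u_inf = u_inf, strain = strain,
                 strain_exponent = strain_exponent, max_n = as.integer(max_n),
                 g_inf = g_inf, sigma = sigma, band_jitter = band_jitter,
                 unique_positions = unique_positions,
                 peak_energy_ev = peak_energy_ev,
                 n_states = as.integer(n_states)),
            class = "generator_spec")
}

#' Generate a cyclic-oligomer series with embedded ground truth
#'
#' Cycle free energies follow G(cyc_n) = n (u_inf + s/n^p) + noise for
#' n = 2..max_n. The monomer is the strain-free unit (G = u_inf + noise) and
#' the water record is back-solved so that, noiselessly, the sequential
#' insertion cyc_n + monomer -> cyc_{n+1} + water evaluates to exactly
#' `g_inf + s((n+1)^(1-p) - n^(1-p))` under `conditions` — approaching
#' `g_inf` from below for n >= 2, with the n = 1 ring closure penalized by
#' the nascent ring's strain (`g_inf + s 2^(1-p)`).
#'
#' @param spec A [generator_spec()].
#' @param conditions The [venus_conditions()] under which the insertion
#'   asymptote is targeted (default: Venus preset).
#' @param water_id,monomer_id,cycle_prefix Identifier conventions.
#' @return An [oligomer_series()] with attribute `truth`: the list of
#'   generating parameters plus the noiseless per-step insertion energies.
#' @export
generate_series <- function(spec, conditions = venus_conditions(),
                            water_id = "h2o", monomer_id = "monomer",
                            cycle_prefix = "cyc_") {
  stopifnot(inherits(spec, "generator_spec"))
  p <- spec$strain_exponent
  ns <- 2:spec$max_n
  g_cycle <- ns * (spec$u_inf + spec$strain / ns^p)
  # water chemical potential pinned to g_inf so every noiseless strain-free
  # step is exactly g_inf (including the n = 1 ring closure)
  RT <- constants_table()$R_kcal * conditions$temperature
  a_w <- if (water_id %in% names(conditions$activities))
    conditions$activities[[water_id]] else 1
  g_water <- spec$g_inf - RT * log(a_w)
  g_monomer <- spec$u_inf
  # noise lands on the cycle free energies; the monomer and water records
  # are the back-solved (noiseless) anchors of the series
  noise <- .with_seed(spec$seed, stats::rnorm(length(ns), 0, spec$sigma))
  water <- species_record(water_id, g_water,
                          phase_class = "fixed-activity")
  monomer <- species_record(monomer_id, g_monomer,
                            phase_class = "solute")
  cycles <- lapply(seq_along(ns), function(i) {
    species_record(paste0(cycle_prefix, ns[i]), g_cycle[i] + noise[i],
                   phase_class = "solute")
  })
  names(cycles) <- ns
  series <- oligomer_series(monomer, water, cycles, monomer_is_cycle1 = TRUE)
  steps <- 1:(spec$max_n - 1L)
  strain_of <- function(n) ifelse(n >= 2, spec$strain * n^(1 - p), 0)
  attr(series, "truth") <- list(
    g_inf = spec$g_inf, u_inf = spec$u_inf, strain = spec$strain,
    strain_exponent = p, sigma = spec$sigma, seed = spec$seed,
    insertion_noiseless = data.frame(
      n = steps,
      delta_g = spec$g_inf + strain_of(steps + 1L) - strain_of(steps)))
  series
}

#' Generate target and reference band tables with planted diagnostics
#'
#' The reference tables emulate the strong/medium/weak stretching bands of
#' the droplet-relevant small molecules (sulfuric and phosphoric acid, SO3,
#' SO2). The target table receives (i) decoy strong bands placed within the
#' exclusion tolerance of reference bands, and (ii) the planted unique bands
#' of `spec$unique_positions`, guaranteed clear of every reference band by
#' more than `tolerance`; those planted positions are returned as ground
#' truth.
#'
#' @param spec A [generator_spec()].
#' @param tolerance Exclusion distance the plants must respect, cm^-1
#'   (default 15).
#' @return List with elements `target` (a [band_table()]), `references`
#'   (list of band tables) and `truth` (planted wavenumbers).
#' @export
generate_band_tables <- function(spec, tolerance = 15) {
  stopifnot(inherits(spec, "generator_spec"))
  ref_template <- list(
    h2so4 = data.frame(wavenumber = c(3609, 1452, 1216, 1157, 891, 550),
                       intensity  = c(150, 450, 380, 250, 350, 60)),
    h3po4 = data.frame(wavenumber = c(3673, 1178, 1008, 890, 520),
                       intensity  = c(120, 420, 380, 340, 40)),
    so3   = data.frame(wavenumber = c(1391, 1065, 529),
                       intensity  = c(520, 20, 90)),
    so2   = data.frame(wavenumber = c(1362, 1151),
                       intensity  = c(400, 320)))
  out <- .with_seed(spec$seed, {
    refs <- lapply(names(ref_template), function(mol) {
      tb <- ref_template[[mol]]
      wn <- tb$wavenumber + stats::rnorm(nrow(tb), 0, spec$band_jitter)
      band_table(mol, wn, tb$intensity)
    })
    ref_wn <- unlist(lapply(refs, function(r) r$wavenumber))
    # decoy strong target bands: each within tolerance of a reference band
    decoy_anchor <- c(1452, 1178, 1008, 891)
    decoy <- decoy_anchor + stats::runif(length(decoy_anchor), -0.6, 0.6) *
      tolerance
    plants <- spec$unique_positions +
      stats::rnorm(length(spec$unique_positions), 0, spec$band_jitter)
    if (length(plants) &&
        any(vapply(plants, function(w) any(abs(w - ref_wn) <= tolerance),
                   logical(1)))) {
      stop("cannot place unique bands clear of references at tolerance ",
           tolerance, " cm^-1 (spec overcrowded)", call. = FALSE)
    }
    weakbands <- c(757, 601, 524)
    target <- band_table(
      "polymer",
      c(decoy, plants, weakbands),
      c(rep(450, length(decoy)), rep(500, length(plants)), c(180, 60, 140)))
    list(target = target, references = refs, truth = sort(plants))
  })
  out
}

#' Generate a full synthetic species library with known ground truth
#'
#' Composes [generate_series()] with a feedstock/cleavage/ion block encoding
#' a chosen weakest-bond dissociation enthalpy and ionization
#' potential/electron affinity, plus vibrational line lists (from
#' [generate_band_tables()]) and a singlet/triplet excitation manifold
#' peaking at `spec$peak_energy_ev`. Every record passes library validation;
#' the same spec yields a bit-identical library.
#'
#' @param spec A [generator_spec()].
#' @param conditions Conditions for the series back-solve.
#' @param weakest_bde Planted weakest-channel dissociation enthalpy,
#'   kcal/mol (default 50, heterolytic P-O).
#' @param ip_ev,ea_ev Planted ionization potential and electron affinity of
#'   the proxy cycle, eV (defaults 11.2 and 1.2).
#' @return List: `library` (a [species_library()]), `series`, `cleavage`,
#'   `band_tables`, and `truth` (all planted values).
#' @export
generate_library <- function(spec, conditions = venus_conditions(),
                             weakest_bde = 50, ip_ev = 11.2, ea_ev = 1.2) {
  stopifnot(inherits(spec, "generator_spec"))
  series <- generate_series(spec, conditions)
  bands <- generate_band_tables(spec)
  ev <- constants_table()$eV_kcal
  proxy <- series$cycles[[length(series$cycles)]]
  # excitation manifold: dense singlets whose oscillator strengths peak at
  # peak_energy_ev; equally many dark triplets
  exc <- .with_seed(spec$seed + 1L, {
    Es <- sort(stats::runif(spec$n_states, spec$peak_energy_ev - 1.2,
                            spec$peak_energy_ev + 2.2))
    fs <- 0.35 * exp(-(Es - spec$peak_energy_ev)^2 / (2 * 0.45^2)) +
      stats::runif(spec$n_states, 0, 0.01)
    Et <- sort(stats::runif(spec$n_states, spec$peak_energy_ev - 2.0,
                            spec$peak_energy_ev + 2.0))
    rbind(data.frame(energy_ev = Es, oscillator_strength = fs,
                     multiplicity = "singlet"),
          data.frame(energy_ev = Et, oscillator_strength = 0,
                     multiplicity = "triplet"))
  })
  tgt <- bands$target
  proxy_freq <- data.frame(wavenumber = tgt$wavenumber,
                           intensity = tgt$intensity,
                           intensity_unit = "a.u.")
  proxy <- species_record(proxy$identifier, proxy$free_energy,
                          enthalpy = proxy$free_energy + 25,
                          phase_class = "solute",
                          frequencies = proxy_freq, excitations = exc,
                          provenance = "synthetic generator")
  series$cycles[[length(series$cycles)]] <- proxy
  # charge states of the proxy for IP/EA
  cation <- species_record(paste0(proxy$identifier, "_cation"),
                           proxy$free_energy + ip_ev * ev, charge = 1L,
                           phase_class = "gas-referenced")
  anion <- species_record(paste0(proxy$identifier, "_anion"),
                          proxy$free_energy - ea_ev * ev, charge = -1L,
                          phase_class = "gas-referenced")
  # cleavage block: heterolytic P-O weakest at weakest_bde, the other
  # channels planted above it
  hm <- series$monomer$free_energy
  parent <- species_record(series$monomer$identifier, hm, enthalpy = hm + 20,
                           phase_class = "solute")
  # each two-fragment channel: fragment enthalpies sum to H(parent) + bde
  frag <- function(id, bde, q = 0L) {
    species_record(id, (hm + bde) / 2,
                   enthalpy = (parent$enthalpy + bde) / 2,
                   charge = as.integer(q),
                   phase_class = if (q == 0) "solute" else "gas-referenced")
  }
  channels <- list(
    list(label = "P-O heterolytic", mode = "heterolytic",
         fragments = list(frag("frag_po_anion", weakest_bde, -1L),
                          frag("frag_po_cation", weakest_bde, +1L))),
    list(label = "S-O heterolytic", mode = "heterolytic",
         fragments = list(frag("frag_so_anion", weakest_bde + 8, -1L),
                          frag("frag_so_cation", weakest_bde + 8, +1L))),
    list(label = "P-O homolytic", mode = "homolytic",
         fragments = list(frag("frag_po_rad1", weakest_bde + 15),
                          frag("frag_po_rad2", weakest_bde + 15))),
    list(label = "S-O homolytic", mode = "homolytic",
         fragments = list(frag("frag_so_rad1", weakest_bde + 20),
                          frag("frag_so_rad2", weakest_bde + 20))))
  cleavage <- cleavage_set(parent, channels)
  # reference small molecules with their band-table line lists
  refs <- lapply(bands$references, function(r) {
    species_record(as.character(r$molecule[1]),
                   free_energy = 0,
                   phase_class = "solute",
                   frequencies = data.frame(wavenumber = r$wavenumber,
                                            intensity = r$intensity,
                                            intensity_unit = "a.u."))
  })
  recs <- c(list(series$water, series$monomer), unname(series$cycles),
            list(cation, anion),
            unlist(lapply(channels, function(ch) ch$fragments),
                   recursive = FALSE),
            refs)
  # parent record already present as the monomer; ensure unique identifiers
  ids <- vapply(recs, function(r) r$identifier, character(1))
  recs <- recs[!duplicated(ids)]
  lib <- species_library(recs)
  list(library = lib, series = series, cleavage = cleavage,
       band_tables = bands,
       truth = list(series = attr(series, "truth"),
                    weakest_bde = weakest_bde, ip_ev = ip_ev, ea_ev = ea_ev,
                    diagnostic_bands = bands$truth,
                    peak_energy_ev = spec$peak_energy_ev))
}

#' Recovery harness for the insertion asymptote
#'
#' Generates `n_seeds` noisy series from a common spec (differing only in
#' seed), fits the insertion asymptote with [fit_insertion_asymptote()], and
#' reports how often the truth is recovered within `tol`.
#'
#' @param spec A [generator_spec()] (its `sigma` is the noise level used).
#' @param n_seeds Number of independent seeds (default 100).
#' @param tol Absolute recovery tolerance, kcal/mol (default 0.1).
#' @param conditions Conditions for generation and fitting.
#' @return List: `recovered` (logical vector), `rate`, `estimates`.
#' @export
recovery_harness <- function(spec, n_seeds = 100, tol = 0.1,
                             conditions = venus_conditions()) {
  est <- vapply(seq_len(n_seeds), function(i) {
    sp <- spec
    sp$seed <- spec$seed + i
    fit_insertion_asymptote(generate_series(sp, conditions), conditions)$g_inf
  }, numeric(1))
  ok <- abs(est - spec$g_inf) <= tol
  list(recovered = ok, rate = mean(ok), estimates = est)
}
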