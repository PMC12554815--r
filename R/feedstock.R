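#' Cloud-droplet feedstock model
#'
#' Describes one aerosol droplet and the trace-gas environment around it for
#' order-of-magnitude feedstock arithmetic. Defaults encode a ~1 micrometre
#' sulfuric-acid cloud droplet in an Earth-like pressure/temperature layer of
#' the cloud deck, with SO2 at 150 ppm.
#'
#' @param radius Droplet radius in metres (default 1e-6).
#' @param ambient_T Ambient temperature, K (default 298.15).
#' @param ambient_P Ambient pressure, Pa (default 1 atm).
#' @param mixing_ratios Named numeric vector of trace-gas mole fractions
#'   (dimensionless; 150 ppm = 150e-6), all in (0, 1).
#' @param scavenging_fraction Fraction of the droplet-volume gas inventory
#'   delivered into the droplet, in \[0, 1\] (default 1).
#' @return Object of class `droplet_model`.
#' @export
droplet_model <- function(radius = 1e-6, ambient_T = 298.15,
                          ambient_P = 101325,
                          mixing_ratios = c(so2 = 150e-6),
                          scavenging_fraction = 1) {
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (ambient_T <= 0 || ambient_P <= 0) {
    stop("ambient T and P must be > 0", call. = FALSE)
  }
  if (length(mixing_ratios) &&
      (any(mixing_ratios <= 0) || any(mixing_ratios >= 1))) {
    stop("mixing ratios must lie in (0, 1)", call. = FALSE)
  }
  if (scavenging_fraction < 0 || scavenging_fraction > 1) {
    stop("scavenging fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(list(radius = radius, ambient_T = ambient_T,
                 ambient_P = ambient_P, mixing_ratios = mixing_ratios,
                 scavenging_fraction = scavenging_fraction),
            class = "droplet_model")
}

.droplet_volume_m3 <- function(d) 4 / 3 * pi * d$radius^3

#' Concentration represented by a single molecule in one droplet
#'
#' 1/(N_A V) with V the droplet volume: the quantization floor of droplet
#' chemistry. A 1 micrometre droplet gives ~0.40 nM per molecule.
#'
#' @param d A [droplet_model()].
#' @return Concentration in mol/L.
#' @export
#' @examples
#' single_molecule_concentration(droplet_model()) * 1e9  # ~0.40 nM
single_molecule_concentration <- function(d) {
  stopifnot(inherits(d, "droplet_model"))
  V_L <- .droplet_volume_m3(d) * 1000
  1 / (constants_table()$N_A * V_L)
}

#' Trace-gas molecules in one droplet-volume of ambient gas
#'
#' \eqn{\chi P V/(k_B T)}: how many molecules of a trace gas occupy a volume
#' of atmosphere equal to the droplet. Reported as a real number; sub-unity
#' counts are meaningful at ppb levels (use `round` for an integer
#' rendering).
#'
#' @param d A [droplet_model()].
#' @param species Name of a species present in `d$mixing_ratios`.
#' @return Molecule count (dimensionless, possibly fractional).
#' @export
#' @examples
#' gas_molecule_count(droplet_model(), "so2")  # ~1.5e4
gas_molecule_count <- function(d, species) {
  stopifnot(inherits(d, "droplet_model"))
  if (!species %in% names(d$mixing_ratios)) {
    stop("no mixing ratio declared for species '", species, "' (has: ",
         paste(names(d$mixing_ratios), collapse = ", "), ")", call. = FALSE)
  }
  cn <- constants_table()
  chi <- d$mixing_ratios[[species]]
  chi * d$ambient_P / (cn$kB_J * d$ambient_T) * .droplet_volume_m3(d)
}

#' Droplet concentration delivered by scavenging a droplet-volume of gas
#'
#' fraction x chi x P/(RT) as mol/L: the droplet volume cancels, so this is
#' the concentration reached if a given fraction of the droplet-volume gas
#' inventory dissolves. At 150 ppm and full scavenging this lands in the
#' micromolar range.
#'
#' @param d A [droplet_model()].
#' @param species Name of a species present in `d$mixing_ratios`.
#' @return Concentration in mol/L.
#' @export
scavenged_concentration <- function(d, species) {
  stopifnot(inherits(d, "droplet_model"))
  if (!species %in% names(d$mixing_ratios)) {
    stop("no mixing ratio declared for species '", species, "'", call. = FALSE)
  }
  cn <- constants_table()
  chi <- d$mixing_ratios[[species]]
  # mol/m^3 -> mol/L
  d$scavenging_fraction * chi * d$ambient_P / (cn$R_J * d$ambient_T) / 1000
}

#' Feedstock summary table for every declared trace gas
#'
#' @param d A [droplet_model()].
#' @return Data frame with one row per species: `species`, `mixing_ratio`,
#'   `molecules_per_droplet_volume`, `delivered_concentration_M`, plus the
#'   model's radius/T/P/fraction as attributes `conditions`.
#' @export
feedstock_table <- function(d) {
  stopifnot(inherits(d, "droplet_model"))
  sp <- names(d$mixing_ratios)
  out <- data.frame(
    species = sp,
    mixing_ratio = unname(d$mixing_ratios),
    molecules_per_droplet_volume =
      vapply(sp, function(s) gas_molecule_count(d, s), numeric(1)),
    delivered_concentration_M =
      vapply(sp, function(s) scavenged_concentration(d, s), numeric(1)),
    stringsAsFactors = FALSE
  )
  attr(out, "conditions") <- list(radius_m = d$radius, T_K = d$ambient_T,
                                  P_Pa = d$ambient_P,
                                  scavenging_fraction = d$scavenging_fraction,
                                  single_molecule_M =
                                    single_molecule_concentration(d))
  out
}
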