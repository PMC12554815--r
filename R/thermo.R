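#' Cloud-deck reaction conditions
#'
#' Bundles the temperature and the activity/concentration conventions that
#' convert tabulated standard-state free energies into condition-specific
#' chemical potentials. The default preset encodes the Venus lower-cloud
#' reference point: 298.15 K, sulfuric acid at 16.3 M on the 1 M solute
#' standard, and a water activity of 0.000533. The gas-phase standard
#' concentration P\eqn{^\circ}/(RT) evaluates to 0.0409 M at 298.15 K and
#' 1 atm and is recomputed from the constants table for any temperature.
#'
#' Sulfuric acid is treated as a solute at 16.3 M on the 1 M standard (an
#' effective activity of 16.3): no activity coefficient is available for the
#' droplet medium, and this is flagged as an approximation in the object.
#'
#' @param temperature Temperature in K (default 298.15).
#' @param activities Named numeric vector of fixed (dimensionless) activities,
#'   e.g. `c(h2o = 0.000533)`.
#' @param concentrations Named numeric vector, mol/L, for solutes held off the
#'   1 M standard state, e.g. `c(h2so4 = 16.3)`.
#' @param solute_standard_c Solute standard concentration, mol/L (default 1).
#' @param gas_reference_pressure Gas reference pressure, atm (default 1).
#' @return Object of class `venus_conditions`. Field `gas_standard_c` holds
#'   P\eqn{^\circ}/(RT) in mol/L.
#' @export
#' @examples
#' cond <- venus_conditions()
#' round(cond$gas_standard_c, 4)  # 0.0409
venus_conditions <- function(temperature = 298.15,
                             activities = c(h2o = 0.000533),
                             concentrations = c(h2so4 = 16.3),
                             solute_standard_c = 1,
                             gas_reference_pressure = 1) {
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (any(activities <= 0)) stop("activities must be > 0", call. = FALSE)
  if (any(concentrations <= 0)) stop("concentrations must be > 0", call. = FALSE)
  cn <- constants_table()
  # P/(R T) in mol/m^3, /1000 -> mol/L
  gas_standard_c <- gas_reference_pressure * cn$atm_Pa /
    (cn$R_J * temperature) / 1000
  structure(
    list(temperature = temperature,
         activities = activities,
         concentrations = concentrations,
         solute_standard_c = solute_standard_c,
         gas_reference_pressure = gas_reference_pressure,
         gas_standard_c = gas_standard_c,
         approximations = c(
           "solute concentrations used as activities (no activity coefficients)")),
    class = "venus_conditions")
}

#' @export
print.venus_conditions <- function(x, ...) {
  cat("<venus_conditions> T =", x$temperature, "K; c°(gas) =",
      signif(x$gas_standard_c, 3), "M\n")
  if (length(x$activities))
    cat("  activities: ",
        paste(names(x$activities), "=", x$activities, collapse = ", "), "\n")
  if (length(x$concentrations))
    cat("  concentrations (M): ",
        paste(names(x$concentrations), "=", x$concentrations, collapse = ", "),
        "\n")
  invisible(x)
}

#' Define a reaction over species identifiers
#'
#' @param label Text label.
#' @param stoichiometry Named numeric vector of stoichiometric coefficients
#'   (negative for reactants, positive for products; rationals permitted for
#'   per-monomer normalization). At least one reactant and one product are
#'   required.
#' @return Object of class `reaction`.
#' @export
#' @examples
#' reaction("hydration", c(so3 = -1, h2o = -1, h2so4 = 1))
reaction <- function(label, stoichiometry) {
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry)))) {
    stop("stoichiometry must be a named vector", call. = FALSE)
  }
  stoichiometry <- stoichiometry[stoichiometry != 0]
  if (!any(stoichiometry < 0) || !any(stoichiometry > 0)) {
    stop("reaction '", label,
         "' needs at least one reactant (nu < 0) and one product (nu > 0)",
         call. = FALSE)
  }
  structure(list(label = label, stoichiometry = stoichiometry),
            class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  nu <- x$stoichiometry
  side <- function(v) paste(ifelse(abs(v) == 1, "", paste0(abs(v), " ")),
                            names(v), sep = "", collapse = " + ")
  cat("<reaction>", x$label, ":", side(nu[nu < 0]), "->", side(nu[nu > 0]),
      "\n")
  invisible(x)
}

#' Reverse a reaction
#' @param rxn A [reaction()].
#' @return The reversed [reaction()].
#' @export
reverse_reaction <- function(rxn) {
  reaction(paste0(rxn$label, " (reverse)"), -rxn$stoichiometry)
}

# charge and element balance against a library; errors on violation
.check_reaction_balance <- function(rxn, lib) {
  nu <- rxn$stoichiometry
  missing <- setdiff(names(nu), names(lib$records))
  if (length(missing)) {
    stop("reaction '", rxn$label, "': species not in library: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  q <- sum(vapply(names(nu), function(id) nu[[id]] * get_species(lib, id)$charge,
                  numeric(1)))
  if (abs(q) > 1e-9) {
    stop("reaction '", rxn$label, "': net charge ", q, " != 0", call. = FALSE)
  }
  forms <- lapply(names(nu), function(id) get_species(lib, id)$formula)
  if (all(!vapply(forms, is.null, logical(1)))) {
    elements <- unique(unlist(lapply(forms, names)))
    bal <- vapply(elements, function(el) {
      sum(vapply(seq_along(nu), function(i) {
        cnt <- forms[[i]][el]
        nu[[i]] * if (is.na(cnt)) 0 else cnt
      }, numeric(1)))
    }, numeric(1))
    if (any(abs(bal) > 1e-9)) {
      bad <- names(bal)[abs(bal) > 1e-9]
      stop("reaction '", rxn$label, "': element imbalance in ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Standard-state / activity correction for one species
#'
#' Returns the RT ln term that moves a species' tabulated free energy from
#' its computational standard state onto the working conditions:
#' \itemize{
#'   \item gas-referenced (1 atm reference): RT ln(c_target / c\eqn{^\circ}gas),
#'     moving 1 atm onto the solute standard (c_target defaults to the 1 M
#'     solute standard);
#'   \item solute at concentration c: RT ln(c / c\eqn{^\circ});
#'   \item fixed-activity (e.g. water in a concentrated acid droplet):
#'     RT ln(a);
#'   \item solute on its standard state, or a solvent with no declared
#'     activity: 0.
#' }
#'
#' @param species A [species_record()].
#' @param cond A [venus_conditions()].
#' @return Correction in kcal/mol.
#' @export
#' @examples
#' w <- species_record("h2o", -47900, phase_class = "fixed-activity")
#' activity_correction(w, venus_conditions())  # RT ln(0.000533) = -4.466
activity_correction <- function(species, cond) {
  stopifnot(inherits(species, "species_record"),
            inherits(cond, "venus_conditions"))
  RT <- constants_table()$R_kcal * cond$temperature
  id <- species$identifier
  switch(species$phase_class,
    "gas-referenced" = {
      target <- if (id %in% names(cond$concentrations))
        cond$concentrations[[id]] else cond$solute_standard_c
      RT * log(target / cond$gas_standard_c)
    },
    "solute" = {
      if (id %in% names(cond$activities)) {
        RT * log(cond$activities[[id]])
      } else if (id %in% names(cond$concentrations)) {
        RT * log(cond$concentrations[[id]] / cond$solute_standard_c)
      } else 0
    },
    "solvent" = ,
    "fixed-activity" = {
      if (id %in% names(cond$activities)) {
        RT * log(cond$activities[[id]])
      } else if (id %in% names(cond$concentrations)) {
        RT * log(cond$concentrations[[id]] / cond$solute_standard_c)
      } else if (species$phase_class == "fixed-activity") {
        stop("species '", id,
             "' is fixed-activity but no activity is declared in conditions",
             call. = FALSE)
      } else 0
    },
    stop("species '", id, "': unknown phase class '", species$phase_class,
         "'", call. = FALSE)
  )
}

#' Condition-corrected chemical potential of one species
#'
#' @param species A [species_record()].
#' @param cond A [venus_conditions()].
#' @return G + activity correction, kcal/mol.
#' @export
chemical_potential <- function(species, cond) {
  species$free_energy + activity_correction(species, cond)
}

#' Activity-corrected reaction Gibbs energy
#'
#' \eqn{\Delta G_r = \sum_i \nu_i (G_i + RT \ln(a_i/c^\circ_i))} over the
#' reaction's stoichiometry. Reversing the reaction negates the result
#' exactly, and the result is additive over reaction sums (Hess's law).
#'
#' @param rxn A [reaction()].
#' @param lib A [species_library()] containing every species of `rxn`.
#' @param cond A [venus_conditions()] (default: Venus cloud-deck preset).
#' @param check_balance Verify charge (and, when formulas are present,
#'   element) balance before evaluating (default `TRUE`).
#' @return \eqn{\Delta G_r} in kcal/mol.
#' @export
reaction_delta_g <- function(rxn, lib, cond = venus_conditions(),
                             check_balance = TRUE) {
  stopifnot(inherits(rxn, "reaction"), inherits(lib, "species_library"))
  if (check_balance) .check_reaction_balance(rxn, lib)
  nu <- rxn$stoichiometry
  missing <- setdiff(names(nu), names(lib$records))
  if (length(missing)) {
    stop("reaction '", rxn$label, "': species not in library: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sum(vapply(names(nu), function(id) {
    nu[[id]] * chemical_potential(get_species(lib, id), cond)
  }, numeric(1)))
}

#' Scan reaction Gibbs energy over water activity
#'
#' For a reaction with net water stoichiometry \eqn{\nu_w}, \eqn{\Delta G_r}
#' is linear in \eqn{\ln a_w} with slope \eqn{\nu_w RT}: water-producing
#' condensations become more favorable as the droplet dries out.
#'
#' @param rxn A [reaction()].
#' @param lib A [species_library()].
#' @param cond Base [venus_conditions()]; its water activity is overridden
#'   point by point.
#' @param activities Numeric vector of water activities (> 0), nonempty.
#' @param water_id Identifier of the water species (default `"h2o"`).
#' @return Data frame with columns `a_w`, `delta_g` (kcal/mol).
#' @export
water_activity_scan <- function(rxn, lib, cond = venus_conditions(),
                                activities, water_id = "h2o") {
  if (missing(activities) || length(activities) == 0L) {
    stop("activities must be a nonempty vector", call. = FALSE)
  }
  if (any(activities <= 0)) stop("activities must be > 0", call. = FALSE)
  dg <- vapply(activities, function(a) {
    ci <- cond
    ci$activities[water_id] <- a
    reaction_delta_g(rxn, lib, ci)
  }, numeric(1))
  data.frame(a_w = activities, delta_g = dg)
}

#' Read a reaction set from a structured-text (JSON) file
#'
#' Format: a JSON array of `{"label": ..., "stoichiometry": {id: nu, ...}}`.
#'
#' @param path File path.
#' @return List of [reaction()] objects.
#' @export
read_reaction_set <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(doc, function(r) reaction(r$label, unlist(r$stoichiometry)))
}

#' Tabulate corrected reaction energies
#'
#' One row per reaction: the raw standard-state free-energy sum, the total
#' activity correction, and the corrected \eqn{\Delta G_r}, mirroring the
#' shape of a supplementary reaction-energy table.
#'
#' @param reactions List of [reaction()] objects.
#' @param lib A [species_library()].
#' @param cond A [venus_conditions()].
#' @return Data frame with columns `label`, `delta_g_raw`, `correction`,
#'   `delta_g` (kcal/mol).
#' @export
reaction_table <- function(reactions, lib, cond = venus_conditions()) {
  if (inherits(reactions, "reaction")) reactions <- list(reactions)
  rows <- lapply(reactions, function(rxn) {
    raw <- sum(vapply(names(rxn$stoichiometry), function(id) {
      rxn$stoichiometry[[id]] * get_species(lib, id)$free_energy
    }, numeric(1)))
    dg <- reaction_delta_g(rxn, lib, cond)
    data.frame(label = rxn$label, delta_g_raw = raw, correction = dg - raw,
               delta_g = dg, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
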