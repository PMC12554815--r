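#' Bundle a monomer, water and cyclic oligomer records into a series
#'
#' The substrate of insertion/strain analysis: a condensation monomer, the
#' water it releases, and cyclic n-mers used as end-group-free proxies for a
#' long chain.
#'
#' @param monomer [species_record()] of the free monomer.
#' @param water [species_record()] of water.
#' @param cycles Named list of cyclic n-mer records; names are the integer
#'   ring sizes (all >= 2).
#' @param monomer_is_cycle1 If `TRUE` (default) the n = 1 "cycle" of the
#'   insertion bookkeeping is interpreted as the free monomer, so the first
#'   insertion step is the ring closure monomer + monomer -> cyc_2 + water.
#' @return Object of class `oligomer_series`.
#' @export
oligomer_series <- function(monomer, water, cycles, monomer_is_cycle1 = TRUE) {
  stopifnot(inherits(monomer, "species_record"),
            inherits(water, "species_record"))
  sizes <- as.integer(names(cycles))
  if (any(is.na(sizes)) || any(sizes < 2)) {
    stop("cycle names must be integer ring sizes >= 2", call. = FALSE)
  }
  for (cyc in cycles) stopifnot(inherits(cyc, "species_record"))
  structure(list(monomer = monomer, water = water,
                 cycles = cycles[order(sizes)],
                 monomer_is_cycle1 = monomer_is_cycle1),
            class = "oligomer_series")
}

#' @export
print.oligomer_series <- function(x, ...) {
  cat("<oligomer_series> monomer:", x$monomer$identifier,
      "| cycles n =", paste(names(x$cycles), collapse = ", "), "\n")
  invisible(x)
}

.series_cycle <- function(series, n) {
  if (n == 1L && series$monomer_is_cycle1) return(series$monomer)
  cyc <- series$cycles[[as.character(n)]]
  if (is.null(cyc)) {
    stop("oligomer size n = ", n, " not in series (has n = ",
         paste(names(series$cycles), collapse = ", "), ")", call. = FALSE)
  }
  cyc
}

#' Gibbs energy of one monomer-insertion step
#'
#' \eqn{\Delta G_r} of the condensation cyc_n + monomer -> cyc_{n+1} + water
#' under the given conditions (water on its declared droplet activity).
#' With `monomer_is_cycle1` the n = 1 step is the ring closure
#' 2 monomer -> cyc_2 + water.
#'
#' @param series An [oligomer_series()].
#' @param n Size of the reactant cycle.
#' @param cond A [venus_conditions()].
#' @return \eqn{\Delta G_r} in kcal/mol.
#' @export
insertion_delta_g <- function(series, n, cond = venus_conditions()) {
  stopifnot(inherits(series, "oligomer_series"))
  reac <- .series_cycle(series, n)
  prod <- .series_cycle(series, n + 1L)
  chemical_potential(prod, cond) + chemical_potential(series$water, cond) -
    chemical_potential(reac, cond) -
    chemical_potential(series$monomer, cond)
}

#' Build the explicit insertion reaction for a series step
#'
#' Provided so the insertion energetics can be cross-checked against the
#' generic reaction bookkeeping of [reaction_delta_g()].
#'
#' @inheritParams insertion_delta_g
#' @return A [reaction()].
#' @export
insertion_reaction <- function(series, n) {
  reac <- .series_cycle(series, n)
  prod <- .series_cycle(series, n + 1L)
  nu <- c(-1, -1, 1, 1)
  names(nu) <- c(reac$identifier, series$monomer$identifier,
                 prod$identifier, series$water$identifier)
  if (reac$identifier == series$monomer$identifier) {
    nu <- c(-2, 1, 1)
    names(nu) <- c(series$monomer$identifier, prod$identifier,
                   series$water$identifier)
  }
  reaction(sprintf("insertion n=%d -> %d", n, n + 1L), nu)
}

#' Free energy per repeat unit of each cyclic oligomer
#'
#' @param series An [oligomer_series()].
#' @return Data frame with columns `n`, `g_per_unit` (G(cyc_n)/n, kcal/mol).
#' @export
per_unit_free_energy <- function(series) {
  stopifnot(inherits(series, "oligomer_series"))
  if (length(series$cycles) < 1L) stop("series has no cycles", call. = FALSE)
  n <- as.integer(names(series$cycles))
  g <- vapply(series$cycles, function(r) r$free_energy, numeric(1))
  data.frame(n = n, g_per_unit = unname(g) / n)
}

#' Select the cyclic proxy for an infinite chain
#'
#' Returns the ring size with the lowest Gibbs free energy per repeat unit;
#' ties break toward the smallest n. The winner is the strain-minimal cycle
#' used to emulate a long polymer without end-group effects.
#'
#' @param series An [oligomer_series()].
#' @return Integer ring size.
#' @export
select_cyclic_proxy <- function(series) {
  pu <- per_unit_free_energy(series)
  pu <- pu[order(pu$g_per_unit, pu$n), ]
  pu$n[1L]
}

#' Ring strain of a cyclic oligomer, per repeat unit
#'
#' Per-unit free energy of cyc_n minus a strain-free reference. The reference
#' is either supplied explicitly or estimated as the large-n asymptote of the
#' per-unit series by least-squares on the model u(n) = u_inf + s/n^p.
#'
#' @param series An [oligomer_series()].
#' @param n Ring size(s) to evaluate (default: all cycles in the series).
#' @param reference `"asymptote"` (default; needs >= 3 cycle sizes) or an
#'   explicit per-unit reference energy in kcal/mol.
#' @param strain_exponent p of the asymptote fit (default 2).
#' @return Data frame with columns `n`, `strain_per_unit` (kcal/mol),
#'   plus attribute `reference` (the per-unit reference used).
#' @export
ring_strain <- function(series, n = NULL, reference = "asymptote",
                        strain_exponent = 2) {
  pu <- per_unit_free_energy(series)
  if (identical(reference, "asymptote")) {
    if (nrow(pu) < 3L) {
      stop("asymptote estimation needs >= 3 cycle sizes; give an explicit ",
           "reference instead", call. = FALSE)
    }
    fit <- stats::lm(g_per_unit ~ I(1 / n^strain_exponent), data = pu)
    ref <- unname(stats::coef(fit)[1L])
  } else {
    stopifnot(is.numeric(reference), length(reference) == 1L)
    ref <- reference
  }
  if (is.null(n)) n <- pu$n
  idx <- match(n, pu$n)
  if (anyNA(idx)) {
    stop("ring size(s) not in series: ", paste(n[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(n = n, strain_per_unit = pu$g_per_unit[idx] - ref)
  attr(out, "reference") <- ref
  out
}

#' Fit the insertion free-energy asymptote
#'
#' Fits \eqn{\Delta G_r(n) = g_\infty + c/(n(n+1))} to the sequential
#' insertion energies of a series by ordinary least squares and returns the
#' asymptotic (large-n) insertion free energy. The n = 1 ring-closure step is
#' excluded when the series interprets cycle 1 as the free monomer, since a
#' strain-free monomer breaks the 1/(n(n+1)) form there.
#'
#' @param series An [oligomer_series()].
#' @param cond A [venus_conditions()].
#' @return List with `g_inf`, `strain_coef` (the fitted c), and the fitted
#'   points as data frame `points` (`n`, `delta_g`).
#' @export
fit_insertion_asymptote <- function(series, cond = venus_conditions()) {
  sizes <- as.integer(names(series$cycles))
  n_lo <- if (series$monomer_is_cycle1) 2L else min(sizes)
  ns <- sizes[sizes >= n_lo & (sizes + 1L) %in% sizes]
  if (length(ns) < 2L) {
    stop("need at least two consecutive insertion steps to fit", call. = FALSE)
  }
  dg <- vapply(ns, function(n) insertion_delta_g(series, n, cond), numeric(1))
  x <- 1 / (ns * (ns + 1))
  fit <- stats::lm(dg ~ x)
  list(g_inf = unname(stats::coef(fit)[1L]),
       strain_coef = unname(stats::coef(fit)[2L]),
       points = data.frame(n = ns, delta_g = dg))
}

# ---- bond cleavage ---------------------------------------------------------

#' Define bond-cleavage channels of a parent species
#'
#' @param parent [species_record()] with an enthalpy.
#' @param channels List of channels, each a list with fields `label`, `mode`
#'   (`"homolytic"` or `"heterolytic"`), and `fragments` (list of >= 2
#'   [species_record()]s). Homolytic fragments must all be neutral;
#'   heterolytic channels must have nonzero fragment charges summing to the
#'   parent charge.
#' @return Object of class `cleavage_set`.
#' @export
cleavage_set <- function(parent, channels) {
  stopifnot(inherits(parent, "species_record"))
  for (ch in channels) {
    if (!ch$mode %in% c("homolytic", "heterolytic")) {
      stop("channel '", ch$label, "': mode must be homolytic or heterolytic",
           call. = FALSE)
    }
    if (length(ch$fragments) < 2L) {
      stop("channel '", ch$label, "' needs >= 2 fragments", call. = FALSE)
    }
    q <- vapply(ch$fragments, function(f) f$charge, integer(1))
    if (ch$mode == "homolytic" && any(q != 0L)) {
      stop("channel '", ch$label, "': homolytic fragments must be neutral",
           call. = FALSE)
    }
    if (ch$mode == "heterolytic") {
      if (all(q == 0L)) {
        stop("channel '", ch$label,
             "': heterolytic fragments must carry charge", call. = FALSE)
      }
      if (sum(q) != parent$charge) {
        stop("channel '", ch$label, "': fragment charges (", sum(q),
             ") do not conserve parent charge (", parent$charge, ")",
             call. = FALSE)
      }
    }
  }
  structure(list(parent = parent, channels = channels), class = "cleavage_set")
}

#' Bond-dissociation energies of every cleavage channel
#'
#' Per channel, sum of fragment energies minus the parent energy. Enthalpies
#' are used by default as the barrier estimate: the entropic gain of the
#' extra rotational/translational degrees of freedom is only realized after
#' the bond is fully broken, so the fragment enthalpy difference is an upper
#' estimate of the true free-energy barrier. A free-energy mode is available
#' behind `use`.
#'
#' @param cs A [cleavage_set()].
#' @param use `"enthalpy"` (default) or `"free_energy"`.
#' @return Data frame with columns `label`, `mode`, `bde` (kcal/mol), sorted
#'   as given; attribute `weakest` holds the row index of the minimum.
#' @export
bond_dissociation <- function(cs, use = c("enthalpy", "free_energy")) {
  use <- match.arg(use)
  field <- if (use == "enthalpy") "enthalpy" else "free_energy"
  getE <- function(rec) {
    v <- rec[[field]]
    if (is.null(v)) {
      stop("species '", rec$identifier, "' has no ", field,
           " (required for dissociation energies)", call. = FALSE)
    }
    v
  }
  ep <- getE(cs$parent)
  rows <- lapply(cs$channels, function(ch) {
    ef <- sum(vapply(ch$fragments, getE, numeric(1)))
    data.frame(label = ch$label, mode = ch$mode, bde = ef - ep,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "weakest") <- which.min(out$bde)
  out
}

#' The weakest cleavage channel of a set
#'
#' @inheritParams bond_dissociation
#' @return One-row data frame (`label`, `mode`, `bde`).
#' @export
weakest_channel <- function(cs, use = c("enthalpy", "free_energy")) {
  tab <- bond_dissociation(cs, use = match.arg(use))
  tab[attr(tab, "weakest"), , drop = FALSE]
}

#' Ionization potential and electron affinity from charge-state energies
#'
#' IP = E(cation) - E(neutral); EA = E(neutral) - E(anion); both reported in
#' eV. Shifting all three energies by a constant leaves both unchanged.
#'
#' @param neutral,cation,anion [species_record()]s with charges 0, +1, -1.
#' @param use Energy field to difference (default `"free_energy"`;
#'   `"electronic_energy"` if vertical values are stored there).
#' @return Named list `ip`, `ea` in eV.
#' @export
ip_ea <- function(neutral, cation, anion,
                  use = c("free_energy", "electronic_energy")) {
  use <- match.arg(use)
  if (neutral$charge != 0L || cation$charge != 1L || anion$charge != -1L) {
    stop("charge pattern must be 0/+1/-1 (got ", neutral$charge, "/",
         cation$charge, "/", anion$charge, ")", call. = FALSE)
  }
  getE <- function(rec) {
    v <- rec[[use]]
    if (is.null(v)) stop("species '", rec$identifier, "' has no ", use,
                         call. = FALSE)
    v
  }
  ev <- constants_table()$eV_kcal
  list(ip = (getE(cation) - getE(neutral)) / ev,
       ea = (getE(neutral) - getE(anion)) / ev)
}
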