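#' Create a species thermochemistry record
#'
#' A `species_record` summarises one chemical species as produced by a
#' frequency analysis: the Gibbs free energy (sum of electronic and thermal
#' free energies), optionally the enthalpy and electronic energy, the harmonic
#' frequency/IR-intensity line list, and the electronic excitation list.
#'
#' @param identifier Short unique name (nonempty string).
#' @param free_energy Gibbs free energy, kcal/mol (canonical unit).
#' @param enthalpy Optional enthalpy, kcal/mol.
#' @param electronic_energy Optional electronic energy, kcal/mol.
#' @param charge Integer net charge in elementary charges (default 0).
#' @param phase_class One of `"gas-referenced"`, `"solute"`, `"solvent"`,
#'   `"fixed-activity"`. Controls which chemical-potential correction the
#'   species receives under non-standard conditions.
#' @param formula Optional named integer vector of element counts,
#'   e.g. `c(H = 2, O = 1)`.
#' @param frequencies Optional data frame with columns `wavenumber` (cm^-1),
#'   `intensity`, `intensity_unit` (opaque tag, e.g. `"a.u."`).
#' @param excitations Optional data frame with columns `energy_ev`,
#'   `oscillator_strength`, `multiplicity` (tag, e.g. `"singlet"`).
#' @param provenance Free-text method string.
#' @param allow_imaginary If `FALSE` (default) negative wavenumbers are a
#'   validation error: an imaginary mode signals a non-minimum structure and
#'   disqualifies the record. Set `TRUE` only to inspect such records.
#' @return Object of class `species_record`.
#' @export
#' @examples
#' species_record("h2o", free_energy = -47900, formula = c(H = 2, O = 1),
#'                phase_class = "fixed-activity")
species_record <- function(identifier, free_energy,
                           enthalpy = NULL, electronic_energy = NULL,
                           charge = 0L,
                           phase_class = c("solute", "gas-referenced",
                                           "solvent", "fixed-activity"),
                           formula = NULL,
                           frequencies = NULL, excitations = NULL,
                           provenance = "",
                           allow_imaginary = FALSE) {
  phase_class <- match.arg(phase_class)
  if (!is.character(identifier) || length(identifier) != 1L ||
      !nzchar(trimws(identifier))) {
    stop("identifier must be a nonempty string", call. = FALSE)
  }
  if (!is.numeric(free_energy) || length(free_energy) != 1L ||
      !is.finite(free_energy)) {
    stop("species '", identifier, "': free_energy must be a finite number",
         call. = FALSE)
  }
  if (abs(charge - round(charge)) > 0) {
    stop("species '", identifier, "': charge must be an integer", call. = FALSE)
  }
  charge <- as.integer(round(charge))
  if (!is.null(formula)) {
    if (is.list(formula)) formula <- unlist(formula)
    if (is.null(names(formula)) || any(!nzchar(names(formula)))) {
      stop("species '", identifier, "': formula must be a named element->count vector",
           call. = FALSE)
    }
    if (any(formula <= 0) || any(formula != round(formula))) {
      stop("species '", identifier,
           "': formula counts must be positive integers", call. = FALSE)
    }
    formula <- stats::setNames(as.integer(round(formula)), names(formula))
  }
  frequencies <- .validate_frequencies(frequencies, identifier, allow_imaginary)
  excitations <- .validate_excitations(excitations, identifier)
  structure(
    list(identifier = identifier,
         formula = formula,
         charge = charge,
         phase_class = phase_class,
         free_energy = free_energy,
         enthalpy = enthalpy,
         electronic_energy = electronic_energy,
         frequencies = frequencies,
         excitations = excitations,
         provenance = provenance),
    class = "species_record"
  )
}

.validate_frequencies <- function(frequencies, identifier, allow_imaginary) {
  if (is.null(frequencies) || NROW(frequencies) == 0L) return(NULL)
  frequencies <- as.data.frame(frequencies, stringsAsFactors = FALSE)
  need <- c("wavenumber", "intensity")
  if (!all(need %in% names(frequencies))) {
    stop("species '", identifier,
         "': frequencies need columns wavenumber, intensity", call. = FALSE)
  }
  if (is.null(frequencies$intensity_unit)) frequencies$intensity_unit <- "a.u."
  if (!allow_imaginary && any(frequencies$wavenumber <= 0)) {
    bad <- frequencies$wavenumber[frequencies$wavenumber <= 0][1L]
    stop("species '", identifier, "': imaginary mode (wavenumber ", bad,
         " cm^-1) - structure is not a minimum", call. = FALSE)
  }
  if (any(frequencies$intensity < 0)) {
    stop("species '", identifier, "': negative IR intensity", call. = FALSE)
  }
  frequencies[c("wavenumber", "intensity", "intensity_unit")]
}

.validate_excitations <- function(excitations, identifier) {
  if (is.null(excitations) || NROW(excitations) == 0L) return(NULL)
  excitations <- as.data.frame(excitations, stringsAsFactors = FALSE)
  need <- c("energy_ev", "oscillator_strength")
  if (!all(need %in% names(excitations))) {
    stop("species '", identifier,
         "': excitations need columns energy_ev, oscillator_strength",
         call. = FALSE)
  }
  if (is.null(excitations$multiplicity)) excitations$multiplicity <- "singlet"
  if (any(excitations$energy_ev <= 0)) {
    stop("species '", identifier, "': excitation energies must be > 0",
         call. = FALSE)
  }
  if (any(excitations$oscillator_strength < 0)) {
    stop("species '", identifier, "': oscillator strengths must be >= 0",
         call. = FALSE)
  }
  excitations[c("energy_ev", "oscillator_strength", "multiplicity")]
}

#' @export
print.species_record <- function(x, ...) {
  cat("<species_record>", x$identifier,
      sprintf("[%s, q=%+d]", x$phase_class, x$charge), "\n")
  cat("  G =", format(x$free_energy), "kcal/mol")
  if (!is.null(x$enthalpy)) cat(";  H =", format(x$enthalpy), "kcal/mol")
  cat("\n")
  if (!is.null(x$frequencies))
    cat("  ", nrow(x$frequencies), "vibrational lines\n")
  if (!is.null(x$excitations))
    cat("  ", nrow(x$excitations), "electronic excitations\n")
  invisible(x)
}

#' Assemble species records into a library
#'
#' @param records List of [species_record()] objects.
#' @param units_declared Energy unit the records were read in
#'   (informational once canonicalized; default `"kcal/mol"`).
#' @return Object of class `species_library`: a named list of records plus
#'   the declared unit.
#' @export
species_library <- function(records, units_declared = "kcal/mol") {
  if (inherits(records, "species_record")) records <- list(records)
  ids <- vapply(records, function(r) r$identifier, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate species identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(list(records = stats::setNames(records, ids),
                 units_declared = units_declared),
            class = "species_library")
}

#' @export
print.species_library <- function(x, ...) {
  cat("<species_library> with", length(x$records), "species:",
      paste(utils::head(names(x$records), 8), collapse = ", "),
      if (length(x$records) > 8) "...", "\n")
  invisible(x)
}

#' Look up a species record, with a helpful error
#'
#' @param lib A [species_library()].
#' @param identifier Species identifier.
#' @return The [species_record()].
#' @export
get_species <- function(lib, identifier) {
  stopifnot(inherits(lib, "species_library"))
  rec <- lib$records[[identifier]]
  if (is.null(rec)) {
    stop("species '", identifier, "' not found in library (has: ",
         paste(utils::head(names(lib$records), 12), collapse = ", "), ")",
         call. = FALSE)
  }
  rec
}

#' Read a species library from a structured-text (JSON) file
#'
#' The file format is `{"units": "<unit>", "species": [ {...}, ... ]}` with
#' per-species fields named exactly as in [species_record()]. Energies are
#' canonicalized to kcal/mol on read using the fixed unit table of
#' [to_kcal()]; the returned library always carries `units_declared =
#' "kcal/mol"` so that a write/read round trip is the identity.
#'
#' @param path Path to the library file.
#' @param allow_imaginary Passed to [species_record()]; by default a negative
#'   wavenumber anywhere in the file is a hard validation error.
#' @return A [species_library()] with canonical (kcal/mol) energies.
#' @export
read_library <- function(path, allow_imaginary = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyVector = TRUE),
    error = function(e) stop("malformed library file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(doc$species)) {
    stop("malformed library file '", path, "': missing 'species' array",
         call. = FALSE)
  }
  units <- if (is.null(doc$units)) "kcal/mol" else doc$units
  recs <- lapply(doc$species, function(sp) {
    if (is.null(sp$identifier)) {
      stop("malformed species entry: missing 'identifier'", call. = FALSE)
    }
    if (is.null(sp$free_energy)) {
      stop("species '", sp$identifier, "': missing 'free_energy'",
           call. = FALSE)
    }
    freq <- if (!is.null(sp$frequencies)) .freq_from_json(sp$frequencies)
    exc  <- if (!is.null(sp$excitations)) .exc_from_json(sp$excitations)
    species_record(
      identifier = sp$identifier,
      free_energy = to_kcal(sp$free_energy, units),
      enthalpy = if (!is.null(sp$enthalpy)) to_kcal(sp$enthalpy, units),
      electronic_energy = if (!is.null(sp$electronic_energy))
        to_kcal(sp$electronic_energy, units),
      charge = if (is.null(sp$charge)) 0L else sp$charge,
      phase_class = if (is.null(sp$phase_class)) "solute" else sp$phase_class,
      formula = sp$formula,
      frequencies = freq,
      excitations = exc,
      provenance = if (is.null(sp$provenance)) "" else sp$provenance,
      allow_imaginary = allow_imaginary
    )
  })
  species_library(recs, units_declared = "kcal/mol")
}

.freq_from_json <- function(x) {
  if (is.data.frame(x)) return(x)
  do.call(rbind, lapply(x, function(row) {
    data.frame(wavenumber = row$wavenumber,
               intensity = row$intensity,
               intensity_unit = if (is.null(row$intensity_unit)) "a.u."
                                else row$intensity_unit,
               stringsAsFactors = FALSE)
  }))
}

.exc_from_json <- function(x) {
  if (is.data.frame(x)) return(x)
  do.call(rbind, lapply(x, function(row) {
    data.frame(energy_ev = row$energy_ev,
               oscillator_strength = row$oscillator_strength,
               multiplicity = if (is.null(row$multiplicity)) "singlet"
                              else row$multiplicity,
               stringsAsFactors = FALSE)
  }))
}

#' Write a species library to a structured-text (JSON) file
#'
#' Energies are written in kcal/mol (the canonical unit), so
#' `read_library(write_library(lib, f))` reproduces `lib` exactly.
#'
#' @param lib A [species_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "species_library"))
  species <- lapply(unname(lib$records), function(r) {
    out <- list(identifier = r$identifier)
    if (!is.null(r$formula)) out$formula <- as.list(r$formula)
    out$charge <- r$charge
    out$phase_class <- r$phase_class
    out$free_energy <- r$free_energy
    if (!is.null(r$enthalpy)) out$enthalpy <- r$enthalpy
    if (!is.null(r$electronic_energy))
      out$electronic_energy <- r$electronic_energy
    if (!is.null(r$frequencies)) out$frequencies <- r$frequencies
    if (!is.null(r$excitations)) out$excitations <- r$excitations
    if (nzchar(r$provenance)) out$provenance <- r$provenance
    out
  })
  jsonlite::write_json(list(units = "kcal/mol", species = species), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Classify an IR intensity as weak, medium or strong
#'
#' Band-table convention: weak below 100, medium from 100 to 300 inclusive
#' (both boundary values fall in the closed interval), strong above 300, in
#' the source's own intensity units, which are carried opaquely.
#'
#' @param intensity Nonnegative numeric vector of IR intensities.
#' @return Ordered factor with levels `weak < medium < strong`.
#' @export
#' @examples
#' classify_intensity(c(50, 300, 301))
classify_intensity <- function(intensity) {
  if (any(intensity < 0)) stop("IR intensity must be >= 0", call. = FALSE)
  lab <- ifelse(intensity < 100, "weak",
                ifelse(intensity <= 300, "medium", "strong"))
  factor(lab, levels = c("weak", "medium", "strong"), ordered = TRUE)
}
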