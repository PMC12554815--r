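#' Physical constants used throughout the package
#'
#' All energies are handled internally in kcal/mol. Every operation in the
#' package draws its physical constants from this single table so that
#' reported numbers are reproducible from one source.
#'
#' @return Named list of constants:
#' \describe{
#'   \item{R_kcal}{Gas constant, kcal/(mol K).}
#'   \item{R_J}{Gas constant, J/(mol K).}
#'   \item{kB_J}{Boltzmann constant, J/K.}
#'   \item{h_J}{Planck constant, J s.}
#'   \item{N_A}{Avogadro constant, 1/mol.}
#'   \item{atm_Pa}{Standard atmosphere, Pa.}
#'   \item{hartree_kcal}{1 hartree in kcal/mol.}
#'   \item{eV_kcal}{1 eV in kcal/mol.}
#'   \item{kJ_kcal}{1 kJ/mol in kcal/mol.}
#'   \item{nm_eV}{Photon wavelength-energy product, nm eV.}
#' }
#' @export
#' @examples
#' constants_table()$R_kcal
constants_table <- function() {
  list(
    R_kcal       = 1.987204e-3,
    R_J          = 8.314462618,
    kB_J         = 1.380649e-23,
    h_J          = 6.62607015e-34,
    N_A          = 6.02214076e23,
    atm_Pa       = 101325,
    hartree_kcal = 627.509474,
    eV_kcal      = 23.060548,
    kJ_kcal      = 1 / 4.184,
    nm_eV        = 1239.84198
  )
}

.const <- constants_table()

# accepted energy units of a species library -> factor to kcal/mol
.energy_unit_table <- c(
  "kcal/mol" = 1,
  "hartree"  = 627.509474,
  "kj/mol"   = 1 / 4.184,
  "ev"       = 23.060548
)

#' Convert an energy to kcal/mol
#'
#' @param x Numeric energy value(s).
#' @param unit One of `"kcal/mol"`, `"hartree"`, `"kJ/mol"`, `"eV"`
#'   (case-insensitive). The conversion table is fixed; converting a value
#'   already in kcal/mol is the identity, so canonicalization is idempotent.
#' @return Numeric, kcal/mol.
#' @export
#' @examples
#' to_kcal(-1, "hartree")
to_kcal <- function(x, unit) {
  key <- tolower(trimws(unit))
  if (!key %in% names(.energy_unit_table)) {
    stop("unknown energy unit '", unit, "'; accepted: ",
         paste(names(.energy_unit_table), collapse = ", "), call. = FALSE)
  }
  x * .energy_unit_table[[key]]
}
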