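.make_spectrum <- function(axis, values, kind, width, axis_unit) {
  stopifnot(all(diff(axis) > 0))
  values[values < 0 & values > -1e-300] <- 0
  structure(list(axis = axis, values = values,
                 lineshape = list(kind = kind, width = width),
                 axis_unit = axis_unit),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum>", length(x$axis), "points on [",
      signif(min(x$axis), 6), ",", signif(max(x$axis), 6), "]", x$axis_unit,
      "|", x$lineshape$kind, "width", x$lineshape$width, "\n")
  invisible(x)
}

# unit-area lineshapes on x centred at x0
.lorentzian <- function(x, x0, fwhm) {
  g <- fwhm / 2
  (g / pi) / ((x - x0)^2 + g^2)
}
.gaussian <- function(x, x0, fwhm) {
  s <- fwhm / (2 * sqrt(2 * base::log(2)))
  stats::dnorm(x, mean = x0, sd = s)
}

#' Broaden an IR stick spectrum
#'
#' Sums unit-area lineshapes centred at `scale * wavenumber` and weighted by
#' intensity, so the integral of the curve equals the summed stick
#' intensities (up to lineshape mass outside the grid; Lorentzian wings are
#' heavy, so pass a wide `range` when integral conservation matters).
#'
#' @param lines Data frame with columns `wavenumber` (cm^-1) and `intensity`
#'   (or a [species_record()], whose line list is used).
#' @param width Full width at half maximum, cm^-1 (default 20).
#' @param scale Global frequency scale factor (default 1 = unscaled harmonic
#'   frequencies).
#' @param shape `"lorentzian"` (default) or `"gaussian"`.
#' @param range Optional c(lo, hi) axis range, cm^-1; default covers all
#'   (scaled) lines +- 5 widths.
#' @param resolution Grid step, cm^-1 (default 0.5).
#' @return A `spectrum` object (axis in cm^-1).
#' @export
broaden_ir <- function(lines, width = 20, scale = 1,
                       shape = c("lorentzian", "gaussian"),
                       range = NULL, resolution = 0.5) {
  shape <- match.arg(shape)
  if (inherits(lines, "species_record")) lines <- lines$frequencies
  if (is.null(lines) || nrow(lines) == 0L) {
    stop("line list is empty", call. = FALSE)
  }
  if (width <= 0) stop("width must be > 0", call. = FALSE)
  if (scale <= 0) stop("scale must be > 0", call. = FALSE)
  centers <- lines$wavenumber * scale
  if (is.null(range)) {
    range <- c(min(centers) - 5 * width, max(centers) + 5 * width)
  }
  axis <- seq(range[1], range[2], by = resolution)
  f <- if (shape == "lorentzian") .lorentzian else .gaussian
  values <- rowSums(vapply(seq_along(centers), function(i) {
    lines$intensity[i] * f(axis, centers[i], width)
  }, numeric(length(axis))))
  .make_spectrum(axis, values, shape, width, "cm-1")
}

#' Convolve an electronic excitation list into a UV-Vis spectrum
#'
#' Gaussian convolution in the energy domain, weighted by oscillator
#' strength; states with f = 0 (e.g. spin-forbidden triplets) contribute
#' nothing. The energy axis is converted to wavelength via
#' \eqn{\lambda = 1239.842/E} (nm, eV) and returned in increasing nm order.
#'
#' @param excitations Data frame with columns `energy_ev` and
#'   `oscillator_strength` (or a [species_record()]).
#' @param width Gaussian sigma in eV (default 0.3).
#' @param energy_range Optional c(lo, hi) in eV; default covers the
#'   contributing states +- 5 sigma (floored above 0).
#' @param n_points Grid size in the energy domain (default 2000).
#' @return A `spectrum` object (axis in nm; values per-eV intensity).
#' @export
uvvis_spectrum <- function(excitations, width = 0.3, energy_range = NULL,
                           n_points = 2000) {
  if (inherits(excitations, "species_record")) {
    excitations <- excitations$excitations
  }
  if (is.null(excitations) || nrow(excitations) == 0L) {
    stop("excitation list is empty", call. = FALSE)
  }
  if (width <= 0) stop("width must be > 0", call. = FALSE)
  E <- excitations$energy_ev
  f <- excitations$oscillator_strength
  if (is.null(energy_range)) {
    energy_range <- c(max(min(E) - 5 * width, 1e-3), max(E) + 5 * width)
  }
  grid <- seq(energy_range[1], energy_range[2], length.out = n_points)
  values <- rowSums(vapply(seq_along(E), function(i) {
    if (f[i] == 0) return(numeric(length(grid)))
    f[i] * stats::dnorm(grid, mean = E[i], sd = width)
  }, numeric(length(grid))))
  lambda <- constants_table()$nm_eV / grid   # decreasing in E
  ord <- order(lambda)
  .make_spectrum(lambda[ord], values[ord], "gaussian", width, "nm")
}

#' Integral of a spectrum (trapezoid rule)
#' @param spec A `spectrum`.
#' @param window Optional c(lo, hi) axis interval; default whole axis.
#' @return Numeric integral.
#' @export
spectrum_integral <- function(spec, window = NULL) {
  x <- spec$axis; y <- spec$values
  if (!is.null(window)) {
    keep <- x >= window[1] & x <= window[2]
    if (sum(keep) < 2L) return(0)
    x <- x[keep]; y <- y[keep]
  }
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Fraction of total spectral intensity inside a window
#'
#' @param spec A `spectrum`.
#' @param window c(lo, hi) in the spectrum's axis units; `Inf` allowed.
#' @return Fraction in \[0, 1\]. A window disjoint from the axis returns 0
#'   and signals a warning.
#' @export
window_fraction <- function(spec, window) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  if (window[2] < min(spec$axis) || window[1] > max(spec$axis)) {
    warning("window [", window[1], ", ", window[2],
            "] is disjoint from the spectrum axis; returning 0")
    return(0)
  }
  total <- spectrum_integral(spec)
  if (total <= 0) return(0)
  spectrum_integral(spec, window) / total
}

#' Write a spectrum as two-column delimited text
#'
#' A `#`-prefixed metadata header records the lineshape kind, width and axis
#' unit so that the file is self-describing.
#'
#' @param spec A `spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# lineshape: %s", spec$lineshape$kind),
    sprintf("# width: %g", spec$lineshape$width),
    sprintf("# axis_unit: %s", spec$axis_unit)), con)
  utils::write.table(data.frame(axis = spec$axis, value = spec$values),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- band tables -----------------------------------------------------------

#' Assemble a band table
#'
#' @param molecule Molecule name (recycled).
#' @param wavenumber Positive wavenumbers, cm^-1.
#' @param intensity Nonnegative intensities (source units); classified with
#'   [classify_intensity()].
#' @param assignment Optional assignment text.
#' @return Data frame of class `band_table` with columns `molecule`,
#'   `wavenumber`, `intensity`, `class`, `assignment`.
#' @export
band_table <- function(molecule, wavenumber, intensity, assignment = "") {
  if (any(wavenumber <= 0)) stop("wavenumbers must be > 0", call. = FALSE)
  out <- data.frame(molecule = molecule, wavenumber = wavenumber,
                    intensity = intensity,
                    class = classify_intensity(intensity),
                    assignment = assignment, stringsAsFactors = FALSE)
  class(out) <- c("band_table", "data.frame")
  out
}

#' Read a band table from delimited text
#'
#' Expects columns `molecule`, `wavenumber`, `intensity` and optionally
#' `assignment` (comma- or tab-separated; `#` comments allowed).
#'
#' @param path File path.
#' @return A [band_table()].
#' @export
read_band_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  need <- c("molecule", "wavenumber", "intensity")
  if (!all(need %in% names(df))) {
    stop("band table '", path, "' needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  band_table(df$molecule, df$wavenumber, df$intensity,
             if (is.null(df$assignment)) "" else df$assignment)
}

#' Find diagnostic bands clear of all reference absorptions
#'
#' Returns the target's bands of at least `min_class` whose distance to
#' every reference band exceeds `tolerance` (strict inequality): candidate
#' fingerprints that could identify the target in a mixed spectrum. The
#' result is ordered by wavenumber and is invariant under the ordering of
#' the reference tables.
#'
#' @param target A [band_table()] for the molecule of interest.
#' @param references A [band_table()] or list of band tables for the
#'   plausible co-occurring absorbers.
#' @param tolerance Exclusion distance in cm^-1 (default 15).
#' @param min_class Minimum intensity class considered (default `"strong"`).
#' @return A [band_table()] subset of `target` with attribute `tolerance`.
#' @export
diagnostic_windows <- function(target, references, tolerance = 15,
                               min_class = "strong") {
  if (is.null(target) || nrow(target) == 0L) {
    stop("target band table is empty", call. = FALSE)
  }
  min_class <- factor(min_class, levels = c("weak", "medium", "strong"),
                      ordered = TRUE)
  if (inherits(references, "data.frame")) references <- list(references)
  ref_wn <- unlist(lapply(references, function(r) r$wavenumber))
  cand <- target[target$class >= min_class, , drop = FALSE]
  keep <- vapply(cand$wavenumber, function(w) {
    length(ref_wn) == 0L || all(abs(w - ref_wn) > tolerance)
  }, logical(1))
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$wavenumber), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tolerance") <- tolerance
  out
}
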