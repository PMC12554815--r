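#' Configure an end-to-end analysis run
#'
#' @param library Path to a species library file, or a [species_library()].
#' @param reactions Optional path to a reaction-set file, or list of
#'   [reaction()]s.
#' @param conditions A [venus_conditions()] (default: Venus preset).
#' @param analyses Character subset of
#'   `c("thermo", "polymer", "kinetics", "feedstock", "spectra")`; at least
#'   one.
#' @param output_dir Directory for report files.
#' @param seed Integer seed recorded in the manifest (the analyses are
#'   deterministic; the seed matters when the config drives the synthetic
#'   generator upstream).
#' @param series Optional [oligomer_series()] for the polymer analysis; when
#'   absent one is assembled from the library using `monomer`/`h2o`/`cyc_<n>`
#'   identifiers if present.
#' @param droplet A [droplet_model()] for the feedstock analysis.
#' @param barriers,temperatures Kinetics grid (kcal/mol, K).
#' @param band_tolerance Diagnostic-window tolerance, cm^-1.
#' @param ir_width,uv_width Lineshape widths (cm^-1 FWHM; eV sigma).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(library, reactions = NULL,
                            conditions = venus_conditions(),
                            analyses = c("thermo", "polymer", "kinetics",
                                         "feedstock", "spectra"),
                            output_dir = tempfile("cloudpolymer_run_"),
                            seed = 1L,
                            series = NULL,
                            droplet = droplet_model(),
                            barriers = c(25, 50),
                            temperatures = c(298.15, 573.15),
                            band_tolerance = 15,
                            ir_width = 20, uv_width = 0.3) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (length(analyses) == 0L) stop("select at least one analysis",
                                   call. = FALSE)
  if (is.character(library)) {
    if (!file.exists(library)) stop("library path does not exist: ", library,
                                    call. = FALSE)
  } else stopifnot(inherits(library, "species_library"))
  if (is.character(reactions) && !file.exists(reactions)) {
    stop("reaction set path does not exist: ", reactions, call. = FALSE)
  }
  structure(list(library = library, reactions = reactions,
                 conditions = conditions, analyses = analyses,
                 output_dir = output_dir, seed = as.integer(seed),
                 series = series, droplet = droplet,
                 barriers = barriers, temperatures = temperatures,
                 band_tolerance = band_tolerance,
                 ir_width = ir_width, uv_width = uv_width),
            class = "pipeline_config")
}

# assemble an oligomer series from bare library records by naming convention
.series_from_library <- function(lib, monomer_id = "monomer",
                                 water_id = "h2o", cycle_prefix = "cyc_") {
  ids <- names(lib$records)
  cyc_ids <- grep(paste0("^", cycle_prefix, "[0-9]+$"), ids, value = TRUE)
  if (!monomer_id %in% ids || !water_id %in% ids || length(cyc_ids) == 0L) {
    return(NULL)
  }
  sizes <- as.integer(sub(cycle_prefix, "", cyc_ids, fixed = TRUE))
  cycles <- stats::setNames(lapply(cyc_ids, function(i) lib$records[[i]]),
                            sizes)
  oligomer_series(lib$records[[monomer_id]], lib$records[[water_id]],
                  cycles[order(sizes)])
}

#' Run the full analysis pipeline and emit a report bundle
#'
#' Deterministic given (inputs, seed). Writes, per selected analysis:
#' a reaction energy table (`reactions.tsv`), an insertion/strain table
#' (`polymer.tsv`), a persistence grid (`kinetics.tsv`), a feedstock table
#' (`feedstock.tsv`), broadened spectra (`ir_spectrum.tsv`,
#' `uvvis_spectrum.tsv`) with a diagnostic-band table (`diagnostics.tsv`),
#' and a machine-readable `manifest.json` listing every default actually
#' used (no silent defaults) plus the constants table. Any stage failure
#' aborts the run and removes partial outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list of the computed tables plus `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  lib <- if (is.character(cfg$library)) read_library(cfg$library) else
    cfg$library
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(cfg$output_dir, name)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    written <<- c(written, path)
    path
  }
  out <- list()
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", stage, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  if ("thermo" %in% cfg$analyses && !is.null(cfg$reactions)) {
    out$reactions <- run_stage("thermo", {
      rxns <- if (is.character(cfg$reactions)) read_reaction_set(cfg$reactions)
        else cfg$reactions
      tab <- reaction_table(rxns, lib, cfg$conditions)
      emit(tab, "reactions.tsv")
      tab
    })
  }

  series <- cfg$series
  if (is.null(series)) series <- .series_from_library(lib)
  if ("polymer" %in% cfg$analyses && !is.null(series)) {
    out$polymer <- run_stage("polymer", {
      sizes <- as.integer(names(series$cycles))
      steps <- c(if (series$monomer_is_cycle1) 1L,
                 sizes[(sizes + 1L) %in% sizes])
      ins <- data.frame(
        n = steps,
        delta_g = vapply(steps, function(n)
          insertion_delta_g(series, n, cfg$conditions), numeric(1)))
      pu <- per_unit_free_energy(series)
      tab <- merge(pu, ins, by = "n", all = TRUE)
      tab$proxy <- tab$n == select_cyclic_proxy(series)
      emit(tab, "polymer.tsv")
      tab
    })
  }

  if ("kinetics" %in% cfg$analyses) {
    out$kinetics <- run_stage("kinetics", {
      tab <- persistence_scan(cfg$barriers, cfg$temperatures)
      emit(tab, "kinetics.tsv")
      tab
    })
  }

  if ("feedstock" %in% cfg$analyses) {
    out$feedstock <- run_stage("feedstock", {
      tab <- feedstock_table(cfg$droplet)
      emit(tab, "feedstock.tsv")
      tab
    })
  }

  if ("spectra" %in% cfg$analyses) {
    out$spectra <- run_stage("spectra", {
      res <- list()
      # species with line lists -> broadened IR of the richest one, band
      # table diagnostics across all
      with_freq <- Filter(function(r) !is.null(r$frequencies), lib$records)
      if (length(with_freq)) {
        nlines <- vapply(with_freq, function(r) nrow(r$frequencies),
                         integer(1))
        target_rec <- with_freq[[which.max(nlines)]]
        spec_ir <- broaden_ir(target_rec, width = cfg$ir_width)
        write_spectrum(spec_ir, file.path(cfg$output_dir, "ir_spectrum.tsv"))
        written <<- c(written, file.path(cfg$output_dir, "ir_spectrum.tsv"))
        res$ir <- spec_ir
        tgt_tab <- band_table(target_rec$identifier,
                              target_rec$frequencies$wavenumber,
                              target_rec$frequencies$intensity)
        refs <- lapply(with_freq[names(with_freq) != target_rec$identifier],
                       function(r) band_table(r$identifier,
                                              r$frequencies$wavenumber,
                                              r$frequencies$intensity))
        diag <- diagnostic_windows(tgt_tab, refs,
                                   tolerance = cfg$band_tolerance)
        diag$tolerance <- rep(attr(diag, "tolerance"), nrow(diag))
        emit(diag, "diagnostics.tsv")
        res$diagnostics <- diag
      }
      with_exc <- Filter(function(r) !is.null(r$excitations), lib$records)
      if (length(with_exc)) {
        spec_uv <- uvvis_spectrum(with_exc[[1]], width = cfg$uv_width)
        write_spectrum(spec_uv, file.path(cfg$output_dir,
                                          "uvvis_spectrum.tsv"))
        written <<- c(written, file.path(cfg$output_dir, "uvvis_spectrum.tsv"))
        res$uvvis <- spec_uv
        res$uv_window_fraction_320_400 <-
          window_fraction(spec_uv, c(320, 400))
      }
      res
    })
  }

  manifest <- list(
    package = "cloudpolymer",
    package_version = as.character(utils::packageVersion("cloudpolymer")),
    seed = cfg$seed,
    analyses = cfg$analyses,
    conditions = list(temperature_K = cfg$conditions$temperature,
                      activities = as.list(cfg$conditions$activities),
                      concentrations = as.list(cfg$conditions$concentrations),
                      solute_standard_c_M = cfg$conditions$solute_standard_c,
                      gas_standard_c_M = cfg$conditions$gas_standard_c),
    droplet = list(radius_m = cfg$droplet$radius,
                   T_K = cfg$droplet$ambient_T, P_Pa = cfg$droplet$ambient_P,
                   mixing_ratios = as.list(cfg$droplet$mixing_ratios),
                   scavenging_fraction = cfg$droplet$scavenging_fraction),
    kinetics = list(barriers_kcal = cfg$barriers,
                    temperatures_K = cfg$temperatures, kappa = 1),
    spectra = list(ir_lineshape = "lorentzian", ir_fwhm_cm1 = cfg$ir_width,
                   ir_scale = 1, uv_lineshape = "gaussian",
                   uv_sigma_ev = cfg$uv_width,
                   band_tolerance_cm1 = cfg$band_tolerance),
    constants = constants_table()
  )
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$manifest <- manifest
  ok <- TRUE
  invisible(out)
}
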