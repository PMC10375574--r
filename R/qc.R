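#' Analysis configuration
#'
#' Bundles the matching thresholds and search settings used across the
#' pipeline. The defaults are the validated operating point for averaged
#' negative-mode QTOF spectra of ~100-mer guides: mass tolerance 0.01 m/z,
#' cosine threshold 0.80, noise floor 500 counts, precursor-region cutoff
#' 1310 m/z, spacer charges 1-..7- and full-length charges 1-..25-.
#'
#' @param tol Fragment m/z tolerance.
#' @param min_cosine Cosine acceptance threshold.
#' @param min_consecutive Minimum adjacent matched isotopologues.
#' @param noise_floor Minimum retained signal count.
#' @param mz_max Upper m/z cutoff (surviving precursor exclusion).
#' @param mz_min Lower end of the scan window.
#' @param spacer_charges,full_charges Charge ranges for spacer and
#'   full-length searches.
#' @param spacer_end Last spacer position.
#' @param fdr_offset_max,fdr_step Decoy FDR offset range and step, ppm.
#' @param seed Seed for any stochastic step.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(tol = 0.01, min_cosine = 0.80,
                            min_consecutive = 2, noise_floor = 500,
                            mz_max = 1310, mz_min = 100,
                            spacer_charges = 1:7, full_charges = 1:25,
                            spacer_end = 20L, fdr_offset_max = 1000,
                            fdr_step = 50, seed = 1L) {
  structure(list(
    tol = tol, min_cosine = min_cosine, min_consecutive = min_consecutive,
    noise_floor = noise_floor, mz_max = mz_max, mz_min = mz_min,
    spacer_charges = spacer_charges, full_charges = full_charges,
    spacer_end = spacer_end, fdr_offset_max = fdr_offset_max,
    fdr_step = fdr_step, seed = as.integer(seed)
  ), class = "analysis_config")
}

#' End-to-end spacer quality-control report
#'
#' Composes the pipeline on one averaged MS/MS acquisition: preprocessing,
#' spacer coverage, decoy FDR, single-base substitution discovery, C>U and
#' U>C isotopic profiles, and (optionally) de novo spacer sequencing.
#' Deterministic: the same inputs and config reproduce the report.
#'
#' @param spectra A `spectrum`, list of scans, or path to a TSV/mzML file.
#' @param sequence The expected guide as an `oligo_seq` or sequence string.
#' @param config An [analysis_config()].
#' @param denovo Also run de novo spacer sequencing (slower).
#' @return A `qc_report` list: `coverage`, `fdr`, `substitutions`,
#'   `substitution_types`, `cu_profiles`, optionally `denovo`, plus the
#'   preprocessed `spectrum`, `config` echo and package `version`.
#' @export
run_spacer_qc <- function(spectra, sequence, config = analysis_config(),
                          denovo = FALSE) {
  if (is.character(spectra) && length(spectra) == 1) {
    spectra <- load_spectra(spectra)
  }
  if (is.character(sequence)) sequence <- parse_oligo(sequence)
  spec <- preprocess(spectra, noise_floor = config$noise_floor,
                     mz_max = config$mz_max)
  mz_range <- c(config$mz_min, config$mz_max)
  spacer_idx <- seq_len(min(config$spacer_end, nrow(sequence) - 1L))
  coverage <- sequence_coverage(spec, sequence, mode = "spacer",
                                indices = spacer_idx,
                                charges = config$spacer_charges,
                                tol = config$tol,
                                min_consecutive = config$min_consecutive,
                                min_cosine = config$min_cosine,
                                mz_range = mz_range)
  fdr <- estimate_fdr(spec, sequence, indices = spacer_idx,
                      charges = config$spacer_charges,
                      offset_max = config$fdr_offset_max,
                      step = config$fdr_step, tol = config$tol,
                      min_consecutive = config$min_consecutive,
                      min_cosine = config$min_cosine, mz_range = mz_range)
  subs <- score_substitutions(spec, sequence,
                              spacer_end = config$spacer_end,
                              exclude_cu = TRUE,
                              charges = config$spacer_charges,
                              tol = config$tol,
                              min_consecutive = config$min_consecutive,
                              min_cosine = config$min_cosine,
                              mz_range = mz_range)
  cu <- dplyr::bind_rows(
    dplyr::mutate(cu_profile(spec, sequence, "U>C",
                             positions = spacer_idx,
                             charges = config$spacer_charges,
                             tol = config$tol, mz_range = mz_range),
                  direction = "U>C"),
    dplyr::mutate(cu_profile(spec, sequence, "C>U",
                             positions = spacer_idx,
                             charges = config$spacer_charges,
                             tol = config$tol, mz_range = mz_range),
                  direction = "C>U")
  )
  report <- list(
    sequence = sequence,
    spectrum = spec,
    coverage = coverage,
    fdr = fdr,
    substitutions = subs,
    substitution_types = substitution_type_summary(subs),
    cu_profiles = cu,
    config = config,
    version = as.character(utils::packageVersion("spacerms"))
  )
  if (isTRUE(denovo)) {
    report$denovo <- denovo_spacer(
      spec, mod_scaffold(oligo = sequence[seq_len(config$spacer_end), ]),
      max_len = config$spacer_end, charges = config$spacer_charges,
      tol = config$tol, min_consecutive = config$min_consecutive,
      min_cosine = config$min_cosine, mz_range = mz_range)
  }
  class(report) <- "qc_report"
  report
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s\n", oligo_name(x$sequence)))
  cat(sprintf("  spacer coverage: %.1f%% (%d fragment ions)\n",
              x$coverage$percent, nrow(x$coverage$matches)))
  if (!x$fdr$undefined) {
    cat(sprintf("  decoy FDR: %.2f%%\n", x$fdr$fdr_percent))
  }
  if (nrow(x$substitutions) > 0 && max(x$substitutions$score) > 0) {
    top <- x$substitutions[1, ]
    cat(sprintf("  top substitution candidate: %d %s>%s (score %.3g)\n",
                top$position, top$from_base, top$to_base, top$score))
  } else {
    cat("  no substitution candidate scored above zero\n")
  }
  if (!is.null(x$denovo) && nrow(x$denovo) > 0) {
    cat(sprintf("  de novo top sequence: %s\n", x$denovo$sequence[1]))
  }
  invisible(x)
}

#' Write a QC report to disk
#'
#' Emits a JSON summary plus TSV tables (matched fragments, substitution
#' candidates, C/U profiles, de novo candidates when present) under `dir`.
#'
#' @param report A `qc_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_qc_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(
    schema = "spacerms-qc/1",
    version = report$version,
    sequence = format_oligo(report$sequence),
    name = oligo_name(report$sequence),
    spacer_coverage_percent = report$coverage$percent,
    n_fragment_ions = nrow(report$coverage$matches),
    fdr_percent = if (report$fdr$undefined) NA else report$fdr$fdr_percent,
    top_substitution = if (nrow(report$substitutions) > 0) {
      top <- report$substitutions[1, ]
      sprintf("%d %s>%s", top$position, top$from_base, top$to_base)
    } else NA,
    config = unclass(report$config)
  )
  jsonlite::write_json(summary, file.path(dir, "qc_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  readr::write_tsv(report$coverage$matches, file.path(dir, "fragments.tsv"))
  readr::write_tsv(report$substitutions, file.path(dir, "substitutions.tsv"))
  readr::write_tsv(report$cu_profiles, file.path(dir, "cu_profiles.tsv"))
  if (!is.null(report$denovo)) {
    readr::write_tsv(report$denovo, file.path(dir, "denovo.tsv"))
  }
  invisible(dir)
}
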