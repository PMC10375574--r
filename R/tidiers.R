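#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a coverage report into its matched-fragment table
#'
#' @param x A `coverage_report`.
#' @param ... Unused.
#' @return The tibble of accepted fragment ions.
#' @method tidy coverage_report
#' @export
tidy.coverage_report <- function(x, ...) x$matches

#' One-row coverage summary
#'
#' @param x A `coverage_report`.
#' @param ... Unused.
#' @method glance coverage_report
#' @export
glance.coverage_report <- function(x, ...) {
  tibble::tibble(
    name = oligo_name(x$oligo),
    mode = x$mode,
    percent_coverage = x$percent,
    n_sites = nrow(x$positions),
    n_fragment_ions = nrow(x$matches),
    median_abs_mass_error = stats::median(abs(x$matches$mass_error)),
    min_cosine = if (nrow(x$matches)) min(x$matches$cosine) else NA_real_
  )
}

#' Per-offset decoy hit counts
#'
#' @param x An `fdr_report`.
#' @param ... Unused.
#' @method tidy fdr_report
#' @export
tidy.fdr_report <- function(x, ...) x$offsets

#' One-row FDR summary
#'
#' @param x An `fdr_report`.
#' @param ... Unused.
#' @method glance fdr_report
#' @export
glance.fdr_report <- function(x, ...) {
  tibble::tibble(
    fdr_percent = x$fdr_percent,
    target_hits = x$target_hits,
    mean_random_hits = mean(x$offsets$hits),
    median_random_hits = stats::median(x$offsets$hits),
    n_offsets = nrow(x$offsets),
    undefined = x$undefined
  )
}

#' Per-isotopologue residuals of a C/U mixture fit
#'
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @method tidy mixture_fit
#' @export
tidy.mixture_fit <- function(x, ...) x$residuals

#' One-row mixture-fit summary
#'
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @method glance mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble::tibble(
    fraction_substitute = x$fraction_substitute,
    fraction_parent = 1 - x$fraction_substitute,
    fit_cosine = x$fit_cosine,
    nnls_fraction = x$nnls_fraction,
    charge = x$charge
  )
}

#' Stack the tables of a QC report into one tidy tibble
#'
#' @param x A `qc_report`.
#' @param ... Unused.
#' @return The matched-fragment table of the spacer coverage search.
#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) x$coverage$matches

#' One-row QC summary
#'
#' @param x A `qc_report`.
#' @param ... Unused.
#' @method glance qc_report
#' @export
glance.qc_report <- function(x, ...) {
  top <- if (nrow(x$substitutions) > 0) x$substitutions[1, ] else NULL
  tibble::tibble(
    name = oligo_name(x$sequence),
    spacer_coverage_percent = x$coverage$percent,
    n_fragment_ions = nrow(x$coverage$matches),
    fdr_percent = if (x$fdr$undefined) NA_real_ else x$fdr$fdr_percent,
    top_substitution_score = if (is.null(top)) NA_real_ else top$score,
    top_substitution = if (is.null(top)) NA_character_ else
      sprintf("%d %s>%s", top$position, top$from_base, top$to_base)
  )
}
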