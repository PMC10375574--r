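#' c- and y-ion fragment series
#'
#' Backbone cleavage of the P--O5' bond in negative-mode MS/MS of RNA yields
#' complementary c/y pairs: the c_n ion is the 5' fragment retaining the
#' first n nucleotides plus the cleavage-site phosphate (thiophosphate when
#' the n-th linkage is a phosphorothioate); the y_n ion is the 3' fragment
#' of the last n nucleotides with a free 5'-OH. Compositions are built so
#' that comp(c_n) + comp(y_(N-n)) equals the parent composition exactly.
#'
#' @param oligo An `oligo_seq`.
#' @param ion_type `"c"` or `"y"`.
#' @param indices Fragment indices, each in `1..(length - 1)`.
#'
#' @return A tibble with columns `ion_type`, `index`, `composition`
#'   (list-column of `elem_comp`), `neutral_mono_mass` and `formula`.
#' @examples
#' xa <- parse_oligo("C(ms)U(ms)G(ms)GUUCCAUGGGAUGCUCU")
#' fragment_series(xa, "c", 1:3)
#' @export
fragment_series <- function(oligo, ion_type = c("c", "y"),
                            indices = seq_len(nrow(oligo) - 1L)) {
  ion_type <- match.arg(ion_type)
  N <- nrow(oligo)
  indices <- as.integer(indices)
  if (any(indices < 1L | indices > N - 1L)) {
    stop(sprintf("fragment index out of range 1..%d", N - 1L), call. = FALSE)
  }
  comps <- purrr::map(indices, function(n) fragment_comp(oligo, ion_type, n))
  tibble::tibble(
    ion_type = ion_type,
    index = indices,
    composition = comps,
    neutral_mono_mass = purrr::map_dbl(comps, neutral_mass),
    formula = purrr::map_chr(comps, format_comp)
  )
}

fragment_comp <- function(oligo, ion_type, n) {
  N <- nrow(oligo)
  if (ion_type == "c") {
    # first n nucleosides, n linkage acids (internal n-1 plus the one at the
    # cleavage site, carried by nucleotide n), minus 2n waters
    comp <- elem_comp()
    for (i in seq_len(n)) {
      comp <- comp + nucleoside_comp(oligo$base[i], oligo$ribose_methyl[i]) +
        linkage_comp(oligo$thio_linkage[i]) - .H2O - .H2O
    }
    comp
  } else {
    # last n nucleosides with n-1 internal linkages, 5'-OH on the fragment
    oligo_composition(oligo, from = N - n + 1L, to = N)
  }
}

#' m/z of a deprotonated negative-mode ion
#'
#' `[M - zH]^z-` with the electron mass folded into the proton constant:
#' m/z = (M - z * 1.007276) / z.
#'
#' @param mass Neutral mass in Da.
#' @param z Charge magnitude (positive integer).
#' @return m/z.
#' @examples
#' ion_mz(671.0522, 1)
#' @export
ion_mz <- function(mass, z) {
  if (any(z < 1)) stop("charge must be a positive integer", call. = FALSE)
  (mass - z * .PROTON_MASS) / z
}

#' Theoretical fragment ion table
#'
#' Expands a fragment series over charge states, keeping only ions whose
#' monoisotopic m/z falls inside the instrument window.
#'
#' @inheritParams fragment_series
#' @param ion_types Character vector from `c("c", "y")`.
#' @param charges Charge magnitudes to consider (negative mode), default 1:7.
#' @param mz_range Keep ions with monoisotopic m/z inside this window;
#'   the 1310 default mirrors the precursor-exclusion cutoff applied during
#'   preprocessing.
#' @return A tibble with one row per (ion, charge): columns of
#'   [fragment_series()] plus `charge` and `mz`.
#' @export
fragment_table <- function(oligo, ion_types = "c",
                           indices = seq_len(nrow(oligo) - 1L),
                           charges = 1:7, mz_range = c(100, 1310)) {
  series <- dplyr::bind_rows(
    purrr::map(ion_types, function(tp) fragment_series(oligo, tp, indices))
  )
  out <- tidyr::expand_grid(series, charge = as.integer(charges))
  out$mz <- ion_mz(out$neutral_mono_mass, out$charge)
  dplyr::filter(out, .data$mz >= mz_range[1], .data$mz <= mz_range[2])
}
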