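#' Cosine similarity between aligned isotopic abundance vectors
#'
#' Standard scale-invariant cosine: dot(obs, theo) / (||obs|| * ||theo||).
#' Unmatched theoretical positions contribute zero observed intensity. An
#' all-zero vector scores 0.
#'
#' @param theoretical,observed Equal-length numeric abundance vectors.
#' @return Score in `[0, 1]`.
#' @examples
#' cosine_score(c(1, 0.5), c(1, 0.6))
#' @export
cosine_score <- function(theoretical, observed) {
  stopifnot(length(theoretical) == length(observed))
  nt <- sqrt(sum(theoretical^2)); no <- sqrt(sum(observed^2))
  if (nt == 0 || no == 0) return(0)
  sum(theoretical * observed) / (nt * no)
}

#' Match one theoretical fragment ion against a centroided spectrum
#'
#' Each theoretical isotopologue is matched to the nearest peak within the
#' m/z tolerance (ties broken toward the higher-intensity peak). The
#' assignment is accepted only if at least `min_consecutive` adjacent
#' isotopologues are matched and the cosine score between the theoretical
#' envelope and the aligned observed intensities exceeds `min_cosine`. The
#' reported abundance is the observed intensity at the most abundant
#' theoretical isotopologue; the mass error is recorded at the most intense
#' matched isotopologue.
#'
#' @param spectrum A centroided `spectrum`.
#' @param composition `elem_comp` of the neutral fragment (or an
#'   `isotope_pattern` already at charge `z`).
#' @param z Charge state (negative mode magnitude).
#' @param tol m/z tolerance (default 0.01).
#' @param min_consecutive Minimum adjacent matched isotopologues (default 2).
#' @param min_cosine Cosine acceptance threshold (default 0.80).
#' @param mz_offset_ppm Shift applied to all theoretical m/z values, in ppm
#'   (used for decoy searches).
#' @return A one-row tibble (`charge`, `mz`, `mass_error`, `cosine`,
#'   `abundance`, `n_matched`, `accepted`, `reason`); `accepted` is FALSE
#'   with a reason code when the match fails.
#' @export
match_fragment <- function(spectrum, composition, z, tol = 0.01,
                           min_consecutive = 2, min_cosine = 0.80,
                           mz_offset_ppm = 0) {
  if (inherits(composition, "isotope_pattern")) {
    pat <- composition
  } else {
    pat <- isotope_distribution(composition, z = z)
  }
  theo_mz <- pat$mz * (1 + mz_offset_ppm * 1e-6)
  theo_ab <- pat$abundance
  n <- length(theo_mz)
  obs <- numeric(n)
  err <- rep(NA_real_, n)
  matched <- logical(n)
  if (nrow(spectrum) > 0) {
    for (i in seq_len(n)) {
      d <- abs(spectrum$mz - theo_mz[i])
      within <- which(d <= tol)
      if (length(within) == 0) next
      best <- within[order(d[within], -spectrum$intensity[within])][1]
      # tie toward higher intensity among near-equal distances
      near <- within[d[within] <= d[best] + 1e-9]
      best <- near[which.max(spectrum$intensity[near])]
      obs[i] <- spectrum$intensity[best]
      err[i] <- spectrum$mz[best] - theo_mz[i]
      matched[i] <- TRUE
    }
  }
  runs <- rle(matched)
  max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  cs <- cosine_score(theo_ab, obs)
  top <- which.max(theo_ab)
  mi <- which(matched)
  mass_error <- if (length(mi)) err[mi[which.max(obs[mi])]] else NA_real_
  accepted <- max_run >= min_consecutive && cs > min_cosine
  reason <- if (accepted) "ok"
            else if (max_run < min_consecutive) "too_few_consecutive_isotopes"
            else "low_cosine"
  tibble::tibble(
    charge = as.integer(z),
    mz = theo_mz[top],
    mass_error = mass_error,
    cosine = cs,
    abundance = if (matched[top]) obs[top] else 0,
    n_matched = sum(matched),
    accepted = accepted,
    reason = reason
  )
}

#' Search a fragment grid against a spectrum
#'
#' Runs [match_fragment()] for every requested fragment at every charge
#' whose monoisotopic m/z falls in the window, and returns the accepted
#' matches.
#'
#' @inheritParams fragment_table
#' @param spectrum A centroided `spectrum`.
#' @param tol,min_consecutive,min_cosine Matching thresholds (see
#'   [match_fragment()]).
#' @param mz_offset_ppm Decoy shift in ppm applied to every theoretical m/z.
#' @param keep_rejected Also return failed assignments with reason codes.
#' @return A tibble of matches: `ion_type`, `index`, `charge`, `mz`,
#'   `mass_error`, `cosine`, `abundance`, `n_matched`.
#' @export
search_fragments <- function(spectrum, oligo, ion_types = "c",
                             indices = seq_len(nrow(oligo) - 1L),
                             charges = 1:7, mz_range = c(100, 1310),
                             tol = 0.01, min_consecutive = 2,
                             min_cosine = 0.80, mz_offset_ppm = 0,
                             keep_rejected = FALSE) {
  out <- list()
  for (tp in ion_types) {
    frags <- fragment_series(oligo, tp, indices)
    for (k in seq_len(nrow(frags))) {
      pat0 <- isotope_distribution(frags$composition[[k]], z = 0L)
      mono <- ion_mz(frags$neutral_mono_mass[k], charges)
      for (z in charges[mono >= mz_range[1] & mono <= mz_range[2]]) {
        pat <- new_isotope_pattern(ion_mz(pat0$mz, z), pat0$abundance,
                                   charge = as.integer(z),
                                   origin = "theoretical")
        m <- match_fragment(spectrum, pat, z, tol = tol,
                            min_consecutive = min_consecutive,
                            min_cosine = min_cosine,
                            mz_offset_ppm = mz_offset_ppm)
        if (m$accepted || keep_rejected) {
          out[[length(out) + 1L]] <- dplyr::bind_cols(
            tibble::tibble(ion_type = tp, index = frags$index[k]), m
          )
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(ion_type = character(), index = integer(),
                          charge = integer(), mz = numeric(),
                          mass_error = numeric(), cosine = numeric(),
                          abundance = numeric(), n_matched = integer(),
                          accepted = logical(), reason = character()))
  }
  dplyr::bind_rows(out)
}

#' Sequence coverage from fragment assignments
#'
#' Spacer mode searches c_1..c_20 at charges 1-..7-; full mode searches the
#' entire c/y ladders at charges 1-..25-. Percent coverage is the fraction
#' of cleavage sites in the requested range supported by at least one
#' accepted fragment ion.
#'
#' @inheritParams search_fragments
#' @param mode `"spacer"` or `"full"`, or NULL to use `indices`/`charges`
#'   as given.
#' @return A `coverage_report` list: `matches` (tibble), `positions`
#'   (per-site evidence flags), `percent`, and the search settings.
#' @export
sequence_coverage <- function(spectrum, oligo, mode = c("spacer", "full"),
                              ion_types = NULL, indices = NULL,
                              charges = NULL, tol = 0.01,
                              min_consecutive = 2, min_cosine = 0.80,
                              mz_range = c(100, 1310)) {
  mode <- match.arg(mode)
  if (mode == "spacer") {
    ion_types <- ion_types %||% "c"
    indices <- indices %||% seq_len(min(20L, nrow(oligo) - 1L))
    charges <- charges %||% 1:7
  } else {
    ion_types <- ion_types %||% c("c", "y")
    indices <- indices %||% seq_len(nrow(oligo) - 1L)
    charges <- charges %||% 1:25
  }
  matches <- search_fragments(spectrum, oligo, ion_types, indices, charges,
                              mz_range = mz_range, tol = tol,
                              min_consecutive = min_consecutive,
                              min_cosine = min_cosine)
  positions <- tibble::tibble(index = indices)
  for (tp in ion_types) {
    hit <- matches$index[matches$ion_type == tp]
    positions[[paste0(tp, "_ion")]] <- positions$index %in% hit
  }
  covered <- rowSums(as.matrix(positions[, -1, drop = FALSE])) > 0
  structure(list(
    matches = matches,
    positions = positions,
    percent = 100 * mean(covered),
    oligo = oligo, mode = mode, ion_types = ion_types,
    charges = charges, tol = tol, min_cosine = min_cosine
  ), class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> %s | %s mode | %.1f%% of %d sites | %d fragment ions\n",
              oligo_name(x$oligo), x$mode, x$percent, nrow(x$positions),
              nrow(x$matches)))
  invisible(x)
}

#' Decoy-based false discovery rate for fragment assignments
#'
#' Shifts all theoretical fragment m/z values by each nonzero ppm offset in
#' `seq(-offset_max, offset_max, step)` (40 decoy searches at the defaults)
#' and treats assignments against shifted lists as random hits; FDR is the
#' mean random hit count divided by the target (zero-offset) hit count.
#'
#' @inheritParams search_fragments
#' @param offset_max,step Decoy offset range and increment, ppm.
#' @return An `fdr_report` list: `fdr`, `target_hits`, `offsets` (per-offset
#'   hit counts), and `scores` (cosine scores of target vs random hits,
#'   including sub-threshold assignments, for threshold diagnostics).
#' @export
estimate_fdr <- function(spectrum, oligo, ion_types = "c",
                         indices = seq_len(min(20L, nrow(oligo) - 1L)),
                         charges = 1:7, offset_max = 1000, step = 50,
                         tol = 0.01, min_consecutive = 2, min_cosine = 0.80,
                         mz_range = c(100, 1310)) {
  offsets <- setdiff(seq(-offset_max, offset_max, by = step), 0)
  run <- function(off) {
    search_fragments(spectrum, oligo, ion_types, indices, charges,
                     mz_range = mz_range, tol = tol,
                     min_consecutive = min_consecutive,
                     min_cosine = min_cosine, mz_offset_ppm = off,
                     keep_rejected = TRUE)
  }
  target <- run(0)
  random <- purrr::map(offsets, run)
  target_hits <- sum(target$accepted)
  random_hits <- purrr::map_int(random, function(m) sum(m$accepted))
  fdr <- if (target_hits == 0) NA_real_ else mean(random_hits) / target_hits
  scores <- dplyr::bind_rows(
    dplyr::mutate(target[target$n_matched >= min_consecutive, ],
                  class = "target"),
    dplyr::mutate(
      dplyr::bind_rows(random)[dplyr::bind_rows(random)$n_matched >=
                                 min_consecutive, ],
      class = "random")
  )
  structure(list(
    fdr = fdr,
    fdr_percent = 100 * fdr,
    target_hits = target_hits,
    offsets = tibble::tibble(offset_ppm = offsets, hits = random_hits),
    scores = scores,
    undefined = target_hits == 0
  ), class = "fdr_report")
}

#' @export
print.fdr_report <- function(x, ...) {
  if (x$undefined) {
    cat("<fdr_report> undefined (no target hits)\n")
  } else {
    cat(sprintf("<fdr_report> FDR %.2f%% | %d target hits | %d decoy offsets\n",
                x$fdr_percent, x$target_hits, nrow(x$offsets)))
  }
  invisible(x)
}
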