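#' Modification scaffold for de novo spacer sequencing
#'
#' A scaffold of "empty" nucleotides: the 2'-O-methyl and phosphorothioate
#' flags at each position are known (from the synthesis design) while the
#' base identities are not. [denovo_spacer()] fills the bases in from the
#' c-ion ladder.
#'
#' @param ribose_methyl,thio_linkage Logical vectors of per-position flags
#'   (equal length).
#' @param oligo Alternatively, an `oligo_seq` whose flags are copied and
#'   whose bases are discarded.
#' @return A `scaffold` tibble with columns `position`, `ribose_methyl`,
#'   `thio_linkage`.
#' @export
mod_scaffold <- function(ribose_methyl = NULL, thio_linkage = NULL,
                         oligo = NULL) {
  if (!is.null(oligo)) {
    ribose_methyl <- oligo$ribose_methyl
    thio_linkage <- oligo$thio_linkage
  }
  stopifnot(length(ribose_methyl) == length(thio_linkage))
  out <- tibble::tibble(position = seq_along(ribose_methyl),
                        ribose_methyl = ribose_methyl,
                        thio_linkage = thio_linkage)
  class(out) <- c("scaffold", class(out))
  out
}

# incremental c_k composition: comp of c_(k-1) plus the k-th (modified)
# nucleoside and its 3' linkage acid, condensing two waters
extend_c_comp <- function(comp, base, methyl, thio) {
  comp + nucleoside_comp(base, methyl) + linkage_comp(thio) - .H2O - .H2O
}

# match one candidate c_k composition across in-window charges; returns the
# accepted rows (or all rows when permissive)
match_c_comp <- function(spectrum, comp, charges, mz_range, tol,
                         min_consecutive, min_cosine) {
  mono <- ion_mz(neutral_mass(comp), charges)
  zz <- charges[mono >= mz_range[1] & mono <= mz_range[2]]
  rows <- list()
  pat0 <- isotope_distribution(comp, z = 0L)
  for (z in zz) {
    pat <- new_isotope_pattern(ion_mz(pat0$mz, z), pat0$abundance,
                               charge = as.integer(z), origin = "theoretical")
    m <- match_fragment(spectrum, pat, z, tol = tol,
                        min_consecutive = min_consecutive,
                        min_cosine = min_cosine)
    if (m$accepted) rows[[length(rows) + 1L]] <- m
  }
  if (length(rows) == 0) {
    return(tibble::tibble(charge = integer(), mz = numeric(),
                          mass_error = numeric(), cosine = numeric(),
                          abundance = numeric(), n_matched = integer(),
                          accepted = logical(), reason = character()))
  }
  dplyr::bind_rows(rows)
}

#' De novo spacer sequencing from the c-ion ladder
#'
#' Breadth-first 5'-to-3' reconstruction: at position k every surviving
#' partial sequence is extended by A, G, C and U (on the scaffold's
#' modification flags) and an extension is kept only when a matching c_k
#' fragment ion is found at some allowed charge. Because a C and a U call
#' differ by only 0.984 Da with overlapping envelopes, C/U extensions are
#' verified by isotopic mixture fitting: when the fitted minority fraction
#' is at least `cu_branch_threshold` both calls are carried forward as
#' separate branches (the spectrum genuinely supports a mixture of
#' sequences). At checkpoints k = 5, 10, 15, 20 candidates are scored
#' (intensity-weighted, coverage-squared) and each set of isomeric
#' (equal-mass) partial sequences is reduced to its best scorer to suppress
#' sequence scrambles. The default search requires full coverage: a partial
#' sequence with no matching c_k dies.
#'
#' @param spectrum A centroided `spectrum`.
#' @param scaffold A [mod_scaffold()] (length >= `max_len`).
#' @param max_len Spacer length to reconstruct (default 20).
#' @param charges,tol,min_consecutive,min_cosine,mz_range Matching settings.
#' @param cu_branch_threshold Minority fraction above which both C and U
#'   branches are kept (default 0.05).
#' @param missed_budget Number of missed fragments tolerated after c_3
#'   (default 0: full coverage). See [denovo_impurity_tags()].
#' @return A `denovo_result` tibble ranked by the coverage-weighted score:
#'   `sequence` (modified-RNA syntax), `score` (sum of abundance * cosine^2
#'   over matched fragments), `score_weighted` (score * coverage^2),
#'   `coverage`, `missed`. Empty when no c_1 matches.
#' @export
denovo_spacer <- function(spectrum, scaffold, max_len = 20L, charges = 1:7,
                          tol = 0.01, min_consecutive = 2, min_cosine = 0.80,
                          mz_range = c(100, 1310),
                          cu_branch_threshold = 0.05, missed_budget = 0L) {
  stopifnot(nrow(scaffold) >= max_len)
  cands <- list(list(bases = character(0), comp = elem_comp(),
                     matches = list(), missed = 0L))
  for (k in seq_len(max_len)) {
    methyl <- scaffold$ribose_methyl[k]
    thio <- scaffold$thio_linkage[k]
    nxt <- list()
    for (cand in cands) {
      ext <- extend_candidate(cand, k, methyl, thio, spectrum, charges,
                              mz_range, tol, min_consecutive, min_cosine,
                              cu_branch_threshold)
      if (length(ext) == 0) {
        # missed fragment: allowed only past c_3 and within budget
        if (k > 3 && cand$missed < missed_budget) {
          for (b in c("A", "C", "G", "U")) {
            nc <- cand
            nc$bases <- c(nc$bases, b)
            nc$comp <- extend_c_comp(nc$comp, b, methyl, thio)
            nc$missed <- nc$missed + 1L
            nxt[[length(nxt) + 1L]] <- nc
          }
        }
      } else {
        nxt <- c(nxt, ext)
      }
    }
    cands <- nxt
    if (length(cands) == 0) break
    if (k %in% c(5L, 10L, 15L, 20L)) {
      cands <- reduce_isomeric(cands, k)
    }
  }
  denovo_result(cands, max_len, scaffold)
}

extend_candidate <- function(cand, k, methyl, thio, spectrum, charges,
                             mz_range, tol, min_consecutive, min_cosine,
                             cu_branch_threshold) {
  out <- list()
  add <- function(base, comp, match_rows) {
    nc <- cand
    nc$bases <- c(nc$bases, base)
    nc$comp <- comp
    nc$matches[[length(nc$matches) + 1L]] <-
      dplyr::mutate(match_rows, index = k)
    out[[length(out) + 1L]] <<- nc
  }
  for (b in c("A", "G")) {
    comp <- extend_c_comp(cand$comp, b, methyl, thio)
    m <- match_c_comp(spectrum, comp, charges, mz_range, tol,
                      min_consecutive, min_cosine)
    if (nrow(m) > 0) add(b, comp, m)
  }
  # C/U pair: verify by isotopic mixture fitting before branching
  comp_c <- extend_c_comp(cand$comp, "C", methyl, thio)
  comp_u <- extend_c_comp(cand$comp, "U", methyl, thio)
  m_c <- match_c_comp(spectrum, comp_c, charges, mz_range, tol,
                      min_consecutive, min_cosine)
  m_u <- match_c_comp(spectrum, comp_u, charges, mz_range, tol,
                      min_consecutive, min_cosine)
  if (nrow(m_c) > 0 || nrow(m_u) > 0) {
    lead <- if (sum(m_u$abundance) >= sum(m_c$abundance)) "U" else "C"
    zbest <- if (lead == "U") m_u$charge[which.max(m_u$abundance)]
             else m_c$charge[which.max(m_c$abundance)]
    obs <- observed_envelope(spectrum, list(comp_u, comp_c), zbest, tol = tol)
    f_c <- tryCatch(
      fit_cu_mixture(obs, comp_u, comp_c)$fraction_substitute,
      error = function(e) if (lead == "C") 1 else 0
    )
    joint <- function(own, other, frac) {
      if (nrow(own) > 0) return(own)
      dplyr::mutate(other, abundance = .data$abundance * frac)
    }
    if (f_c >= cu_branch_threshold) add("C", comp_c, joint(m_c, m_u, f_c))
    if (1 - f_c >= cu_branch_threshold) add("U", comp_u, joint(m_u, m_c, 1 - f_c))
  }
  out
}

reduce_isomeric <- function(cands, k) {
  mass_key <- purrr::map_chr(cands, function(cc)
    sprintf("%.3f", neutral_mass(cc$comp)))
  eq3 <- purrr::map_dbl(cands, cand_eq3)
  cov <- purrr::map_dbl(cands, function(cc) cand_coverage(cc, k))
  eq4 <- eq3 * cov^2
  seqs <- purrr::map_chr(cands, function(cc) paste0(cc$bases, collapse = ""))
  keep <- integer()
  for (key in unique(mass_key)) {
    idx <- which(mass_key == key)
    # best score; ties broken lexicographically by sequence
    best <- idx[order(-eq4[idx], seqs[idx])][1]
    keep <- c(keep, best)
  }
  cands[sort(keep)]
}

cand_eq3 <- function(cand) {
  if (length(cand$matches) == 0) return(0)
  m <- dplyr::bind_rows(cand$matches)
  sum(m$abundance * m$cosine^2)
}

cand_coverage <- function(cand, k) {
  if (length(cand$matches) == 0) return(0)
  length(unique(dplyr::bind_rows(cand$matches)$index)) / k
}

denovo_result <- function(cands, max_len, scaffold) {
  if (length(cands) == 0) {
    out <- tibble::tibble(sequence = character(), score = numeric(),
                          score_weighted = numeric(), coverage = numeric(),
                          missed = integer())
  } else {
    out <- purrr::map_dfr(cands, function(cc) {
      k <- length(cc$bases)
      oligo <- new_oligo(cc$bases, scaffold$ribose_methyl[1:k],
                         scaffold$thio_linkage[1:k])
      tibble::tibble(
        sequence = format_oligo(oligo),
        score = cand_eq3(cc),
        score_weighted = cand_eq3(cc) * cand_coverage(cc, k)^2,
        coverage = cand_coverage(cc, k),
        missed = cc$missed
      )
    })
    out <- dplyr::arrange(out, dplyr::desc(.data$score_weighted),
                          .data$sequence)
  }
  class(out) <- c("denovo_result", class(out))
  out
}

#' De novo sequence tags for low-abundance dissimilar impurities
#'
#' Relaxes the full-coverage requirement of [denovo_spacer()] to find
#' sequence tags of minority components: one missed fragment is tolerated
#' per five nucleotides of tag length, but the c_1, c_2 and c_3 fragments
#' (typically the most abundant) must all be identified. Scores are
#' weighted by the squared final coverage.
#'
#' @inheritParams denovo_spacer
#' @param tag_len Tag length: 5, 10, 15 or 20.
#' @param missed_per_5 Missed fragments allowed per 5 nucleotides (default 1).
#' @return A ranked `denovo_result` tibble.
#' @export
denovo_impurity_tags <- function(spectrum, scaffold, tag_len = 20L,
                                 missed_per_5 = 1L, charges = 1:7,
                                 tol = 0.01, min_consecutive = 2,
                                 min_cosine = 0.80, mz_range = c(100, 1310),
                                 cu_branch_threshold = 0.05) {
  stopifnot(tag_len %in% c(5L, 10L, 15L, 20L))
  denovo_spacer(spectrum, scaffold, max_len = tag_len, charges = charges,
                tol = tol, min_consecutive = min_consecutive,
                min_cosine = min_cosine, mz_range = mz_range,
                cu_branch_threshold = cu_branch_threshold,
                missed_budget = (tag_len %/% 5L) * missed_per_5)
}

#' De novo localization of 2'-O-methyl and phosphorothioate modifications
#'
#' The inverse scaffold problem: bases are known, per-position modification
#' flags are not. The c-ion ladder is searched 5' to 3' over the flag
#' vocabulary {unmodified, 2'-O-methyl, 2'-O-methyl + phosphorothioate}
#' (a phosphorothioate linkage implies a methylated ribose on the same
#' nucleotide, mirroring the synthesis chemistry). Complete c-ion coverage
#' is required over positions 1..20; up to `missed_budget` missed cleavages
#' are tolerated over positions 21..`max_pos`, where a missing flanking
#' fragment leaves the placement ambiguous -- such candidates tie on score
#' and [localize_modifications()] reports the placement as a sequence
#' stretch rather than a single position.
#'
#' @param spectrum A centroided `spectrum`.
#' @param base_sequence An `oligo_seq` (flags ignored) or plain base string.
#' @param max_pos Last position searched (default 28; c-ion coverage beyond
#'   is too sparse to localize).
#' @param missed_budget Missed cleavages allowed over positions 21..max_pos
#'   (default 2).
#' @inheritParams denovo_spacer
#' @return A ranked `denovo_result` tibble of flag assignments.
#' @export
denovo_modifications <- function(spectrum, base_sequence, max_pos = 28L,
                                 missed_budget = 2L, charges = 1:7,
                                 tol = 0.01, min_consecutive = 2,
                                 min_cosine = 0.80, mz_range = c(100, 1310)) {
  if (is.character(base_sequence)) base_sequence <- parse_oligo(base_sequence)
  max_pos <- min(max_pos, nrow(base_sequence) - 1L)
  flag_opts <- list(c(FALSE, FALSE), c(TRUE, FALSE), c(TRUE, TRUE))
  cands <- list(list(methyl = logical(0), thio = logical(0),
                     comp = elem_comp(), matches = list(), missed = 0L))
  for (k in seq_len(max_pos)) {
    base <- base_sequence$base[k]
    nxt <- list()
    for (cand in cands) {
      hit <- FALSE
      for (fl in flag_opts) {
        comp <- extend_c_comp(cand$comp, base, fl[1], fl[2])
        m <- match_c_comp(spectrum, comp, charges, mz_range, tol,
                          min_consecutive, min_cosine)
        if (nrow(m) > 0) {
          hit <- TRUE
          nc <- cand
          nc$methyl <- c(nc$methyl, fl[1]); nc$thio <- c(nc$thio, fl[2])
          nc$comp <- comp
          nc$matches[[length(nc$matches) + 1L]] <- dplyr::mutate(m, index = k)
          nxt[[length(nxt) + 1L]] <- nc
        }
      }
      if (!hit && k > 20 && cand$missed < missed_budget) {
        for (fl in flag_opts) {
          nc <- cand
          nc$methyl <- c(nc$methyl, fl[1]); nc$thio <- c(nc$thio, fl[2])
          nc$comp <- extend_c_comp(cand$comp, base, fl[1], fl[2])
          nc$missed <- nc$missed + 1L
          nxt[[length(nxt) + 1L]] <- nc
        }
      }
    }
    cands <- nxt
    if (length(cands) == 0) break
  }
  if (length(cands) == 0) {
    out <- tibble::tibble(sequence = character(), score = numeric(),
                          score_weighted = numeric(), coverage = numeric(),
                          missed = integer())
    class(out) <- c("denovo_result", class(out))
    return(out)
  }
  out <- purrr::map_dfr(cands, function(cc) {
    k <- length(cc$methyl)
    oligo <- new_oligo(base_sequence$base[1:k], cc$methyl, cc$thio)
    tibble::tibble(
      sequence = format_oligo(oligo),
      score = cand_eq3(cc),
      score_weighted = cand_eq3(cc) * cand_coverage(cc, k)^2,
      coverage = cand_coverage(cc, k),
      missed = cc$missed
    )
  })
  out <- dplyr::arrange(out, dplyr::desc(.data$score_weighted), .data$sequence)
  class(out) <- c("denovo_result", class(out))
  out
}

#' Consensus modification placement with ambiguity stretches
#'
#' Summarizes the top-scoring tie set of a [denovo_modifications()] result:
#' positions on which all tied candidates agree are assigned; positions on
#' which they disagree (missing flanking fragments) are reported as
#' ambiguous, with the run of disagreeing adjacent positions forming the
#' localization stretch.
#'
#' @param result A `denovo_result` from [denovo_modifications()].
#' @param score_tol Relative score window treated as a tie (default 1e-9).
#' @return A tibble: `position`, `ribose_methyl`, `thio_linkage` (logical,
#'   NA where ambiguous), `ambiguous`; ambiguous stretches as an attribute
#'   `"stretches"` (tibble of `start`, `end`).
#' @export
localize_modifications <- function(result, score_tol = 1e-9) {
  stopifnot(nrow(result) > 0)
  top <- result$score_weighted[1]
  tied <- result[result$score_weighted >= top * (1 - score_tol), ]
  oligos <- purrr::map(tied$sequence, parse_oligo)
  k <- nrow(oligos[[1]])
  methyl <- purrr::map(oligos, "ribose_methyl")
  thio <- purrr::map(oligos, "thio_linkage")
  agree <- function(lst, i) length(unique(purrr::map_lgl(lst, i))) == 1
  out <- purrr::map_dfr(seq_len(k), function(i) {
    am <- !agree(methyl, i); at <- !agree(thio, i)
    tibble::tibble(
      position = i,
      ribose_methyl = if (am) NA else methyl[[1]][i],
      thio_linkage = if (at) NA else thio[[1]][i],
      ambiguous = am || at
    )
  })
  r <- rle(out$ambiguous)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  attr(out, "stretches") <- tibble::tibble(start = starts[r$values],
                                           end = ends[r$values])
  out
}
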