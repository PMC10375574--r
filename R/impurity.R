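#' Discover single-base substitution impurities
#'
#' Scores every single-base permutation of the spacer against the spectrum.
#' For a substitution at position n, only c-fragments c_n..c_m (m = last
#' spacer position) distinguish the variant from the parent; the candidate
#' score is
#'
#'   score = (unique-region coverage fraction)^2 *
#'           sum over accepted unique fragment ions of abundance * cosine^2
#'
#' where abundance is the observed intensity at the most abundant
#' theoretical isotopologue. C/U interconversions are excluded by default
#' because their overlapping isotopic envelopes are better handled by
#' [fit_cu_mixture()] / [cu_profile()].
#'
#' Isomeric candidates (e.g. G>A substitutions at different positions whose
#' larger fragments share masses) legitimately co-score; the per-type
#' maximum view in [substitution_type_summary()] is the headline output.
#'
#' @param spectrum A centroided `spectrum`.
#' @param parent Parent `oligo_seq` (spacer or full guide; the spacer is
#'   taken as positions 1..`spacer_end`).
#' @param spacer_end Last spacer position (default 20, clipped to length-1).
#' @param exclude_cu Drop C->U / U->C candidates (default TRUE).
#' @param charges,tol,min_consecutive,min_cosine,mz_range Matching settings.
#' @return A tibble of candidates ranked by decreasing score: `position`,
#'   `from_base`, `to_base`, `score`, `coverage`, `n_unique_matched`.
#' @export
score_substitutions <- function(spectrum, parent, spacer_end = 20L,
                                exclude_cu = TRUE, charges = 1:7,
                                tol = 0.01, min_consecutive = 2,
                                min_cosine = 0.80, mz_range = c(100, 1310)) {
  m <- min(spacer_end, nrow(parent) - 1L)
  cands <- enumerate_substitutions(parent, region = seq_len(m),
                                   exclude_cu = exclude_cu)
  rows <- purrr::pmap(cands, function(position, from_base, to_base, variant) {
    matches <- search_fragments(spectrum, variant, "c",
                                indices = position:m, charges = charges,
                                mz_range = mz_range, tol = tol,
                                min_consecutive = min_consecutive,
                                min_cosine = min_cosine)
    coverage <- length(unique(matches$index)) / (m - position + 1)
    tibble::tibble(
      position = position, from_base = from_base, to_base = to_base,
      score = coverage^2 * sum(matches$abundance * matches$cosine^2),
      coverage = coverage,
      n_unique_matched = nrow(matches)
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$score))
  class(out) <- c("substitution_scores", class(out))
  out
}

#' Per-substitution-type maximum scores
#'
#' Collapses a [score_substitutions()] table to the best-scoring position
#' for each substitution type (from_base > to_base), the view that remains
#' informative when isomeric positional candidates share fragment masses.
#'
#' @param scores A `substitution_scores` tibble.
#' @return A tibble ranked by score with one row per substitution type.
#' @export
substitution_type_summary <- function(scores) {
  dplyr::arrange(
    dplyr::summarise(
      dplyr::group_by(scores, .data$from_base, .data$to_base),
      score = max(.data$score),
      position = .data$position[which.max(.data$score)],
      .groups = "drop"
    ),
    dplyr::desc(.data$score)
  )
}

#' Quantify a known variant site-by-site from c-ion abundance ratios
#'
#' At each requested position n the variant fraction is estimated as
#' 100 * A_variant(c_n) / (A_variant(c_n) + A_parent(c_n)). Abundances are
#' summed over all charge states at which either species is confidently
#' assigned, reading each species' intensity at its most abundant
#' theoretical isotopologue; anchoring the charge inventory this way keeps
#' the ratio unbiased when congestion from co-occurring fragment envelopes
#' distorts minor isotopologues of the low-abundance species at some
#' charges. Positions where the variant and
#' parent c_n fragments have identical composition (all substitution sites
#' lie beyond n) are flagged indistinguishable and report NA.
#'
#' @param spectrum A centroided `spectrum`.
#' @param parent,variant `oligo_seq` objects differing in the spacer.
#' @param positions Fragment indices to evaluate (default c(2, 5, 10, 15, 20)).
#' @param charges,tol,min_consecutive,min_cosine,mz_range Matching settings.
#' @return A tibble: `position`, `percent`, `parent_abundance`,
#'   `variant_abundance`, `distinguishable`, `defined`.
#' @export
quantify_variant_sites <- function(spectrum, parent, variant,
                                   positions = c(2, 5, 10, 15, 20),
                                   charges = 1:7, tol = 0.01,
                                   min_consecutive = 2, min_cosine = 0.80,
                                   mz_range = c(100, 1310)) {
  purrr::map_dfr(as.integer(positions), function(n) {
    cp <- fragment_comp(parent, "c", n)
    cv <- fragment_comp(variant, "c", n)
    if (cp == cv) {
      return(tibble::tibble(position = n, percent = NA_real_,
                            parent_abundance = NA_real_,
                            variant_abundance = NA_real_,
                            distinguishable = FALSE, defined = FALSE))
    }
    # charge inventory: charges where either species is confidently
    # assigned; abundances are then read at the most abundant theoretical
    # isotopologue for both species at those charges, so that spectral
    # congestion on minor isotopologues does not bias the ratio
    mono <- ion_mz(neutral_mass(cp), charges)
    zz <- charges[mono >= mz_range[1] & mono <= mz_range[2]]
    ap <- 0; av <- 0
    for (z in zz) {
      mp <- match_fragment(spectrum, cp, z, tol = tol,
                           min_consecutive = min_consecutive,
                           min_cosine = min_cosine)
      mv <- match_fragment(spectrum, cv, z, tol = tol,
                           min_consecutive = min_consecutive,
                           min_cosine = min_cosine)
      if (mp$accepted || mv$accepted) {
        ap <- ap + mp$abundance
        av <- av + mv$abundance
      }
    }
    defined <- (ap + av) > 0
    tibble::tibble(
      position = n,
      percent = if (defined) 100 * av / (av + ap) else NA_real_,
      parent_abundance = ap, variant_abundance = av,
      distinguishable = TRUE, defined = defined
    )
  })
}

#' Fit an observed envelope as a mixture of C/U-substituted isotopologue
#' patterns
#'
#' A C<->U interconversion shifts the monoisotopic mass by only 0.984 Da
#' (O vs NH), and the first carbon-13 isotopologue of the C form sits a mere
#' 0.019 Da above the monoisotopic peak of the U form, so the two envelopes
#' interfere rather than separate. The observed distribution is therefore
#' modelled as (1 - f) * parent + f * substitute: stage 1 solves
#' non-negative least squares on the two-column design of theoretical
#' patterns binned to a shared grid; stage 2 refines f by minimizing the
#' cosine distance between the mixture envelope and the observation.
#'
#' @param observed An `isotope_pattern` of observed peaks (charge attribute
#'   set), e.g. from [observed_envelope()].
#' @param parent_comp,substitute_comp `elem_comp`s differing by one C<->U
#'   (i.e. by O vs NH).
#' @return A `mixture_fit` list: `fraction_substitute`, `fit_cosine`,
#'   `nnls_fraction`, and a `residuals` tibble (grid m/z, observed and
#'   fitted abundances).
#' @export
fit_cu_mixture <- function(observed, parent_comp, substitute_comp) {
  z <- attr(observed, "charge")
  if (is.null(z) || z < 1) stop("observed pattern must carry a charge", call. = FALSE)
  delta <- unclass(substitute_comp) - unclass(parent_comp)
  ok <- all(delta == c(C = 0, H = 1, N = 1, O = -1, P = 0, S = 0)) ||
    all(delta == c(C = 0, H = -1, N = -1, O = 1, P = 0, S = 0))
  if (!ok) {
    stop("parent and substitute compositions must differ by one C<->U (O vs NH)",
         call. = FALSE)
  }
  pa <- isotope_distribution(parent_comp, z = z)
  pb <- isotope_distribution(substitute_comp, z = z)
  grid <- mixture_grid(pa$mz, pb$mz, z)
  A <- cbind(parent = bin_onto_grid(pa, grid, z),
             substitute = bin_onto_grid(pb, grid, z))
  if (sqrt(sum((A[, 1] / max(A[, 1]) - A[, 2] / max(A[, 2]))^2)) < 1e-9) {
    stop("degenerate design: parent and substitute patterns are identical",
         call. = FALSE)
  }
  b <- bin_observed(observed, grid, z)
  x <- nnls_two_column(A, b)
  f0 <- if (sum(x) > 0) x[2] / sum(x) else 0
  cos_of <- function(f) {
    mix <- (1 - f) * A[, 1] + f * A[, 2]
    cosine_score(mix, b)
  }
  opt <- stats::optimize(function(f) 1 - cos_of(f), interval = c(0, 1))
  f_hat <- if (1 - opt$objective >= cos_of(f0)) opt$minimum else f0
  fit_cos <- cos_of(f_hat)
  mix <- (1 - f_hat) * A[, 1] + f_hat * A[, 2]
  scale <- if (sum(mix^2) > 0) sum(mix * b) / sum(mix^2) else 0
  structure(list(
    fraction_substitute = unname(f_hat),
    fit_cosine = fit_cos,
    nnls_fraction = unname(f0),
    charge = z,
    residuals = tibble::tibble(mz = grid, observed = b, fitted = scale * mix)
  ), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> %.1f%% substitute / %.1f%% parent | fit cosine %.4f | %d-\n",
              100 * x$fraction_substitute, 100 * (1 - x$fraction_substitute),
              x$fit_cosine, x$charge))
  invisible(x)
}

# exact non-negative least squares for a two-column design: enumerate the
# active sets {both free, x1 = 0, x2 = 0, both 0} and keep the feasible
# candidate with the smallest residual (finite and deterministic, unlike
# iterative NNLS on near-degenerate envelopes)
nnls_two_column <- function(A, b) {
  cands <- list(c(0, 0))
  G <- crossprod(A)
  if (abs(det(G)) > 1e-12 * max(diag(G))^2) {
    free <- solve(G, crossprod(A, b))
    if (all(free >= 0)) cands <- c(cands, list(as.numeric(free)))
  }
  for (j in 1:2) {
    xj <- max(0, sum(A[, j] * b) / sum(A[, j]^2))
    x <- c(0, 0); x[j] <- xj
    cands <- c(cands, list(x))
  }
  resid <- vapply(cands, function(x) sum((b - A %*% x)^2), 0)
  cands[[which.min(resid)]]
}

# map observed peaks onto the shared theoretical grid (nearest grid point
# within the matching tolerance; grid spacing >= 0.2/z so each peak maps to
# at most one point)
bin_observed <- function(observed, grid, z, tol = 0.01) {
  b <- numeric(length(grid))
  for (i in seq_len(nrow(observed))) {
    j <- which.min(abs(grid - observed$mz[i]))
    if (abs(grid[j] - observed$mz[i]) <= tol) {
      b[j] <- b[j] + observed$abundance[i]
    }
  }
  b
}

#' Extract the observed envelope around a set of theoretical isotopologues
#'
#' Collects spectrum peaks lying within `tol` of any theoretical
#' isotopologue m/z of the given composition(s) at charge `z`.
#'
#' @param spectrum A centroided `spectrum`.
#' @param comps A list of `elem_comp`s whose envelopes delimit the window.
#' @param z Charge.
#' @param tol m/z tolerance (default 0.01).
#' @return An `isotope_pattern` with `origin = "observed"` (intensities,
#'   not normalized).
#' @export
observed_envelope <- function(spectrum, comps, z, tol = 0.01) {
  if (inherits(comps, "elem_comp")) comps <- list(comps)
  theo <- sort(unique(unlist(
    purrr::map(comps, function(cc) isotope_distribution(cc, z = z)$mz)
  )))
  keep <- purrr::map_lgl(spectrum$mz, function(m) any(abs(theo - m) <= tol))
  new_isotope_pattern(spectrum$mz[keep], spectrum$intensity[keep],
                      charge = as.integer(z), origin = "observed")
}

#' Site-wise C>U / U>C substitution profile across the spacer
#'
#' For every c_n fragment across the spacer, the observed envelope is fitted
#' as a mixture of the parent fragment and its C<->U-substituted counterpart
#' (one U replaced by C for `direction = "U>C"`, one C by U for `"C>U"`;
#' the fragment's isotopic pattern does not depend on which position within
#' the fragment is substituted). Because the parent ladder is known, charge
#' states whose substitute-diagnostic bins collide (within the matching
#' tolerance) with another theoretical fragment ion of the parent are
#' excluded as interfered rather than fitted; the surviving per-charge
#' fractions are combined by their median, which further discounts residual
#' congestion. Fits with mean cosine below `min_fit_cosine` are flagged low
#' confidence. A substitution at site s shows up as near-zero percentages
#' for n < s and a plateau near the variant's molar fraction for n >= s.
#'
#' @param spectrum A centroided `spectrum`.
#' @param parent Parent `oligo_seq`.
#' @param direction `"U>C"` or `"C>U"` (which substitute to test for).
#' @param positions Fragment indices (default 1..20 clipped).
#' @param charges Charge states to evaluate.
#' @param tol Matching tolerance.
#' @param min_fit_cosine Confidence flag threshold on the fit cosine.
#' @param mz_range Instrument window.
#' @return A tibble: `position`, `percent_substitute`, `fit_cosine`,
#'   `n_charges`, `low_confidence` (`percent_substitute` is NA where the
#'   fragment holds no substitutable base or no signal was found).
#' @export
cu_profile <- function(spectrum, parent, direction = c("U>C", "C>U"),
                       positions = seq_len(min(20L, nrow(parent) - 1L)),
                       charges = 1:7, tol = 0.01, min_fit_cosine = 0.95,
                       mz_range = c(100, 1310)) {
  direction <- match.arg(direction)
  from <- if (direction == "U>C") "U" else "C"
  delta_add <- if (direction == "U>C") elem_comp(H = 1, N = 1) else elem_comp(O = 1)
  delta_sub <- if (direction == "U>C") elem_comp(O = 1) else elem_comp(H = 1, N = 1)
  ladder <- ladder_peaks(parent, seq_len(min(20L, nrow(parent) - 1L)),
                         charges, mz_range)
  purrr::map_dfr(as.integer(positions), function(n) {
    empty <- tibble::tibble(position = n, percent_substitute = NA_real_,
                            fit_cosine = NA_real_, n_charges = 0L,
                            low_confidence = NA)
    if (!from %in% parent$base[1:n]) return(empty)
    cp <- fragment_comp(parent, "c", n)
    cs <- cp + delta_add - delta_sub
    mono <- ion_mz(neutral_mass(cp), charges)
    zz <- charges[mono >= mz_range[1] & mono <= mz_range[2]]
    fits <- list()
    for (z in zz) {
      if (substitute_bins_interfered(cp, cs, n, z, ladder, tol)) next
      obs <- observed_envelope(spectrum, list(cp, cs), z, tol = tol)
      if (nrow(obs) < 2) next
      fit <- fit_cu_mixture(obs, cp, cs)
      fits[[length(fits) + 1L]] <- fit
    }
    if (length(fits) == 0) return(empty)
    fr <- purrr::map_dbl(fits, "fraction_substitute")
    fc <- purrr::map_dbl(fits, "fit_cosine")
    tibble::tibble(
      position = n,
      percent_substitute = 100 * stats::median(fr),
      fit_cosine = mean(fc),
      n_charges = length(fits),
      low_confidence = mean(fc) < min_fit_cosine
    )
  })
}

# all theoretical isotopologue peaks of the parent's c-ion ladder (above 1%
# relative abundance), tagged by (index, charge)
ladder_peaks <- function(parent, indices, charges, mz_range) {
  rows <- list()
  for (i in indices) {
    comp <- fragment_comp(parent, "c", i)
    pat0 <- isotope_distribution(comp, z = 0L)
    mono <- ion_mz(neutral_mass(comp), charges)
    for (z in charges[mono >= mz_range[1] & mono <= mz_range[2]]) {
      keep <- pat0$abundance >= 0.01
      rows[[length(rows) + 1L]] <- tibble::tibble(
        index = i, charge = z, mz = ion_mz(pat0$mz[keep], z)
      )
    }
  }
  dplyr::bind_rows(rows)
}

# TRUE when a bin that only the substitute populates falls within the
# matching tolerance of a theoretical peak of some *other* parent fragment
# ion -- such a charge state cannot distinguish a genuine substitution from
# ladder congestion
substitute_bins_interfered <- function(cp, cs, n, z, ladder, tol) {
  pa <- isotope_distribution(cp, z = z)
  pb <- isotope_distribution(cs, z = z)
  grid <- mixture_grid(pa$mz, pb$mz, z)
  A <- cbind(bin_onto_grid(pa, grid, z), bin_onto_grid(pb, grid, z))
  diagnostic <- grid[A[, 2] > 0.02 * max(A[, 2]) & A[, 1] < 1e-3 * max(A[, 1])]
  if (length(diagnostic) == 0) return(FALSE)
  foreign <- ladder$mz[!(ladder$index == n & ladder$charge == z)]
  any(vapply(diagnostic, function(m) any(abs(foreign - m) <= tol), TRUE))
}

#' Mean substitution percentage downstream of a designated site
#'
#' Averages the [cu_profile()] percentages over positions `site..max`, the
#' region whose c-fragments contain the substituted base.
#'
#' @param profile A [cu_profile()] result.
#' @param site Substitution site.
#' @return A one-row tibble: `site`, `mean_percent`, `n_positions`.
#' @export
cu_site_summary <- function(profile, site) {
  sub <- profile[profile$position >= site & !is.na(profile$percent_substitute), ]
  tibble::tibble(site = site,
                 mean_percent = mean(sub$percent_substitute),
                 n_positions = nrow(sub))
}
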