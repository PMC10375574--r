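#' Theoretical isotopic distribution of a composition
#'
#' Aggregated (nucleon-binned) isotopologue abundances are computed by
#' per-element convolution of the natural isotope vectors, using
#' exponentiation-by-squaring over atom counts. Fine structure within a
#' nucleon bin is collapsed to an abundance-weighted centroid mass, which is
#' adequate at QTOF resolution (matching tolerance 0.01 m/z). Peaks below
#' `prune` of the maximum are dropped; abundances are normalized so the most
#' abundant peak is 1.
#'
#' @param comp An `elem_comp` (non-empty).
#' @param z Charge magnitude for the deprotonated negative ion; `z = 0`
#'   returns the neutral pattern (mz column holds neutral isotopologue mass).
#' @param prune Relative abundance cutoff (default 1e-4).
#'
#' @return An `isotope_pattern`: a tibble with columns `mz` and `abundance`
#'   (max-normalized), with attributes `charge` and `origin = "theoretical"`.
#' @examples
#' isotope_distribution(elem_comp(C = 100), z = 1)
#' @export
isotope_distribution <- function(comp, z = 0L, prune = 1e-4) {
  if (is_empty_comp(comp)) stop("empty composition", call. = FALSE)
  key <- paste(format_comp(comp), prune)
  agg <- .iso_cache[[key]]
  if (is.null(agg)) {
    agg <- neutral_isotopologues(comp, prune = prune)
    .iso_cache[[key]] <- agg
  }
  mz <- if (z >= 1) ion_mz(agg$mass, z) else agg$mass
  new_isotope_pattern(mz, agg$abundance / max(agg$abundance),
                      charge = as.integer(z), origin = "theoretical")
}

# memo of neutral aggregated distributions, keyed by formula + prune level
.iso_cache <- new.env(parent = emptyenv())

new_isotope_pattern <- function(mz, abundance, charge, origin) {
  out <- tibble::tibble(mz = mz, abundance = abundance)
  class(out) <- c("isotope_pattern", class(out))
  attr(out, "charge") <- charge
  attr(out, "origin") <- origin
  out
}

# Neutral aggregated isotopologue list: nucleon offset k -> (probability,
# centroided exact mass). Probabilities over the full (unpruned) distribution
# sum to 1; pruning is applied last.
neutral_isotopologues <- function(comp, prune = 1e-4) {
  dist <- list(prob = 1.0, mass = 0.0)  # indexed by nucleon offset 0,1,2,...
  for (el in .ELEMENTS) {
    n <- unclass(comp)[[el]]
    if (n == 0) next
    iso <- .ISOTOPES[[el]]
    base <- list(prob = numeric(max(iso$offset) + 1L),
                 mass = numeric(max(iso$offset) + 1L))
    base$prob[iso$offset + 1L] <- iso$abundance
    base$mass[iso$offset + 1L] <- iso$mass
    dist <- dist_convolve(dist, dist_power(base, n))
  }
  # contiguous run from the first to the last bin above the pruning cutoff,
  # so adjacent peaks stay ~1 nucleon apart
  keep <- which(dist$prob > prune * max(dist$prob))
  idx <- seq(min(keep), max(keep))
  idx <- idx[dist$prob[idx] > 0]
  list(abundance = dist$prob[idx], mass = dist$mass[idx] / dist$prob[idx])
}

# distributions are stored with mass as the probability-weighted *sum*
# (prob * centroid), so convolution is linear in both fields
dist_convolve <- function(a, b, tail_prune = 1e-12) {
  na <- length(a$prob); nb <- length(b$prob)
  prob <- numeric(na + nb - 1L)
  mass <- numeric(na + nb - 1L)
  for (i in seq_len(na)) {
    if (a$prob[i] == 0) next
    j <- seq_len(nb)
    prob[i + j - 1L] <- prob[i + j - 1L] + a$prob[i] * b$prob[j]
    mass[i + j - 1L] <- mass[i + j - 1L] +
      a$prob[i] * b$prob[j] * (mass_centroid(a, i) + mass_centroid(b, j))
  }
  trim_tail(list(prob = prob, mass = mass), tail_prune)
}

mass_centroid <- function(d, i) ifelse(d$prob[i] > 0, d$mass[i] / d$prob[i], 0)

trim_tail <- function(d, tail_prune) {
  keep <- d$prob > tail_prune * max(d$prob)
  last <- max(which(keep))
  list(prob = d$prob[1:last], mass = d$mass[1:last])
}

dist_power <- function(base, n) {
  # base has mass as centroid; convert to weighted-sum convention
  acc <- NULL
  cur <- list(prob = base$prob, mass = base$prob * base$mass)
  while (n > 0) {
    if (n %% 2 == 1) {
      acc <- if (is.null(acc)) cur else dist_convolve(acc, cur)
    }
    n <- n %/% 2
    if (n > 0) cur <- dist_convolve(cur, cur)
  }
  acc
}

#' Mixture of two isotopic distributions
#'
#' Merges the peaks of two same-charge patterns on a shared m/z grid (bin
#' width 0.2/z, below half the isotopologue spacing) and combines abundances
#' as (1 - f) * a + f * b before renormalizing to max = 1. Used to model the
#' distorted envelopes produced by C/U substitution impurities, whose
#' first-isotope interference sits only ~0.019/z from the lighter species'
#' monoisotopic peak.
#'
#' @param a,b `isotope_pattern`s at the same charge.
#' @param f Fraction of `b`, in `[0, 1]`.
#' @return An `isotope_pattern` on the merged grid.
#' @export
mixture_distribution <- function(a, b, f) {
  za <- attr(a, "charge"); zb <- attr(b, "charge")
  if (!identical(za, zb)) stop("charge mismatch between patterns", call. = FALSE)
  if (f < 0 || f > 1) stop("mixture fraction must be in [0, 1]", call. = FALSE)
  z <- max(1L, za)
  grid <- mixture_grid(a$mz, b$mz, z)
  ab <- (1 - f) * bin_onto_grid(a, grid, z) + f * bin_onto_grid(b, grid, z)
  keep <- ab > 0
  new_isotope_pattern(grid[keep], ab[keep] / max(ab), charge = za,
                      origin = "theoretical")
}

mixture_grid <- function(mza, mzb, z) {
  width <- 0.2 / z
  pts <- sort(c(mza, mzb))
  grid <- pts[1]
  for (p in pts[-1]) {
    if (p - grid[length(grid)] > width) grid <- c(grid, p)
  }
  grid
}

bin_onto_grid <- function(pattern, grid, z) {
  out <- numeric(length(grid))
  for (i in seq_len(nrow(pattern))) {
    j <- which.min(abs(grid - pattern$mz[i]))
    if (abs(grid[j] - pattern$mz[i]) <= 0.2 / z) {
      out[j] <- out[j] + pattern$abundance[i]
    }
  }
  out
}
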