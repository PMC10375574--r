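#' Spectrum containers
#'
#' A spectrum is a tibble of peaks with columns `mz` and `intensity`, sorted
#' by m/z, carrying a `mode` attribute (`"profile"` or `"centroid"`).
#'
#' @param mz,intensity Numeric vectors.
#' @param mode `"centroid"` or `"profile"`.
#' @return A `spectrum` tibble.
#' @export
new_spectrum <- function(mz, intensity, mode = "centroid") {
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (length(mz) && any(mz <= 0)) stop("m/z values must be > 0", call. = FALSE)
  ord <- order(mz)
  out <- tibble::tibble(mz = as.numeric(mz[ord]),
                        intensity = as.numeric(intensity[ord]))
  class(out) <- c("spectrum", class(out))
  attr(out, "mode") <- mode
  out
}

spectrum_mode <- function(x) attr(x, "mode") %||% "centroid"

#' Read MS/MS scans from a TSV peak list or an mzML file
#'
#' The native TSV dialect is two tab-separated columns (mz, intensity);
#' multiple scans are separated by blank lines, and lines starting with `#`
#' are comments. mzML files are read through the `mzR` package.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"`, or `"mzml"`.
#' @param mode Peak mode to stamp on TSV scans (mzML metadata decides for
#'   mzML input).
#' @return A list of `spectrum` objects, in scan order.
#' @export
load_spectra <- function(path, format = c("auto", "tsv", "mzml"),
                         mode = "centroid") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "tsv"
  }
  if (format == "mzml") return(load_mzml(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  blank <- !nzchar(trimws(lines))
  if (all(blank)) stop("empty spectrum file: ", path, call. = FALSE)
  scan_id <- cumsum(c(TRUE, blank[-length(blank)] & !blank[-1]))
  scans <- split(lines[!blank], scan_id[!blank])
  purrr::map(unname(scans), function(block) {
    fields <- strsplit(block, "\t| +")
    bad <- which(purrr::map_int(fields, length) < 2)
    if (length(bad)) {
      stop(sprintf("malformed peak record '%s' in %s", block[bad[1]], path),
           call. = FALSE)
    }
    mz <- suppressWarnings(as.numeric(purrr::map_chr(fields, 1)))
    it <- suppressWarnings(as.numeric(purrr::map_chr(fields, 2)))
    if (anyNA(mz) || anyNA(it)) {
      bad <- which(is.na(mz) | is.na(it))[1]
      stop(sprintf("malformed peak record '%s' in %s", block[bad], path),
           call. = FALSE)
    }
    new_spectrum(mz, it, mode = mode)
  })
}

load_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the 'mzR' package", call. = FALSE)
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  purrr::map2(pk, seq_along(pk), function(m, i) {
    centroided <- isTRUE(hdr$centroided[i])
    new_spectrum(m[, 1], m[, 2],
                 mode = if (centroided) "centroid" else "profile")
  })
}

#' Write a spectrum (or scans) to the TSV peak-list format
#'
#' @param spectra A `spectrum` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spectra, path) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(spectra)) {
    if (i > 1) writeLines("", con)
    writeLines(sprintf("%.6f\t%.6f", spectra[[i]]$mz, spectra[[i]]$intensity),
               con)
  }
  invisible(path)
}

#' Average, centroid and filter MS/MS scans
#'
#' Mirrors the averaged-QTOF preprocessing used for top-down guide RNA
#' spectra: scans are averaged (point-wise for profile data on a shared
#' axis; by pooling peaks within `pool_width` m/z for centroided data),
#' profile data are centroided by local-maximum detection with an
#' intensity-weighted centroid over contiguous above-baseline points, then
#' peaks below the noise floor and above the precursor-region m/z cutoff
#' are removed.
#'
#' @param scans A `spectrum` or list of scans.
#' @param noise_floor Minimum signal count retained (default 500).
#' @param mz_max Peaks above this m/z are discarded (default 1310, excluding
#'   the uninformative surviving-precursor region).
#' @param pool_width m/z window for pooling centroided peaks while averaging
#'   (default 0.005, below the 0.01 matching tolerance).
#' @return A centroided, filtered `spectrum`.
#' @export
preprocess <- function(scans, noise_floor = 500, mz_max = 1310,
                       pool_width = 0.005) {
  if (inherits(scans, "spectrum")) scans <- list(scans)
  if (length(scans) == 0) stop("no scans to preprocess", call. = FALSE)
  modes <- purrr::map_chr(scans, spectrum_mode)
  if (all(modes == "profile")) {
    avg <- average_profile(scans)
    cen <- centroid_profile(avg)
  } else {
    cen <- pool_centroids(scans, pool_width)
  }
  keep <- cen$intensity >= noise_floor & cen$mz <= mz_max
  new_spectrum(cen$mz[keep], cen$intensity[keep], mode = "centroid")
}

average_profile <- function(scans) {
  axis <- scans[[1]]$mz
  compatible <- purrr::every(scans, function(s) {
    nrow(s) == length(axis) && max(abs(s$mz - axis)) < 1e-9
  })
  if (!compatible) stop("profile scans are not on a shared m/z axis", call. = FALSE)
  it <- Reduce(`+`, purrr::map(scans, "intensity")) / length(scans)
  new_spectrum(axis, it, mode = "profile")
}

# local-maximum centroiding: contiguous runs of points above baseline become
# one peak at the intensity-weighted mean m/z with the summed intensity
centroid_profile <- function(spec, baseline = 0) {
  above <- spec$intensity > baseline
  if (!any(above)) return(new_spectrum(numeric(), numeric(), mode = "centroid"))
  run <- cumsum(c(above[1], diff(above) == 1))
  run[!above] <- NA
  groups <- split(which(above), run[above])
  mz <- purrr::map_dbl(groups, function(i) {
    sum(spec$mz[i] * spec$intensity[i]) / sum(spec$intensity[i])
  })
  it <- purrr::map_dbl(groups, function(i) max(spec$intensity[i]))
  new_spectrum(mz, it, mode = "centroid")
}

pool_centroids <- function(scans, pool_width) {
  all <- dplyr::bind_rows(purrr::map(scans, function(s) s[, c("mz", "intensity")]))
  all <- dplyr::arrange(all, .data$mz)
  if (nrow(all) == 0) return(new_spectrum(numeric(), numeric()))
  all$grp <- cumsum(c(1, diff(all$mz) > pool_width))
  pooled <- dplyr::summarise(
    dplyr::group_by(all, .data$grp),
    mzc = sum(.data$mz * .data$intensity) / sum(.data$intensity),
    it = sum(.data$intensity) / length(scans),
    .groups = "drop"
  )
  new_spectrum(pooled$mzc, pooled$it, mode = "centroid")
}
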