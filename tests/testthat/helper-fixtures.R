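# Shared fixtures: guides, cached simulated spectra, and a minimal mzML
# writer for round-trip tests. Everything is generated in code.

.guides <- example_guides()
.spacers <- example_guides(spacer_only = TRUE)

guide <- function(name) .guides$oligo[[match(name, .guides$name)]]
spacer_string <- function(name) .spacers$sequence[match(name, .spacers$name)]

# simulated spectra are expensive enough to share across tests
.spec_cache <- new.env(parent = emptyenv())

sim_spec <- function(key, cfg, noise_floor = 500) {
  if (is.null(.spec_cache[[key]])) {
    .spec_cache[[key]] <- preprocess(simulate_msms(cfg),
                                     noise_floor = noise_floor)
  }
  .spec_cache[[key]]
}

# clean (noise- and jitter-free) single-component spectrum
clean_spec <- function(name, seed = 1L, indices = NULL) {
  key <- paste0("clean_", name, "_", seed, "_", paste(range(indices %||% 0),
                                                      collapse = "-"))
  sim_spec(key, sim_config(guide(name), indices = indices, noise_peaks = 0,
                           jitter_sd = 0, seed = seed), noise_floor = 0)
}

# default-condition mixture spectrum: parent + variant at fraction f
mix_spec <- function(parent, variant, f, seed = 42L) {
  key <- sprintf("mix_%s_%s_%g_%d", parent, variant, f, seed)
  comp <- tibble::tibble(oligo = list(guide(parent), guide(variant)),
                         fraction = c(1 - f, f))
  sim_spec(key, sim_config(comp, seed = seed))
}

# minimal uncompressed 64-bit mzML, enough for the mzR reader
write_test_mzml <- function(scans, path) {
  enc <- function(x) {
    jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                  endian = "little"))
  }
  arr <- function(x, acc, nm) {
    b <- enc(x)
    sprintf(paste0(
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="%s" name="%s" value=""/>',
      '<binary>%s</binary></binaryDataArray>'), nchar(b), acc, nm, b)
  }
  one <- function(i, s) {
    sprintf(paste0(
      '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">\n',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="2"/>\n',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>\n',
      '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan" value=""/>\n',
      '<binaryDataArrayList count="2">\n%s\n%s\n</binaryDataArrayList></spectrum>'),
      i - 1L, i, nrow(s),
      arr(s$mz, "MS:1000514", "m/z array"),
      arr(s$intensity, "MS:1000515", "intensity array"))
  }
  body <- paste(mapply(one, seq_along(scans), scans), collapse = "\n")
  writeLines(sprintf(paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="1"><cv id="MS" fullName="PSI-MS" URI="http://psidev.info"/></cvList>\n',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>',
    '</fileContent></fileDescription>\n',
    '<run id="run1">\n<spectrumList count="%d">\n%s\n</spectrumList>\n</run>\n</mzML>'),
    length(scans), body), path)
  path
}

# brute-force isotopologue oracle: enumerate every per-atom isotope
# assignment of a tiny composition and aggregate by nucleon count
brute_force_isotopologues <- function(comp) {
  v <- unclass(comp)
  atoms <- rep(names(v), v)
  iso <- spacerms:::.ISOTOPES
  choices <- lapply(atoms, function(el) seq_along(iso[[el]]$abundance))
  grid <- expand.grid(choices)
  agg <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(grid))) {
    p <- 1; off <- 0L; m <- 0
    for (a in seq_along(atoms)) {
      el <- iso[[atoms[a]]]
      j <- grid[r, a]
      p <- p * el$abundance[j]
      off <- off + el$offset[j]
      m <- m + el$mass[j]
    }
    key <- as.character(off)
    prev <- agg[[key]] %||% c(0, 0)
    agg[[key]] <- c(prev[1] + p, prev[2] + p * m)
  }
  offs <- sort(as.integer(ls(agg)))
  tibble::tibble(
    offset = offs,
    abundance = vapply(offs, function(o) agg[[as.character(o)]][1], 0),
    mass = vapply(offs, function(o) {
      x <- agg[[as.character(o)]]
      x[2] / x[1]
    }, 0)
  )
}
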