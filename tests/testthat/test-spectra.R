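test_that("TSV peak lists round-trip and split into scans", {
  path <- withr::local_tempfile(fileext = ".tsv")
  s1 <- new_spectrum(c(100.123456, 200.5), c(1000, 2000))
  s2 <- new_spectrum(c(150.25), c(700))
  write_spectrum_tsv(list(s1, s2), path)
  back <- load_spectra(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$mz, s1$mz, tolerance = 1e-6)
  expect_equal(back[[2]]$intensity, s2$intensity, tolerance = 1e-6)
})

test_that("malformed and empty spectrum files raise informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("100.0\t10", "not-a-peak"), path)
  expect_error(load_spectra(path), "not-a-peak")
  writeLines(character(0), path)
  expect_error(load_spectra(path), "empty")
  expect_error(load_spectra("/nonexistent/file.tsv"), "not found")
})

test_that("mzML files written externally are read scan-by-scan", {
  skip_if_not_installed("mzR")
  path <- withr::local_tempfile(fileext = ".mzML")
  s1 <- new_spectrum(c(100.5, 200.25, 300.125), c(1000, 2000, 600))
  s2 <- new_spectrum(c(150.1, 250.2), c(700, 800))
  write_test_mzml(list(s1, s2), path)
  back <- suppressWarnings(load_spectra(path))
  expect_length(back, 2)
  expect_equal(back[[1]]$mz, s1$mz, tolerance = 1e-9)
  expect_equal(back[[2]]$intensity, s2$intensity, tolerance = 1e-9)
})

test_that("preprocess applies the noise-floor and precursor-region rules", {
  s <- new_spectrum(c(500.0, 600.0, 1309.9, 1310.1),
                    c(499, 501, 1e4, 1e6))
  out <- preprocess(s)
  expect_equal(out$mz, c(600.0, 1309.9))
  expect_equal(out$intensity, c(501, 1e4))
  # empty after filtering is fine
  empty <- preprocess(new_spectrum(c(50), c(10)))
  expect_equal(nrow(empty), 0)
  expect_error(preprocess(list()), "no scans")
})

test_that("preprocess is idempotent on centroided, filtered input", {
  spec <- mix_spec("gRNA_X", "gRNA_XA", 0.1)
  again <- preprocess(spec)
  expect_equal(again$mz, spec$mz)
  expect_equal(again$intensity, spec$intensity)
})

test_that("profile scans average point-wise and centroid at weighted maxima", {
  axis <- seq(99.9, 100.4, by = 0.01)
  shape <- exp(-((axis - 100.15)^2) / (2 * 0.02^2))
  s1 <- new_spectrum(axis, 2000 * shape, mode = "profile")
  s2 <- new_spectrum(axis, 1000 * shape, mode = "profile")
  out <- preprocess(list(s1, s2), noise_floor = 100)
  expect_equal(nrow(out), 1)
  expect_equal(out$mz, 100.15, tolerance = 1e-3)
  expect_equal(out$intensity, 1500, tolerance = 1)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(guide("gRNA_X"), seed = 99)
  a <- simulate_msms(cfg)
  b <- simulate_msms(cfg)
  expect_identical(a$mz, b$mz)
  expect_identical(a$intensity, b$intensity)
})

test_that("component fractions must sum to one", {
  comp <- tibble::tibble(oligo = list(guide("gRNA_X"), guide("gRNA_XA")),
                         fraction = c(0.8, 0.1))
  expect_error(sim_config(comp), "sum to 1")
})

test_that("a clean simulated ladder yields full spacer assignment downstream", {
  spec <- clean_spec("gRNA_X")
  cov <- sequence_coverage(spec, guide("gRNA_X"), "spacer", indices = 1:20)
  expect_equal(cov$percent, 100)
})

test_that("fragment intensity ratios track molar fractions as noise vanishes", {
  f <- 0.25
  comp <- tibble::tibble(oligo = list(guide("gRNA_X"), guide("gRNA_XA")),
                         fraction = c(1 - f, f))
  cfg <- sim_config(comp, noise_peaks = 0, jitter_sd = 0, seed = 5)
  spec <- preprocess(simulate_msms(cfg), noise_floor = 0)
  q <- quantify_variant_sites(spec, guide("gRNA_X"), guide("gRNA_XA"),
                              positions = c(2, 5, 10))
  expect_true(all(abs(q$percent - 100 * f) < 1))
})

test_that("a 1% variant's diagnostic fragment rises above the noise floor", {
  spec <- mix_spec("gRNA_X", "gRNA_XA", 0.01)
  c2 <- fragment_series(guide("gRNA_XA"), "c", 2)
  mono <- ion_mz(c2$neutral_mono_mass, 1)
  near <- spec[abs(spec$mz - mono) < 0.01, ]
  expect_true(nrow(near) >= 1 && max(near$intensity) > 500)
})

test_that("the precursor region option adds signal that preprocessing removes", {
  cfg <- sim_config(guide("gRNA_X"), precursor_region = TRUE, seed = 4)
  raw <- simulate_msms(cfg)
  expect_true(any(raw$mz > 1310))
  expect_true(all(preprocess(raw)$mz <= 1310))
})
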