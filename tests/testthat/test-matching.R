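test_that("cosine similarity behaves as the standard scale-invariant score", {
  expect_equal(cosine_score(c(1, 0.5, 0.2), c(1, 0.5, 0.2)), 1)
  expect_equal(cosine_score(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_score(c(1, 0.5), c(1, 0.6)), 0.99705, tolerance = 1e-4)
  expect_equal(cosine_score(c(1, 0.5), 10 * c(1, 0.6)),
               cosine_score(c(1, 0.5), c(1, 0.6)))
  expect_equal(cosine_score(c(0, 0), c(0, 0)), 0)
})

test_that("a clean simulated fragment matches with near-perfect cosine", {
  spec <- clean_spec("gRNA_X")
  c5 <- fragment_series(guide("gRNA_X"), "c", 5)$composition[[1]]
  m <- match_fragment(spec, c5, z = 2)
  expect_true(m$accepted)
  expect_gt(m$cosine, 0.99)
  expect_lt(abs(m$mass_error), 0.01)
  expect_gt(m$abundance, 0)
})

test_that("displaced peaks and lone monoisotopic peaks are rejected", {
  c5 <- fragment_series(guide("gRNA_X"), "c", 5)$composition[[1]]
  pat <- isotope_distribution(c5, z = 2)
  # every peak displaced beyond tolerance
  off <- new_spectrum(pat$mz + 0.02, pat$abundance * 1e4)
  m <- match_fragment(off, c5, z = 2)
  expect_false(m$accepted)
  # only the monoisotopic peak present: fails the consecutive-isotope rule
  lone <- new_spectrum(pat$mz[1], 1e4)
  m2 <- match_fragment(lone, c5, z = 2)
  expect_false(m2$accepted)
  expect_equal(m2$reason, "too_few_consecutive_isotopes")
})

test_that("match decisions are invariant under global intensity scaling", {
  spec <- mix_spec("gRNA_X", "gRNA_XB", 0.1)
  scaled <- new_spectrum(spec$mz, spec$intensity * 37)
  a <- search_fragments(spec, guide("gRNA_X"), indices = 1:20)
  b <- search_fragments(scaled, guide("gRNA_X"), indices = 1:20)
  expect_equal(nrow(a), nrow(b))
  expect_equal(b$abundance, a$abundance * 37)
  expect_equal(a$cosine, b$cosine)
})

test_that("spacer coverage counts supported cleavage sites", {
  x <- guide("gRNA_X")
  spec <- clean_spec("gRNA_X")
  cov <- sequence_coverage(spec, x, "spacer", indices = 1:20)
  expect_equal(cov$percent, 100)
  expect_equal(nrow(cov$positions), 20)
  # empty spectrum: zero coverage, no error
  cov0 <- sequence_coverage(new_spectrum(numeric(), numeric()), x, "spacer")
  expect_equal(cov0$percent, 0)
  # half ladder: 50%
  half <- sim_config(x, indices = 1:10, noise_peaks = 0, jitter_sd = 0,
                     seed = 2)
  spec_half <- preprocess(simulate_msms(half), noise_floor = 0)
  cov_half <- sequence_coverage(spec_half, x, "spacer", indices = 1:20)
  expect_equal(cov_half$percent, 50)
})

test_that("full-length mode finds c and y ladders over wide charge ranges", {
  o <- parse_oligo("C(ms)A(ms)G(ms)GUUCCAUGC")
  cfg <- sim_config(o, ion_types = c("c", "y"), indices = 1:11,
                    noise_peaks = 0, jitter_sd = 0, seed = 8)
  spec <- preprocess(simulate_msms(cfg), noise_floor = 0)
  cov <- sequence_coverage(spec, o, "full", charges = 1:10)
  expect_equal(cov$percent, 100)
  expect_setequal(unique(cov$matches$ion_type), c("c", "y"))
})

test_that("decoy offsets number 40 and clean spectra give near-zero FDR", {
  spec <- clean_spec("gRNA_X")
  fdr <- estimate_fdr(spec, guide("gRNA_X"), indices = 1:20)
  expect_equal(nrow(fdr$offsets), 40)
  expect_false(fdr$undefined)
  # a dense c-ion ladder leaves a small residual decoy rate where shifted
  # broad envelopes re-align with real ones near integer isotopologue
  # offsets; the cosine threshold keeps it to a few percent
  expect_lt(fdr$fdr, 0.05)
  no_thr <- estimate_fdr(spec, guide("gRNA_X"), indices = 1:20,
                         min_cosine = 0)
  expect_lt(fdr$fdr, no_thr$fdr)
})

test_that("FDR is flagged undefined without target hits", {
  fdr <- estimate_fdr(new_spectrum(numeric(), numeric()), guide("gRNA_X"),
                      indices = 1:3, offset_max = 100, step = 50)
  expect_true(fdr$undefined)
  expect_true(is.na(fdr$fdr))
})

test_that("raising the cosine threshold never increases the decoy FDR", {
  spec <- mix_spec("gRNA_X", "gRNA_XB", 0.1)
  x <- guide("gRNA_X")
  fdrs <- vapply(c(0.0, 0.5, 0.8, 0.95), function(thr) {
    estimate_fdr(spec, x, indices = 1:20, offset_max = 300, step = 100,
                 min_cosine = thr)$fdr
  }, 0)
  expect_true(all(diff(fdrs) <= 1e-12))
  # and the 0.80 threshold retains every planted spacer fragment site
  cov <- sequence_coverage(spec, x, "spacer", indices = 1:20)
  expect_equal(cov$percent, 100)
})
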