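test_that("the discovery score follows the coverage-squared rule", {
  # one matched unique fragment, abundance 1000, cosine 0.9, full coverage
  # of a one-position unique region -> 1^2 * 1000 * 0.81 = 810
  x <- guide("gRNA_X")
  c20 <- fragment_series(x, "c", 20)$composition[[1]]
  pat <- isotope_distribution(c20, z = 7)
  spec <- new_spectrum(pat$mz, pat$abundance * 1000)
  m <- match_fragment(spec, c20, z = 7)
  expect_true(m$accepted)
  score <- (1)^2 * m$abundance * m$cosine^2
  expect_equal(score, 1000 * m$cosine^2, tolerance = 1e-6)
  expect_gt(score, 810 - 15)  # cosine ~1 here; 0.9 would give exactly 810
})

test_that("a 10% planted G>A variant is discovered and localized", {
  spec <- mix_spec("gRNA_X", "gRNA_XB", 0.1)
  sc <- score_substitutions(spec, guide("gRNA_X"))
  expect_equal(sc$position[1], 11)
  expect_equal(sc$from_base[1], "G")
  expect_equal(sc$to_base[1], "A")
  types <- substitution_type_summary(sc)
  expect_equal(paste(types$from_base[1], types$to_base[1]), "G A")
  # the G>A type dominates every other substitution type by a wide margin
  expect_gt(types$score[1], 10 * max(types$score[-1], 1e-12))
  # C/U interconversions are excluded from discovery output
  expect_false(any(sc$from_base == "C" & sc$to_base == "U"))
  expect_false(any(sc$from_base == "U" & sc$to_base == "C"))
})

test_that("discovery scores grow with matched abundance and cosine", {
  x <- guide("gRNA_X")
  c15 <- fragment_series(x, "c", 15)$composition[[1]]
  pat <- isotope_distribution(c15, z = 5)
  base <- new_spectrum(pat$mz, pat$abundance * 2000)
  m1 <- match_fragment(base, c15, z = 5)
  stronger <- new_spectrum(pat$mz, pat$abundance * 4000)
  m2 <- match_fragment(stronger, c15, z = 5)
  expect_gte(m2$abundance * m2$cosine^2, m1$abundance * m1$cosine^2)
})

test_that("site quantitation recovers spiked fractions and flags shared masses", {
  x <- guide("gRNA_X")
  # 50:50 with the position-2 variant
  f <- 0.5
  comp <- tibble::tibble(oligo = list(x, guide("gRNA_XA")),
                         fraction = c(1 - f, f))
  spec <- preprocess(simulate_msms(sim_config(comp, noise_peaks = 0,
                                              jitter_sd = 0, seed = 21)),
                     noise_floor = 0)
  q <- quantify_variant_sites(spec, x, guide("gRNA_XA"), positions = c(2, 5))
  expect_true(all(abs(q$percent - 50) < 1))
  # the position-11 variant shares c_5 with the parent: indistinguishable
  q5 <- quantify_variant_sites(spec, x, guide("gRNA_XB"), positions = 5)
  expect_false(q5$distinguishable)
  expect_true(is.na(q5$percent))
  # 0% spike: nothing at any unique position
  pure <- clean_spec("gRNA_X")
  q0 <- quantify_variant_sites(pure, x, guide("gRNA_XA"),
                               positions = c(2, 5, 10))
  expect_true(all(q0$percent[q0$defined] == 0))
})

test_that("noiseless C/U mixture fits recover the fraction within 0.02", {
  cp <- fragment_series(guide("gRNA_X"), "c", 5)$composition[[1]]
  cs <- fragment_series(guide("gRNA_XD"), "c", 5)$composition[[1]]
  pa <- isotope_distribution(cp, z = 2)
  pb <- isotope_distribution(cs, z = 2)
  for (f in c(0, 0.01, 0.05, 0.1, 0.5)) {
    obs <- mixture_distribution(pa, pb, f)
    fit <- fit_cu_mixture(obs, cp, cs)
    expect_lt(abs(fit$fraction_substitute - f), 0.02)
    expect_gt(fit$fit_cosine, 0.999)
  }
  # pure parent observed: fraction ~0
  fit0 <- fit_cu_mixture(pa, cp, cs)
  expect_lt(fit0$fraction_substitute, 0.01)
})

test_that("mixture fitting validates its inputs", {
  cp <- fragment_series(guide("gRNA_X"), "c", 5)$composition[[1]]
  cs <- fragment_series(guide("gRNA_XD"), "c", 5)$composition[[1]]
  pa <- isotope_distribution(cp, z = 2)
  # not a C<->U pair
  other <- fragment_series(guide("gRNA_X"), "c", 6)$composition[[1]]
  expect_error(fit_cu_mixture(pa, cp, other), "C<->U")
  # neutral pattern carries no charge
  neutral <- isotope_distribution(cp, z = 0)
  expect_error(fit_cu_mixture(neutral, cp, cs), "charge")
})

test_that("the spacer-wide U>C profile localizes the substituted site", {
  spec <- mix_spec("gRNA_X", "gRNA_XD", 0.5, seed = 42)
  prof <- cu_profile(spec, guide("gRNA_X"), "U>C")
  # positions 1-4 hold no U: no U>C test is possible there
  expect_true(all(is.na(prof$percent_substitute[prof$position <= 4])))
  plateau <- prof$percent_substitute[prof$position >= 5]
  expect_true(all(abs(plateau - 50) < 15))
  summ <- cu_site_summary(prof, 5)
  expect_lt(abs(summ$mean_percent - 50), 5)
})

test_that("an unspiked clean spectrum yields a near-zero C/U profile", {
  spec <- clean_spec("gRNA_X")
  prof <- cu_profile(spec, guide("gRNA_X"), "U>C")
  vals <- prof$percent_substitute[!is.na(prof$percent_substitute)]
  expect_true(all(vals < 2))
})

test_that("the inverse spike direction shows a rising C>U profile", {
  spec <- mix_spec("gRNA_XD", "gRNA_X", 0.5, seed = 43)
  prof <- cu_profile(spec, guide("gRNA_XD"), "C>U")
  before <- prof$percent_substitute[prof$position < 5 &
                                      !is.na(prof$percent_substitute)]
  after <- prof$percent_substitute[prof$position >= 5 &
                                     !is.na(prof$percent_substitute)]
  expect_true(all(before < 10))
  expect_lt(abs(mean(after) - 50), 10)
})
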