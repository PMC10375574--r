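test_that("de novo ranks the true spacer first for every bundled guide", {
  spacers <- example_guides(spacer_only = TRUE)
  for (nm in .guides$name) {
    spec <- clean_spec(nm)
    scaf <- mod_scaffold(oligo = guide(nm)[1:20, ])
    dn <- denovo_spacer(spec, scaf)
    expect_gt(nrow(dn), 0)
    expect_identical(dn$sequence[1],
                     spacers$sequence[match(nm, spacers$name)])
    expect_equal(dn$coverage[1], 1)
  }
})

test_that("a spectrum without c-ions yields no de novo candidates", {
  scaf <- mod_scaffold(oligo = guide("gRNA_X")[1:20, ])
  dn <- denovo_spacer(new_spectrum(numeric(), numeric()), scaf)
  expect_equal(nrow(dn), 0)
})

test_that("checkpoint search matches exhaustive enumeration on small instances", {
  # length-6 search over {A, G} against a planted 7-mer, oracle = all 2^6
  planted <- parse_oligo("GAGGAAA")
  cfg <- sim_config(planted, noise_peaks = 0, jitter_sd = 0, seed = 31)
  spec <- preprocess(simulate_msms(cfg), noise_floor = 0)
  scaf <- mod_scaffold(rep(FALSE, 6), rep(FALSE, 6))

  combos <- expand.grid(rep(list(c("A", "G")), 6), stringsAsFactors = FALSE)
  oracle <- purrr::pmap_dfr(combos, function(...) {
    bases <- c(...)
    oligo <- parse_oligo(paste0(c(bases, "A"), collapse = ""))
    m <- search_fragments(spec, oligo, "c", indices = 1:6)
    cov <- length(unique(m$index)) / 6
    tibble::tibble(sequence = paste0(bases, collapse = ""),
                   eq4 = sum(m$abundance * m$cosine^2) * cov^2,
                   full = cov == 1)
  })
  oracle_top <- oracle$sequence[oracle$full][which.max(oracle$eq4[oracle$full])]

  dn <- denovo_spacer(spec, scaf, max_len = 6)
  expect_identical(dn$sequence[1], oracle_top)
  expect_identical(dn$sequence[1], "GAGGAA")
})

test_that("impurity tags surface both components of a 50:50 mixture", {
  spec <- mix_spec("gRNA_X", "gRNA_Y", 0.5, seed = 11)
  tags <- denovo_impurity_tags(spec, mod_scaffold(oligo = guide("gRNA_X")[1:20, ]),
                               tag_len = 20L)
  expect_true(spacer_string("gRNA_X") %in% tags$sequence)
  expect_true(spacer_string("gRNA_Y") %in% tags$sequence)
})

test_that("tag search requires the first three fragments", {
  # ladder starting at c_2: no c_1 anywhere, so no tags at all
  x <- guide("gRNA_X")
  cfg <- sim_config(x, indices = 2:20, noise_peaks = 0, jitter_sd = 0,
                    seed = 13)
  spec <- preprocess(simulate_msms(cfg), noise_floor = 0)
  tags <- denovo_impurity_tags(spec, mod_scaffold(oligo = x[1:20, ]),
                               tag_len = 5L)
  expect_equal(nrow(tags), 0)
})

test_that("a 5% dissimilar impurity is recoverable as a 5-mer tag", {
  spec <- mix_spec("gRNA_X", "gRNA_Y", 0.05, seed = 12)
  tags <- denovo_impurity_tags(spec, mod_scaffold(oligo = guide("gRNA_X")[1:20, ]),
                               tag_len = 5L)
  y5 <- format_oligo(guide("gRNA_Y")[1:5, ])
  expect_true(y5 %in% tags$sequence)
})

test_that("tag scores scale linearly with the planted molar fraction", {
  y5 <- format_oligo(guide("gRNA_Y")[1:5, ])
  fracs <- c(0.05, 0.1, 0.5)
  scores <- vapply(fracs, function(f) {
    spec <- mix_spec("gRNA_X", "gRNA_Y", f, seed = 17)
    tags <- denovo_impurity_tags(spec,
                                 mod_scaffold(oligo = guide("gRNA_X")[1:20, ]),
                                 tag_len = 5L)
    tags$score[match(y5, tags$sequence)]
  }, 0)
  expect_false(anyNA(scores))
  fit <- stats::lm(scores ~ fracs)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("modification search recovers methyl and thio placements", {
  xa <- guide("gRNA_XA")
  cfg <- sim_config(xa, indices = 1:28, noise_peaks = 0, jitter_sd = 0,
                    seed = 3)
  spec <- preprocess(simulate_msms(cfg), noise_floor = 0)
  dm <- denovo_modifications(spec, xa, charges = 1:8)
  expect_gt(nrow(dm), 0)
  top <- parse_oligo(dm$sequence[1])
  expect_equal(which(top$ribose_methyl), c(1, 2, 3, 21, 28))
  expect_equal(which(top$thio_linkage), c(1, 2, 3))
})

test_that("a missing flanking fragment widens placement to a stretch", {
  xa <- guide("gRNA_XA")
  # drop c_21 from the ladder: methyl at 21 vs 22 becomes ambiguous
  cfg <- sim_config(xa, indices = setdiff(1:28, 21L), noise_peaks = 0,
                    jitter_sd = 0, seed = 6)
  spec <- preprocess(simulate_msms(cfg), noise_floor = 0)
  dm <- denovo_modifications(spec, xa, charges = 1:8)
  loc <- localize_modifications(dm)
  stretches <- attr(loc, "stretches")
  expect_true(any(stretches$start <= 21 & stretches$end >= 22))
  expect_true(all(is.na(loc$ribose_methyl[21:22])))
})

test_that("an unmodified sequence yields no modification flags", {
  o <- parse_oligo("GAUCGAUCGAUC")
  cfg <- sim_config(o, indices = 1:11, noise_peaks = 0, jitter_sd = 0,
                    seed = 9)
  spec <- preprocess(simulate_msms(cfg), noise_floor = 0)
  dm <- denovo_modifications(spec, o, max_pos = 11)
  top <- parse_oligo(dm$sequence[1])
  expect_false(any(top$ribose_methyl))
  expect_false(any(top$thio_linkage))
})
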