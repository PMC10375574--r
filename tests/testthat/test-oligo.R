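test_that("modified-sequence parsing handles tokens, flags and positions", {
  o <- parse_oligo("C(ms)A(ms)G(ms)GUUCCAUGGGAUGCUCU")
  expect_equal(nrow(o), 20)
  expect_equal(o$base[1:4], c("C", "A", "G", "G"))
  expect_true(all(o$ribose_methyl[1:3]))
  expect_true(all(o$thio_linkage[1:3]))
  expect_false(o$ribose_methyl[4])
  expect_false(any(o$thio_linkage[4:20]))
  expect_equal(o$position, 1:20)

  single <- parse_oligo("A")
  expect_equal(nrow(single), 1)
  expect_false(single$ribose_methyl)
})

test_that("parse errors carry offsets and reject impossible chemistry", {
  expect_error(parse_oligo("C(xz)A"), "offset 1")
  expect_error(parse_oligo("T"), "unknown token")
  expect_error(parse_oligo(""), "non-empty")
  # a 3'-terminal phosphorothioate has no 3' linkage to modify
  expect_error(parse_oligo("AU(ms)"), "3'-terminal")
  expect_error(parse_oligo("A(m"), "unterminated")
})

test_that("parse/format round trip is byte-identical for all bundled guides", {
  tab <- example_guides()
  for (i in seq_len(nrow(tab))) {
    expect_identical(format_oligo(tab$oligo[[i]]), tab$sequence[i])
  }
})

test_that("elemental composition arithmetic matches nucleoside chemistry", {
  # adenosine
  expect_true(oligo_composition(parse_oligo("A")) ==
                elem_comp(C = 10, H = 13, N = 5, O = 4))
  # Cm-ps-Um dinucleotide: Cm + Um + thiophosphoric acid - 2 H2O
  expect_true(oligo_composition(parse_oligo("C(ms)U(m)")) ==
                elem_comp(C = 20, H = 28, N = 5, O = 12, P = 1, S = 1))
  # additivity: joining an n-mer and m-mer adds one linkage acid - 2 H2O
  left <- parse_oligo("C(ms)A(ms)G")
  right <- parse_oligo("GUUCC")
  joined <- parse_oligo("C(ms)A(ms)GGUUCC")
  expect_true(
    oligo_composition(joined) ==
      oligo_composition(left) + oligo_composition(right) +
      elem_comp(H = 3, O = 4, P = 1) - elem_comp(H = 4, O = 2)
  )
  expect_error(elem_comp(C = 1) - elem_comp(C = 2), "negative")
})

test_that("neutral masses reproduce printed guide values and known anchors", {
  expect_equal(neutral_mass(elem_comp(C = 10, H = 13, N = 5, O = 4)),
               267.0968, tolerance = 1e-6)
  tab <- example_guides()
  printed <- c(gRNA_X = 33148.39, gRNA_XA = 33125.35, gRNA_XB = 33132.39,
               gRNA_XC = 33187.43, gRNA_XD = 33147.41, gRNA_Y = 33101.39)
  avg <- vapply(tab$oligo, oligo_mass, 0, mode = "average")
  names(avg) <- tab$name
  expect_true(all(abs(avg - printed[names(avg)]) < 0.02))
  # base-composition differences between the variants
  expect_equal(avg[["gRNA_X"]] - avg[["gRNA_XA"]], 23.04, tolerance = 0.02)
  expect_equal(avg[["gRNA_X"]] - avg[["gRNA_XB"]], 16.00, tolerance = 0.02)
  expect_equal(avg[["gRNA_XC"]] - avg[["gRNA_X"]], 39.04, tolerance = 0.02)
  expect_equal(avg[["gRNA_X"]] - avg[["gRNA_XD"]], 0.98, tolerance = 0.02)
})

test_that("substitution enumeration covers n x 3 variants and can drop C/U", {
  sp <- guide("gRNA_X")
  all_subs <- enumerate_substitutions(sp, region = 1:20)
  expect_equal(nrow(all_subs), 60)
  no_cu <- enumerate_substitutions(sp, region = 1:20, exclude_cu = TRUE)
  expect_equal(nrow(no_cu), 49)  # 5 C and 6 U spacer positions lose one each
  expect_false(any(no_cu$from_base == "C" & no_cu$to_base == "U"))
  expect_false(any(no_cu$from_base == "U" & no_cu$to_base == "C"))
  # modification scaffold preserved
  v <- all_subs$variant[[which(all_subs$position == 2)[1]]]
  expect_true(v$ribose_methyl[2] && v$thio_linkage[2])
  expect_equal(nrow(enumerate_substitutions(sp, region = integer(0))), 0)
})

test_that("FASTA input yields unmodified oligos", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">seq1", "ACGU", ">seq2", "AAA"), path)
  out <- read_oligo_fasta(path)
  expect_named(out, c("seq1", "seq2"))
  expect_equal(out$seq1$base, c("A", "C", "G", "U"))
  expect_false(any(out$seq1$ribose_methyl))
})
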