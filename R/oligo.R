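#' Parse a modified-RNA sequence string
#'
#' Sequences are written 5' to 3' in a compact token syntax: each of `A`,
#' `C`, `G`, `U` may be followed by `(m)` for a 2'-O-methylribonucleotide or
#' `(ms)` for a 2'-O-methylribonucleotide whose 3' backbone linkage is a
#' phosphorothioate. Both termini are hydroxyl (the synthetic sgRNA
#' convention): there is no terminal phosphate, so a trailing `(ms)` on the
#' last nucleotide has no 3' linkage to modify and is rejected.
#'
#' @param text Sequence string, e.g. `"C(ms)A(ms)G(ms)GUUCCAUGGGAUGCUCU"`.
#' @param name Optional label carried along in results.
#'
#' @return An `oligo_seq`: a tibble with one row per nucleotide and columns
#'   `position` (1-based from the 5' end), `base`, `ribose_methyl`,
#'   `thio_linkage`, with the label stored in `attr(, "name")`.
#' @examples
#' oligo <- parse_oligo("C(ms)A(ms)G(ms)GUUCCAUGGGAUGCUCU", name = "spacer")
#' oligo
#' format_oligo(oligo)
#' @export
parse_oligo <- function(text, name = NULL) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(text)) {
    stop("sequence string must be a single non-empty string", call. = FALSE)
  }
  n <- nchar(text)
  pos <- 1L
  base <- character()
  methyl <- logical()
  thio <- logical()
  while (pos <= n) {
    b <- substr(text, pos, pos)
    if (!b %in% c("A", "C", "G", "U")) {
      stop(sprintf("unknown token '%s' at offset %d (expected A, C, G or U)",
                   b, pos - 1L), call. = FALSE)
    }
    pos <- pos + 1L
    m <- FALSE; s <- FALSE
    if (pos <= n && substr(text, pos, pos) == "(") {
      close <- regexpr(")", substr(text, pos, n), fixed = TRUE)
      if (close < 0) {
        stop(sprintf("unterminated modifier at offset %d", pos - 1L),
             call. = FALSE)
      }
      mod <- substr(text, pos + 1L, pos + close - 2L)
      if (mod == "m") {
        m <- TRUE
      } else if (mod == "ms") {
        m <- TRUE; s <- TRUE
      } else {
        stop(sprintf("unknown modifier '(%s)' at offset %d", mod, pos - 1L),
             call. = FALSE)
      }
      pos <- pos + close
    }
    base <- c(base, b); methyl <- c(methyl, m); thio <- c(thio, s)
  }
  if (thio[length(thio)]) {
    stop("phosphorothioate '(ms)' on the 3'-terminal nucleotide has no 3' linkage",
         call. = FALSE)
  }
  new_oligo(base, methyl, thio, name = name)
}

new_oligo <- function(base, ribose_methyl, thio_linkage, name = NULL) {
  out <- tibble::tibble(
    position = seq_along(base),
    base = base,
    ribose_methyl = ribose_methyl,
    thio_linkage = thio_linkage
  )
  class(out) <- c("oligo_seq", class(out))
  attr(out, "name") <- name
  out
}

#' @export
print.oligo_seq <- function(x, ...) {
  nm <- attr(x, "name", exact = TRUE)
  cat(sprintf("<oligo_seq%s> %d nt: %s\n",
              if (is.null(nm)) "" else paste0(" ", nm),
              nrow(x), format_oligo(x)))
  invisible(x)
}

oligo_name <- function(oligo) {
  nm <- attr(oligo, "name", exact = TRUE)
  if (is.null(nm)) "oligo" else nm
}

#' Format an `oligo_seq` back to its sequence string
#'
#' Inverse of [parse_oligo()]: formatting a parsed string reproduces it
#' byte-identically.
#'
#' @param oligo An `oligo_seq`.
#' @return The sequence string.
#' @export
format_oligo <- function(oligo) {
  mod <- ifelse(oligo$thio_linkage, "(ms)", ifelse(oligo$ribose_methyl, "(m)", ""))
  paste0(oligo$base, mod, collapse = "")
}

# Ribonucleoside compositions (free nucleoside, 5'-OH / 3'-OH).
.NUCLEOSIDE <- list(
  A = elem_comp(C = 10, H = 13, N = 5, O = 4),
  C = elem_comp(C = 9,  H = 13, N = 3, O = 5),
  G = elem_comp(C = 10, H = 13, N = 5, O = 5),
  U = elem_comp(C = 9,  H = 12, N = 2, O = 6)
)
.CH2 <- elem_comp(C = 1, H = 2)
.H2O <- elem_comp(H = 2, O = 1)
.PHOSPHORIC <- elem_comp(H = 3, O = 4, P = 1)        # H3PO4
.THIOPHOSPHORIC <- elem_comp(H = 3, O = 3, P = 1, S = 1)  # H3PO3S

nucleoside_comp <- function(base, ribose_methyl) {
  comp <- .NUCLEOSIDE[[base]]
  if (ribose_methyl) comp <- comp + .CH2
  comp
}

linkage_comp <- function(thio) {
  if (thio) .THIOPHOSPHORIC else .PHOSPHORIC
}

#' Elemental composition of an oligonucleotide
#'
#' The full-length composition is the sum of the nucleoside compositions
#' (2'-O-methyl adds CH2) plus one linkage acid per internucleotide bond --
#' phosphoric acid H3PO4, or thiophosphoric acid H3PO3S where the 5'-side
#' nucleotide carries a phosphorothioate flag -- with two waters condensed
#' out per bond. Termini are 5'-OH and 3'-OH.
#'
#' @param oligo An `oligo_seq`.
#' @param from,to 1-based positions delimiting a subsequence (defaults to the
#'   whole oligo). Internal linkages only; use the fragment constructors in
#'   [fragment_series()] for backbone cleavage products.
#' @return An `elem_comp`.
#' @examples
#' oligo_composition(parse_oligo("A"))        # adenosine
#' oligo_composition(parse_oligo("C(ms)U(m)"))
#' @export
oligo_composition <- function(oligo, from = 1L, to = nrow(oligo)) {
  stopifnot(from >= 1, to <= nrow(oligo), from <= to)
  comp <- elem_comp()
  for (i in from:to) {
    comp <- comp + nucleoside_comp(oligo$base[i], oligo$ribose_methyl[i])
    if (i < to) {
      comp <- comp + linkage_comp(oligo$thio_linkage[i]) - .H2O - .H2O
    }
  }
  comp
}

#' Neutral mass of an oligonucleotide
#'
#' @param oligo An `oligo_seq`.
#' @inheritParams neutral_mass
#' @return Mass in Da.
#' @export
oligo_mass <- function(oligo, mode = c("monoisotopic", "average")) {
  neutral_mass(oligo_composition(oligo), match.arg(mode))
}

#' Enumerate single-base substitution variants
#'
#' Every single-base permutation of the requested region, preserving the
#' modification scaffold (2'-O-methyl / phosphorothioate flags) at each
#' position: a region of n positions yields n x 3 variants. Because a C/U
#' interconversion shifts the mass by only ~0.98 Da and its isotopic envelope
#' overlaps the parent's, those candidates are better handled by isotopic
#' mixture fitting ([fit_cu_mixture()]); set `exclude_cu = TRUE` to omit
#' them from discovery lists.
#'
#' @param oligo Parent `oligo_seq`.
#' @param region Integer vector of positions to permute (default: the 20-nt
#'   spacer, clipped to the oligo length).
#' @param exclude_cu Drop C->U and U->C entries.
#' @return A tibble with columns `position`, `from_base`, `to_base` and a
#'   list-column `variant` of `oligo_seq` objects.
#' @export
enumerate_substitutions <- function(oligo, region = seq_len(min(20L, nrow(oligo))),
                                    exclude_cu = FALSE) {
  region <- intersect(as.integer(region), seq_len(nrow(oligo)))
  bases <- c("A", "C", "G", "U")
  rows <- list()
  for (p in region) {
    from <- oligo$base[p]
    for (to in setdiff(bases, from)) {
      if (exclude_cu && ((from == "C" && to == "U") || (from == "U" && to == "C"))) next
      variant <- oligo
      variant$base[p] <- to
      attr(variant, "name") <- sprintf("%s_%d%s>%s", oligo_name(oligo), p, from, to)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        position = p, from_base = from, to_base = to, variant = list(variant)
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(position = integer(), from_base = character(),
                          to_base = character(), variant = list()))
  }
  dplyr::bind_rows(rows)
}

#' Read unmodified sequences from FASTA
#'
#' Plain FASTA is accepted for unmodified RNA; all modification flags are set
#' to FALSE. `T` is rejected (RNA only).
#'
#' @param path FASTA file.
#' @return A named list of `oligo_seq` objects.
#' @export
read_oligo_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("not a FASTA file: ", path, call. = FALSE)
  idx <- cumsum(hdr)
  out <- list()
  for (i in unique(idx)) {
    block <- lines[idx == i]
    nm <- sub("^>\\s*", "", block[1])
    nm <- sub("\\s.*$", "", nm)
    seq <- toupper(paste0(block[-1], collapse = ""))
    out[[nm]] <- parse_oligo(seq, name = nm)
  }
  out
}

#' Example guide RNA sequences
#'
#' Heavily modified 100-mer single guide RNA sequences (and their 20-nt
#' spacers) bundled with the package: a parent guide, four single-base
#' substitution variants of it, and one guide with a highly dissimilar
#' spacer. These exercise every stage of the toolchain and are used
#' throughout the tests and documentation.
#'
#' @param spacer_only Return only the first 20 nucleotides of each guide.
#' @return A tibble with columns `name`, `sequence` and a list-column
#'   `oligo` of parsed `oligo_seq` objects.
#' @export
example_guides <- function(spacer_only = FALSE) {
  path <- system.file("extdata", "example_guides.tsv", package = "spacerms")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  oligos <- purrr::map2(tab$sequence, tab$name, parse_oligo)
  if (spacer_only) {
    oligos <- purrr::map(oligos, function(o) {
      sp <- o[1:20, ]
      sp$thio_linkage[20] <- FALSE
      attr(sp, "name") <- attr(o, "name")
      class(sp) <- class(o)
      sp
    })
    tab$sequence <- purrr::map_chr(oligos, format_oligo)
  }
  tibble::tibble(name = tab$name, sequence = tab$sequence, oligo = oligos)
}
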