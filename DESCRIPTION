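Package: spacerms
Title: Top-Down Mass Spectrometry Assessment of Guide RNA Spacer Fidelity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for assessing the fidelity of chemically modified single
    guide RNA (sgRNA) spacers from top-down MS/MS spectra acquired in negative
    ion mode. Parses the modified-nucleotide sequence syntax (2'-O-methyl and
    phosphorothioate), computes elemental compositions, neutral masses, c-/y-ion
    fragment ladders and theoretical isotopic distributions; reads, averages and
    filters centroided peak lists (TSV or mzML); assigns fragments with
    cosine-scored isotopic fidelity and estimates false discovery rates with
    mass-offset decoys; discovers and quantifies single-base substitution
    impurities, including non-negative least-squares isotopologue mixture
    fitting for C/U interconversions; performs de novo spacer sequencing and
    modification localization from c-ion ladders; and simulates QTOF-like MS/MS
    spectra of guide RNA mixtures for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mzR,
    withr
Config/testthat/edition: 3
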