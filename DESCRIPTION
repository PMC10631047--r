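Package: specshift
Title: Spectral Alignment of Peptide-Spectrum Matches with Localized Mass Shifts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns candidate peptides against tandem mass spectra by dynamic
    programming over the b-ion prefix series, splitting the precursor mass
    difference into localized mass shifts plus a residual non-aligned mass,
    without any a-priori modification list. Experimental spectra are first
    completed with complementary peaks so that y-ion evidence is transferred
    into the b-ion coordinate frame. Includes readers for MGF and mzML spectra
    and delimited PSM tables, a post-processing step that relocates or discards
    unsupported shifts, a simulator producing modified tryptic-peptide spectra
    with ground truth, and an evaluation harness for modification-recovery
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    Biostrings,
    mzR,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
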