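Package: subsite
Title: Protease Cleavage-Site Specificity Profiling from Phage Display
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the extended cleavage specificity of
    serine proteases from phage-displayed peptide selections and substrate
    assays. Selected nonapeptides are aligned into a Schechter-Berger
    P4-P3' register by a one-cleavage-site-per-sequence expectation
    maximization, summarized as position frequency and log-odds weight
    matrices, reduced to degenerate consensus patterns, and used to scan
    protein collections for candidate in vivo cleavage sites. Companion
    functions derive primary-specificity calls from chromogenic substrate
    panels, fit first-order cleavage time courses, and compare cleavage
    efficiencies by rate ratios or enzyme titration. A synthetic-data
    module emulates every input, from biopanning selection dynamics to
    noisy absorbance series, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
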