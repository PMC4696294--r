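Package: omapr
Title: Single-Molecule Optical Genome Mapping Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ordered restriction (optical) mapping of genomes:
    in-silico digestion of a reference sequence with built-in or user-defined
    restriction enzymes, enzyme-selection reports based on usable fragment
    size windows, a single-molecule Rmap simulator with a configurable error
    model (partial digestion, false cuts, small-fragment loss, sizing noise),
    a glocal dynamic-programming aligner of molecule fragment patterns to a
    reference restriction map, and quality-control summaries with
    alignment-based estimators of digestion and extra-cut rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
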