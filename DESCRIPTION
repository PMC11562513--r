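Package: neovax
Title: Neoantigen DNA Vaccine Design and Immune Monitoring Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for personalized neoantigen DNA vaccine studies in
    triple-negative breast cancer and similar settings: conversion of
    protein-altering somatic variants into mutant peptide windows,
    enumeration of minimal 8-11-mer epitopes, ensemble MHC class I
    binding aggregation (median IC50, anchor fold-change), filtering and
    ranked selection of vaccine epitopes, assembly of ubiquitin(G76V)
    polyepitope constructs with reverse translation, overlapping-peptide
    monitoring panel design, tiered ELISpot response calling with ICS
    positivity rules, TCR CDR3 clonotype expansion testing, and
    recurrence-free survival analysis. A fully synthetic cohort
    generator with known ground truth supports end-to-end testing
    without access to protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
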