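Package: xenostep
Title: Cross-Species MHC Peptidome Overlap and Shared T-Cell Epitope Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for comparing the human (HLA) and swine (SLA) major
    histocompatibility complex at the level of linear T-cell epitopes.
    Provides parsers for HLA/SLA allele nomenclature and genotype files,
    pairwise protein alignment with Hamming distance matrices and
    neighbor-joining trees, sliding-window 15mer peptidome construction
    with cross-species overlap statistics, an indirect T-cell epitope
    (PIRCHE-T2 style) scorer with a pluggable class-II binding predictor
    contract and a bundled deterministic mock predictor, a shared
    T-cell epitope (STEP) memory score for sequential grafts, a virtual
    patient/donor cohort simulator driven by weighted haplotype
    frequencies, and a fully specified synthetic two-species world
    generator with recorded ground truth for parameter-recovery testing.
License: MIT
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Encoding: UTF-8
Config/testthat/edition: 3
RoxygenNote: 7.3.3
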