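Package: csfcirc
Title: Cerebrospinal-Fluid Circular RNA Profiling, Screening and Survival Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end analysis toolkit for circular RNA (circRNA) liquid-biopsy
    studies across cerebrospinal fluid (CSF), plasma and tumor tissue. Calls
    back-splice junctions from chimeric read records, quantifies circRNAs with a
    junction-specific effective length and linear-transcript-derived TMM/FPKM
    normalization, compares compartment profiles (species counts, abundance,
    sharing, correlations), screens candidate CSF circRNAs through a normal-brain
    exclusion and tumor-recurrence cascade with detection-burden dichotomization,
    predicts circRNA-miRNA-mRNA sponge networks with a position-weighted duplex
    scorer and co-expression edges, and relates candidate detection burden to
    overall survival (Kaplan-Meier, log-rank, Cox). Includes a synthetic cohort
    generator with known ground truth so every stage is testable without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    edgeR,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
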