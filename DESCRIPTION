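Package: hccantigens
Title: Tumor-Associated Antigen Discovery Analytics for Hepatocellular Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested reimplementation of a staged discovery pipeline for
    hepatocellular carcinoma (HCC) tumor-associated antigens: parsing of
    protein-atlas-style normal-tissue and pathology tables, a five-stage
    HCC-specific protein selection cascade, Kaplan-Meier best-cutoff survival
    prioritization, MHC class I nonamer epitope enumeration with combined
    affinity/stability strong-binder selection, an exhaustive ungapped
    molecular-mimicry scan of viral proteomes, and quantification of the
    validation assays (T2 binding fluorescence index, brefeldin-A decay DC50,
    pMHC-multimer frequencies and cross-reactivity). A synthetic-data module
    generates every input format with planted, machine-readable ground truth
    so the full pipeline is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
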