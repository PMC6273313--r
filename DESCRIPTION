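Package: silacemt
Title: SILAC Quantitative Proteomics of TGF-beta-Induced
    Epithelial-Mesenchymal Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for SILAC (stable isotope labeling by amino
    acids in cell culture) quantitative proteomics of TGF-beta-induced
    epithelial-to-mesenchymal transition (EMT) in bladder epithelial cells.
    Aggregates peptide-level heavy/light intensity evidence into protein
    log2 H/L ratios, merges replicate experiments with Venn accounting,
    standardizes ratios into population z-scores with 95/99/99.9 percent
    confidence tiers, performs GO term over-representation with a
    from-scratch one-sided Fisher exact test, EASE score and fold
    enrichment, and screens for proteins whose EMT regulation direction is
    concordant with bladder-cancer cell-line comparisons. Includes a
    synthetic-data generator with ground-truth regulation labels so every
    stage is testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
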