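Package: isobalance
Title: Isoform Expression-Balance Diversity Between Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of alternative-splicing isoform expression balance
    (e_T-ratios) for two-isoform genes across population panels. Applies
    coverage masking and gene filters to per-accession FPKM tables, computes
    per-gene per-accession e_T-ratios with a fixed numerator convention,
    contrasts the within-population dispersion of the ratios (variance and
    inter-quartile range) between a cultivated and a wild compartment with
    paired tests, ordinates accessions by PCA on the ratio matrix, flags
    genes with contrasted ratio spread or location, tests GO-term
    over-representation by a hypergeometric Singular Enrichment Analysis
    with Bonferroni control, and classifies the functional impact of the
    alternative isoform's predicted protein into four categories. Ships a
    synthetic-study generator with known ground truth for calibration and
    power assessment.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
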