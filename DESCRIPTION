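Package: midfuse
Title: Mid-Level Fusion of Multi-Platform Omics Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mid-level data fusion for two or more omics feature tables
    (e.g. LC-MS peptide abundances and binned NMR intensities) measured on
    overlapping sample sets. Each platform is compressed with extended
    Canonical Variates Analysis (eCVA), a PLS-solved discriminant method
    that tolerates many more variables than samples; the per-platform
    discriminant scores are concatenated and analysed with a
    missing-value-tolerant iterative PCA, so samples measured on only a
    subset of platforms still contribute. Includes nearest-centroid
    classification in the global score space, Kennard-Stone test-set
    selection, back-projection of global loadings to variable-level
    importances, peptide-to-protein roll-up, class-conditional Pearson
    correlation networks with Graphviz DOT export, and a seeded generator
    of synthetic two-block studies with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
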