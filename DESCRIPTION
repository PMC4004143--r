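Package: poolscan
Title: Pooled-Sequencing Population Genomics for Transcriptome-Anchored SNPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of pooled whole-genome resequencing data aligned to a
    transcriptome reference, with each assembled unigene treated as a locus.
    Provides read filtering and per-site base-count profile extraction from SAM
    records, bias-corrected within-pool nucleotide diversity (pi), the
    frequency-based absolute-divergence statistic pi_xy (an estimator of Nei's
    d_XY suitable for pooled data), per-unigene pairwise F_ST, permutation
    outlier scans between phenotype-defined population groups, SNP-discovery
    rarefaction curves, principal coordinates analysis, isolation-by-distance
    regression with a Mantel test, in-silico CAPS marker design, and a
    Balding-Nichols pooled-sequencing simulator with known ground truth for
    calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    geosphere,
    Biostrings,
    BiocGenerics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    vegan,
    jsonlite
Config/testthat/edition: 3
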