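Package: clinescan
Title: Gene-Based Local-Adaptation Scans and Cross-Transect Parallelism Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and comparing signatures of local adaptation
    along environmental gradients from common-garden genotype-phenotype-climate
    data. Implements gene-based "top candidate" scans (first-percentile SNP
    outliers aggregated per gene with a binomial 0.999-quantile rule), the
    null-W rank-sum test of parallel adaptation between two transects,
    genotype-environment association by per-SNP Spearman correlation,
    from-scratch redundancy analysis (RDA) with locus-score outlier detection,
    hypergeometric candidate-overlap tests, clone BLUP estimation from
    randomized-block common-garden designs, GLM/MLM association scans with
    principal-component and kinship structure correction selected by genomic
    inflation factor, and a synthetic two-transect study generator with known
    causal ground truth for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    lme4,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
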