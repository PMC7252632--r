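Package: promoterFPCA
Title: Histone-Modification Promoter Signatures via Functional PCA and
    Mixture Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Characterizes combinatorial histone-modification binding
    patterns around transcription start sites and predicts novel or
    alternative promoters genome-wide. Four-mark ChIP-seq coverage
    (H3K4me2, H3K4me3, H3K9ac, H4K20me1) is binned into 100 bp bins,
    concatenated into 400-bin promoter profiles, reduced by functional
    principal component analysis (Karhunen-Loeve expansion), and
    clustered with an EM-fitted mixture of diagonal-covariance
    Gaussians on the component scores. Cluster mean profiles
    (characteristic patterns) then drive a sliding-window genome scan:
    windows whose Pearson correlation with a pattern exceeds a
    percentile threshold learned from the training clusters are merged
    into significance regions and grouped into putative promoters,
    which can be summarized against annotation interval sets (ESTs,
    CpG islands, SNPs). Includes a synthetic-data generator emulating
    the four canonical promoter patterns for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
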