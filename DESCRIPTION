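Package: hepacult
Title: Comparative Transcriptomics of Cultivated Hepatocytes and Diseased Liver
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies how closely gene-expression changes in cultivated
    primary hepatocytes resemble those in diseased or damaged liver tissue.
    Provides differential expression calling against a fresh-hepatocyte
    reference, sample quality control by PCA and replicate correlation,
    fuzzy c-means clustering of time-dependent fold-change profiles into
    biological motifs, metagene scoring of gene sets across sample groups,
    in vitro/in vivo concordance statistics (Spearman correlation and
    sign-coincidence odds ratios), cross-species orthologue quadrant
    analysis, and a synthetic-data generator with planted structure for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
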