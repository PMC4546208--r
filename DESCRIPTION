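Package: promethyl
Title: Paired Tumor/Normal Promoter Methylome and Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for promoter-restricted bisulfite sequencing of
    paired tumor and adjacent non-tumor tissue. Computes per-CpG beta and M
    values from methylated/unmethylated read counts, applies coverage filters,
    annotates strand-aware promoters and CpG islands, classifies promoters by
    CpG content (HCP/ICP/LCP), detects per-pair differentially methylated
    regions with a sliding-window strategy, calls per-pair differentially
    expressed genes from RPKM, integrates recurrent DMRs with recurrent DEGs
    into candidate genes with an inverse methylation-expression relationship,
    and provides cohort-level statistics (bootstrap-supported hierarchical
    clustering, top-variable CpG-island selection, PCA, paired validation
    tests, delta-delta-Ct). Includes a synthetic paired-cohort generator with
    planted effects for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite,
    ape,
    withr
Suggests:
    testthat (>= 3.0.0),
    tools
Config/testthat/edition: 3
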