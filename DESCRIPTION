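Package: aplmeth
Title: Differential Methylation Analysis and Subtype Stratification for
    Colorectal Precancerous Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-genome bisulfite sequencing (WGBS) analysis of advanced
    precancerous colorectal lesions (APLs) and paired normal adjacent tissue:
    per-CpG coverage filtering and SNP masking, paired Wilcoxon signed-rank
    and rank-sum site testing with Benjamini-Hochberg correction, aggregation
    of significant CpGs into differentially methylated regions (DMRs),
    selection of subtype-unique hypermethylated signature regions, chromosome
    enrichment normalized by chromosome length, PCA-based stratification of
    histological subtypes with Kruskal-Wallis testing, and CIMP-like
    classification by consensus K-means clustering of variable promoter CpGs.
    Includes a synthetic paired-cohort simulator with planted regions so the
    full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
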