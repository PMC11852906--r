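#!/usr/bin/env Rscript
# Stage 4 - PCA of the signature region-beta matrix over tumor samples and
# Kruskal-Wallis testing of PC1 scores across histological subtypes, with
# the top-30 contributing regions of PC1.

suppressPackageStartupMessages(library(aplmeth))

sig <- read.delim("results/signature_regions.tsv")
samples <- read_sample_sheet("results/cohort/samples.tsv")
paths <- list.files("results/cohort/cov", full.names = TRUE)
names(paths) <- sub("\\.cov$", "", basename(paths))
filtered <- filter_sites(read_cov_files(paths))

tumors <- samples[samples$tissue == "tumor", ]
mat <- region_beta_matrix(sig, filtered, tumors$sample_id)
pca <- pca_stratify(mat, top_n = 30L)
message(sprintf("PC1/PC2 explain %.1f%% / %.1f%% of variance",
                100 * pca$var_explained[1], 100 * pca$var_explained[2]))

kw <- kruskal_subtypes(pca$scores[, 1],
                       tumors$subtype[match(rownames(pca$scores),
                                            tumors$sample_id)])
print(kw)

scores <- data.frame(sample_id = rownames(pca$scores),
                     subtype = tumors$subtype[match(rownames(pca$scores),
                                                    tumors$sample_id)],
                     pca$scores[, 1:2])
write.table(scores, "results/pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(pca$top_regions[[1]], "results/pca_top30_pc1.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(kw$pairwise, "results/kw_pairwise.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
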