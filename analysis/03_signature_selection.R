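#!/usr/bin/env Rscript
# Stage 3 - subtype-unique hypermethylated signature: take the elevated side
# of every inter-subtype DMR, remove regions overlapping any lesion-vs-NAT
# DMR, drop multi-subtype claims, and compute length-normalized DMR
# enrichment per chromosome.

suppressPackageStartupMessages(library(aplmeth))

read_set <- function(nm) read_dmr_bed(sprintf("results/dmrs_%s.bed", nm))
inter <- c("SSL_vs_TA", "SSL_vs_VA_TVA", "TA_vs_VA_TVA")
vs_nat <- c("SSL_vs_SSL_NAT", "TA_vs_TA_NAT", "VA_TVA_vs_VA_TVA_NAT")

sig <- select_unique_hyper(setNames(lapply(inter, read_set), inter),
                           setNames(lapply(vs_nat, read_set), vs_nat))
message(sprintf("Signature: %d subtype-unique hypermethylated regions", nrow(sig)))
print(table(sig$subtype))
write.table(sig, "results/signature_regions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

genome <- read_chrom_sizes("results/cohort/chrom.sizes")
enr <- chromosome_enrichment(sig, genome)
print(enr)
message(if (any(enr$flagged))
          paste("Chromosomes with enrichment > 1.5:",
                paste(enr$chrom[enr$flagged], collapse = ", "))
        else "No chromosome exceeds enrichment 1.5")
write.table(enr, "results/chrom_enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
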