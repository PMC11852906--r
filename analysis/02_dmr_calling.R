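#!/usr/bin/env Rscript
# Stage 2 - site-level testing and DMR calling for all nine comparisons
# (three lesion-vs-NAT paired, three inter-subtype, three NAT-vs-NAT),
# reading the cohort written by 01_simulate_cohort.R. Writes per-comparison
# site tables, DMR BED files and the summary count table, and checks the
# calls against the planted truth.

suppressPackageStartupMessages(library(aplmeth))

cov_dir <- "results/cohort/cov"
paths <- list.files(cov_dir, full.names = TRUE)
names(paths) <- sub("\\.cov$", "", basename(paths))
sites <- read_cov_files(paths)
samples <- read_sample_sheet("results/cohort/samples.tsv")

cfg <- analysis_config()
filtered <- filter_sites(sites, cfg)
message(sprintf("Coverage filter (>= %d reads in all samples): %d of %d CpGs kept",
                cfg$min_coverage, n_sites(filtered), n_sites(sites)))

cmps <- default_comparisons(samples)
dmr_sets <- list()
for (nm in names(cmps)) {
  cm <- cmps[[nm]]
  res <- test_sites(filtered, cm$a, cm$b, cm$paired, cfg)
  write.table(res, sprintf("results/sites_%s.tsv", nm), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dmr_sets[[nm]] <- call_dmrs(res, cfg, nm)
  write_dmr_bed(dmr_sets[[nm]], sprintf("results/dmrs_%s.bed", nm))
}

sm <- summarize_comparisons(dmr_sets)
print(sm)
write.table(sm$per_comparison, "results/dmr_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- list(
  regions = read.delim("results/cohort/truth_regions.tsv"),
  promoters = read_bed_regions("results/cohort/promoters.bed"))
ev <- evaluate_recovery(truth, dmr_sets)
message(sprintf("Planted-truth recovery: %.1f%% of %d expected calls; %d false positives",
                100 * ev$recovery_rate, nrow(ev$expected),
                ev$n_false_positives))
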