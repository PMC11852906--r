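#!/usr/bin/env Rscript
# Stage 1 - simulate the synthetic APL cohort used throughout the analysis:
# 10 paired tumor/NAT patients per subtype (SSL, TA, VA/TVA) at mean depth
# 22.5x, with planted subtype-specific, signature and shared regions plus a
# CIMP-H tumor subpopulation. Writes the cohort in the pipeline's on-disk
# formats and a summary of the planted truth.

suppressPackageStartupMessages(library(aplmeth))

out <- "results/cohort"
dir.create("results", showWarnings = FALSE)

cfg <- simulation_config(seed = 20260920L %% 100000L)
cohort <- generate_cohort(cfg)
paths <- write_cohort(cohort, out)

message(sprintf("Simulated %d CpGs x %d samples (%d discovery pairs/subtype)",
                n_sites(cohort$sites), nrow(cohort$samples),
                cfg$n_patients_per_subtype))
print(table(cohort$truth$regions$class, cohort$truth$regions$direction))
message(sprintf("CIMP-H tumors: %d of %d",
                sum(cohort$truth$cimp_labels$cimp == "CIMP-H"),
                nrow(cohort$truth$cimp_labels)))
message("Cohort written under ", out)
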