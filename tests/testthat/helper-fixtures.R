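# Shared fixture builders. Everything is generated in code at test time.

# Desk-scale simulation config for structural tests (fast: ~0.1 s cohorts).
small_sim_config <- function(seed = 1L, ...) {
  simulation_config(n_cpgs = 600L, n_chroms = 2L, chrom_length = 3e5,
                    planted_regions_per_subtype = 6L,
                    signature_regions_per_subtype = 3L,
                    shared_regions = 4L, cimp_promoter_regions = 8L,
                    seed = seed, ...)
}

# A one-comparison site-result data.frame for DMR-calling tests.
make_site_results <- function(pos, significant, delta, chrom = "chr1") {
  data.frame(chrom = chrom, pos = as.integer(pos), n_used = 10L,
             delta_beta = delta, p_raw = ifelse(significant, 0.001, 0.5),
             p_adj = ifelse(significant, 0.01, 0.6),
             testable = TRUE, significant = significant)
}

# A CpGSiteTable from a beta matrix at fixed large depth, so beta values are
# exactly meth/depth.
table_from_betas <- function(betas, chrom = "chr1", pos = NULL, depth = 1000L) {
  betas <- as.matrix(betas)
  if (is.null(pos)) pos <- seq_len(nrow(betas)) * 100L
  meth <- round(betas * depth)
  total <- matrix(depth, nrow(betas), ncol(betas))
  dimnames(meth) <- dimnames(total) <-
    list(NULL, colnames(betas) %||% paste0("S", seq_len(ncol(betas))))
  cpg_site_table(rep(chrom, nrow(betas)), pos, meth, total)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal DMR data.frame builder.
dmr_row <- function(chrom, start, end, mean_delta = 0.3, comparison = "",
                    n_cpgs = 5L, n_sig = 3L) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             n_cpgs = n_cpgs, n_sig = n_sig,
             frac_significant = n_sig / n_cpgs, mean_delta = mean_delta,
             direction = ifelse(mean_delta > 0, "hyper", "hypo"),
             comparison = comparison)
}
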