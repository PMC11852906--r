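# Site-level analysis: coverage filtering, SNP masking, per-CpG paired
# signed-rank / unpaired rank-sum testing on beta values, BH correction and
# effect-size flagging.

#' Analysis configuration for site testing and DMR calling
#'
#' Defaults mirror the study design the pipeline implements: CpGs must have
#' at least 5 reads in every sample; a CpG is significant when its BH-adjusted
#' p-value is below 0.05 and the group beta difference is at least 0.2;
#' regions aggregate CpGs within 50 bp, need 3 or more CpGs and at least 60%
#' of them significant.
#'
#' @param min_coverage minimum reads per sample at a retained CpG
#' @param alpha significance level on BH-adjusted p-values
#' @param min_delta minimum absolute beta difference for significance
#' @param max_gap maximum distance (bp) between consecutive CpGs in a region
#' @param min_cpgs minimum CpGs per region
#' @param min_sig_frac minimum fraction of significant CpGs per region
#'   (inclusive)
#' @return an `AnalysisConfig` list
#' @export
analysis_config <- function(min_coverage = 5L, alpha = 0.05, min_delta = 0.2,
                            max_gap = 50L, min_cpgs = 3L, min_sig_frac = 0.6) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (min_delta < 0 || min_delta > 1) stop("min_delta must lie in [0, 1]")
  if (min_cpgs < 1L) stop("min_cpgs must be >= 1")
  if (min_sig_frac <= 0 || min_sig_frac > 1)
    stop("min_sig_frac must lie in (0, 1]")
  structure(list(min_coverage = as.integer(min_coverage), alpha = alpha,
                 min_delta = min_delta, max_gap = as.integer(max_gap),
                 min_cpgs = as.integer(min_cpgs),
                 min_sig_frac = min_sig_frac),
            class = "AnalysisConfig")
}

#' Coverage filter and SNP mask
#'
#' Retains CpGs with at least `min_coverage` reads in every listed sample
#' and not overlapping the mask (e.g. common SNPs with minor allele
#' frequency above 1%, pre-computed by the caller).
#'
#' @param sites a [cpg_site_table()]
#' @param config an [analysis_config()]
#' @param samples sample ids defining "all samples" for the coverage rule;
#'   defaults to every sample in the table
#' @param mask optional data.frame(chrom, start, end) of positions to drop
#'   (1-based inclusive, as returned by [read_bed_regions()])
#' @return the filtered `CpGSiteTable`; warns if no site survives
#' @export
filter_sites <- function(sites, config = analysis_config(), samples = NULL,
                         mask = NULL) {
  stopifnot(inherits(sites, "CpGSiteTable"))
  if (is.null(samples)) samples <- sites$samples
  d <- sites$total[, samples, drop = FALSE]
  keep <- rowSums(d >= config$min_coverage) == length(samples)
  if (!is.null(mask) && nrow(mask)) {
    hit <- GenomicRanges::findOverlaps(
      positions_to_granges(sites$chrom, sites$pos), regions_to_granges(mask))
    keep[unique(S4Vectors::queryHits(hit))] <- FALSE
  }
  if (!any(keep)) warning("no CpG site survives filtering")
  subset_sites(sites, keep)
}

# ---- Wilcoxon engines -------------------------------------------------
# Exact null distributions (psignrank / pwilcox) when the sample is small
# (n <= 25) and neither ties nor zero differences intervene; otherwise the
# normal approximation with continuity correction. Semantics match
# stats::wilcox.test, which serves as a cross-check oracle in the tests.

.signed_rank_p <- function(d) {
  d <- d[!is.na(d)]
  zeros <- any(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n < 3L) return(c(p = 1, testable = 0))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(r))
  mu <- n * (n + 1) / 4
  if (!zeros && !ties && n <= 25L) {
    p <- if (v > mu) stats::psignrank(v - 1, n, lower.tail = FALSE)
         else stats::psignrank(v, n)
    return(c(p = min(2 * p, 1), testable = 1))
  }
  nt <- table(r)
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(nt^3 - nt) / 48)
  if (sigma == 0) return(c(p = 1, testable = 1))
  z <- v - mu
  z <- (z - sign(z) * 0.5) / sigma
  c(p = min(2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)), 1),
    testable = 1)
}

.rank_sum_p <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 3L || ny < 3L) return(c(p = 1, testable = 0))
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(r))
  mu <- nx * ny / 2
  if (!ties && nx <= 25L && ny <= 25L) {
    p <- if (w > mu) stats::pwilcox(w - 1, nx, ny, lower.tail = FALSE)
         else stats::pwilcox(w, nx, ny)
    return(c(p = min(2 * p, 1), testable = 1))
  }
  nt <- table(r)
  n <- nx + ny
  sigma <- sqrt((nx * ny / 12) * ((n + 1) - sum(nt^3 - nt) / (n * (n - 1))))
  if (sigma == 0) return(c(p = 1, testable = 1))
  z <- w - mu
  z <- (z - sign(z) * 0.5) / sigma
  c(p = min(2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)), 1),
    testable = 1)
}

#' Per-CpG differential methylation testing
#'
#' For every site, compares beta values of group A against group B with a
#' two-sided Wilcoxon test: signed-rank on per-pair differences when
#' `paired` (zero differences dropped before ranking, Wilcoxon's original
#' convention), rank-sum otherwise. Exact null distributions are used when
#' the effective sample size is at most 25 and no ties or zeros prevent
#' them; otherwise the normal approximation with continuity correction.
#' P-values are then BH-adjusted jointly over all sites of the comparison.
#'
#' A site with fewer than 3 informative pairs (or fewer than 3 non-missing
#' betas per group) is reported with p = 1 and `testable = FALSE`, never
#' silently dropped, so region CpG counts always match the filtered table.
#'
#' @param sites a filtered [cpg_site_table()]
#' @param group_a,group_b sample id vectors; when `paired`, element i of
#'   each names the two tissues of the same patient
#' @param paired logical: signed-rank on pair differences vs rank-sum
#' @param config an [analysis_config()]
#' @return data.frame with columns `chrom`, `pos`, `n_used`, `delta_beta`
#'   (mean A - mean B, missing betas ignored), `p_raw`, `p_adj`, `testable`,
#'   `significant` (p_adj < alpha and |delta_beta| >= min_delta)
#' @export
test_sites <- function(sites, group_a, group_b, paired,
                       config = analysis_config()) {
  stopifnot(inherits(sites, "CpGSiteTable"))
  if (length(group_a) < 3L || length(group_b) < 3L)
    stop("each group needs at least 3 samples")
  if (paired && length(group_a) != length(group_b))
    stop("paired groups must have equal length and matching order")
  ba <- beta_values(sites, group_a)
  bb <- beta_values(sites, group_b)
  ns <- n_sites(sites)
  if (paired) {
    d <- ba - bb
    res <- matrix(0, ns, 3)
    for (i in seq_len(ns)) {
      di <- d[i, ]
      out <- .signed_rank_p(di)
      res[i, ] <- c(out, sum(!is.na(di) & di != 0))
    }
  } else {
    res <- matrix(0, ns, 3)
    for (i in seq_len(ns)) {
      out <- .rank_sum_p(ba[i, ], bb[i, ])
      res[i, ] <- c(out, sum(!is.na(ba[i, ])) + sum(!is.na(bb[i, ])))
    }
  }
  delta <- rowMeans(ba, na.rm = TRUE) - rowMeans(bb, na.rm = TRUE)
  delta[is.nan(delta)] <- NA_real_
  p_raw <- res[, 1]
  p_adj <- adjust_bh(p_raw)
  testable <- res[, 2] == 1
  sig <- testable & p_adj < config$alpha & !is.na(delta) &
    abs(delta) >= config$min_delta
  data.frame(chrom = sites$chrom, pos = sites$pos, n_used = as.integer(res[, 3]),
             delta_beta = delta, p_raw = p_raw, p_adj = p_adj,
             testable = testable, significant = sig)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted p-values (clipped at 1, input order preserved),
#' controlling the false discovery rate across the sites of one comparison.
#'
#' @param p_values numeric vector of raw p-values in (0, 1\]
#' @return adjusted p-values, same length and order
#' @export
adjust_bh <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
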