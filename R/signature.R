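# Subtype-unique hypermethylated signature selection, chromosome
# enrichment, and the region-level beta matrix used for stratification.

.parse_comparison <- function(name) {
  parts <- strsplit(name, "_vs_", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("cannot parse comparison label: ", name)
  parts
}

#' Select subtype-unique hypermethylated signature regions
#'
#' Every DMR from the inter-subtype comparisons is assigned to the subtype
#' in which it is hypermethylated — the elevated side of its source
#' comparison, given by the sign of `mean_delta` (positive: first-named
#' subtype, negative: second-named). Regions overlapping (by at least 1 bp)
#' any lesion-vs-NAT DMR are removed, and regions claimed by two different
#' subtypes are dropped. Regions claimed repeatedly by the same subtype
#' (e.g. elevated against both other subtypes) are kept once, with merged
#' provenance.
#'
#' @param inter_subtype_dmrs named list: inter-subtype comparison label
#'   (e.g. `"SSL_vs_TA"`) -> DMR data.frame
#' @param vs_nat_dmrs named list of lesion-vs-NAT DMR data.frames used as
#'   the exclusion set
#' @return data.frame: `subtype`, `chrom`, `start`, `end`, `mean_delta`,
#'   `source` (semicolon-joined provenance comparisons)
#' @export
select_unique_hyper <- function(inter_subtype_dmrs, vs_nat_dmrs = list()) {
  empty <- data.frame(subtype = character(), chrom = character(),
                      start = integer(), end = integer(),
                      mean_delta = numeric(), source = character())
  cand <- do.call(rbind, lapply(sort(names(inter_subtype_dmrs)), function(cmp) {
    d <- inter_subtype_dmrs[[cmp]]
    if (is.null(d) || nrow(d) == 0L) return(NULL)
    sides <- .parse_comparison(cmp)
    data.frame(subtype = ifelse(d$mean_delta > 0, sides[1], sides[2]),
               chrom = d$chrom, start = d$start, end = d$end,
               mean_delta = abs(d$mean_delta), source = cmp)
  }))
  if (is.null(cand) || nrow(cand) == 0L) return(empty)

  nat <- do.call(rbind, lapply(vs_nat_dmrs, function(d)
    if (is.null(d) || nrow(d) == 0L) NULL else d[c("chrom", "start", "end")]))
  if (!is.null(nat) && nrow(nat)) {
    hit <- GenomicRanges::findOverlaps(regions_to_granges(cand),
                                       regions_to_granges(nat))
    drop <- unique(S4Vectors::queryHits(hit))
    if (length(drop)) cand <- cand[-drop, , drop = FALSE]
  }
  if (nrow(cand) == 0L) return(empty)

  # Drop regions claimed by two different subtypes (>= 1 bp overlap).
  gr <- regions_to_granges(cand)
  hit <- GenomicRanges::findOverlaps(gr, gr)
  qh <- S4Vectors::queryHits(hit)
  sh <- S4Vectors::subjectHits(hit)
  conflict <- unique(qh[cand$subtype[qh] != cand$subtype[sh]])
  if (length(conflict)) cand <- cand[-conflict, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)

  # Merge duplicate claims by the same subtype into one region.
  key <- paste(cand$subtype, cand$chrom, cand$start, cand$end)
  out <- do.call(rbind, lapply(split(seq_len(nrow(cand)), key), function(idx) {
    data.frame(subtype = cand$subtype[idx[1]], chrom = cand$chrom[idx[1]],
               start = cand$start[idx[1]], end = cand$end[idx[1]],
               mean_delta = mean(cand$mean_delta[idx]),
               source = paste(sort(cand$source[idx]), collapse = ";"))
  }))
  out <- out[order(out$subtype, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' DMR enrichment per chromosome, normalized by chromosome length
#'
#' For autosome c with n_c DMRs and length L_c,
#' `enrichment(c) = (n_c / L_c) / (N_total / L_total)`, with totals over
#' autosomes. The length-weighted mean enrichment is exactly 1 whenever all
#' DMRs lie on autosomes present in the table.
#'
#' @param dmrs DMR data.frame (any set of regions with a `chrom` column)
#' @param genome a [genome_info()] table; analysis is restricted to rows
#'   flagged as autosomes
#' @param flag_threshold chromosomes with enrichment strictly above this
#'   value are flagged (the conventional cut is 1.5)
#' @return data.frame: `chrom`, `length`, `n_dmrs`, `enrichment`, `flagged`
#' @export
chromosome_enrichment <- function(dmrs, genome, flag_threshold = 1.5) {
  missing_chr <- setdiff(unique(dmrs$chrom), genome$chrom)
  if (length(missing_chr))
    stop("chromosome(s) absent from genome table: ",
         paste(missing_chr, collapse = ", "))
  auto <- genome[genome$autosome, , drop = FALSE]
  if (!nrow(auto)) stop("genome table contains no autosomes")
  n_c <- vapply(auto$chrom, function(ch) sum(dmrs$chrom == ch), 0)
  n_total <- sum(n_c)
  l_total <- sum(auto$length)
  enr <- if (n_total == 0) rep(0, nrow(auto))
         else (n_c / auto$length) / (n_total / l_total)
  data.frame(chrom = auto$chrom, length = auto$length, n_dmrs = as.integer(n_c),
             enrichment = enr, flagged = enr > flag_threshold,
             row.names = NULL)
}

#' Region-level beta matrix
#'
#' Per region and sample, the unweighted mean of site betas at CpGs within
#' `[start, end]`; missing when the sample covers no CpG of the region.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive); row identity is kept as `chrom:start-end`
#' @param sites a [cpg_site_table()]
#' @param samples sample ids (default: all)
#' @return numeric matrix regions x samples with `NA` for uncovered entries;
#'   warns for regions containing no tested CpG
#' @export
region_beta_matrix <- function(regions, sites, samples = NULL) {
  stopifnot(inherits(sites, "CpGSiteTable"))
  if (is.null(samples)) samples <- sites$samples
  if (!nrow(regions)) stop("regions must be non-empty")
  b <- beta_values(sites, samples)
  hit <- GenomicRanges::findOverlaps(regions_to_granges(regions),
                                     positions_to_granges(sites$chrom, sites$pos))
  qh <- S4Vectors::queryHits(hit)
  sh <- S4Vectors::subjectHits(hit)
  out <- matrix(NA_real_, nrow(regions), length(samples),
                dimnames = list(paste0(regions$chrom, ":", regions$start, "-",
                                       regions$end), samples))
  for (r in seq_len(nrow(regions))) {
    idx <- sh[qh == r]
    if (!length(idx)) next
    sub <- b[idx, , drop = FALSE]
    m <- colMeans(sub, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    out[r, ] <- m
  }
  empty <- which(tabulate(qh, nbins = nrow(regions)) == 0L)
  if (length(empty))
    warning(length(empty), " region(s) contain no tested CpG; rows are all-missing")
  out
}
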