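# DMR aggregation: greedy gap-based clustering of tested CpGs and region
# filtering on CpG count, significant fraction and sign consistency.

#' Cluster sorted CpG positions by maximum gap
#'
#' Greedy single-pass clustering: consecutive positions whose difference is
#' at most `max_gap` share a run; a difference of `max_gap + 1` or more
#' starts a new run.
#'
#' @param positions strictly increasing integer positions (one chromosome)
#' @param max_gap maximum distance in bp
#' @return list of position runs
#' @export
cluster_sites <- function(positions, max_gap) {
  if (!length(positions)) return(list())
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be sorted ascending and unique")
  id <- cumsum(c(1L, as.integer(diff(positions) > max_gap)))
  unname(split(positions, id))
}

#' Call differentially methylated regions from site test results
#'
#' All tested CpGs of the comparison (significant or not, testable or not)
#' are clustered per chromosome with the `max_gap` rule; a cluster becomes a
#' DMR when it has at least `min_cpgs` CpGs, at least `min_sig_frac` of them
#' significant, and all its significant CpGs agree in the sign of
#' `delta_beta`. Mixed-sign clusters are discarded. Region coordinates span
#' the first to last CpG; `mean_delta` averages `delta_beta` over the
#' significant CpGs and sets the direction (hyper = first-named group
#' higher).
#'
#' @param results a site result data.frame from [test_sites()]
#' @param config an [analysis_config()]
#' @param comparison label attached to each region
#' @return DMR data.frame: `chrom`, `start`, `end` (1-based inclusive),
#'   `n_cpgs`, `n_sig`, `frac_significant`, `mean_delta`, `direction`,
#'   `comparison`
#' @export
call_dmrs <- function(results, config = analysis_config(), comparison = "") {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_cpgs = integer(), n_sig = integer(),
                      frac_significant = numeric(), mean_delta = numeric(),
                      direction = character(), comparison = character())
  if (is.null(results) || nrow(results) == 0L) return(empty)
  o <- order_sites(results$chrom, results$pos)
  results <- results[o, , drop = FALSE]
  out <- list()
  for (chr in unique(results$chrom)) {
    sub <- results[results$chrom == chr, , drop = FALSE]
    runs <- cluster_sites(sub$pos, config$max_gap)
    off <- 0L
    for (run in runs) {
      n <- length(run)
      idx <- off + seq_len(n)
      off <- off + n
      if (n < config$min_cpgs) next
      sig <- which(sub$significant[idx])
      n_sig <- length(sig)
      if (n_sig < config$min_sig_frac * n - 1e-9) next
      deltas <- sub$delta_beta[idx][sig]
      signs <- unique(sign(deltas))
      if (length(signs) != 1L) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = run[1L], end = run[n], n_cpgs = n, n_sig = n_sig,
        frac_significant = n_sig / n, mean_delta = mean(deltas),
        direction = if (signs > 0) "hyper" else "hypo",
        comparison = comparison
      )
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize per-comparison DMR counts
#'
#' Accepts a counts table with columns `comparison`, `n_dmrs`, `n_hyper`,
#' `n_hypo` (the latter two may be NA where no direction was assigned) and
#' adds grand totals: `n_dmrs` over all rows, hyper/hypo totals over rows
#' where direction was assigned.
#'
#' @param counts per-comparison counts data.frame
#' @return list of class `ComparisonSummary`: `per_comparison` (the counts)
#'   and `total` (list `n_dmrs`, `n_hyper`, `n_hypo`)
#' @export
summarize_dmr_counts <- function(counts) {
  need <- c("comparison", "n_dmrs", "n_hyper", "n_hypo")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("counts table lacks column(s): ", paste(miss, collapse = ", "))
  directed <- !is.na(counts$n_hyper) & !is.na(counts$n_hypo)
  bad <- directed & (counts$n_hyper + counts$n_hypo != counts$n_dmrs)
  if (any(bad))
    stop("n_hyper + n_hypo != n_dmrs for: ",
         paste(counts$comparison[bad], collapse = ", "))
  structure(
    list(per_comparison = counts,
         total = list(n_dmrs = sum(counts$n_dmrs),
                      n_hyper = sum(counts$n_hyper[directed]),
                      n_hypo = sum(counts$n_hypo[directed]))),
    class = "ComparisonSummary"
  )
}

#' Summarize DMR sets across comparisons
#'
#' @param dmr_sets named list: comparison label -> DMR data.frame
#' @return a `ComparisonSummary` (see [summarize_dmr_counts()])
#' @export
summarize_comparisons <- function(dmr_sets) {
  if (!length(dmr_sets)) {
    counts <- data.frame(comparison = character(), n_dmrs = integer(),
                         n_hyper = integer(), n_hypo = integer())
    return(structure(list(per_comparison = counts,
                          total = list(n_dmrs = 0L, n_hyper = 0L, n_hypo = 0L)),
                     class = "ComparisonSummary"))
  }
  counts <- do.call(rbind, lapply(names(dmr_sets), function(cmp) {
    d <- dmr_sets[[cmp]]
    data.frame(comparison = cmp, n_dmrs = nrow(d),
               n_hyper = sum(d$direction == "hyper"),
               n_hypo = sum(d$direction == "hypo"))
  }))
  summarize_dmr_counts(counts)
}

#' @export
print.ComparisonSummary <- function(x, ...) {
  print(x$per_comparison, row.names = FALSE)
  cat(sprintf("Total: %d DMRs (%d hyper, %d hypo where directed)\n",
              x$total$n_dmrs, x$total$n_hyper, x$total$n_hypo))
  invisible(x)
}
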