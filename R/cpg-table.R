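#' CpG site count table
#'
#' The central container of the pipeline: per-CpG methylated and total read
#' counts across samples. Sites are keyed by (chromosome, 1-based position);
#' beta values are always derived from counts as
#' beta = methylated / (methylated + unmethylated), and are missing where a
#' sample has no reads at a site.
#'
#' @param chrom character vector of chromosome names
#' @param pos integer vector of 1-based CpG positions
#' @param meth integer matrix (sites x samples) of methylated read counts
#' @param total integer matrix (sites x samples) of total read counts
#'   (methylated + unmethylated)
#' @return an object of class `CpGSiteTable` with components `chrom`, `pos`,
#'   `meth`, `total` and `samples` (column names of the count matrices)
#' @export
cpg_site_table <- function(chrom, pos, meth, total) {
  meth <- as.matrix(meth)
  total <- as.matrix(total)
  n <- length(chrom)
  if (length(pos) != n || nrow(meth) != n || nrow(total) != n)
    stop("chrom, pos, meth and total must describe the same number of sites")
  if (!identical(dim(meth), dim(total)))
    stop("meth and total must have identical dimensions")
  if (is.null(colnames(meth)))
    stop("count matrices must carry sample ids as column names")
  if (!identical(colnames(meth), colnames(total)))
    stop("meth and total column names disagree")
  pos <- as.integer(pos)
  if (any(pos < 1L)) stop("CpG positions must be >= 1 (1-based)")
  if (any(meth < 0L) || any(total < 0L)) stop("read counts must be non-negative")
  if (any(meth > total)) stop("methylated count exceeds total count")
  o <- order_sites(chrom, pos)
  structure(
    list(chrom = as.character(chrom)[o], pos = pos[o],
         meth = meth[o, , drop = FALSE], total = total[o, , drop = FALSE],
         samples = colnames(meth)),
    class = "CpGSiteTable"
  )
}

#' @export
print.CpGSiteTable <- function(x, ...) {
  cat(sprintf("CpGSiteTable: %d CpG sites x %d samples on %d chromosome(s)\n",
              n_sites(x), length(x$samples), length(unique(x$chrom))))
  invisible(x)
}

#' Number of CpG sites in a table
#' @param x a `CpGSiteTable`
#' @return integer site count
#' @export
n_sites <- function(x) length(x$pos)

#' Beta values of a CpG site table
#'
#' @param x a `CpGSiteTable`
#' @param samples optional character vector restricting the columns
#' @return numeric matrix of beta values in \[0, 1\]; `NA` where total = 0
#' @export
beta_values <- function(x, samples = NULL) {
  stopifnot(inherits(x, "CpGSiteTable"))
  m <- x$meth
  d <- x$total
  if (!is.null(samples)) {
    miss <- setdiff(samples, x$samples)
    if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
    m <- m[, samples, drop = FALSE]
    d <- d[, samples, drop = FALSE]
  }
  b <- m / d
  b[d == 0L] <- NA_real_
  b
}

#' Subset the sites of a CpG table
#' @param x a `CpGSiteTable`
#' @param keep logical or integer index over sites
#' @return a `CpGSiteTable` with the selected sites
#' @export
subset_sites <- function(x, keep) {
  stopifnot(inherits(x, "CpGSiteTable"))
  cpg_site_table(x$chrom[keep], x$pos[keep],
                 x$meth[keep, , drop = FALSE], x$total[keep, , drop = FALSE])
}
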