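# Readers and writers for the plain-text formats the pipeline touches:
# Bismark cytosine coverage reports, sample sheets, BED intervals,
# UCSC-style chrom.sizes tables.

VALID_TISSUES <- c("tumor", "NAT")
VALID_SUBTYPES <- c("SSL", "TA", "VA_TVA", "CRC")
VALID_SPLITS <- c("discovery", "validation")

#' Read a Bismark cytosine coverage report for one sample
#'
#' Expects the 6-column coverage format written by
#' `bismark_methylation_extractor`: chromosome, start, end, methylation
#' percentage, methylated count, unmethylated count, with start = end
#' (single cytosine, 1-based). The methylation-percentage column is ignored
#' and betas are recomputed from the counts, so no rounding from upstream
#' tools propagates.
#'
#' @param path path to the coverage file (tab- or whitespace-delimited)
#' @param sample_id sample identifier to attach to the records
#' @return data.frame with columns `sample_id`, `chrom`, `pos`, `meth_count`,
#'   `unmeth_count`, `beta` (NA when depth is zero)
#' @export
read_bismark_cov <- function(path, sample_id) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), meth_count = integer(),
                      unmeth_count = integer(), beta = numeric()))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf != 6L)
  if (length(bad))
    stop(sprintf("malformed line %d in %s: expected 6 fields, found %d",
                 bad[1], path, nf[bad[1]]))
  m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  meth <- suppressWarnings(as.integer(m[, 5]))
  unmeth <- suppressWarnings(as.integer(m[, 6]))
  bad <- which(is.na(start) | is.na(end) | is.na(meth) | is.na(unmeth))
  if (length(bad))
    stop(sprintf("malformed line %d in %s: non-integer coordinate or count",
                 bad[1], path))
  bad <- which(start != end)
  if (length(bad))
    stop(sprintf("line %d in %s: start != end; expected single-cytosine records",
                 bad[1], path))
  if (any(start < 1L))
    stop("positions must be 1-based (>= 1) in ", path)
  bad <- which(meth < 0L | unmeth < 0L)
  if (length(bad))
    stop(sprintf("line %d in %s: negative read count", bad[1], path))
  depth <- meth + unmeth
  beta <- ifelse(depth > 0L, meth / depth, NA_real_)
  data.frame(sample_id = sample_id, chrom = m[, 1], pos = start,
             meth_count = meth, unmeth_count = unmeth, beta = beta)
}

#' Assemble a CpG site table from per-sample coverage files
#'
#' Takes the union of sites seen across samples; a site absent from a
#' sample's report (Bismark omits uncovered cytosines) gets zero counts and
#' a missing beta there.
#'
#' @param paths named character vector: sample_id -> coverage file path
#' @return a [cpg_site_table()] over the union of sites
#' @export
read_cov_files <- function(paths) {
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("paths must be named by sample_id")
  recs <- lapply(names(paths), function(s) read_bismark_cov(paths[[s]], s))
  all_sites <- unique(do.call(rbind, lapply(recs, function(r) r[c("chrom", "pos")])))
  o <- order_sites(all_sites$chrom, all_sites$pos)
  all_sites <- all_sites[o, , drop = FALSE]
  key <- paste(all_sites$chrom, all_sites$pos)
  ns <- nrow(all_sites)
  meth <- matrix(0L, ns, length(paths), dimnames = list(NULL, names(paths)))
  total <- meth
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    idx <- match(paste(r$chrom, r$pos), key)
    meth[idx, i] <- r$meth_count
    total[idx, i] <- r$meth_count + r$unmeth_count
  }
  cpg_site_table(all_sites$chrom, all_sites$pos, meth, total)
}

#' Read and validate a cohort sample sheet
#'
#' Tab-delimited with header `sample_id, patient_id, tissue, subtype, split`.
#' Tissue is `tumor` or `NAT`; subtype one of `SSL, TA, VA_TVA, CRC`; split
#' `discovery` or `validation`. A paired patient has exactly one tumor and
#' one NAT record; validation samples need no NAT partner.
#'
#' @param path sample sheet path
#' @return data.frame of validated records with a `pairs` attribute:
#'   data.frame(patient_id, tumor, nat) for fully paired patients
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' Validate an in-memory sample sheet
#' @param df data.frame with the sample-sheet columns
#' @return the validated data.frame with a `pairs` attribute
#' @export
validate_sample_sheet <- function(df) {
  need <- c("sample_id", "patient_id", "tissue", "subtype", "split")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(df$tissue), VALID_TISSUES)
  if (length(bad)) stop("unknown tissue value: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$subtype), VALID_SUBTYPES)
  if (length(bad)) stop("unknown subtype value: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$split), VALID_SPLITS)
  if (length(bad)) stop("unknown split value: ", paste(bad, collapse = ", "))
  for (p in unique(df$patient_id)) {
    sub <- df[df$patient_id == p, ]
    if (sum(sub$tissue == "tumor") > 1L)
      stop("patient with more than one tumor record: ", p)
    if (sum(sub$tissue == "NAT") > 1L)
      stop("patient with more than one NAT record: ", p)
  }
  tum <- df[df$tissue == "tumor", ]
  nat <- df[df$tissue == "NAT", ]
  both <- intersect(tum$patient_id, nat$patient_id)
  pairs <- data.frame(
    patient_id = both,
    tumor = tum$sample_id[match(both, tum$patient_id)],
    nat = nat$sample_id[match(both, nat$patient_id)],
    stringsAsFactors = FALSE
  )
  attr(df, "pairs") <- pairs
  df
}

#' Paired tumor/NAT sample map of a sample sheet
#' @param samples a validated sample sheet
#' @param subtype optional subtype filter
#' @return data.frame(patient_id, tumor, nat)
#' @export
sample_pairs <- function(samples, subtype = NULL) {
  pairs <- attr(samples, "pairs")
  if (is.null(pairs)) {
    samples <- validate_sample_sheet(samples)
    pairs <- attr(samples, "pairs")
  }
  if (!is.null(subtype)) {
    keep_pat <- samples$patient_id[samples$subtype %in% subtype]
    pairs <- pairs[pairs$patient_id %in% keep_pat, , drop = FALSE]
  }
  pairs
}

#' Write DMRs as a BED6+ file
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open. Columns: chrom, start, end, name (comparison label),
#' score (`frac_significant * 1000`, rounded), strand ("."), then
#' `n_cpgs`, `n_sig`, `mean_delta`, `direction`. Rows are sorted by
#' (chrom, start).
#'
#' @param dmrs a DMR data.frame as returned by [call_dmrs()]
#' @param path output path
#' @return the path, invisibly
#' @export
write_dmr_bed <- function(dmrs, path) {
  header <- paste("#chrom", "start", "end", "name", "score", "strand",
                  "n_cpgs", "n_sig", "mean_delta", "direction", sep = "\t")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  if (is.null(dmrs) || nrow(dmrs) == 0L) return(invisible(path))
  o <- order(dmrs$chrom, dmrs$start)
  dmrs <- dmrs[o, , drop = FALSE]
  lines <- paste(dmrs$chrom, dmrs$start - 1L, dmrs$end, dmrs$comparison,
                 round(dmrs$frac_significant * 1000),
                 ".", dmrs$n_cpgs, dmrs$n_sig,
                 sprintf("%.17g", dmrs$mean_delta), dmrs$direction,
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a DMR BED file written by [write_dmr_bed()]
#' @param path BED path
#' @return DMR data.frame with 1-based inclusive coordinates
#' @export
read_dmr_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_cpgs = integer(), n_sig = integer(),
                      frac_significant = numeric(), mean_delta = numeric(),
                      direction = character(), comparison = character())
  if (!length(lines)) return(empty)
  f <- strsplit(lines, "\t")
  if (any(lengths(f) != 10L)) stop("unexpected column count in ", path)
  m <- matrix(unlist(f), ncol = 10L, byrow = TRUE)
  n_cpgs <- as.integer(m[, 7])
  n_sig <- as.integer(m[, 8])
  data.frame(
    chrom = m[, 1],
    start = as.integer(m[, 2]) + 1L,
    end = as.integer(m[, 3]),
    n_cpgs = n_cpgs,
    n_sig = n_sig,
    frac_significant = n_sig / n_cpgs,
    mean_delta = as.numeric(m[, 9]),
    direction = m[, 10],
    comparison = m[, 4]
  )
}

#' Read a BED file of regions (e.g. an SNP mask or promoter annotation)
#' @param path BED path (first three columns used; 0-based half-open)
#' @return data.frame(chrom, start, end) with 1-based inclusive coordinates
#' @export
read_bed_regions <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  f <- strsplit(lines, "[ \t]+")
  if (any(lengths(f) < 3L)) stop("BED line with fewer than 3 fields in ", path)
  chrom <- vapply(f, `[[`, "", 1L)
  start <- as.integer(vapply(f, `[[`, "", 2L)) + 1L
  end <- as.integer(vapply(f, `[[`, "", 3L))
  if (any(is.na(start) | is.na(end)) || any(end < start))
    stop("invalid BED coordinates in ", path)
  data.frame(chrom = chrom, start = start, end = end)
}

#' Write regions as a minimal 3-column BED file
#' @param regions data.frame(chrom, start, end), 1-based inclusive
#' @param path output path
#' @return the path, invisibly
#' @export
write_bed_regions <- function(regions, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(regions)) {
    o <- order(regions$chrom, regions$start)
    writeLines(paste(regions$chrom[o], regions$start[o] - 1L, regions$end[o],
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a two-column chrom.sizes table
#' @param path UCSC chrom.sizes-style file: chromosome name, length in bp
#' @return data.frame(chrom, length, autosome); `autosome` flags chr1-chr22
#'   (with or without the "chr" prefix)
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, col.names = c("chrom", "length"),
                          stringsAsFactors = FALSE)
  if (any(df$length <= 0)) stop("chromosome lengths must be positive")
  genome_info(df$chrom, df$length)
}

#' Build a genome table from chromosome names and lengths
#' @param chrom chromosome names
#' @param length lengths in bp
#' @param autosome optional logical flag; by default chr1-chr22 / 1-22
#' @return data.frame(chrom, length, autosome)
#' @export
genome_info <- function(chrom, length, autosome = NULL) {
  if (any(length <= 0)) stop("chromosome lengths must be positive")
  if (is.null(autosome)) {
    core <- sub("^chr", "", chrom)
    autosome <- core %in% as.character(1:22)
  }
  data.frame(chrom = as.character(chrom), length = as.numeric(length),
             autosome = autosome)
}
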