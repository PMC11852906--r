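# CIMP-like classification: variable promoter CpG selection and consensus
# K-means clustering into CIMP-H vs CIMP-L/N.

#' CIMP classification configuration
#'
#' @param sd_threshold minimum beta standard deviation across tumors
#' @param normal_mean_max maximum mean beta across normal samples
#' @param k number of clusters (2: CIMP-H vs CIMP-L/N)
#' @param n_resamples consensus resampling rounds
#' @param subsample_frac fraction of samples (and CpGs) drawn per round
#' @param init center initialization: `"kmeans++"` (randomized, from the
#'   round's substream) or `"farthest"` (deterministic farthest-first)
#' @param seed integer seed for the resampling substreams
#' @return a `CIMPConfig` list
#' @export
cimp_config <- function(sd_threshold = 0.2, normal_mean_max = 0.05, k = 2L,
                        n_resamples = 100L, subsample_frac = 0.8,
                        init = c("kmeans++", "farthest"), seed = 1L) {
  init <- match.arg(init)
  if (subsample_frac <= 0 || subsample_frac > 1)
    stop("subsample_frac must lie in (0, 1]")
  if (k < 2L) stop("k must be >= 2")
  structure(list(sd_threshold = sd_threshold,
                 normal_mean_max = normal_mean_max, k = as.integer(k),
                 n_resamples = as.integer(n_resamples),
                 subsample_frac = subsample_frac, init = init,
                 seed = as.integer(seed)),
            class = "CIMPConfig")
}

#' Select variable promoter CpGs for CIMP classification
#'
#' Keeps CpGs inside promoter regions whose beta standard deviation across
#' tumor samples exceeds `sd_threshold` and whose mean beta across normal
#' samples is below `normal_mean_max`.
#'
#' @param sites a [cpg_site_table()]
#' @param tumors,normals sample id vectors
#' @param promoters data.frame(chrom, start, end) of promoter regions
#' @param config a [cimp_config()]
#' @return data.frame(chrom, pos, tumor_sd, normal_mean); errors if no CpG
#'   passes, advising threshold relaxation
#' @export
select_cimp_cpgs <- function(sites, tumors, normals, promoters,
                             config = cimp_config()) {
  stopifnot(inherits(sites, "CpGSiteTable"))
  if (!length(tumors) || !length(normals))
    stop("tumors and normals must be non-empty")
  if (!nrow(promoters)) stop("promoter region table is empty")
  hit <- GenomicRanges::findOverlaps(
    positions_to_granges(sites$chrom, sites$pos),
    regions_to_granges(promoters))
  in_prom <- unique(S4Vectors::queryHits(hit))
  bt <- beta_values(sites, tumors)[in_prom, , drop = FALSE]
  bn <- beta_values(sites, normals)[in_prom, , drop = FALSE]
  tumor_sd <- apply(bt, 1, stats::sd, na.rm = TRUE)
  normal_mean <- rowMeans(bn, na.rm = TRUE)
  keep <- !is.na(tumor_sd) & tumor_sd > config$sd_threshold &
    !is.na(normal_mean) & normal_mean < config$normal_mean_max
  if (!any(keep))
    stop("no promoter CpG passes the variability/normal-methylation filter; ",
         "consider relaxing sd_threshold or normal_mean_max")
  idx <- in_prom[keep]
  data.frame(chrom = sites$chrom[idx], pos = sites$pos[idx],
             tumor_sd = tumor_sd[keep], normal_mean = normal_mean[keep])
}

# Center initialization over the rows of x. kmeans++: distance-weighted
# random seeding; farthest: deterministic farthest-first traversal from the
# point farthest from the grand mean (ties -> lowest index).
.init_centers <- function(x, k, init) {
  n <- nrow(x)
  centers <- integer(k)
  if (init == "farthest") {
    d0 <- rowSums(sweep(x, 2, colMeans(x))^2)
    centers[1] <- which.max(d0)
  } else {
    centers[1] <- sample.int(n, 1L)
  }
  d2 <- rowSums(sweep(x, 2, x[centers[1], ])^2)
  for (j in seq_len(k - 1L)) {
    if (init == "farthest") {
      centers[j + 1L] <- which.max(d2)
    } else {
      if (sum(d2) == 0) {
        pool <- setdiff(seq_len(n), centers[seq_len(j)])
        centers[j + 1L] <- pool[sample.int(length(pool), 1L)]
      } else {
        centers[j + 1L] <- sample.int(n, 1L, prob = d2 / sum(d2))
      }
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[centers[j + 1L], ])^2))
  }
  centers
}

# One K-means round robust to duplicate rows: if fewer distinct rows than
# k, cluster by row identity instead.
.kmeans_round <- function(x, k, init) {
  ux <- unique(x)
  if (nrow(ux) <= k) {
    key <- apply(x, 1, paste, collapse = ",")
    return(as.integer(factor(key, levels = unique(key))))
  }
  ci <- .init_centers(x, k, init)
  cent <- x[ci, , drop = FALSE]
  if (nrow(unique(cent)) < k) {
    # fall back to k distinct rows closest to the chosen ones
    cent <- ux[seq_len(k), , drop = FALSE]
  }
  suppressWarnings(stats::kmeans(x, centers = cent, iter.max = 100L)$cluster)
}

#' Consensus K-means clustering
#'
#' Repeats K-means `n_resamples` times, each round on a random subset of
#' samples and items (CpGs), and records how often each sample pair lands in
#' the same cluster among the rounds where both were drawn:
#' `consensus(i, j) = co-cluster count / co-sampled count`. The final
#' partition cuts average-linkage hierarchical clustering of
#' `1 - consensus` into `k` groups. Fully reproducible from the seed.
#'
#' @param matrix sample x CpG beta matrix (rownames = sample ids)
#' @param config a [cimp_config()]
#' @return list of class `consensus_clustering`: `consensus` (sample x
#'   sample), `partition` (named integer cluster vector), `config`
#' @export
consensus_cluster <- function(matrix, config = cimp_config()) {
  x <- as.matrix(matrix)
  n <- nrow(x)
  if (n < config$k + 1L) stop("need at least k + 1 samples")
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(n))
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  ns <- max(config$k + 1L, ceiling(config$subsample_frac * n))
  ni <- max(1L, ceiling(config$subsample_frac * ncol(x)))
  co <- matrix(0, n, n)
  tog <- matrix(0, n, n)
  for (b in seq_len(config$n_resamples)) {
    res <- with_seed(derive_seed(config$seed, "resample", b), {
      si <- sort(sample.int(n, ns))
      ii <- sort(sample.int(ncol(x), ni))
      cl <- .kmeans_round(x[si, ii, drop = FALSE], config$k, config$init)
      list(si = si, cl = cl)
    })
    tog[res$si, res$si] <- tog[res$si, res$si] + 1
    same <- outer(res$cl, res$cl, `==`)
    co[res$si, res$si] <- co[res$si, res$si] + same
  }
  cons <- co / tog
  if (any(tog == 0)) {
    warning("some sample pairs were never co-sampled; ",
            "their consensus entries are mean-imputed")
    cons[tog == 0] <- mean(cons[tog > 0])
  }
  diag(cons) <- 1
  dimnames(cons) <- list(rownames(x), rownames(x))
  hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
  part <- stats::cutree(hc, k = config$k)
  structure(list(consensus = cons, partition = part, config = config),
            class = "consensus_clustering")
}

#' Assign CIMP labels to a 2-group partition
#'
#' The cluster with the higher mean beta over the selected CpGs becomes
#' CIMP-H; the other CIMP-L/N. A tie in cluster means labels everything
#' CIMP-L/N with a warning.
#'
#' @param partition integer cluster vector named by sample (2 clusters)
#' @param matrix sample x CpG beta matrix used for clustering
#' @return data.frame(sample_id, cluster, label)
#' @export
assign_cimp <- function(partition, matrix) {
  ks <- sort(unique(partition))
  if (length(ks) != 2L)
    stop("CIMP assignment requires exactly 2 non-empty clusters, found ",
         length(ks))
  x <- as.matrix(matrix)[names(partition), , drop = FALSE]
  m <- vapply(ks, function(k) mean(x[partition == k, , drop = FALSE],
                                   na.rm = TRUE), 0)
  if (m[1] == m[2]) {
    warning("tied cluster means; labelling all samples CIMP-L/N")
    lab <- rep("CIMP-L/N", length(partition))
  } else {
    high <- ks[which.max(m)]
    lab <- ifelse(partition == high, "CIMP-H", "CIMP-L/N")
  }
  data.frame(sample_id = names(partition), cluster = unname(partition),
             label = unname(lab))
}

#' CIMP classification of a cohort
#'
#' Wires CpG selection, consensus clustering and label assignment: selects
#' variable promoter CpGs (tumor SD and normal-mean thresholds), clusters
#' the tumor samples on those CpGs, and labels the high-methylation cluster
#' CIMP-H.
#'
#' @param sites a [cpg_site_table()]
#' @param samples validated sample sheet; tumors and NATs are taken from it
#' @param promoters promoter region data.frame(chrom, start, end)
#' @param config a [cimp_config()]
#' @return list of class `cimp_result`: `labels` (sample_id, cluster,
#'   label), `consensus`, `selected_cpgs`
#' @export
cimp_classify <- function(sites, samples, promoters, config = cimp_config()) {
  tumors <- samples$sample_id[samples$tissue == "tumor"]
  normals <- samples$sample_id[samples$tissue == "NAT"]
  sel <- select_cimp_cpgs(sites, tumors, normals, promoters, config)
  key <- paste(sites$chrom, sites$pos)
  idx <- match(paste(sel$chrom, sel$pos), key)
  mat <- t(beta_values(sites, tumors)[idx, , drop = FALSE])
  cc <- consensus_cluster(mat, config)
  labels <- assign_cimp(cc$partition, mat)
  structure(list(labels = labels, consensus = cc$consensus,
                 selected_cpgs = sel),
            class = "cimp_result")
}
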