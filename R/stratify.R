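# PCA of the signature region-beta matrix and Kruskal-Wallis testing of
# subtype separation on first-component scores.

#' PCA stratification of samples on a region-beta matrix
#'
#' Samples are observations, regions variables. Missing entries are imputed
#' with the region mean; zero-variance regions are dropped with a warning;
#' columns are centered and unit-scaled before singular-value decomposition
#' (via `prcomp`). Each component is oriented so that its largest-magnitude
#' loading is positive, making signs deterministic. The contribution of a
#' region to a component is its squared-loading share in percent.
#'
#' @param matrix region x sample beta matrix (see [region_beta_matrix()])
#' @param top_n how many top-contributing regions to report per component
#' @param project optional second region x sample matrix (same regions)
#'   whose samples are projected onto the fitted components rather than
#'   co-decomposed
#' @return list of class `pca_stratification`: `scores` (samples x PCs),
#'   `loadings` (regions x PCs), `var_explained`, `contributions` (percent),
#'   `top_regions` (list per PC), `projected` (scores of `project` samples,
#'   or NULL), `dropped_regions`
#' @export
pca_stratify <- function(matrix, top_n = 30L, project = NULL) {
  x <- t(matrix)
  if (nrow(x) < 3L) stop("PCA stratification needs at least 3 samples")
  if (ncol(x) < 2L) stop("PCA stratification needs at least 2 regions")
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mu[j]
  v <- apply(x, 2, stats::var)
  dropped <- colnames(x)[v == 0 | is.na(v)]
  if (length(dropped)) {
    warning(length(dropped), " zero-variance region(s) dropped before PCA")
    x <- x[, v > 0 & !is.na(v), drop = FALSE]
    if (ncol(x) < 2L) stop("fewer than 2 regions left after dropping")
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(pr$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  pr$rotation <- sweep(pr$rotation, 2, flip, `*`)
  pr$x <- sweep(pr$x, 2, flip, `*`)
  var_exp <- pr$sdev^2 / sum(pr$sdev^2)
  contrib <- sweep(pr$rotation^2, 2, colSums(pr$rotation^2), `/`) * 100
  top <- lapply(seq_len(ncol(contrib)), function(c) {
    o <- order(contrib[, c], decreasing = TRUE)
    utils::head(data.frame(region = rownames(contrib)[o],
                           contribution = contrib[o, c],
                           loading = pr$rotation[o, c]), top_n)
  })
  names(top) <- colnames(pr$rotation)
  projected <- NULL
  if (!is.null(project)) {
    px <- t(project[rownames(pr$rotation), , drop = FALSE])
    pmu <- colMeans(px, na.rm = TRUE)
    for (j in seq_len(ncol(px))) px[is.na(px[, j]), j] <- pmu[j]
    projected <- stats::predict(pr, px)
  }
  structure(list(scores = pr$x, loadings = pr$rotation,
                 var_explained = var_exp, contributions = contrib,
                 top_regions = top, projected = projected,
                 dropped_regions = dropped, center = pr$center,
                 scale = pr$scale),
            class = "pca_stratification")
}

#' Kruskal-Wallis test of subtype separation on PC scores
#'
#' Global rank-based k-group test (tie-corrected H referred to chi-square on
#' k - 1 degrees of freedom) plus pairwise two-group rank-sum tests,
#' reported unadjusted.
#'
#' @param scores numeric vector (e.g. PC1 sample scores)
#' @param labels group labels, same length; every group needs >= 2 samples
#' @return list of class `kw_result`: `H`, `df`, `p_global`, `pairwise`
#'   (data.frame `group1`, `group2`, `p`)
#' @export
kruskal_subtypes <- function(scores, labels) {
  labels <- as.character(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L))
    stop("every group needs at least 2 samples; too small: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  kt <- stats::kruskal.test(scores, factor(labels))
  groups <- names(tab)
  pw <- utils::combn(groups, 2)
  pairwise <- data.frame(
    group1 = pw[1, ], group2 = pw[2, ],
    p = apply(pw, 2, function(g) {
      suppressWarnings(stats::wilcox.test(scores[labels == g[1]],
                                          scores[labels == g[2]])$p.value)
    })
  )
  structure(list(H = unname(kt$statistic), df = unname(kt$parameter),
                 p_global = kt$p.value, pairwise = pairwise),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g on %d df, p = %.3g\n",
              x$H, x$df, x$p_global))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
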