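test_that("coverage filter requires the minimum depth in every sample", {
  total <- rbind(c(5L, 5L, 5L), c(5L, 4L, 5L), c(20L, 20L, 20L))
  meth <- matrix(1L, 3, 3)
  colnames(total) <- colnames(meth) <- c("a", "b", "c")
  st <- cpg_site_table(rep("chr1", 3), c(100L, 200L, 300L), meth, total)
  kept <- filter_sites(st, analysis_config())
  expect_equal(kept$pos, c(100L, 300L))
})

test_that("masked positions are dropped regardless of depth; empty mask is identity", {
  total <- matrix(50L, 3, 3, dimnames = list(NULL, c("a", "b", "c")))
  meth <- matrix(10L, 3, 3, dimnames = list(NULL, c("a", "b", "c")))
  st <- cpg_site_table(rep("chr1", 3), c(100L, 200L, 300L), meth, total)
  mask <- data.frame(chrom = "chr1", start = 100L, end = 100L)
  expect_equal(filter_sites(st, mask = mask)$pos, c(200L, 300L))
  expect_equal(filter_sites(st)$pos, st$pos)
})

test_that("paired signed-rank p-values hit the exact small-sample values", {
  # 6 pairs, all differences positive, no ties: p = 2/2^6
  betas <- rbind(c(0.81, 0.72, 0.63, 0.54, 0.45, 0.36,
                   0.1, 0.2, 0.3, 0.4, 0.05, 0.15))
  colnames(betas) <- c(paste0("T", 1:6), paste0("N", 1:6))
  st <- table_from_betas(betas, pos = 100L)
  res <- test_sites(st, paste0("T", 1:6), paste0("N", 1:6), paired = TRUE)
  expect_equal(res$p_raw, 0.03125)
  # 5 pairs all positive: p = 2/2^5 = 0.0625, never below alpha = 0.05
  d5 <- aplmeth:::.signed_rank_p(c(0.11, 0.22, 0.33, 0.44, 0.55))
  expect_equal(unname(d5["p"]), 0.0625)
})

test_that("unpaired rank-sum with complete 4 vs 4 separation gives 2/70", {
  p <- aplmeth:::.rank_sum_p(c(0.8, 0.7, 0.65, 0.6), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(unname(p["p"]), 2 / 70)
})

test_that("sites with fewer than 3 informative pairs are flagged untestable", {
  # 3 pairs, one zero difference -> 2 informative
  out <- aplmeth:::.signed_rank_p(c(0.2, -0.1, 0))
  expect_equal(unname(out["p"]), 1)
  expect_equal(unname(out["testable"]), 0)
})

test_that("the site engine agrees with wilcox.test on tied and untied data", {
  withr::local_seed(99)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    mine <- aplmeth:::.signed_rank_p(x - y)
    ref <- suppressWarnings(wilcox.test(x, y, paired = TRUE))$p.value
    expect_equal(unname(mine["p"]), ref, tolerance = 1e-12)
    # tied, discrete data exercise the normal-approximation branch
    xt <- sample(seq(0, 1, 0.25), n, replace = TRUE)
    yt <- sample(seq(0, 1, 0.25), n, replace = TRUE)
    if (any(xt != yt)) {
      mine <- aplmeth:::.signed_rank_p(xt - yt)
      ref <- suppressWarnings(wilcox.test(xt, yt, paired = TRUE))$p.value
      expect_equal(unname(mine["p"]), ref, tolerance = 1e-12)
    }
    m <- sample(3:10, 1)
    z <- rnorm(m)
    mine <- aplmeth:::.rank_sum_p(x, z)
    ref <- suppressWarnings(wilcox.test(x, z))$p.value
    expect_equal(unname(mine["p"]), ref, tolerance = 1e-12)
    zt <- sample(seq(0, 1, 0.25), m, replace = TRUE)
    mine <- aplmeth:::.rank_sum_p(xt, zt)
    ref <- suppressWarnings(wilcox.test(xt, zt))$p.value
    if (is.finite(ref)) expect_equal(unname(mine["p"]), ref, tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up formula on worked examples", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(c(0.04, 0.01)), c(0.04, 0.02))
  expect_equal(adjust_bh(0.5), 0.5)
  expect_equal(adjust_bh(numeric(0)), numeric(0))
  expect_error(adjust_bh(c(0.5, 0)), "0, 1")
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")
})

test_that("BH output dominates input and is permutation-equivariant", {
  withr::local_seed(4)
  for (rep in 1:10) {
    p <- runif(sample(1:50, 1))
    adj <- adjust_bh(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    perm <- sample(length(p))
    expect_equal(adjust_bh(p[perm]), adj[perm])
  }
})

test_that("delta_beta follows the A-minus-B sign convention and flags jointly", {
  betas <- cbind(matrix(0.9, 4, 4), matrix(0.1, 4, 4))
  colnames(betas) <- c(paste0("A", 1:4), paste0("B", 1:4))
  st <- table_from_betas(betas)
  res <- test_sites(st, paste0("A", 1:4), paste0("B", 1:4), paired = FALSE)
  expect_true(all(res$delta_beta == 0.8))
  expect_true(all(res$significant))
  res_rev <- test_sites(st, paste0("B", 1:4), paste0("A", 1:4), paired = FALSE)
  expect_true(all(res_rev$delta_beta == -0.8))
})

test_that("raw p-values are calibrated (conservative) on null cohorts", {
  ch <- generate_null_cohort(simulation_config(n_cpgs = 2000L, n_chroms = 2L,
                                               chrom_length = 1e6, seed = 17))
  ft <- filter_sites(ch$sites)
  pr <- sample_pairs(ch$samples, "SSL")
  res <- test_sites(ft, pr$tumor, pr$nat, paired = TRUE)
  frac <- mean(res$p_raw < 0.05)
  bound <- 0.05 + 2 * sqrt(0.05 * 0.95 / nrow(res))
  expect_lte(frac, bound)
  expect_equal(mean(res$significant), 0)
})
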