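test_that("gap clustering groups positions within 50 bp and splits beyond", {
  expect_equal(cluster_sites(c(100L, 130L, 170L, 300L), 50L),
               list(c(100L, 130L, 170L), 300L))
  expect_equal(cluster_sites(c(100L, 151L), 50L), list(100L, 151L))
  expect_equal(cluster_sites(c(100L, 150L), 50L), list(c(100L, 150L)))
  expect_equal(cluster_sites(7L, 50L), list(7L))
  expect_equal(cluster_sites(integer(0), 50L), list())
  expect_error(cluster_sites(c(200L, 100L), 50L), "sorted")
})

test_that("region filters enforce CpG count, significant fraction and sign", {
  cfg <- analysis_config()
  # 5 CpGs, 3 significant, same sign: retained at the inclusive 60% boundary
  res <- make_site_results(c(100, 120, 140, 160, 180),
                           c(TRUE, TRUE, TRUE, FALSE, FALSE),
                           c(0.3, 0.25, 0.3, 0.05, 0.02))
  d <- call_dmrs(res, cfg, "cmp")
  expect_equal(nrow(d), 1L)
  expect_equal(d$n_cpgs, 5L)
  expect_equal(d$frac_significant, 0.6)
  expect_equal(d$start, 100L)
  expect_equal(d$end, 180L)
  expect_equal(d$direction, "hyper")
  expect_equal(d$mean_delta, mean(c(0.3, 0.25, 0.3)))
  expect_equal(d$comparison, "cmp")

  # 2-CpG cluster is never a region, even fully significant
  res2 <- make_site_results(c(100, 120), c(TRUE, TRUE), c(0.3, 0.3))
  expect_equal(nrow(call_dmrs(res2, cfg)), 0L)

  # 4 CpGs, 3 significant but mixed sign: discarded
  res3 <- make_site_results(c(100, 120, 140, 160),
                            c(TRUE, TRUE, TRUE, FALSE),
                            c(0.3, 0.25, -0.3, 0.02))
  expect_equal(nrow(call_dmrs(res3, cfg)), 0L)

  # 5 CpGs with only 2 significant (40%): below the fraction threshold
  res4 <- make_site_results(c(100, 120, 140, 160, 180),
                            c(TRUE, TRUE, FALSE, FALSE, FALSE),
                            rep(0.3, 5))
  expect_equal(nrow(call_dmrs(res4, cfg)), 0L)
})

test_that("a 51 bp gap always splits a candidate region", {
  # 6 significant CpGs but a 51 bp gap in the middle: two 3-CpG regions
  res <- make_site_results(c(100, 120, 140, 191, 211, 231), rep(TRUE, 6),
                           rep(0.3, 6))
  d <- call_dmrs(res, analysis_config(), "x")
  expect_equal(nrow(d), 2L)
  expect_equal(d$start, c(100L, 191L))
  expect_equal(d$end, c(140L, 231L))
  # at exactly 50 bp the run stays together
  res50 <- make_site_results(c(100, 120, 140, 190, 210, 230), rep(TRUE, 6),
                             rep(0.3, 6))
  expect_equal(nrow(call_dmrs(res50, analysis_config())), 1L)
})

test_that("DMR calling is invariant to input row order", {
  withr::local_seed(8)
  res <- rbind(
    make_site_results(c(100, 130, 160, 190, 220), rep(TRUE, 5), rep(0.25, 5)),
    make_site_results(c(500, 530, 560), rep(TRUE, 3), rep(-0.3, 3), chrom = "chr2"))
  base <- call_dmrs(res, analysis_config(), "c")
  shuf <- call_dmrs(res[sample(nrow(res)), ], analysis_config(), "c")
  expect_equal(base, shuf)
  expect_equal(base$direction, c("hyper", "hypo"))
})

test_that("untestable sites count toward region size but not significance", {
  res <- make_site_results(c(100, 120, 140, 160, 180),
                           c(TRUE, TRUE, TRUE, FALSE, FALSE),
                           c(0.3, 0.3, 0.3, 0.1, 0.1))
  res$testable[4:5] <- FALSE
  d <- call_dmrs(res, analysis_config(), "c")
  expect_equal(d$n_cpgs, 5L)
  expect_equal(d$n_sig, 3L)
})

test_that("comparison summaries add per-row and grand totals", {
  s <- summarize_comparisons(list())
  expect_equal(s$total, list(n_dmrs = 0L, n_hyper = 0L, n_hypo = 0L))

  one <- rbind(dmr_row("chr1", 100, 200, 0.3), dmr_row("chr1", 400, 500, 0.4),
               dmr_row("chr1", 700, 800, 0.5), dmr_row("chr2", 100, 200, -0.3),
               dmr_row("chr2", 400, 500, -0.2))
  s <- summarize_comparisons(list(A_vs_B = one))
  expect_equal(s$total$n_dmrs, 5L)
  expect_equal(s$total$n_hyper, 3L)
  expect_equal(s$total$n_hypo, 2L)

  counts <- data.frame(comparison = c("a", "b"), n_dmrs = c(3L, 2L),
                       n_hyper = c(1L, NA), n_hypo = c(2L, NA))
  s <- summarize_dmr_counts(counts)
  expect_equal(s$total$n_dmrs, 5L)
  expect_equal(s$total$n_hyper, 1L)
  bad <- counts; bad$n_hyper[1] <- 2L
  expect_error(summarize_dmr_counts(bad), "!=")
})
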