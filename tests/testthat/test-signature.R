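test_that("signature selection drops NAT-overlapping and multi-subtype regions", {
  # r1, r2 hyper in SSL (vs TA); r2, r3 hyper in TA (vs VA/TVA);
  # r3 overlaps a lesion-vs-NAT DMR.
  r1 <- dmr_row("chr1", 100, 200, 0.30, "SSL_vs_TA")
  r2a <- dmr_row("chr1", 500, 600, 0.30, "SSL_vs_TA")
  r2b <- dmr_row("chr1", 550, 650, 0.25, "TA_vs_VA_TVA")
  r3 <- dmr_row("chr2", 100, 200, 0.30, "TA_vs_VA_TVA")
  inter <- list(SSL_vs_TA = rbind(r1, r2a), TA_vs_VA_TVA = rbind(r2b, r3))
  vs_nat <- list(TA_vs_TA_NAT = dmr_row("chr2", 150, 160, 0.3, "TA_vs_TA_NAT"))
  sig <- select_unique_hyper(inter, vs_nat)
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$subtype, "SSL")
  expect_equal(sig$start, 100L)

  # empty exclusion set: pure uniqueness partition (r3 survives as TA)
  sig2 <- select_unique_hyper(inter, list())
  expect_setequal(sig2$subtype, c("SSL", "TA"))
  expect_equal(nrow(sig2), 2L)

  # everything overlapping NAT results: empty signature
  sig3 <- select_unique_hyper(inter, list(x = rbind(
    dmr_row("chr1", 1, 1000, 0.3), dmr_row("chr2", 1, 1000, 0.3))))
  expect_equal(nrow(sig3), 0L)
})

test_that("negative mean_delta assigns a region to the second-named subtype", {
  inter <- list(SSL_vs_VA_TVA = dmr_row("chr1", 100, 200, -0.4, "SSL_vs_VA_TVA"))
  sig <- select_unique_hyper(inter)
  expect_equal(sig$subtype, "VA_TVA")
  expect_equal(sig$mean_delta, 0.4)
})

test_that("repeated claims by one subtype merge with joined provenance", {
  inter <- list(SSL_vs_TA = dmr_row("chr1", 100, 200, 0.3, "SSL_vs_TA"),
                SSL_vs_VA_TVA = dmr_row("chr1", 100, 200, 0.5, "SSL_vs_VA_TVA"))
  sig <- select_unique_hyper(inter)
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$source, "SSL_vs_TA;SSL_vs_VA_TVA")
  expect_equal(sig$mean_delta, 0.4)
})

test_that("signature selection is invariant to comparison order", {
  a <- dmr_row("chr1", 100, 200, 0.3, "SSL_vs_TA")
  b <- dmr_row("chr1", 400, 500, -0.3, "TA_vs_VA_TVA")
  s1 <- select_unique_hyper(list(SSL_vs_TA = a, TA_vs_VA_TVA = b))
  s2 <- select_unique_hyper(list(TA_vs_VA_TVA = b, SSL_vs_TA = a))
  expect_equal(s1, s2)
})

test_that("chromosome enrichment follows the length-normalized formula", {
  genome <- genome_info(c("chr1", "chr2"), c(1e6, 1e6))
  dmrs <- rbind(dmr_row("chr1", 100, 200), dmr_row("chr1", 300, 400),
                dmr_row("chr1", 500, 600), dmr_row("chr2", 100, 200))
  enr <- chromosome_enrichment(dmrs, genome)
  expect_equal(enr$enrichment, c(1.5, 0.5))
  expect_equal(enr$flagged, c(FALSE, FALSE))
  expect_true(chromosome_enrichment(dmrs, genome, flag_threshold = 1.4)$flagged[1])

  # counts proportional to lengths -> all 1; weighted mean exactly 1
  genome2 <- genome_info(c("chr1", "chr2"), c(2e6, 1e6))
  dmrs2 <- rbind(dmr_row("chr1", 1, 10), dmr_row("chr1", 100, 110),
                 dmr_row("chr2", 1, 10))
  enr2 <- chromosome_enrichment(dmrs2, genome2)
  expect_equal(enr2$enrichment, c(1, 1))
  expect_equal(sum(enr$enrichment * enr$length) / sum(enr$length), 1)

  expect_error(chromosome_enrichment(dmr_row("chrZ", 1, 10), genome),
               "absent from genome")
})

test_that("non-autosomes are excluded from enrichment totals", {
  genome <- genome_info(c("chr1", "chr2", "chrX"), c(1e6, 1e6, 1e6))
  dmrs <- rbind(dmr_row("chr1", 100, 200), dmr_row("chr2", 100, 200),
                dmr_row("chrX", 100, 200))
  enr <- chromosome_enrichment(dmrs, genome)
  expect_equal(enr$chrom, c("chr1", "chr2"))
  expect_equal(enr$enrichment, c(1, 1))
})

test_that("region beta matrix averages member CpGs per sample", {
  betas <- cbind(s1 = c(0.2, 0.4, 0.9), s2 = c(0.5, 0, 0.1))
  st <- table_from_betas(betas, pos = c(100L, 140L, 500L))
  st$total[2, "s2"] <- 0L  # no coverage at second CpG for s2
  st$meth[2, "s2"] <- 0L
  regions <- data.frame(chrom = "chr1", start = c(90L, 480L, 900L),
                        end = c(150L, 510L, 950L))
  expect_warning(m <- region_beta_matrix(regions, st), "no tested CpG")
  expect_equal(unname(m[1, "s1"]), 0.3)   # mean of 0.2, 0.4
  expect_equal(unname(m[1, "s2"]), 0.5)   # missing CpG ignored
  expect_equal(unname(m[2, ]), c(0.9, 0.1))  # single-CpG overlap
  expect_true(all(is.na(m[3, ])))
})
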