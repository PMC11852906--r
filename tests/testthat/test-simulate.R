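test_that("identical seeds give bit-identical cohorts", {
  a <- generate_cohort(small_sim_config(seed = 42))
  b <- generate_cohort(small_sim_config(seed = 42))
  expect_identical(a$sites$meth, b$sites$meth)
  expect_identical(a$sites$total, b$sites$total)
  expect_identical(a$truth$regions, b$truth$regions)
  c <- generate_cohort(small_sim_config(seed = 43))
  expect_false(identical(a$sites$meth, c$sites$meth))
})

test_that("count matrices and pairing respect the generative contract", {
  ch <- generate_cohort(small_sim_config(seed = 5))
  st <- ch$sites
  expect_true(all(st$meth >= 0L))
  expect_true(all(st$meth <= st$total))
  b <- beta_values(st)
  expect_true(all(is.na(b) | (b >= 0 & b <= 1)))
  expect_true(all(is.na(b) == (st$total == 0L)))
  # every discovery patient has exactly one tumor and one NAT sample
  disc <- ch$samples[ch$samples$split == "discovery", ]
  tab <- table(disc$patient_id, disc$tissue)
  expect_true(all(tab == 1L))
})

test_that("planted-region geometry satisfies the aggregation rules", {
  ch <- generate_cohort(small_sim_config(seed = 9))
  reg <- ch$truth$regions
  expect_true(all(reg$n_cpgs >= ch$config$region_n_cpgs |
                  reg$class == "cimp_panel"))
  # regions are non-overlapping and contain >= 3 CpGs with gaps <= 50 bp
  gr <- GenomicRanges::GRanges(reg$chrom, IRanges::IRanges(reg$start, reg$end))
  expect_equal(sum(GenomicRanges::countOverlaps(gr, gr) > 1), 0L)
  for (i in seq_len(nrow(reg))) {
    inside <- ch$sites$pos[ch$sites$chrom == reg$chrom[i] &
                           ch$sites$pos >= reg$start[i] &
                           ch$sites$pos <= reg$end[i]]
    expect_gte(length(inside), 3L)
    expect_true(all(diff(sort(inside)) <= 50L))
  }
})

test_that("null cohorts have empty truth and Poisson-consistent depth", {
  cfg <- small_sim_config(seed = 7)
  ch <- generate_null_cohort(cfg)
  expect_equal(nrow(ch$truth$regions), 0L)
  expect_equal(nrow(ch$truth$promoters), 0L)
  expect_true(all(ch$truth$cimp_labels$cimp == "CIMP-L/N"))
  d <- as.numeric(ch$sites$total)
  se <- sqrt(cfg$mean_depth / length(d))
  expect_lt(abs(mean(d) - cfg$mean_depth), 3 * se)
})

test_that("planted tumor-NAT beta shift matches the configured effect size", {
  # Monte-Carlo check against the generating model: depth 50, delta 0.4,
  # 10 pairs/subtype, hyper-only plants.
  cfg <- simulation_config(n_cpgs = 1000L, n_chroms = 2L, chrom_length = 5e5,
                           mean_depth = 50, planted_delta = 0.4,
                           region_n_cpgs = 5L, hypo_fraction = 0,
                           planted_regions_per_subtype = 10L,
                           signature_regions_per_subtype = 0L,
                           shared_regions = 0L, cimp_fraction = 0,
                           cimp_promoter_regions = 0L, seed = 31)
  ch <- generate_cohort(cfg)
  b <- beta_values(ch$sites)
  reg <- ch$truth$regions
  diffs <- c()
  for (i in which(reg$class == "subtype_tumor")) {
    idx <- ch$sites$chrom == reg$chrom[i] & ch$sites$pos >= reg$start[i] &
      ch$sites$pos <= reg$end[i]
    pr <- sample_pairs(ch$samples, reg$subtype[i])
    diffs <- c(diffs, rowMeans(b[idx, pr$tumor, drop = FALSE]) -
                 rowMeans(b[idx, pr$nat, drop = FALSE]))
  }
  expect_lt(abs(mean(diffs) - 0.4), 0.05)
})

test_that("a zero-delta cohort plants regions with no expected shift", {
  cfg <- small_sim_config(seed = 3, planted_delta = 0)
  ch <- generate_cohort(cfg)
  expect_gt(nrow(ch$truth$regions), 0L)
  b <- beta_values(ch$sites)
  reg <- ch$truth$regions[ch$truth$regions$class == "subtype_tumor", ]
  diffs <- c()
  for (i in seq_len(nrow(reg))) {
    idx <- ch$sites$chrom == reg$chrom[i] & ch$sites$pos >= reg$start[i] &
      ch$sites$pos <= reg$end[i]
    pr <- sample_pairs(ch$samples, reg$subtype[i])
    diffs <- c(diffs, rowMeans(b[idx, pr$tumor, drop = FALSE]) -
                 rowMeans(b[idx, pr$nat, drop = FALSE]))
  }
  expect_lt(abs(mean(diffs)), 0.05)
})

test_that("adding validation samples does not perturb discovery counts", {
  base <- generate_cohort(small_sim_config(seed = 12))
  ext <- generate_cohort(small_sim_config(seed = 12,
                                          n_validation_per_subtype = 3L))
  expect_identical(base$sites$meth, ext$sites$meth[, base$sites$samples])
  expect_identical(base$sites$total, ext$sites$total[, base$sites$samples])
})

test_that("emitted coverage files reconstruct the count matrix bit-exactly", {
  ch <- generate_cohort(small_sim_config(seed = 21))
  dir <- withr::local_tempdir()
  paths <- write_cohort(ch, dir)
  back <- read_cov_files(paths$cov)
  # uncovered sites are omitted from files; both representations put 0 there
  common <- match(paste(ch$sites$chrom, ch$sites$pos),
                  paste(back$chrom, back$pos))
  covered <- rowSums(ch$sites$total) > 0
  expect_true(all(!is.na(common[covered])))
  idx <- common[covered]
  expect_identical(back$meth[idx, ch$sites$samples],
                   ch$sites$meth[covered, , drop = FALSE])
  expect_identical(back$total[idx, ch$sites$samples],
                   ch$sites$total[covered, , drop = FALSE])
  # sample sheet round-trips
  sheet <- read_sample_sheet(paths$samples)
  expect_equal(sheet$sample_id, ch$samples$sample_id)
})

test_that("infeasible geometry is rejected", {
  expect_error(
    generate_cohort(simulation_config(n_cpgs = 5000L, n_chroms = 1L,
                                      chrom_length = 1e4)),
    "infeasible")
})
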