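# End-to-end workflow: simulate -> filter -> test -> dmr -> summarize ->
# signature -> stratify -> cimp, with a reproducibility manifest, plus the
# planted-truth recovery evaluator used for validation.

#' Standard comparison set for a cohort
#'
#' For every APL subtype with at least 3 discovery pairs: a paired
#' lesion-vs-NAT comparison (tumor and NAT columns ordered by patient).
#' Between subtypes: unpaired tumor-vs-tumor and NAT-vs-NAT comparisons.
#' Cross-subtype comparisons involve different patients, so they use the
#' unpaired rank-sum test; pairing applies only to tumor-vs-NAT.
#'
#' @param samples a validated sample sheet
#' @param include_validation include validation tumors in inter-subtype
#'   comparisons (default FALSE: discovery only)
#' @return named list of comparisons: each a list(name, a, b, paired)
#' @export
default_comparisons <- function(samples, include_validation = FALSE) {
  subtypes <- intersect(APL_SUBTYPES, unique(samples$subtype))
  disc <- samples[samples$split == "discovery", , drop = FALSE]
  cmps <- list()
  for (s in subtypes) {
    pr <- sample_pairs(samples, s)
    if (nrow(pr) >= 3L) {
      nm <- sprintf("%s_vs_%s_NAT", s, s)
      cmps[[nm]] <- list(name = nm, a = pr$tumor, b = pr$nat, paired = TRUE)
    }
  }
  tumor_ids <- function(s) {
    pool <- if (include_validation) samples else disc
    pool$sample_id[pool$subtype == s & pool$tissue == "tumor"]
  }
  nat_ids <- function(s) disc$sample_id[disc$subtype == s & disc$tissue == "NAT"]
  if (length(subtypes) >= 2L) {
    pairs <- utils::combn(subtypes, 2)
    for (j in seq_len(ncol(pairs))) {
      s1 <- pairs[1, j]; s2 <- pairs[2, j]
      nm <- sprintf("%s_vs_%s", s1, s2)
      cmps[[nm]] <- list(name = nm, a = tumor_ids(s1), b = tumor_ids(s2),
                         paired = FALSE)
      if (length(nat_ids(s1)) >= 3L && length(nat_ids(s2)) >= 3L) {
        nm <- sprintf("%s_NAT_vs_%s_NAT", s1, s2)
        cmps[[nm]] <- list(name = nm, a = nat_ids(s1), b = nat_ids(s2),
                           paired = FALSE)
      }
    }
  }
  cmps
}

# Inter-subtype tumor comparisons among the named list
.inter_subtype_names <- function(nms) {
  pat <- sprintf("^(%s)_vs_(%s)$", paste(APL_SUBTYPES, collapse = "|"),
                 paste(APL_SUBTYPES, collapse = "|"))
  grep(pat, nms, value = TRUE)
}

.vs_nat_names <- function(nms) {
  pat <- sprintf("^(%s)_vs_\\1_NAT$", paste(APL_SUBTYPES, collapse = "|"))
  grep(pat, nms, value = TRUE)
}

#' Run the full analysis workflow on a synthetic cohort
#'
#' Stages: simulate, filter, test (all configured comparisons), dmr,
#' summarize, signature, stratify, cimp. All outputs are plain text (TSV /
#' BED) under `out_dir`, and a JSON manifest records the configuration
#' snapshot, seed, per-stage outputs with MD5 digests, and the package
#' version. Any stage failure aborts with the stage name; outputs of
#' completed stages are retained.
#'
#' @param config a configuration list (or path to a YAML file) with optional
#'   blocks `simulation`, `analysis`, `cimp` (passed to the respective
#'   `*_config()` constructors) and a top-level `seed` from which all
#'   randomness derives
#' @param out_dir output directory
#' @return the manifest, invisibly
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  sim_args <- config$simulation %||% list()
  if (is.null(sim_args$seed)) sim_args$seed <- derive_seed(seed, "simulate")
  sim_cfg <- do.call(simulation_config, sim_args)
  an_cfg <- do.call(analysis_config, config$analysis %||% list())
  cimp_args <- config$cimp %||% list()
  if (is.null(cimp_args$seed)) cimp_args$seed <- derive_seed(seed, "cimp")
  cimp_cfg <- do.call(cimp_config, cimp_args)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool = "aplmeth",
                   version = as.character(utils::packageVersion("aplmeth")),
                   seed = seed, config = config, stages = list())
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- res$record
    res$value
  }
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  digest <- function(paths) {
    md5 <- unname(tools::md5sum(unlist(paths)))
    stats::setNames(md5, basename(unlist(paths)))
  }

  cohort <- run_stage("simulate", {
    ch <- generate_cohort(sim_cfg)
    paths <- write_cohort(ch, file.path(out_dir, "cohort"))
    list(value = ch,
         record = list(n_sites = n_sites(ch$sites),
                       n_samples = nrow(ch$samples),
                       outputs = digest(paths[-1])))
  })

  filtered <- run_stage("filter", {
    ft <- filter_sites(cohort$sites, an_cfg)
    list(value = ft, record = list(n_sites_in = n_sites(cohort$sites),
                                   n_sites_kept = n_sites(ft)))
  })

  cmps <- default_comparisons(cohort$samples)
  site_results <- run_stage("test", {
    res <- lapply(cmps, function(cm)
      test_sites(filtered, cm$a, cm$b, cm$paired, an_cfg))
    paths <- lapply(names(res), function(nm)
      tsv(res[[nm]], sprintf("sites_%s.tsv", nm)))
    list(value = res,
         record = list(comparisons = names(res), outputs = digest(paths)))
  })

  dmr_sets <- run_stage("dmr", {
    sets <- lapply(names(site_results), function(nm)
      call_dmrs(site_results[[nm]], an_cfg, nm))
    names(sets) <- names(site_results)
    paths <- lapply(names(sets), function(nm)
      write_dmr_bed(sets[[nm]], file.path(out_dir, sprintf("dmrs_%s.bed", nm))))
    list(value = sets,
         record = list(n_dmrs = vapply(sets, nrow, 0L), outputs = digest(paths)))
  })

  summary <- run_stage("summarize", {
    sm <- summarize_comparisons(dmr_sets)
    path <- tsv(sm$per_comparison, "dmr_summary.tsv")
    list(value = sm, record = list(total = sm$total, outputs = digest(path)))
  })

  signature <- run_stage("signature", {
    inter <- dmr_sets[.inter_subtype_names(names(dmr_sets))]
    vsnat <- dmr_sets[.vs_nat_names(names(dmr_sets))]
    sig <- select_unique_hyper(inter, vsnat)
    paths <- list(tsv(sig, "signature_regions.tsv"))
    enr <- NULL
    if (nrow(sig)) {
      enr <- chromosome_enrichment(sig, cohort$truth$genome)
      paths <- c(paths, tsv(enr, "chrom_enrichment.tsv"))
    }
    list(value = sig,
         record = list(n_signature_regions = nrow(sig), outputs = digest(paths)))
  })

  strat <- run_stage("stratify", {
    if (nrow(signature) < 2L) {
      warning("fewer than 2 signature regions; stratification skipped")
      list(value = NULL, record = list(skipped = TRUE))
    } else {
      tumors <- cohort$samples[cohort$samples$tissue == "tumor", ]
      mat <- region_beta_matrix(signature, filtered, tumors$sample_id)
      pca <- pca_stratify(mat)
      kw <- kruskal_subtypes(pca$scores[, 1],
                             tumors$subtype[match(rownames(pca$scores),
                                                  tumors$sample_id)])
      scores <- data.frame(sample_id = rownames(pca$scores),
                           subtype = tumors$subtype[match(rownames(pca$scores),
                                                          tumors$sample_id)],
                           pca$scores[, seq_len(min(5L, ncol(pca$scores)))])
      paths <- list(tsv(scores, "pca_scores.tsv"),
                    tsv(pca$top_regions[[1]], "pca_top_regions_pc1.tsv"),
                    tsv(kw$pairwise, "kw_pairwise.tsv"))
      list(value = list(pca = pca, kw = kw),
           record = list(kw_p_global = kw$p_global, outputs = digest(paths)))
    }
  })

  run_stage("cimp", {
    if (nrow(cohort$truth$promoters) == 0L) {
      list(value = NULL, record = list(skipped = TRUE))
    } else {
      cr <- cimp_classify(filtered, cohort$samples, cohort$truth$promoters,
                          cimp_cfg)
      path <- tsv(cr$labels, "cimp_labels.tsv")
      list(value = cr,
           record = list(n_cimp_h = sum(cr$labels$label == "CIMP-H"),
                         n_selected_cpgs = nrow(cr$selected_cpgs),
                         outputs = digest(path)))
    }
  })

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate recovery of planted regions by called DMRs
#'
#' Each planted truth region is expected in specific comparisons:
#' `subtype_tumor` plants in their subtype's lesion-vs-NAT comparison;
#' `shared` plants in every lesion-vs-NAT comparison; `signature` plants in
#' the inter-subtype comparisons involving their subtype (hyper when the
#' subtype is first-named, hypo otherwise). A (region, comparison) pair
#' counts as recovered when some DMR of that comparison overlaps the region
#' by at least 1 bp with the expected direction. DMRs overlapping no truth
#' region (padded by `pad` bp; promoter-panel regions included) are counted
#' as false positives.
#'
#' @param truth the `truth` component of an `apl_cohort`
#' @param dmr_sets named list of called DMR data.frames
#' @param pad padding in bp around truth regions for the false-positive
#'   count
#' @return list: `expected` (per region-comparison data.frame with
#'   `recovered`), `recovery_rate`, `n_false_positives`
#' @export
evaluate_recovery <- function(truth, dmr_sets, pad = 1000L) {
  regions <- truth$regions
  expected <- list()
  if (nrow(regions)) {
    vs_nat <- .vs_nat_names(names(dmr_sets))
    inter <- .inter_subtype_names(names(dmr_sets))
    for (i in seq_len(nrow(regions))) {
      r <- regions[i, ]
      if (r$class == "subtype_tumor") {
        cmp <- sprintf("%s_vs_%s_NAT", r$subtype, r$subtype)
        if (cmp %in% names(dmr_sets))
          expected[[length(expected) + 1L]] <-
            data.frame(region = i, comparison = cmp, direction = r$direction)
      } else if (r$class == "shared") {
        for (cmp in vs_nat)
          expected[[length(expected) + 1L]] <-
            data.frame(region = i, comparison = cmp, direction = r$direction)
      } else if (r$class == "signature") {
        for (cmp in inter) {
          sides <- .parse_comparison(cmp)
          if (r$subtype %in% sides)
            expected[[length(expected) + 1L]] <-
              data.frame(region = i, comparison = cmp,
                         direction = if (r$subtype == sides[1]) "hyper" else "hypo")
        }
      }
    }
  }
  expected <- if (length(expected)) do.call(rbind, expected)
              else data.frame(region = integer(), comparison = character(),
                              direction = character())
  expected$recovered <- FALSE
  for (j in seq_len(nrow(expected))) {
    r <- regions[expected$region[j], ]
    d <- dmr_sets[[expected$comparison[j]]]
    if (is.null(d) || !nrow(d)) next
    hit <- d$chrom == r$chrom & d$start <= r$end & d$end >= r$start &
      d$direction == expected$direction[j]
    expected$recovered[j] <- any(hit)
  }

  all_truth <- rbind(regions[c("chrom", "start", "end")],
                     truth$promoters[c("chrom", "start", "end")])
  n_fp <- 0L
  for (d in dmr_sets) {
    if (is.null(d) || !nrow(d)) next
    if (!nrow(all_truth)) { n_fp <- n_fp + nrow(d); next }
    ov <- GenomicRanges::findOverlaps(
      regions_to_granges(d),
      regions_to_granges(transform(all_truth, start = pmax(1L, start - pad),
                                   end = end + pad)))
    n_fp <- n_fp + nrow(d) - length(unique(S4Vectors::queryHits(ov)))
  }
  list(expected = expected,
       recovery_rate = if (nrow(expected)) mean(expected$recovered) else NA_real_,
       n_false_positives = n_fp)
}
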