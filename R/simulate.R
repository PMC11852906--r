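# Synthetic paired tumor/NAT WGBS cohort generator.
#
# The generator emulates the cohort structure the analysis assumes: paired
# tumor and normal-adjacent-tissue (NAT) samples per patient, three
# precancerous-lesion subtypes (SSL, TA, VA/TVA), clustered CpG placement,
# binomial read sampling at Poisson depth, and planted differentially
# methylated regions of three kinds:
#
#   * subtype_tumor - methylation shifted in one subtype's tumor samples
#     only; recovered by the lesion-vs-NAT comparisons.
#   * signature     - methylation elevated in BOTH tissues of one subtype's
#     patients; invisible to lesion-vs-NAT testing and therefore the only
#     regions that can survive the signature-selection exclusion rule.
#   * shared        - shifted in the tumors of every subtype; these appear
#     in all lesion-vs-NAT comparisons and must be excluded from any
#     subtype-unique signature.
#
# A CIMP-H subpopulation of tumors additionally hypermethylates a designated
# promoter-panel CpG set.

APL_SUBTYPES <- c("SSL", "TA", "VA_TVA")

#' Simulation configuration
#'
#' Defaults define a desk-scale cohort: 10 tumor/NAT pairs per subtype at
#' mean depth 22.5x with planted effect size 0.35, sized so that the paired
#' signed-rank test (whose smallest attainable two-sided p-value with 10
#' pairs is 2/2^10) retains power after genome-wide Benjamini-Hochberg
#' correction.
#'
#' @param n_patients_per_subtype paired discovery patients per subtype
#' @param n_validation_per_subtype unpaired validation tumors per subtype
#' @param n_cpgs total CpG sites across the genome
#' @param n_chroms number of chromosomes
#' @param chrom_length chromosome length in bp
#' @param mean_depth mean sequencing depth (Poisson); must exceed 5
#' @param planted_regions_per_subtype subtype_tumor regions per subtype
#' @param signature_regions_per_subtype signature regions per subtype
#' @param shared_regions regions shifted in all subtypes' tumors
#' @param hypo_fraction fraction of subtype_tumor/shared plants that are
#'   hypomethylation events (high-baseline sites shifted down)
#' @param region_n_cpgs minimum CpGs per planted region (>= 3)
#' @param planted_delta planted beta shift in (0, 1\]; >= 0.2 keeps plants
#'   above the DMR effect-size threshold
#' @param background_beta_alpha,background_beta_beta Beta shape parameters
#'   of baseline methylation at background CpGs (bimodal by default)
#' @param planted_beta_alpha,planted_beta_beta Beta shape parameters of the
#'   low-methylation baseline at hyper-planted CpGs (mirrored for hypo)
#' @param cimp_fraction fraction of tumors per subtype that are CIMP-H
#' @param cimp_delta beta shift applied to panel CpGs in CIMP-H tumors
#' @param cimp_promoter_regions number of promoter-panel regions
#' @param cimp_beta_alpha,cimp_beta_beta Beta shape parameters of the
#'   near-zero baseline at promoter-panel CpGs
#' @param seed integer seed; all randomness flows from it through
#'   per-chromosome / per-patient substreams
#' @return a `SimulationConfig` list
#' @export
simulation_config <- function(n_patients_per_subtype = 10L,
                              n_validation_per_subtype = 0L,
                              n_cpgs = 3000L,
                              n_chroms = 3L,
                              chrom_length = 1e6,
                              mean_depth = 22.5,
                              planted_regions_per_subtype = 40L,
                              signature_regions_per_subtype = 8L,
                              shared_regions = 20L,
                              hypo_fraction = 0.25,
                              region_n_cpgs = 5L,
                              planted_delta = 0.35,
                              background_beta_alpha = 0.8,
                              background_beta_beta = 0.8,
                              planted_beta_alpha = 1.5,
                              planted_beta_beta = 15,
                              cimp_fraction = 0.4,
                              cimp_delta = 0.5,
                              cimp_promoter_regions = 25L,
                              cimp_beta_alpha = 1,
                              cimp_beta_beta = 40,
                              seed = 1L) {
  cfg <- list(
    n_patients_per_subtype = as.integer(n_patients_per_subtype),
    n_validation_per_subtype = as.integer(n_validation_per_subtype),
    n_cpgs = as.integer(n_cpgs), n_chroms = as.integer(n_chroms),
    chrom_length = as.numeric(chrom_length), mean_depth = mean_depth,
    planted_regions_per_subtype = as.integer(planted_regions_per_subtype),
    signature_regions_per_subtype = as.integer(signature_regions_per_subtype),
    shared_regions = as.integer(shared_regions),
    hypo_fraction = hypo_fraction,
    region_n_cpgs = as.integer(region_n_cpgs),
    planted_delta = planted_delta,
    background_beta_alpha = background_beta_alpha,
    background_beta_beta = background_beta_beta,
    planted_beta_alpha = planted_beta_alpha,
    planted_beta_beta = planted_beta_beta,
    cimp_fraction = cimp_fraction, cimp_delta = cimp_delta,
    cimp_promoter_regions = as.integer(cimp_promoter_regions),
    cimp_beta_alpha = cimp_beta_alpha, cimp_beta_beta = cimp_beta_beta,
    seed = as.integer(seed)
  )
  if (cfg$mean_depth <= 5) stop("mean_depth must exceed 5")
  if (cfg$planted_delta < 0 || cfg$planted_delta > 1)
    stop("planted_delta must lie in [0, 1]")
  if (cfg$region_n_cpgs < 3L) stop("region_n_cpgs must be >= 3")
  if (cfg$cimp_fraction < 0 || cfg$cimp_fraction > 1)
    stop("cimp_fraction must lie in [0, 1]")
  if (cfg$n_patients_per_subtype < 3L)
    stop("need at least 3 patients per subtype")
  class(cfg) <- "SimulationConfig"
  cfg
}

# Clustered CpG placement on one chromosome: runs of 3-8 CpGs with 10-40 bp
# internal gaps, separated by >50 bp (200-2000 bp) inter-cluster gaps.
.layout_chromosome <- function(quota, chrom_length, seed) {
  with_seed(seed, {
    pos <- integer(quota)
    cluster <- integer(quota)
    n <- 0L
    cur <- 0
    cl <- 0L
    while (n < quota) {
      cur <- cur + sample(200:2000, 1L)
      size <- min(sample(3:8, 1L), quota - n)
      gaps <- if (size > 1L) sample(10:40, size - 1L, replace = TRUE) else integer()
      p <- cur + c(0, cumsum(gaps))
      cur <- p[size]
      if (cur > chrom_length)
        stop("infeasible geometry: CpG layout exceeds chromosome length")
      cl <- cl + 1L
      pos[(n + 1L):(n + size)] <- as.integer(p)
      cluster[(n + 1L):(n + size)] <- cl
      n <- n + size
    }
    list(pos = pos, cluster = cluster)
  })
}

#' Generate a synthetic paired APL cohort
#'
#' See the module header for the generative model. Identical configuration
#' (including seed) yields bit-identical output; patients draw from
#' independent substreams so enlarging the cohort does not perturb
#' existing samples.
#'
#' @param config a [simulation_config()]
#' @return a list of class `apl_cohort` with components `sites`
#'   (a [cpg_site_table()]), `samples` (validated sample sheet), `truth`
#'   (list: `regions`, `cimp_labels`, `promoters`, `genome`), and `config`
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  quota <- rep(cfg$n_cpgs %/% cfg$n_chroms, cfg$n_chroms)
  quota[cfg$n_chroms] <- quota[cfg$n_chroms] + cfg$n_cpgs %% cfg$n_chroms

  chrom <- character(0); pos <- integer(0); cluster <- integer(0)
  cl_off <- 0L
  for (i in seq_len(cfg$n_chroms)) {
    lay <- .layout_chromosome(quota[i], cfg$chrom_length,
                              derive_seed(cfg$seed, "layout", chroms[i]))
    chrom <- c(chrom, rep(chroms[i], quota[i]))
    pos <- c(pos, lay$pos)
    cluster <- c(cluster, lay$cluster + cl_off)
    cl_off <- cl_off + max(lay$cluster)
  }
  ns <- length(pos)
  cl_sizes <- tabulate(cluster)
  n_clusters <- length(cl_sizes)

  # --- plant assignment ------------------------------------------------
  n_tum <- cfg$planted_regions_per_subtype
  n_sig <- cfg$signature_regions_per_subtype
  n_shr <- cfg$shared_regions
  n_prom <- cfg$cimp_promoter_regions
  eligible <- which(cl_sizes >= cfg$region_n_cpgs)
  need_big <- 3L * (n_tum + n_sig) + n_shr
  if (length(eligible) < need_big)
    stop(sprintf(paste0("infeasible geometry: %d planted regions requested but ",
                        "only %d clusters have >= %d CpGs"),
                 need_big, length(eligible), cfg$region_n_cpgs))
  plants <- with_seed(derive_seed(cfg$seed, "plants"), {
    big <- if (need_big > 0L) sample(eligible, need_big) else integer()
    rest <- setdiff(seq_len(n_clusters), big)
    if (length(rest) < n_prom)
      stop("infeasible geometry: not enough clusters left for promoter panel")
    prom <- if (n_prom > 0L) sample(rest, n_prom) else integer()
    classes <- c(rep("subtype_tumor", 3L * n_tum),
                 rep("signature", 3L * n_sig),
                 rep("shared", n_shr))
    subtypes <- c(rep(APL_SUBTYPES, each = n_tum),
                  rep(APL_SUBTYPES, each = n_sig),
                  rep("all", n_shr))
    direction <- rep("hyper", length(classes))
    dirpool <- which(classes %in% c("subtype_tumor", "shared"))
    n_hypo <- round(cfg$hypo_fraction * length(dirpool))
    if (n_hypo > 0L) direction[sample(dirpool, n_hypo)] <- "hypo"
    list(cluster = big, class = classes, subtype = subtypes,
         direction = direction, promoters = prom)
  })

  region_of_cluster <- rep(NA_integer_, n_clusters)
  region_of_cluster[plants$cluster] <- seq_along(plants$cluster)
  site_region <- region_of_cluster[cluster]
  site_in_panel <- cluster %in% plants$promoters

  truth_regions <- if (length(plants$cluster)) {
    data.frame(
      chrom = vapply(plants$cluster, function(cl) chrom[match(cl, cluster)], ""),
      start = vapply(plants$cluster, function(cl) min(pos[cluster == cl]), 0L),
      end = vapply(plants$cluster, function(cl) max(pos[cluster == cl]), 0L),
      n_cpgs = cl_sizes[plants$cluster],
      class = plants$class, subtype = plants$subtype,
      direction = plants$direction, delta = cfg$planted_delta
    )
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_cpgs = integer(), class = character(), subtype = character(),
               direction = character(), delta = numeric())
  }
  promoters <- if (length(plants$promoters)) {
    data.frame(
      chrom = vapply(plants$promoters, function(cl) chrom[match(cl, cluster)], ""),
      start = vapply(plants$promoters, function(cl) min(pos[cluster == cl]), 0L),
      end = vapply(plants$promoters, function(cl) max(pos[cluster == cl]), 0L)
    )
  } else data.frame(chrom = character(), start = integer(), end = integer())

  # Baseline distribution class per site: hyper plants sit on a tight
  # low-methylation baseline (CpG-island-like), hypo plants on its mirror,
  # panel CpGs near zero, everything else on the bimodal background.
  site_dist <- rep("bg", ns)
  planted_sites <- !is.na(site_region)
  site_dir <- rep(NA_character_, ns)
  site_dir[planted_sites] <- plants$direction[site_region[planted_sites]]
  site_dist[planted_sites & site_dir == "hyper"] <- "low"
  site_dist[planted_sites & site_dir == "hypo"] <- "high"
  site_dist[site_in_panel] <- "panel"
  i_bg <- which(site_dist == "bg"); i_low <- which(site_dist == "low")
  i_high <- which(site_dist == "high"); i_pan <- which(site_dist == "panel")

  # --- cohort table ----------------------------------------------------
  n_disc <- cfg$n_patients_per_subtype
  n_val <- cfg$n_validation_per_subtype
  sheet <- do.call(rbind, lapply(APL_SUBTYPES, function(s) {
    pid <- sprintf("%s_P%02d", s, seq_len(n_disc + n_val))
    disc <- data.frame(
      sample_id = c(paste0(pid[seq_len(n_disc)], "_T"),
                    paste0(pid[seq_len(n_disc)], "_N")),
      patient_id = rep(pid[seq_len(n_disc)], 2L),
      tissue = rep(c("tumor", "NAT"), each = n_disc),
      subtype = s, split = "discovery"
    )
    if (n_val > 0L) {
      val <- data.frame(
        sample_id = paste0(pid[n_disc + seq_len(n_val)], "_T"),
        patient_id = pid[n_disc + seq_len(n_val)],
        tissue = "tumor", subtype = s, split = "validation"
      )
      rbind(disc, val)
    } else disc
  }))

  # CIMP-H tumors: a fixed rounded count per (subtype, split) stratum, each
  # drawn from its own substream so enlarging the cohort (e.g. adding
  # validation samples) never reassigns existing tumors.
  cimp_h <- character(0)
  for (s in APL_SUBTYPES) {
    for (sp in unique(sheet$split)) {
      tums <- sheet$sample_id[sheet$subtype == s & sheet$tissue == "tumor" &
                              sheet$split == sp]
      n_h <- round(cfg$cimp_fraction * length(tums))
      if (n_h > 0L)
        cimp_h <- c(cimp_h, with_seed(derive_seed(cfg$seed, "cimp", s, sp),
                                      sample(tums, n_h)))
    }
  }
  cimp_labels <- data.frame(
    sample_id = sheet$sample_id[sheet$tissue == "tumor"],
    cimp = ifelse(sheet$sample_id[sheet$tissue == "tumor"] %in% cimp_h,
                  "CIMP-H", "CIMP-L/N")
  )

  # Per-region site index lists for effect application
  reg_sites <- if (length(plants$cluster))
    lapply(seq_along(plants$cluster), function(r) which(site_region == r))
  else list()

  sgn <- ifelse(plants$direction == "hyper", 1, -1)
  meth <- matrix(0L, ns, nrow(sheet), dimnames = list(NULL, sheet$sample_id))
  total <- meth

  for (s in APL_SUBTYPES) {
    pids <- unique(sheet$patient_id[sheet$subtype == s])
    for (pi in seq_along(pids)) {
      pid <- pids[pi]
      p0 <- with_seed(derive_seed(cfg$seed, "p0", s, pi), {
        v <- numeric(ns)
        v[i_bg] <- stats::rbeta(length(i_bg), cfg$background_beta_alpha,
                                cfg$background_beta_beta)
        v[i_low] <- stats::rbeta(length(i_low), cfg$planted_beta_alpha,
                                 cfg$planted_beta_beta)
        v[i_high] <- stats::rbeta(length(i_high), cfg$planted_beta_beta,
                                  cfg$planted_beta_alpha)
        v[i_pan] <- stats::rbeta(length(i_pan), cfg$cimp_beta_alpha,
                                 cfg$cimp_beta_beta)
        v
      })
      # signature plants shift both tissues of this subtype's patients
      p_base <- p0
      for (r in which(plants$class == "signature" & plants$subtype == s))
        p_base[reg_sites[[r]]] <- p_base[reg_sites[[r]]] + cfg$planted_delta
      p_tum <- p_base
      for (r in which((plants$class == "subtype_tumor" & plants$subtype == s) |
                      plants$class == "shared"))
        p_tum[reg_sites[[r]]] <- p_tum[reg_sites[[r]]] + sgn[r] * cfg$planted_delta
      rows <- sheet[sheet$patient_id == pid, ]
      for (k in seq_len(nrow(rows))) {
        sid <- rows$sample_id[k]
        p <- if (rows$tissue[k] == "tumor") p_tum else p_base
        if (rows$tissue[k] == "tumor" && sid %in% cimp_h)
          p[i_pan] <- p[i_pan] + cfg$cimp_delta
        p <- pmin(pmax(p, 0), 1)
        cnt <- with_seed(derive_seed(cfg$seed, "counts", sid), {
          d <- stats::rpois(ns, cfg$mean_depth)
          list(d = d, m = stats::rbinom(ns, d, p))
        })
        total[, sid] <- as.integer(cnt$d)
        meth[, sid] <- as.integer(cnt$m)
      }
    }
  }

  sites <- cpg_site_table(chrom, pos, meth, total)
  structure(
    list(sites = sites,
         samples = validate_sample_sheet(sheet),
         truth = list(regions = truth_regions, cimp_labels = cimp_labels,
                      promoters = promoters,
                      genome = genome_info(chroms, rep(cfg$chrom_length,
                                                       cfg$n_chroms))),
         config = cfg),
    class = "apl_cohort"
  )
}

#' Generate a null cohort (no planted regions, no CIMP subpopulation)
#'
#' [generate_cohort()] with all plant counts and the CIMP fraction forced to
#' zero: every tumor/NAT difference is pure sampling noise. Used for
#' empirical type-I-error control of the DMR caller.
#'
#' @param config a [simulation_config()]; plant and CIMP settings are
#'   overridden
#' @return an `apl_cohort` whose truth region list is empty
#' @export
generate_null_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  config$planted_regions_per_subtype <- 0L
  config$signature_regions_per_subtype <- 0L
  config$shared_regions <- 0L
  config$cimp_fraction <- 0
  config$cimp_promoter_regions <- 0L
  generate_cohort(config)
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Emits one Bismark-style coverage file per sample (sites with zero depth
#' are omitted, matching extractor behaviour), the sample sheet, the truth
#' tables, the promoter-panel BED and a chrom.sizes table.
#'
#' @param cohort an `apl_cohort`
#' @param dir output directory (created if needed)
#' @return named list of written paths (`cov` is a named vector)
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "apl_cohort"))
  dir.create(file.path(dir, "cov"), recursive = TRUE, showWarnings = FALSE)
  st <- cohort$sites
  cov_paths <- character(0)
  for (sid in st$samples) {
    m <- st$meth[, sid]
    d <- st$total[, sid]
    keep <- d > 0L
    path <- file.path(dir, "cov", paste0(sid, ".cov"))
    writeLines(paste(st$chrom[keep], st$pos[keep], st$pos[keep],
                     sprintf("%.6g", 100 * m[keep] / d[keep]),
                     m[keep], d[keep] - m[keep], sep = "\t"), path)
    cov_paths[sid] <- path
  }
  sheet_path <- file.path(dir, "samples.tsv")
  utils::write.table(cohort$samples, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_path <- file.path(dir, "truth_regions.tsv")
  utils::write.table(cohort$truth$regions, truth_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cimp_path <- file.path(dir, "truth_cimp.tsv")
  utils::write.table(cohort$truth$cimp_labels, cimp_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  prom_path <- file.path(dir, "promoters.bed")
  write_bed_regions(cohort$truth$promoters, prom_path)
  genome_path <- file.path(dir, "chrom.sizes")
  utils::write.table(cohort$truth$genome[c("chrom", "length")], genome_path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  list(cov = cov_paths, samples = sheet_path, truth_regions = truth_path,
       truth_cimp = cimp_path, promoters = prom_path, genome = genome_path)
}
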