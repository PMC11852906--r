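---
title: "Methods: DMR calling, signature selection and subtype stratification for colorectal precancerous lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DMR calling, signature selection and subtype stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aplmeth)
```

## The analysis model

`aplmeth` analyses whole-genome bisulfite sequencing of advanced
precancerous colorectal lesions (APLs) and matched normal adjacent tissue
(NAT). The unit observation is a CpG site's methylation level
β = m/(m+u), the fraction of methylated reads; β is always recomputed from
counts, never taken from upstream percentage columns. Samples belong to
patients (pairing tumor and NAT), histological subtypes (SSL, TA, VA/TVA)
and a discovery/validation split.

### Site testing

After a coverage filter (every retained CpG needs `min_coverage = 5` reads
in **all** samples) and an optional mask of common-SNP positions, each CpG
is tested per comparison:

* **Lesion vs own NAT** — paired: Wilcoxon signed-rank on the per-patient
  β differences. Zero differences are dropped before ranking (Wilcoxon's
  original convention, matching the default of standard routines).
* **Subtype vs subtype / NAT vs NAT** — these involve different patients,
  so no pairing exists; the unpaired rank-sum test is used.

Exact null distributions (`psignrank`/`pwilcox`) apply when the effective
n is at most 25 and no ties or zeros intervene; otherwise the normal
approximation with continuity correction. The implementation is written in
the package (it is the computational core of the workflow) and is checked
in the test suite against two independent references: `stats::wilcox.test`
and a brute-force enumeration of all sign assignments / rank subsets.

P-values are adjusted per comparison across all filtered CpGs jointly with
Benjamini–Hochberg (`p.adjust`); a site is *significant* when
p_adj < `alpha` (0.05) and |Δβ| ≥ `min_delta` (0.2), with
Δβ = mean(group A) − mean(group B), so "hyper" always means elevated in
the first-named group. Sites with fewer than three informative pairs are
reported with p = 1 and an `untestable` flag rather than dropped, keeping
region CpG counts consistent with the filtered table.

### Region aggregation

All tested CpGs (not only significant ones — the 60% rule presupposes
regions containing non-significant CpGs) are clustered greedily: a gap of
more than `max_gap = 50` bp between consecutive CpG coordinates splits. A
cluster is a DMR when it has ≥ `min_cpgs = 3` CpGs, a significant fraction
≥ `min_sig_frac = 0.6` (inclusive — a 3-of-5 cluster qualifies), and all
significant CpGs share one sign of Δβ. Mixed-sign clusters are discarded
rather than split, since regions carry a single hyper/hypo label and no
splitting rule is canonical. Region coordinates span the first to last
CpG, without flanking padding.

### Signature selection

The subtype-unique hypermethylated signature takes every inter-subtype
DMR, assigns it to the subtype in which it is *elevated* (sign of
`mean_delta`: positive → first-named, negative → second-named subtype —
using only positively-signed regions would make the last-ordered subtype
unrepresentable), then removes any region overlapping (≥ 1 bp, the least
restrictive standard predicate) a DMR from *any* lesion-vs-NAT comparison,
and finally drops regions claimed by two different subtypes. Repeated
claims by one subtype merge with joined provenance. Chromosome enrichment
is (n_c/L_c)/(N/L) over autosomes only; its length-weighted mean is
exactly 1, which the tests assert.

### Stratification

The region-level β matrix (unweighted mean of member-CpG βs per sample)
over the signature regions feeds a PCA with samples as observations.
Columns are centered and unit-scaled — β variances differ strongly across
regions, and scaling stabilises the stratification; missing entries are
imputed by the region mean; zero-variance regions are dropped with a
warning. Components are oriented so the largest-magnitude loading is
positive, making signs deterministic. Subtype separation is tested with
Kruskal–Wallis on the **PC1 sample scores** grouped by subtype — the only
reading of "contributions of the first principal component" that yields
per-sample groups; region-contribution percentages (squared-loading
shares) are reported separately as a top-30 table. Pairwise subtype
differences use unadjusted rank-sum tests. Validation samples can either
be co-decomposed (default) or projected onto discovery components via the
`project` argument.

### CIMP classification

CpGs inside promoter regions (an input BED; the synthetic genome
designates promoter clusters) qualify when their tumor β standard
deviation exceeds 0.2 and their normal mean β stays below 0.05. Consensus
K-means then clusters tumors: each of `n_resamples = 100` rounds draws 80%
of samples *and* of CpGs (item subsampling follows common
consensus-clustering practice), runs K-means with k-means++-style seeding
from the round's RNG substream, and the consensus matrix of co-clustering
frequencies is cut by average-linkage hierarchical clustering into k = 2
groups — the dichotomy (CIMP-H vs CIMP-L/N) reflects cohort sizes too
small for a finer k. The higher-mean cluster becomes CIMP-H. With
`subsample_frac = 1` and the deterministic `farthest` initialisation the
consensus matrix is exactly 0/1, a property the tests exercise.

## The synthetic cohort generator

No patient-level WGBS data can ship with the package, so the generator
defines the study conditions under which everything is validated:

* **Design**: 10 paired tumor/NAT patients per subtype (plus optional
  unpaired validation tumors), mean depth 22.5× (Poisson; read counts
  binomial given depth and the sample's methylation probability).
* **Geometry**: CpGs are placed in clusters of 3–8 sites with 10–40 bp
  internal gaps and 200–2000 bp between clusters, so the 50 bp aggregation
  rule sees realistic structure. Planted regions occupy whole clusters
  with at least `region_n_cpgs = 5` CpGs.
* **Baselines**: per patient and site, β₀ is drawn from a bimodal
  Beta(0.8, 0.8) background; a patient's tumor and NAT share β₀, which
  induces exactly the pairing correlation the signed-rank test exploits.
  Planted hyper regions sit on a tight low-methylation baseline
  Beta(1.5, 15) (CpG-island-like; its mirror for hypo plants), so planted
  shifts are not drowned by between-patient baseline variance in the
  unpaired inter-subtype comparisons.
* **Plants** (effect Δβ = 0.35, clipped to [0, 1]): per subtype 40
  `subtype_tumor` regions (tumor-only shift, 25% of them hypo) and 8
  `signature` regions (shift in both tissues of that subtype's patients);
  plus 20 `shared` regions shifted in every subtype's tumors. The three
  classes deliberately separate the two roles a planted effect can play:
  tumor-only plants are recovered by the paired lesion-vs-NAT comparisons
  but — appearing in those very comparisons — can never survive the
  signature exclusion rule; signature plants are invisible to
  lesion-vs-NAT testing and are precisely the regions the signature step
  must recover and attribute; shared plants must be excluded from any
  subtype-unique signature.
* **CIMP**: 25 promoter clusters carry a near-zero baseline Beta(1, 40);
  40% of each subtype's tumors are CIMP-H and shift panel CpGs by +0.5.
  A +0.5 shift in 40% of tumors puts the tumor SD safely above the 0.2
  selection threshold; smaller fractions or shifts would straddle it.
* **Determinism**: one seed feeds per-chromosome, per-patient and
  per-sample substreams (a small string hash), so identical configurations
  are bit-identical and enlarging the cohort never perturbs existing
  samples.

### Why these sizes

With 10 pairs, the smallest attainable two-sided signed-rank p-value is
2/2¹⁰ ≈ 0.00195. Under BH with m tested sites, sites at that floor are
only rejected when roughly ≥ 3.9% of all sites reach it. The default
cohort therefore uses 3,000 CpGs with ~160 truly shifted sites per
lesion-vs-NAT comparison — about 5%, comfortably above the floor — rather
than a genome-scale site count that no 10-pair design could survive. The
null-control experiments, which need no power, run at 50,000 CpGs. These
are statements about the synthetic study design, derived from the
generating model before any empirical tuning.

What the generator does **not** emulate: between-NAT biological
differences (NATs of different subtypes are exchangeable up to signature
plants), over-dispersed coverage (Poisson, not negative binomial),
strand-level effects, bisulfite conversion error, and correlated
methylation beyond the planted block structure. Passing tests therefore
demonstrate correctness of the algorithms under the stated model, not
performance on real tissue data.

## Numerical choices and degenerate inputs

* Wilcoxon: exactness requires n ≤ 25, no ties, no zero differences —
  mirroring `wilcox.test` so the two implementations are comparable at
  machine precision; σ = 0 (all observations tied) yields p = 1.
* The 60% region rule is evaluated as `n_sig ≥ 0.6·n − 1e-9` to keep the
  inclusive boundary robust to floating-point division.
* BH inputs are validated to (0, 1]; empty vectors pass through.
* `filter_sites` warns (not errors) on an empty result; region β rows
  without tested CpGs warn and stay all-missing; PCA needs ≥ 3 samples
  and ≥ 2 surviving regions; Kruskal–Wallis requires ≥ 2 groups of ≥ 2.
* Consensus clustering guards against duplicate rows (fewer distinct rows
  than k clusters by row identity) and never-co-sampled pairs
  (mean-imputed with a warning).
* Coordinates are 1-based inclusive internally (the native convention of
  the coverage input); BED export converts to 0-based half-open. Strand is
  not modelled — sites are keyed by position as emitted by the methylation
  extractor.

## Problem sizes

The bundled experiments run at desk scale, chosen so the whole validation
suite completes in minutes on one core: null control over 20 seeds at
50,000 CpGs and 10 pairs per subtype; recovery, stratification (20 seeds)
and CIMP recovery (20 seeds) on the 3,000-CpG default cohort. The same
code paths scale to genome-wide tables; only the per-site testing loop
grows linearly.

## Known limitations

* The paired test's resolution bounds sensitivity for small cohorts; with
  fewer than 6 pairs no site can reach p < 0.05 even before adjustment.
* The signature's set algebra (elevated-side assignment, 1 bp overlap
  exclusion) is one defensible reading of a procedure whose published
  descriptions leave the overlap predicate and the treatment of
  negatively-signed regions open; counts per exclusion step are exposed so
  alternative predicates can be compared.
* CIMP consensus-clustering hyperparameters (resample count, subsampling
  fraction, linkage) are documented defaults, not inferred from any
  reference cohort.
* NAT-vs-NAT comparisons on synthetic cohorts show the planted signature
  regions (elevated in both tissues of a subtype's patients); real NAT
  baselines may differ for reasons the generator does not model.
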