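---
title: "methlink: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methlink: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methlink)
```

# The analytical model

`methlink` analyses cohorts in which each patient contributes one or
more tumor samples profiled for CpG methylation (β = methylated /
total reads per site), gene expression (counts and TPM) and, for a
subset, H3K27ac and H3K27me3 peak calls with a peak × sample signal
matrix. The pipeline asks three nested questions:

1. **Is methylation patient-specific?** Samples are compared by Pearson
   correlation over the most variable CpGs; intra-patient pairs are
   contrasted with inter-patient pairs by a two-sided Wilcoxon rank-sum
   test. Pairs are treated as independent observations — no
   patient-level clustering correction is applied, matching the standard
   presentation of this comparison.
2. **What transcriptional state is each sample in?** Five AR/NE
   subtypes are assigned from signature z-sums and an AR enrichment
   score with fixed thresholds (below).
3. **Which genes does methylation regulate, and in what chromatin
   context?** CpG regions are tested against candidate genes selected
   by histone or genic context, with BH control at FDR < 0.01, and the
   surviving links feed a conjunctive nomination rule for
   methylation-regulated genes.

## CpG regions and candidate links

Regions are built by single-linkage chaining: consecutive CpGs at most
`max_gap` = 200 bp apart join one cluster, and clusters with fewer than
`min_cpgs` = 3 members are dropped. Chaining on consecutive distances
was chosen over a fixed 200-bp window because it is order-independent
and matches the idea of "grouping CpGs within 200 bp"; region β is the
unweighted mean of member-CpG β per sample (a coverage-weighted mean is
available via `region_beta(weighted = TRUE)`). Region coordinates span
the member CpGs, 0-based half-open with `end` = last position + 1.

Histone context comes from per-mark union peak sets (overlapping
per-sample calls merged; union peaks detected in fewer than 2 samples
excluded). Peak signal is correlated with the expression of every gene
whose TSS lies within ±0.5 Mb of the peak; the distance anchor is the
TSS to the *nearest peak edge*, with a TSS inside the peak counting as
distance 0 — the anchor is not specified by convention, and edge
distance is the least arbitrary choice for wide peaks. Retained
peak–gene pairs must pass FDR < 0.01 *and* the mark's sign convention
(H3K27ac positive, H3K27me3 negative). Significant same-gene peaks
within 1 kb merge, with a gap of exactly 1000 bp merging (inclusive
semantics, documented in `merge_linked_peaks`); merged r and p are
recomputed on the mean constituent signal, while the FDR is carried as
the minimum constituent FDR because re-running BH after merging would
redefine the test family.

Regions are then categorized, multi-label: within ±1 kb (inclusive of
touching) of a significantly linked H3K27ac or H3K27me3 peak, the
region inherits that peak's genes; regions overlapping a strand-aware
promoter (1,500 bp upstream of the TSS) or a gene body (TSS–TES span)
take the containing gene regardless of peak proximity. Histone-category
regions are additionally annotated by the first match in the hierarchy
promoter > 5′UTR > 3′UTR > gene body, else intergenic. Region–gene
correlations are BH-corrected **within each category family** — the
conservative reading when the correction family is not stated — and
both signs are admitted at this stage, since promoter/gene-body links
are genuinely bidirectional.

Replication validation recomputes each link in an independent cohort by
pooling the replication CpGs inside the region's coordinates; a link
validates when the replication correlation has the same sign and
p < 0.05. This criterion is this package's own definition (the original
analysis does not state one), so validated counts are
criterion-sensitive and should be read as such.

## Statistical engines

- Pearson p-values use the t transform with n − 2 df; |r| = 1 maps to
  p = 0.
- Wilcoxon rank-sum: exact distribution when both groups have ≤ 25
  values and no ties; otherwise the normal approximation with tie
  correction (`stats::wilcox.test` supplies both; the exact path is
  property-tested against full enumeration for group sizes ≤ 8).
- BH adjustment via `stats::p.adjust`, checked against the hand formula.
- Over-representation is the hypergeometric upper tail
  (`stats::phyper`), i.e. a one-sided Fisher test, BH-corrected across
  sets. No gene-set database is bundled; sets are user inputs.
- The DE step is a documented substitute for a negative-binomial model:
  median-of-ratios size factors, per-gene two-sided Welch t on
  log2(normalized + 1), BH. Gene-level p-values will differ from a
  count-model fit; the *nomination thresholds* (|log2FC| > 1 with BH
  p ≤ 0.05, the single-sample |log2FC| > 2 variant, > 10% β difference,
  mean ± SD extremes) are implemented exactly, and
  `nominate_regulated()` accepts an externally produced DE table to
  bypass the substitute.
- The AR/NE enrichment score is a rank-based single-sample KS-style
  running sum (hits step +1/|S|, misses −1/(N−|S|); score = max positive
  deviation + min negative deviation). The published analysis delegates
  this score to an external gene-set variance-analysis package whose
  kernel settings are not stated; the classifier consumes only the
  score's sign, so any statistic monotone in the signature's ranking is
  admissible. The score is invariant under strictly monotone transforms
  of a sample's expression, which is the property the tests pin.
- Classical MDS is `stats::cmdscale` (double-centering +
  eigendecomposition); negative-eigenvalue axes are dropped with a
  warning and each axis is oriented so its largest-magnitude loading is
  positive, making the embedding deterministic up to that convention.

## Expression scales

Correlation screens, z-scores, signature z-sums and the mean ± SD
extremes all operate on log2(TPM + 1); DE operates on normalized
counts. The source analyses do not state these scales; both are fixed
here and documented rather than configurable per call, so that numbers
are comparable across the pipeline.

# The cohort simulator

`simulate_cohort()` generates the joint structure the pipeline is built
to detect; `simulate_null()` is the identical generator with every
coupling removed (used for FDR calibration). All draws flow from one
seeded generator in a fixed order, so a fixed `SimulationConfig` is
byte-identical across runs.

**Methylation.** Site β is generated on the logit scale: a global
per-site level (SD 1.2), a per-site *patient* offset
(SD `patient_baseline_sd`, default 0.6) shared by all samples of a
patient, the planted coupling term, and residual noise (SD 0.3); the
inverse logit keeps β in [0, 1] with tunable correlation. Coverage is
negative-binomial (mean 40, size 20) and methylated counts are
binomial(coverage, β), so the emitted β carries realistic count noise
and the coverage ≥ 5 filter is actually exercised. Patient offsets are
per-site, which is what makes intra-patient correlation exceed
inter-patient correlation over variable sites.

**Planted links.** Each planted (region, gene) pair shares a latent
per-sample factor: the region's logit-β and the gene's log-expression
both load on it, with the region-side sign set by category convention —
negative for promoter and H3K27ac-associated links, positive for
H3K27me3-associated links (the repressive-mark inversion), alternating
for gene bodies. The latent correlation is inflated by a fixed factor
(1.10) chosen once from the variance accounting: the logit transform,
binomial count noise, patient offsets and residual expression noise
each attenuate the emitted correlation, and the inflation re-centres
the realised |r| on `link_effect`. Planted H3K27ac peaks' signal tracks
the target gene's expression positively (H3K27me3 negatively) with
correlation ≈ 0.95 before noise, and planted peaks sit 100–850 bp from
their region so the ±1 kb flank rule finds them. Background peaks carry
pure noise, and a pair of single-sample peaks exercises the
detected-in-≥2 filter.

**Subtypes.** Signature genes (AR program, NE1; editable TSVs under
`inst/extdata/signatures/` — the AR/NE membership lists are
curator-entered defaults anchored on the canonical program genes, the
BMP4/FGF eight-gene sets are fixed) start from a low baseline and are
shifted per sample label: +5 log2 units for the AR program in AR+
samples, +2.5 in AR-low, +4 for NE1 in NE+; BMP4 (+3) and FGF (+2)
programs activate in double-negative samples. The default assignment
allocates patient subtypes by largest remainder over the target
composition (34/15/8/39/4%), because z-sum thresholds are absolute
while z-scores are cohort-composition-relative: an extreme random
composition would change what the threshold *means*, which is a
property of the score, not of the classifier.

**Regulated genes.** With `n_regulated_genes > 0`, patient 1 becomes a
heterogeneous case (4 reference + 4 double-negative samples), and the
regulated genes couple methylation and expression through the group
contrast itself (expression ±3.5 log2 units, region logit ∓2.5 in the
DN samples) rather than through an extra latent factor — the
within-group variance stays at the residual level, which is the regime
in which a two-subtype patient is analysable at all.

**What the simulator does not emulate:** read-level data (no FASTQ,
alignment or peak calling), copy-number or tumor-purity effects,
genome-wide methylation domain structure (CpG islands, PMDs),
co-regulated gene modules beyond the planted links, and batch effects.
Passing tests therefore demonstrate that the inference machinery
recovers the planted statistical structure at the stated scales — not
that real cohorts satisfy those generative assumptions.

# Problem sizes and thresholds used in the tests

The test suite runs cohorts of 40–48 samples (10–12 patients), 300
genes and 500 regions — large enough that BH families, union peak sets
and category multiplicity behave as in full-scale data while the whole
suite stays interactive. FDR calibration averages 20 null cohorts;
recovery, subtyping and nomination checks average 5–10 seeds.
Brute-force oracle comparisons (region chaining, interval union and
flank logic, peak merging, BH, exact Wilcoxon, one-sided Fisher) run on
over 1,000 random instances of size ≤ 50. Numerical comparisons use
tolerance 1e-12 for closed-form quantities and 1e-6 for eigenvalue
computations (MDS reconstruction).

# Degenerate inputs and tie-breaks

- Variance selection breaks ties by genomic order and is invariant
  under sample permutation.
- A constant gene has z = 0 in every sample (the SD = 0 rule), so
  signature z-sums of a constant cohort are identically zero.
- A sample with zero variance across features yields `NA` correlations
  with a warning rather than an error; a cohort whose filter retains no
  CpG warns and returns an empty matrix.
- Constant region β or constant gene expression skips that pair in the
  correlation screens (it is reported only with `keep_all = TRUE`).
- `enrichment_score` with signature = all genes returns 0 for every
  sample (the running sum has no misses to step down on).
- Boundary semantics follow the stated operators exactly: AR-signature
  z-sum of exactly 3.5 is AR-low, NE1 z-sum of exactly 0 is NE−,
  |log2FC| of exactly 2 is not a single-sample DEG, a peak gap of
  exactly 1000 bp merges, and a region touching a ±1 kb flank
  associates.

# Known limitations

- The validation criterion (sign + p < 0.05) and the BH family choices
  are package definitions where the source is silent; both are
  configurable and results at the margin depend on them.
- The Welch-on-log DE substitute is anti-conservative for very low
  counts relative to a negative-binomial model; use the DE-table
  plug-in for production analyses.
- The intra/inter Wilcoxon treats sample pairs as exchangeable;
  with few patients the effective sample size is smaller than the pair
  count suggests.
- Region ids are coordinate-derived; if the coverage filter removes a
  terminal member CpG, the region's span (and id) shifts accordingly,
  which matters when intersecting link sets across differently filtered
  runs.
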