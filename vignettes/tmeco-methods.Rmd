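---
title: "Methods: dissecting an inflammation-to-cancer ecosystem with tmeco"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting an inflammation-to-cancer ecosystem with tmeco}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

tmeco implements, as a tested and reusable pipeline, the analysis stages
used to dissect a chronic-inflammation-to-carcinoma ecosystem from
single-cell RNA-seq: malignant-cell identification from
expression-inferred copy number, compositional tissue-preference
quantification (Ro/e), signature derivation and scoring, malignant
subtype discovery with bulk-cohort projection, permutation
ligand-receptor crosstalk, and clinical scoring. Because the data such
studies rest on are typically controlled-access patient cohorts, the
package ships a fully specified synthetic-data generator with planted
ground truth so that every stage is testable offline and end to end.

This vignette is the package's own account of the underlying methods:
what each stage assumes, which tunable parameters matter, and where the
design was genuinely open and a choice had to be made.

## The synthetic ecosystem generator

`simulate_ecosystem()` draws a sparse genes-by-cells UMI matrix under a
gamma-Poisson (negative binomial) model: each cell's library size is
lognormal (default meanlog `log(5000)`, sdlog 0.3 — a typical droplet
depth), and each gene's rate is its lognormal baseline abundance
modulated multiplicatively by

* a cell-type marker program (default fold-change 4 over 10 canonical
  markers per type; eight cell types: epithelial, T, B, plasma B,
  myeloid, mast, endothelial, mesenchymal),
* planted chromosome-block dosage changes, applied to malignant
  epithelial cells only (the dosage logic expression-CNV inference
  assumes),
* one of three disjoint malignant-subtype gene programs (40 genes each,
  fold-change 3; subtype follows the sample, mimicking patient-dominant
  tumor clustering),
* a latent co-expression module around a reference gene ("GZMK") in T
  cells: a random half of T cells is module-active with a per-cell
  activation `z ~ N(1, 0.3)` and per-gene loadings in `[0.75, 1.25]`
  entering as `exp(z * loading)`,
* planted ligand-receptor axes (fold-change on the ligand in the source
  type and the receptor in the target type).

Per-cell rates are renormalized so the expected library size equals the
drawn one; a planted 1.5x block therefore scales block-gene means by
slightly less than 1.5 (the renormalization denominator grows), which is
exactly what expression-based CNV inference sees in real data. Genes are
laid out on 22 synthetic autosomes with sizes proportional to the human
annotation (so multi-hundred-gene blocks fit the larger chromosomes)
plus an `MT-` prefixed mitochondrial contig that exercises the QC
filter. Planted module and subtype genes are drawn from background genes
with above-median baseline abundance — a co-expression or activation
program is only biologically meaningful for genes expressed above the
dropout floor — and are kept disjoint from the planted CNV blocks so the
two kinds of planted structure never confound each other. The
co-expression anchor and the planted ligand/receptor genes have their
baselines floored at the upper-quartile rate: they emulate abundantly
expressed canonical genes (a GZMK-like anchor that is itself below the
detection floor could not anchor a signature).

The default study design emulates a three-tissue inflammation-to-cancer
cohort (6 chronic cholecystitis, 12 primary tumors, 6 metastases, 250
cells each); tests and the acceptance script use smaller explicit
configurations (2,000-6,000 genes, 1,000-2,000 cells) chosen so the full
suite runs in minutes on a single core. What the generator deliberately
does **not** emulate: doublets, ambient RNA, batch effects beyond sample
identity, transcriptional bursting, or realistic gene-gene correlation
outside the planted programs. Passing tests therefore demonstrate that
the algorithms recover planted structure under the stated noise model,
not that they are robust to every artifact of real droplet data.

`simulate_bulk_cohort()` mixes one subtype's expected malignant profile
with a shared stromal profile at a drawn purity and Poisson-resamples;
`simulate_clinical()` produces exponential survival with a
hazard-ratio-scaled rate for marker-high patients, independent
exponential censoring, integer IHC scores in 1..4, and a MAF-lite
mutation table with Poisson(40) nonsynonymous and Poisson(20) synonymous
mutations per sample.

## Quality control, normalization, markers

`filter_qc()` keeps cells with **more than** 200 detected genes and a
mitochondrial UMI fraction **at or below** 20%, and genes detected in
more than 0.1% of cells. The two stated boundary rules ("fewer than 200
genes" removes; "more than 200 genes" keeps) leave a cell with exactly
200 genes ambiguous; we resolve it by requiring strictly more than 200,
and retain a mitochondrial fraction of exactly 0.20 (the removal rule is
strictly greater). A single filtering pass is not idempotent — removing
rare genes can drop a borderline cell's detected-gene count below
threshold — so the cell and gene filters iterate to a fixed point.

`normalize_log()` is the log counts-per-10k transform
`ln(1 + count/libsize * 1e4)`. `select_hvg()` ranks genes by the
residual of log variance from a loess mean-variance trend (2,000 genes
by default), ties broken by gene id. `scale_expression()` z-scores per
gene and clips at ±10.

Cell annotation is marker-based: each canonical marker set is scored
with the bin-matched module score and cells take the argmax label, with
the margin and runner-up recorded. This replaces graph-based clustering
plus manual annotation deliberately: it gives the pipeline a
deterministic, testable labelling surface, and a hook accepts externally
computed cluster labels wherever per-cell labels are consumed.

`find_markers()` performs the one-vs-rest two-sided Wilcoxon rank-sum
test per gene with Benjamini-Hochberg adjustment across tested genes and
the conventional retention filters (log fold change at least 0.25,
adjusted p at most 0.01, expressed fraction at least 10% on one side,
upregulated-only by default). The log fold change is
`ln(mean(expm1(x)) + 1e-9)` difference between groups — the convention
of the ecosystem these thresholds were calibrated in. The rank-sum
p-value uses the normal approximation with tie and continuity
corrections, switching to exact enumeration of all rank splits when both
groups have at most 10 cells; the implementation is checked against an
independent exhaustive-enumeration oracle for all group sizes up to 8.

## Expression-inferred CNV and malignancy calling

`build_cnv_profile()` infers relative copy number from expression with a
moving average over gene windows (default 101 genes), using known-diploid
endothelial cells as the reference panel and as spike-ins among the
interrogated cells. The operation order is: restrict to positioned
genes, order by (chromosome, start), subtract the per-gene reference
mean, clip at ±3, smooth within each chromosome with a centered window
that shrinks symmetrically at chromosome edges (so constants are
preserved and windows never cross chromosomes), median-center each cell,
and finally subtract the smoothed reference-average profile — the
moving-average scheme the classical expression-CNV tools implement. The
reference design follows the original: up to 100 endothelial reference
cells and 10 spike-ins per sample, scaled down proportionally when a
sample has fewer endothelial cells.

Malignancy calling is a two-part rule. K-means clusters the interrogated
profiles; the number of clusters is not prescribed by the source
procedure, so we select it by maximum mean silhouette over k = 2..10
with smallest-k tie-breaking and a mandatory seed — reproducible and
defensible without the original authors' manual choice. "Lack of CNVs"
is likewise unquantified; we operationalize it as a per-cell CNV burden
(mean squared smoothed score) at or below the 99th percentile of the
reference panel's burdens. A cluster is called non-malignant when it
co-clusters with the spike-ins (it holds at least half of all spike-ins,
or one spike-in per 50 member cells) *and* its median burden passes the
threshold; every other interrogated cell is malignant. Both thresholds
are exposed as arguments, and the reference burdens pass through a
robust fence (median + 10 MAD) before the quantile is taken, so a few
mislabeled cells in the diploid panel — inevitable when the labels come
from automatic annotation — cannot inflate the threshold to
malignant-level values. Whether the original clustering was run
jointly or per sample is not stated; the default is joint, and the
functions accept any cell subset for a per-sample mode.

Two scale caveats matter in practice. The window width must stay well
below the per-chromosome gene count: near chromosome edges the centered
window shrinks, and if the window rivals the chromosome size the profile
is dominated by high-variance edge windows (a 101-gene window presumes a
transcriptome of several thousand positioned genes, as in the default
configurations). And the magnitude of the null noise envelope scales as
the per-gene sampling noise divided by the square root of the window, so
absolute score readouts are only comparable between datasets of similar
depth; the classification rule relies on relative cluster structure and
reference quantiles for exactly that reason.

## Tissue preference (Ro/e)

`roe_table()` forms the clusters-by-tissues contingency table, computes
expected counts from the marginals (the chi-square expectation), and
reports the elementwise observed/expected ratio. A ratio above 1 is read
as enrichment; the Pearson chi-square statistic and p-value are reported
alongside but do not gate the enrichment mask, because the ratio itself
is the quantity of interest. Cells with expected 0 (legitimately empty
strata) yield missing ratios, never infinities. Pooling is per tissue
class by default; per-sample tables are obtained by passing sample ids
as the second margin.

## Signature derivation and scoring

`derive_signature()` anchors a signature on a reference gene (GZMK for
cytotoxicity, HAVCR2 for exhaustion, IL2RA for the Treg program in the
motivating study): Pearson correlation of the reference gene with every
other gene across the chosen cell subset of the **scaled** (z-scored,
clipped) matrix, descending sort, top 30 genes. The reference gene
anchors but does not join the signature (it is the probe, not a member);
`include_reference = TRUE` restores it. Correlations are computed on the
clipped matrix as scored; an unclipped mode is available by scaling with
a large clip bound.

`module_score()` is the bin-matched control scheme: genes are binned
into 24 average-expression bins over the scored cells, each signature
gene draws 100 control genes from its bin (with replacement when the bin
is small), and the score is mean signature expression minus mean pooled
control expression. The bin count and control count are the scheme's
common defaults — the source procedure names neither — and both are
arguments. Bins are computed on the scored subset (not all cells), since
scores are compared within that subset. The control draw is seeded and
therefore reproducible.

## Subtype discovery and bulk projection

`ss_enrichment()` is a rank-weighted running-sum single-sample
enrichment score: genes are ranked by expression within the entity
(average ranks on ties), and the score accumulates the difference
between the `rank^alpha`-weighted cumulative fraction of set genes and
the cumulative fraction of non-set genes, walking genes in decreasing
expression (ties broken by gene id). The default alpha is 0.25. This is
a deliberate substitution for GSVA's kernel-CDF statistic, which "default
parameters" under-determines for reimplementation: the running-sum form
is a single well-defined statistic that an exhaustive brute-force oracle
can verify exactly, and the downstream use (z-scored columns feeding
hierarchical clustering) is rank-based enough that the choice is nearly
inert. For the same reason the bulk pipeline uses `log2(CPM + 1)` in
place of a regularized-log transform: the enrichment score depends only
on within-sample expression ranks, which the two transforms share.

`assign_subtypes()` clusters the per-set z-scored enrichment rows with
Ward linkage on Euclidean distances and cuts at k = 3, labelling groups
I/II/III by decreasing size (ties by first entity id). `top_signature()`
builds each subtype's characteristic set as the top 15 marker genes; the
source text does not state the ranking statistic behind "top genes", so
we rank by ascending adjusted p-value, ties by descending log fold
change, then gene id — all configurable. `project_bulk()` scores the
three signatures on a bulk cohort, clusters, and maps each cluster to
the signature it scores highest on (the exact best matching over the 3!
assignments), with a per-sample argmax reported as a simpler diagnostic.
Subtype semantics (I metaplastic, II inflammatory, III mesenchymal)
attach only when marker-bearing signatures are supplied; otherwise the
labels are group ids ordered by size.

## Ligand-receptor crosstalk

`lr_interaction_test()` scores each (ligand, receptor, source, target)
as the arithmetic mean of the two group means of log-normalized
expression — the convention of the permutation tool this re-implements —
and builds the null by shuffling cell-to-group labels (globally by
default; a per-sample stratified mode is available). The p-value uses
the add-one correction `(1 + #{null >= obs}) / (n_perm + 1)` and can
never be 0. Pairs below a 10% expressed-fraction gate on either side are
reported but flagged non-testable; the retained set applies the p <=
0.05 filter. Multi-subunit receptor complexes are out of scope — pairs
are binary.

## Clinical scoring

Tumor mutational burden is nonsynonymous mutations per megabase of
assayed exon; the exon length is capture-kit specific and therefore an
input, and the nonsynonymous vocabulary (missense, nonsense, frameshift
and in-frame indels, splice site) is configurable. The IHC composite is
the density score (quartiles of positive-cell percentage, 1-4) times the
intensity score (negative to strong, 1-4), spanning 1..16.
`median_split()` sends ties at the median to the low group (a
deterministic reading of "divided by the median"; a flag flips the
convention), and `km_logrank()` pairs product-limit curves with the
two-group log-rank test.

## Numerical choices and degenerate inputs

Zero-variance genes z-score to 0 and are flagged; a constant reference
gene is an error for signature derivation. Annotation ties break
lexicographically and are flagged. K-means restarts, silhouette model
selection, module-score control draws, and permutation tests all consume
explicit seeds; every stochastic operation is byte-reproducible under a
fixed seed. Identical CNV profiles collapse to a single cluster with a
warning rather than an error. A gene set covering the entire universe
has enrichment 0 by convention (the miss term is undefined).

## Known limitations

The pipeline identifies malignancy from smoothed relative expression —
a proxy for genomic copy number that inherits expression bandwidth
limits (small or expression-silent events are invisible) and assumes the
reference cells are genuinely diploid. Subtype discovery assumes the
enrichment matrix separates entities linearly enough for Ward clustering.
The synthetic generator's independence assumptions make recovery tasks
easier than real data; the acceptance checks quantify recovery under the
stated conditions only. HMM-based CNV state calling, subclone phylogeny,
doublet detection, batch correction, embeddings, regulon inference and
immune deconvolution are deliberately out of scope.
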