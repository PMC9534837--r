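# tmeco

Tools for dissecting an inflammation-to-cancer tumor ecosystem from
single-cell RNA-seq, built for cohorts that span benign inflamed tissue,
primary tumors and matched metastases (the motivating system is chronic
cholecystitis progressing to gallbladder carcinoma). The package is aimed
at computational biologists who need the full analysis chain as tested,
scriptable functions rather than a collection of notebook fragments.

## What it does

* **Malignant-cell identification from expression-inferred CNV.**
  Log-normalized expression is reference-centered against known-diploid
  endothelial cells, clipped, and smoothed along the genome with a
  101-gene moving average within chromosomes; K-means clusters the
  profiles (silhouette-selected k) and a cluster is non-malignant iff it
  co-clusters with diploid *spike-in* cells **and** its median CNV burden
  (mean squared score) stays below the 99th percentile of the reference
  panel's burdens. Everything else is malignant epithelium.
* **Tissue preference (Ro/e).** For clusters-by-tissues contingency
  tables, Ro/e = observed / expected cell numbers with expected counts
  from the chi-square marginals; Ro/e > 1 reads as enrichment.
* **Signature derivation and scoring.** Signatures anchored on a
  reference gene (e.g. GZMK for cytotoxicity, HAVCR2 for exhaustion,
  IL2RA for the Treg program) as the top-30 genes by Pearson correlation
  on scaled expression; per-cell scoring via the bin-matched
  control-gene module score.
* **Malignant subtype discovery and bulk projection.** Rank-weighted
  running-sum single-sample enrichment (`sum_i [P_hit(i) - P_miss(i)]`
  with `|rank|^alpha` weights), Ward clustering into three subtypes,
  top-15 characteristic signatures, and projection onto bulk cohorts via
  log2(CPM+1).
* **Ligand-receptor crosstalk.** Permutation test on the mean of the
  ligand's source-group mean and the receptor's target-group mean, with
  add-one-corrected p-values and the p <= 0.05 retention rule.
* **Clinical scoring.** TMB (nonsynonymous mutations per exon megabase),
  IHC composites (density x intensity, 1..16), median-split survival
  stratification with Kaplan-Meier curves and the log-rank test.
* **A synthetic-data generator** (`simulate_ecosystem()`,
  `simulate_bulk_cohort()`, `simulate_clinical()`) with planted ground
  truth — cell-type marker programs, CNV dosage blocks, a latent
  co-expression module, three malignant subtypes, ligand-receptor axes,
  survival linked to a marker — so the whole pipeline is testable
  offline.

Marker-score argmax annotation replaces graph clustering + manual
labels; externally computed cluster labels can be passed anywhere
per-cell labels are consumed.

## Worked example

```r
library(tmeco)

cfg <- sim_config(
  n_genes = 6000, n_cells_per_sample = 200,
  samples = data.frame(sample_id = c("CC1", "GBC1", "GBC2", "GBC3", "MT1"),
                       tissue    = c("CC", "PT", "PT", "PT", "MT")),
  cnv_blocks = data.frame(chromosome = "chr1", start_gene_idx = 50,
                          length_in_genes = 300, dosage_factor = 1.5),
  seed = 5)
sim  <- simulate_ecosystem(cfg)
qc   <- filter_qc(sim$counts)          # >200 genes, <=20% mito, >0.1% prevalence
norm <- normalize_log(qc)

# marker-based annotation, then malignancy calling with endothelial
# reference + spike-ins
ann  <- annotate_cells(norm, cell_type_markers(), seed = 1)
call <- call_malignancy(qc, sim$truth$gene_table, ann$label, seed = 1)
glance(call)
```

```
#> # A tibble: 1 x 5
#>   k_used burden_threshold n_malignant n_non_malignant n_spikein
#>    <int>            <dbl>       <int>           <int>     <int>
#> 1      2           0.0147         221              37        25
```

K-means found k = 2 CNV clusters: 221 interrogated epithelial cells
carry the planted 1.5x chromosomal block and are called malignant, while
the cluster holding all 25 diploid spike-ins with low CNV burden (below
the 0.0147 reference threshold) is non-malignant. Against the generator's
ground truth this call has sensitivity 0.96 and specificity 0.94 — the
residual errors are annotation mistakes feeding the reference design,
not CNV errors.

```r
# tissue preference of the annotated populations
roe_table(ann$label, qc$cell_meta$tissue)
```

```
#> <roe_table> 8 clusters x 3 tissues; chi2 = 41.8 (df 14, p = 0.000131)
#>              tissue
#> cluster          CC    MT    PT
#>   B           1.667 0.938 0.799
#>   Endothelial 0.926 0.926 1.049
#>   Epithelial  0.543 1.260 1.066
#>   Mast        0.682 0.455 1.288
#>   Mesenchymal 0.774 0.806 1.140
#>   Myeloid     1.241 1.095 0.888
#>   PlasmaB     1.594 0.652 0.918
#>   T           1.261 0.978 0.920
```

Ro/e > 1 marks enrichment: benign tissue (CC) is enriched for B, plasma
and T cells while the tumors hold more epithelium and mesenchyme — the
compositional shift the generator plants.

```r
# permutation test for the planted epithelium -> T cell axes
lr <- lr_interaction_test(norm, ann$label,
        data.frame(ligand   = c("MIF", "FAM3C", "CD55"),
                   receptor = c("TNFRSF14", "CLEC2D", "ADGRE5")),
        n_perm = 1000, seed = 1)
dplyr::filter(lr, source == "Epithelial", target == "T")
```

```
#>   ligand receptor score  p_value retained
#> 1    MIF TNFRSF14 1.774 0.000999     TRUE
#> 2  FAM3C   CLEC2D 1.460 0.000999     TRUE
#> 3   CD55   ADGRE5 1.832 0.000999     TRUE
```

All three planted axes reach the permutation floor `1/(n_perm + 1)` and
survive the p <= 0.05 retention rule. Signature derivation
(`derive_signature()`, `module_score()`), subtype discovery
(`enrichment_matrix()`, `assign_subtypes()`, `project_bulk()`) and the
clinical scores (`compute_tmb()`, `ihc_composite()`, `median_split()`,
`km_logrank()`) follow the same pattern; the methods vignette
(`vignettes/tmeco-methods.Rmd`) walks through each model and its
assumptions.

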