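# scregion

Regional enrichment and cis-regulatory statistics for multi-region
single-cell atlases.

Brain-scale single-nucleus atlases profile the same cell types across many
anatomical regions, and the recurring analytical questions are the same:
*how regionally structured is this cell population, which genes drive that
structure, which wells and nuclei are technical artefacts, and which
accessible-chromatin peaks regulate which genes?* scregion packages the
statistical machinery for those questions — for analysts working with
paired snRNA-seq / snATAC-seq data from combinatorial-indexing protocols —
validated end to end on a built-in synthetic-data generator with planted
ground truth, so no external download is needed to verify any stage.

## What it computes

**lochNESS** — a per-cell regional neighbourhood enrichment score. For
cell *n* and region *m* within one cell type,

```
lochNESS(n, m) = (#region-m cells among the k nearest neighbours of n / k)
                 ---------------------------------------------------------
                                  (N_m / N)
```

so 1 means the cell's transcriptional neighbourhood mirrors the region's
overall share. Downstream: normalization over regions of interest
(`lochNESS*`), dominant-region labelling, and a per-gene robust-Poisson
regression `log E[y] = b0 + sum_m b_m lochNESS_m + log(size factor)` that
finds region-biased genes with BH correction over all gene × region tests.

**Jensen-Shannon screens** — base-2 JSD (range [0, 1]) drives (i) regional
specificity scores per cell class/subtype against the pooled atlas
distribution, (ii) an RT-barcode contamination screen (flag wells with
> 10,000 cells, class JSD > 0.15 *and* subtype JSD > 0.075 against the
sample's mean barcode composition), and (iii) capped log2 composition
enrichment ratios (`clamp(log2(prop/mean prop), ±2)`).

**QC rules** — the printed nucleus filters (RNA: UMI ≥ 100, genes < 2500,
mito < 5%; ATAC: binarized UMI in [1000, 100000), FRiP ≥ 30%), per-cell
doublet flags (score > 0.20) and doublet-cluster flags (mean score > 0.15).

**Metacell peak–gene links** — k-means metacells on the integrated
embedding (`floor(n_cells/250)` metacells by default), pseudobulk
log2(CPM+1), candidate pairs within 150 kb of the strand-aware promoter
(TSS − 2 kb), a per-pair logistic regression of single-cell peak
accessibility on metacell expression (likelihood-ratio test), two-stream
evidence combination (both adjusted p < 0.05) with direction from the
coefficient sign, and one-vs-rest differential-accessibility marker calling
(regularized LR coefficient > 0, log2FC > 0, t-test P_adj < 0.05).

**TF activity signs** — Pearson correlation of motif accessibility vs
cognate gene expression across cell-class × region groups: activators
(r > 0) vs repressors (r < 0).

## A worked example

```r
library(scregion)
library(dplyr)

cfg <- sim_config(n_cells = 2000, n_genes = 50,
                  region_bias = tibble::tibble(gene = "g0010",
                                               region = "A", log2fc = 1.5),
                  shifted_regions = c("A", "B", "C", "D"), seed = 1)
sim <- simulate_rna(cfg)

L <- compute_lochness(sim$embedding, sim$meta, k = 25)
round(colMeans(L$raw), 3)
#>     A     B     C     D
#> 1.002 1.006 0.994 0.998

lochness_glm(sim$counts, L) |> tidy() |> arrange(p_adj) |> head(3)
#> dropping collinear lochNESS column 'D'.
#> # A tibble: 3 × 7
#>   gene_id term  estimate std_error statistic        p    p_adj
#> 1 g0010   A       0.257     0.0154     16.7  1.28e-62 1.92e-60
#> 2 g0024   A      -0.0779    0.0216     -3.61 3.06e- 4 2.30e- 2
#> 3 g0028   B       0.0922    0.0286      3.23 1.26e- 3 6.29e- 2
```

The per-region means sit at 1 because region labels are exchangeable under
the null parts of this embedding; the planted gene `g0010` (+1.5 log2 in
region A) tops the regression table with a positive region-A coefficient at
overwhelming significance, while the runner-up null genes hover at the
detection edge. The collinearity message is expected: the share-weighted
sum of lochNESS scores is identically 1, so one region column is always
redundant with the intercept.

```r
m <- tibble::tibble(cell_id = paste0("c", 1:6),
                    total_umi = c(500L, 1000L, 99999L, 100000L, 2000L, 3000L),
                    frip = 0.5)
filter_nuclei(m, qc_thresholds(), "atac")
#> # A tibble: 6 × 3
#>   cell_id kept  reason
#> 1 c1      FALSE umi_low
#> 2 c2      TRUE  <NA>
#> 3 c3      TRUE  <NA>
#> 4 c4      FALSE umi_high
#> 5 c5      TRUE  <NA>
#> 6 c6      TRUE  <NA>
```

Boundary semantics are encoded verbatim: 1000 is kept (≥), 100000 is
dropped (<), 99999 is kept.

A command-line dispatcher over the same functions ships in
`inst/scripts/scregion` (subcommands `simulate`, `qc`, `lochness`,
`specificity`, `links`, `tfcorr`, each driven by a YAML config); the
methods vignette (`vignettes/scregion-methods.Rmd`) documents the models,
parameter defaults, and numerical choices.

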