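---
title: "Methods: regional enrichment and cis-regulatory statistics in scregion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional enrichment and cis-regulatory statistics in scregion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scregion)
library(dplyr)
```

scregion implements the statistical layer of a multi-region single-nucleus
RNA + ATAC analysis: given per-cell metadata, a low-dimensional embedding,
and sparse count matrices, it quantifies how regionally structured each cell
population is, screens the data for technical artefacts specific to
combinatorial indexing, and links accessible chromatin to nearby genes
through metacell pseudobulks. This vignette explains each model, its
assumptions, the tunable parameters, and the numerical choices, in the order
a practitioner would meet them.

## The lochNESS statistic

For one cell type at a time, every cell $n$ receives a score per region $m$:

$$\mathrm{lochNESS}_{n,m} =
  \frac{\#\{\text{region-}m\text{ cells among the } k \text{ nearest
  neighbours of } n\}/k}
       {N_m / N},$$

where $N$ is the number of cells of the type and $N_m$ the number from
region $m$. The numerator is the local regional composition of the cell's
transcriptional neighbourhood; the denominator the global share, so 1 means
"no enrichment". The normalized variant $\mathrm{lochNESS}^*$ rescales each
cell's scores over a chosen region subset to sum to 1, which makes scores
comparable when only, say, cortical regions are of interest.

Neighbourhoods are exact Euclidean $k$-nearest neighbours on the supplied
embedding. Two choices are deliberate:

* **The focal cell is excluded from its own neighbourhood.** Self-inclusion
  adds a bias of order $1/k$ that depends on the cell's own region,
  distorting exactly the quantity the score measures.
* **Distance ties are broken by ascending cell index.** kNN graphs on
  quantized or duplicated coordinates are otherwise non-deterministic; with
  this rule the whole matrix is reproducible by a brute-force sort, which
  the test suite exploits. Search is exact at all sizes the package
  targets (one cell type at a time, up to a few tens of thousands of
  cells); no approximate backend is provided, which is a known limitation
  for atlas-scale reuse.

`k` defaults to 25: small enough to stay local in a 10-dimensional
embedding, large enough that the neighbourhood composition (a
$\mathrm{Binomial}(k, p)/k$ fraction) has usable precision. Under a
label-independent embedding the expected per-region mean of the raw score is
exactly 1 (the $n$-th cell's inclusion/exclusion bookkeeping cancels in the
average), which the acceptance suite verifies at $N = 5000$.

## The region-bias gene regression

To find genes whose expression tracks regional neighbourhood structure, each
gene is fit with a log-link count regression on the cell's lochNESS scores:

$$\log E[y_{n}] = \beta_0 + \sum_m \beta_m \,\mathrm{lochNESS}_{n,m}
  + \log s_n,$$

with size factors $s_n$ defaulting to total UMI over its median. Two
consequences of the statistic's algebra matter here:

* The region-share-weighted sum $\sum_m (N_m/N)\,\mathrm{lochNESS}_{n,m}$
  equals 1 for every cell, so the intercept plus all $M$ region columns is
  always rank-deficient. The last region column (in region order) is
  dropped with a message; coefficients are interpreted relative to that
  reference region.
* Single-cell UMI counts are overdispersed relative to Poisson, so Wald
  tests use heteroskedasticity-robust (HC0 sandwich) standard errors around
  the Poisson point estimates — the standard robust-Poisson recipe, which
  keeps type-I error near nominal under the negative-binomial noise the
  generator produces (verified: null false-positive rate within
  [0.02, 0.10] at nominal 0.05 in the acceptance suite). p-values are
  Benjamini-Hochberg adjusted across all gene-by-region tests as one
  family, matching a single pooled table of region-associated genes.

## Jensen-Shannon screens

Two screens use the same divergence. With base-2 logarithms,
$\mathrm{JSD}(p, q) = \tfrac12 KL(p\,\|\,m) + \tfrac12 KL(q\,\|\,m)$,
$m = (p+q)/2$, lies in $[0, 1]$; the base is chosen so that published
specificity scores in the $[0.04, 0.81]$ range are reproducible on the
bounded scale (a natural-log variant would top out at $\ln 2$).

* **Regional specificity**: per cell class or subtype, the JSD between the
  group's count distribution over regions and the pooled distribution of
  the whole dataset. 0 means the group mirrors the atlas; values near 1
  mean regional confinement.
* **Barcode contamination**: within each sample, each RT barcode's cell
  class and subtype proportions are compared to the unweighted mean of the
  sample's per-barcode proportion vectors. A barcode is flagged only when
  it is large (> 10,000 cells) *and* divergent at both label resolutions
  (class JSD > 0.15, subtype JSD > 0.075); small wells have noisy
  compositions and would otherwise be flagged spuriously. Subtype
  proportions are computed over the union of subtypes present in the
  sample with zeros retained — JSD stays finite under zeros through the
  mixture term, so no pseudocounts are needed.

A practical note on the thresholds: because the reference is the mean
*including* the suspect barcode, the screen only separates a contaminated
well cleanly when most of the sample's wells are clean — with $B$ barcodes
the reference is pulled $1/B$ of the way toward the contaminated
composition. The synthetic validation therefore uses 21 barcodes (one
contaminated), the regime the rule was designed for.

* **Composition enrichment ratios**: the per-region display statistic
  $\mathrm{clamp}(\log_2(p_{rs} / \overline{p_{\cdot s}}), \pm 2)$, where
  $p_{rs}$ is subtype $s$'s share of region $r$'s cells and the denominator
  is the unweighted mean over regions (a pooled-denominator variant is
  available by flag). Subtypes under 100 cells are dropped by default (a
  display rule, exposed as a parameter). A zero within-region proportion is
  replaced by half the subtype's smallest nonzero proportion before the
  log; the $\pm 2$ cap bounds the effect of this pseudo-proportion anyway.

## Nucleus- and cluster-level QC

The numeric filters encode printed inequalities verbatim: RNA nuclei keep
`total_umi >= 100`, `n_genes < 2500`, `mito_frac < 0.05`; ATAC nuclei keep
`total_umi` in `[1000, 100000)` and `frip >= 0.30`; cells with doublet
score `> 0.20` (strict) and clusters with mean score `> 0.15` (strict) are
flagged. Where the source rule is written `>=` the boundary is inclusive,
where `<`/`>` it is strict; a cell at exactly 0.20 is *not* a doublet.
Reason codes report the first failing filter in a fixed order (umi, genes,
mito / umi_low, umi_high, frip), so reruns are byte-identical. Doublet
scores themselves (Scrublet-style) are consumed as input, never recomputed.

## Metacell peak-gene linking

The cis-regulatory stage works on metacells: k-means clusters of the
integrated embedding (k-means++-style seeding, fixed RNG seed, empty
clusters re-seeded). The metacell count follows
`floor(n_cells / target)` with a target of ~250 RNA transcriptomes per
metacell (the atlas worked example: 2,583,967 cells gives 10,335
metacells). RNA counts are summed per metacell and normalized to
$\log_2(\mathrm{CPM} + 1)$.

Candidate peak-gene pairs are all peaks whose interval lies within 150 kb
(inclusive) of the gene's promoter — the strand-aware TSS extended 2000 bp
upstream, one gene-wide TSS per gene (the most upstream isoform start is the
caller's responsibility; using a single TSS is a stated limitation of the
windowing approach). Reported signed distances are measured peak-to-TSS,
negative upstream.

For each pair, the accessibility of each ATAC cell at the peak (1 open / 0
closed) is regressed on the log2CPM of the gene in the cell's metacell.
Because all cells of a metacell share the predictor, the fit is computed on
metacell-aggregated binomial counts — algebraically the same maximum
likelihood problem at a fraction of the cost. The slope p-value is the
likelihood-ratio (deviance) test rather than the Wald test: with strongly
predictive links the fitted probabilities saturate and the Wald statistic
collapses (the Hauck-Donner effect), silently discarding exactly the
strongest links; the LRT does not. Degenerate fits are still reported with
reason codes: constant response or predictor, and quasi-separation (zero
residual deviance or a slope beyond ±25, where only the sign is
identified) return a capped coefficient with a null p-value.

Evidence is combined across two streams: the logistic test and an external
regulatory score (e.g. an embedding-similarity inference), each BH-adjusted
within its own set of tested pairs. A pair is a candidate regulatory link
iff both adjusted p-values fall below 0.05, and candidates are classified
positive/negative by the sign of the logistic coefficient. Pairs without
external evidence are left untestable (`NA`), not rejected. A
permutation-style utility converts any user-supplied pair score into
empirical upper-tail p-values when the external stream provides scores only.

Differential accessibility uses a one-vs-rest design per peak and cell
class: an L2-regularized logistic coefficient (ridge IRLS, penalty `1/n`,
mirroring an unscaled C = 1 default; the intercept is unpenalized), a
log2 fold change of mean open fractions with a `1e-9` pseudocount on both
means (so an everywhere-closed peak has log2FC exactly 0), and a Welch
t-test BH-adjusted across peaks within each class. A marker requires all
three: positive coefficient, positive fold change, adjusted p below 0.05.

## TF activity signs

Given aligned per-group (cell class × region subclass) summaries of motif
accessibility and cognate gene expression, the Pearson correlation across
groups classifies each TF as activator (r > 0) or repressor (r < 0);
constant vectors return "undetermined" rather than a sign claim. At least
3 groups are required; a Spearman flag covers rank-based use. How the
group summaries are aggregated upstream (motif scoring, deviations) is
deliberately out of scope — the contract starts at aligned vectors.

## The synthetic-data generator

Every stage is validated against `sim_config()` / `simulate_rna()` /
`simulate_atac()` data with planted truth:

* **Counts**: negative binomial with per-cell log-normal library sizes
  (mean 1500 UMI, log-SD 0.3 — typical combinatorial-indexing depth), per
  cell class gamma-shaped expression profiles, and multiplicative
  $2^{\log_2 FC}$ effects for region-biased genes. `dispersion` is the
  field-standard $\alpha$ with $\mathrm{var} = \mu + \alpha\mu^2$
  (default 0.5, the upper end of realistic single-nucleus overdispersion;
  0 gives Poisson).
* **Embedding**: generated directly (per-class Gaussian centres, a
  displacement of 3 noise-SD units along a region-specific direction for
  shifted regions, isotropic unit noise) rather than recomputed by
  dimensionality reduction — the only contract the statistics need is that
  transcriptionally similar cells are near each other. By default only
  regions carrying biased genes are shifted; validation of the region-bias
  regression uses the regionalized setting (all regions shifted), since a
  multi-region atlas has broad regional structure and lochNESS covariates
  carry no signal when the embedding itself cannot separate regions.
* **Doublets**: mean-of-two-parents expression rates and coordinates,
  grouped into their own cluster with scores from Beta(8, 2)
  (mean 0.8); singlets draw from Beta(2, 30) (mean ~0.06). The bimodal
  gap reproduces what doublet-score histograms look like in practice and
  is what the per-cell (0.20) and cluster-mean (0.15) rules assume; a
  singlet distribution with mass above those cuts would make the rules
  unusable by construction.
* **Contamination**: a configured fraction of a barcode's cells get labels
  copied from randomly drawn cells of the donor sample, so the barcode's
  composition becomes the analytic host/donor mixture.
* **ATAC**: planted links open each cell's peak with probability
  $\mathrm{logit}^{-1}(\beta_0 + \beta \cdot \mathrm{log_2CPM})$ of the
  linked gene in the cell's metacell, with $\beta_0$ centring the mean
  open rate at the base rate (default 0.1); unlinked peaks open at the
  base rate. Planted links in the validation suite are placed on
  moderately variable genes (ranks 16-45 by pseudobulk variance):
  all-or-nothing bimodal genes produce perfectly separated fits whose
  slope is unidentified, which is a property of logistic regression, not
  of the linking method.

What the generator does *not* emulate: sequence content, batch effects,
co-accessibility beyond planted links, ambient RNA, or realistic cluster
geometry. Passing tests therefore demonstrate that the statistics recover
the structure they are defined on — not that they are robust to every
artefact of real data.

## Problem sizes and determinism

The test and acceptance workloads use 2,000-5,000 cells, 20-60 genes,
50-100 peaks, and up to 260,000 cells for the metadata-only contamination
screens — sizes chosen so the full validation runs on a laptop in about two
minutes while keeping each check adequately powered (e.g. 470 null pairs
for candidate-rate calibration, ~1,700 null coefficients for GLM
calibration). All generators are deterministic given the config seed
(`withr::with_seed` throughout); identical configs produce byte-identical
outputs.

## A compact example

```{r example, eval = FALSE}
cfg <- sim_config(n_cells = 2000, n_genes = 50,
                  region_bias = tibble::tibble(gene = "g0010",
                                               region = "A", log2fc = 1.5),
                  shifted_regions = c("A", "B", "C", "D"), seed = 1)
sim <- simulate_rna(cfg)
L <- compute_lochness(sim$embedding, sim$meta, k = 25)
argmax_region(L) |> head()
lochness_glm(sim$counts, L) |> tidy() |> arrange(p_adj) |> head()
```
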