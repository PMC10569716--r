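#' Quality-control thresholds
#'
#' Bundles the nucleus-, cluster-, and barcode-level QC cutoffs. Defaults
#' follow the atlas filtering rules: RNA nuclei keep total UMI >= 100
#' (inclusive), expressed genes < 2500 (strict) and mitochondrial fraction
#' < 0.05 (strict); ATAC nuclei keep binarized UMI in [1000, 100000) and
#' FRiP >= 0.30; cells with doublet score > 0.20 and clusters with mean
#' doublet score > 0.15 are flagged; RT barcodes are flagged when they hold
#' more than 10,000 cells AND have cell-class JSD > 0.15 AND cell-subtype
#' JSD > 0.075 against the sample's mean barcode composition.
#'
#' @param rna_min_umi,rna_max_genes,rna_max_mito RNA nucleus filters.
#' @param atac_min_umi,atac_max_umi,atac_min_frip ATAC nucleus filters.
#' @param cell_doublet_cut,cluster_doublet_cut Doublet-score cutoffs.
#' @param barcode_min_cells,barcode_class_jsd_cut,barcode_subtype_jsd_cut
#'   Barcode contamination-screen cutoffs.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(rna_min_umi = 100L, rna_max_genes = 2500L,
                          rna_max_mito = 0.05,
                          atac_min_umi = 1000L, atac_max_umi = 100000L,
                          atac_min_frip = 0.30,
                          cell_doublet_cut = 0.20, cluster_doublet_cut = 0.15,
                          barcode_min_cells = 10000L,
                          barcode_class_jsd_cut = 0.15,
                          barcode_subtype_jsd_cut = 0.075) {
  stopifnot(rna_min_umi >= 0, rna_max_genes > 0,
            rna_max_mito >= 0, rna_max_mito <= 1,
            atac_min_umi >= 0, atac_max_umi > atac_min_umi,
            atac_min_frip >= 0, atac_min_frip <= 1,
            cell_doublet_cut >= 0, cell_doublet_cut <= 1,
            cluster_doublet_cut >= 0, cluster_doublet_cut <= 1,
            barcode_min_cells >= 0)
  structure(as.list(environment()), class = "qc_thresholds")
}

#' Filter nuclei on the per-modality numeric QC rules
#'
#' A nucleus is kept iff it passes all filters of its modality. Boundary
#' semantics mirror the printed rules exactly: RNA keeps `total_umi >= 100`
#' (inclusive), `n_genes < 2500` (strict), `mito_frac < 0.05` (strict);
#' ATAC keeps `total_umi >= 1000` (inclusive), `total_umi < 100000`
#' (strict), `frip >= 0.30` (inclusive). The per-cell `reason` reports the
#' first failing filter in a fixed order (RNA: umi, genes, mito; ATAC:
#' umi_low, umi_high, frip) so output is deterministic.
#'
#' @param meta Per-cell metadata tibble with `cell_id`, `total_umi` and,
#'   depending on modality, `n_genes` + `mito_frac` (RNA) or `frip` (ATAC).
#' @param thresholds A [qc_thresholds()] object.
#' @param modality `"rna"` or `"atac"`.
#' @return A tibble with `cell_id`, `kept` (logical), `reason` (`NA` when
#'   kept).
#' @export
filter_nuclei <- function(meta, thresholds = qc_thresholds(),
                          modality = c("rna", "atac")) {
  modality <- match.arg(modality)
  th <- thresholds
  if (modality == "rna") {
    need <- c("cell_id", "total_umi", "n_genes", "mito_frac")
    if (!all(need %in% names(meta))) {
      abort(paste("rna filtering needs columns:", paste(need, collapse = ", ")))
    }
    reason <- dplyr::case_when(
      meta$total_umi < th$rna_min_umi ~ "min_umi",
      meta$n_genes >= th$rna_max_genes ~ "max_genes",
      meta$mito_frac >= th$rna_max_mito ~ "max_mito",
      TRUE ~ NA_character_
    )
  } else {
    need <- c("cell_id", "total_umi", "frip")
    if (!all(need %in% names(meta)) || all(is.na(meta[["frip"]]))) {
      abort("atac filtering needs columns cell_id, total_umi and non-missing frip.")
    }
    reason <- dplyr::case_when(
      meta$total_umi < th$atac_min_umi ~ "umi_low",
      meta$total_umi >= th$atac_max_umi ~ "umi_high",
      meta$frip < th$atac_min_frip ~ "low_frip",
      TRUE ~ NA_character_
    )
  }
  tibble(cell_id = meta$cell_id, kept = is.na(reason), reason = reason)
}

#' Flag individual nuclei as doublets
#'
#' Flags nuclei whose doublet score strictly exceeds the cutoff
#' (`score > cut`; a score exactly at the cutoff is not flagged). Missing
#' scores yield `NA` flags with a warning.
#'
#' @param meta Per-cell metadata with `cell_id` and `doublet_score`.
#' @param cut Cutoff (default 0.20).
#' @return A tibble with `cell_id`, `doublet_score`, `is_doublet`.
#' @export
flag_doublet_cells <- function(meta, cut = 0.20) {
  if (!"doublet_score" %in% names(meta)) abort("`doublet_score` column missing.")
  s <- meta$doublet_score
  if (anyNA(s)) {
    warn(sprintf("%d missing doublet score(s) flagged NA.", sum(is.na(s))))
  }
  tibble(cell_id = meta$cell_id, doublet_score = s, is_doublet = s > cut)
}

#' Flag doublet-derived clusters by mean doublet score
#'
#' A cluster is flagged iff the mean doublet score over its member cells
#' strictly exceeds the cutoff; all member cells of a flagged cluster are
#' marked for removal.
#'
#' @param meta Per-cell metadata with `cell_id`, `cluster_id`,
#'   `doublet_score`.
#' @param cut Cutoff on the cluster mean (default 0.15).
#' @return A tibble with one row per cluster: `cluster_id`, `n_cells`,
#'   `mean_score`, `flagged`.
#' @export
flag_doublet_clusters <- function(meta, cut = 0.15) {
  need <- c("cluster_id", "doublet_score")
  if (!all(need %in% names(meta))) {
    abort("need columns cluster_id and doublet_score.")
  }
  meta |>
    filter(!is.na(cluster_id)) |>
    group_by(cluster_id) |>
    summarise(n_cells = dplyr::n(),
              mean_score = mean(doublet_score, na.rm = TRUE),
              .groups = "drop") |>
    mutate(flagged = mean_score > cut)
}

barcode_jsd_one <- function(meta_sample, label_col) {
  # per-barcode label proportions vs the unweighted mean across barcodes,
  # over the union of labels in the sample (zeros retained)
  labs <- factor(meta_sample[[label_col]])
  bc <- factor(meta_sample$rt_barcode)
  tab <- unclass(table(bc, labs, dnn = NULL))
  props <- tab / rowSums(tab)
  ref <- colMeans(props)
  vapply(seq_len(nrow(props)),
         function(i) jsd(props[i, ], ref / sum(ref)),
         numeric(1)) |>
    setNames(rownames(props))
}

#' Screen RT barcodes for cross-well contamination
#'
#' Within each sample, compares each reverse-transcription barcode's cell
#' class and cell subtype proportions to the mean proportions across all of
#' that sample's barcodes, using base-2 Jensen-Shannon divergence. A barcode
#' is flagged iff it holds more than `barcode_min_cells` cells AND its class
#' JSD exceeds `barcode_class_jsd_cut` AND its subtype JSD exceeds
#' `barcode_subtype_jsd_cut`. Cells of flagged barcodes should be excluded
#' from downstream regional-proportion analyses.
#'
#' @param meta Per-cell metadata with `sample_id`, `rt_barcode`,
#'   `cell_class`, `cell_subtype`.
#' @param thresholds A [qc_thresholds()] object.
#' @return A tibble with one row per (sample, barcode): `sample_id`,
#'   `rt_barcode`, `n_cells`, `class_jsd`, `subtype_jsd`, `flagged`.
#' @export
screen_barcodes <- function(meta, thresholds = qc_thresholds()) {
  need <- c("sample_id", "rt_barcode", "cell_class", "cell_subtype")
  if (!all(need %in% names(meta))) {
    abort(paste("need columns:", paste(need, collapse = ", ")))
  }
  th <- thresholds
  meta |>
    filter(!is.na(cell_class), !is.na(cell_subtype)) |>
    dplyr::group_split(sample_id) |>
    map(function(ms) {
      cj <- barcode_jsd_one(ms, "cell_class")
      sj <- barcode_jsd_one(ms, "cell_subtype")
      nb <- table(ms$rt_barcode)
      tibble(sample_id = ms$sample_id[1],
             rt_barcode = names(cj),
             n_cells = as.integer(nb[names(cj)]),
             class_jsd = unname(cj),
             subtype_jsd = unname(sj))
    }) |>
    list_rbind() |>
    mutate(flagged = n_cells > th$barcode_min_cells &
             class_jsd > th$barcode_class_jsd_cut &
             subtype_jsd > th$barcode_subtype_jsd_cut)
}
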