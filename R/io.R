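#' Sparse count matrix container
#'
#' A thin S3 container pairing a sparse cells x features count matrix with its
#' modality. RNA counts are UMI counts; ATAC counts are binarized (1 = open,
#' 0 = closed) at construction time, so every downstream stage sees a single
#' representation.
#'
#' @param counts A matrix or sparse `Matrix` with cells as rows and features
#'   as columns. Dimnames are required (cell ids, feature ids).
#' @param modality Either `"rna"` or `"atac"`.
#' @return An object of class `sc_counts`: a list with elements `counts`
#'   (a `dgCMatrix`) and `modality`.
#' @examples
#' m <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 2), x = c(5, 2),
#'                           dims = c(3, 2),
#'                           dimnames = list(paste0("c", 1:3), c("g1", "g2")))
#' sc_counts(m, "rna")
#' @export
sc_counts <- function(counts, modality = c("rna", "atac")) {
  modality <- match.arg(modality)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    abort("`counts` must carry cell ids as rownames and feature ids as colnames.")
  }
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    abort("cell ids and feature ids must be unique.")
  }
  if (length(counts@x) && any(counts@x < 0)) {
    abort("counts must be non-negative.")
  }
  if (modality == "atac") {
    counts@x <- as.numeric(counts@x > 0)
    counts <- Matrix::drop0(counts)
  }
  structure(list(counts = counts, modality = modality), class = "sc_counts")
}

#' @export
print.sc_counts <- function(x, ...) {
  cat(sprintf("<sc_counts> %s: %d cells x %d features, %d nonzero\n",
              x$modality, nrow(x$counts), ncol(x$counts),
              length(x$counts@x)))
  invisible(x)
}

#' @export
dim.sc_counts <- function(x) dim(x$counts)

sidecar_paths <- function(path) {
  stem <- sub("\\.mtx$", "", path)
  list(cells = paste0(stem, ".cells.tsv"), features = paste0(stem, ".features.tsv"))
}

#' Read a sparse count matrix from MatrixMarket triplets
#'
#' Reads an MTX-style triplet file (cells as rows, features as columns)
#' together with its two sidecar id files, `<stem>.cells.tsv` and
#' `<stem>.features.tsv`, each holding one id per line. ATAC matrices are
#' binarized on load.
#'
#' @param path Path to the `.mtx` file.
#' @param modality `"rna"` or `"atac"`.
#' @return An [sc_counts] object.
#' @seealso [write_counts()]
#' @export
read_counts <- function(path, modality = c("rna", "atac")) {
  modality <- match.arg(modality)
  side <- sidecar_paths(path)
  m <- Matrix::readMM(path)
  cells <- readr::read_tsv(side$cells, col_names = "cell_id",
                           col_types = readr::cols(cell_id = "c"))$cell_id
  feats <- readr::read_tsv(side$features, col_names = "feature_id",
                           col_types = readr::cols(feature_id = "c"))$feature_id
  if (nrow(m) != length(cells) || ncol(m) != length(feats)) {
    abort(sprintf(
      "matrix is %d x %d but sidecars declare %d cells and %d features.",
      nrow(m), ncol(m), length(cells), length(feats)))
  }
  dimnames(m) <- list(cells, feats)
  sc_counts(m, modality)
}

#' Write a sparse count matrix as MatrixMarket triplets
#'
#' Inverse of [read_counts()]: writes `<path>` plus the `.cells.tsv` /
#' `.features.tsv` sidecars next to it.
#'
#' @param x An [sc_counts] object.
#' @param path Output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "sc_counts"))
  side <- sidecar_paths(path)
  Matrix::writeMM(x$counts, path)
  readr::write_lines(rownames(x$counts), side$cells)
  readr::write_lines(colnames(x$counts), side$features)
  invisible(path)
}

#' Read peak intervals from a BED file
#'
#' Parses a 3+ column BED file into a tibble of 0-based half-open peak
#' records, sorted within chromosome. Records with `end <= start` are dropped
#' with a warning; when the name column is absent, peak ids are synthesized
#' as `chrom:start-end`.
#'
#' @param path Path to a BED file (tab-separated; `track`/`browser`/comment
#'   lines are skipped).
#' @return A tibble with columns `peak_id`, `chrom`, `start`, `end`.
#' @export
read_intervals <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(tibble(peak_id = character(), chrom = character(),
                  start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- min(lengths(fields))
  if (ncol_min < 3) abort("BED file must have at least 3 columns.")
  bed <- tibble(
    chrom = map_chr(fields, 1),
    start = as.integer(map_chr(fields, 2)),
    end   = as.integer(map_chr(fields, 3)),
    peak_id = if (ncol_min >= 4) map_chr(fields, 4) else NA_character_
  )
  bad <- which(!(bed$end > bed$start))
  if (length(bad)) {
    warn(sprintf("dropping %d record(s) with end <= start (lines: %s).",
                 length(bad), paste(head(bad, 5), collapse = ", ")))
    bed <- bed[-bad, ]
  }
  bed <- bed |>
    mutate(peak_id = dplyr::coalesce(peak_id,
                                     sprintf("%s:%d-%d", chrom, start, end))) |>
    arrange(chrom, start, end) |>
    select(peak_id, chrom, start, end)
  bed
}

#' Read a gene table and derive strand-aware promoters
#'
#' Reads a TSV with columns `gene_id`, `chrom`, `strand`, `tss` and attaches
#' promoter intervals: the strand-specific TSS extended 2000 bp upstream,
#' as a 0-based half-open interval. Coordinates supplied 1-based are
#' converted on read via `one_based = TRUE`.
#'
#' @param path Path to the gene TSV (header required).
#' @param one_based Set `TRUE` if the table's TSS coordinates are 1-based;
#'   they are shifted to the internal 0-based convention on read.
#' @param upstream Promoter extent upstream of the TSS in bp (default 2000).
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `tss`,
#'   `promoter_start`, `promoter_end`.
#' @export
read_gene_table <- function(path, one_based = FALSE, upstream = 2000L) {
  genes <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", chrom = "c", strand = "c", tss = "i"))
  if (!all(c("gene_id", "chrom", "strand", "tss") %in% names(genes))) {
    abort("gene table needs columns gene_id, chrom, strand, tss.")
  }
  if (one_based) genes$tss <- genes$tss - 1L
  add_promoters(genes, upstream = upstream)
}

#' Attach promoter intervals to a gene table
#'
#' @param genes Tibble with `gene_id`, `chrom`, `strand` (`"+"`/`"-"`),
#'   `tss` (0-based).
#' @param upstream Upstream extent in bp.
#' @return `genes` with `promoter_start`, `promoter_end` columns appended
#'   (0-based half-open; covers the TSS base plus `upstream` bp upstream of
#'   it, clamped at the chromosome start).
#' @export
add_promoters <- function(genes, upstream = 2000L) {
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'.")
  }
  if (any(genes$tss < 0)) abort("tss must be non-negative (0-based).")
  genes |>
    mutate(
      promoter_start = ifelse(strand == "+",
                              pmax(0L, tss - as.integer(upstream)),
                              tss),
      promoter_end = ifelse(strand == "+", tss + 1L,
                            tss + 1L + as.integer(upstream))
    ) |>
    as_tibble()
}
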