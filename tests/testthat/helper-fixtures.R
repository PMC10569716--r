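# Shared fixtures and independent oracles, built in code at test time.

# Dense toy count object.
toy_counts <- function(m, modality = "rna",
                       cells = paste0("c", seq_len(nrow(m))),
                       genes = paste0("g", seq_len(ncol(m)))) {
  dimnames(m) <- list(cells, genes)
  sc_counts(m, modality)
}

# Brute-force lochNESS oracle: all-pairs distances via stats::dist, ordered
# by (distance, index), then the printed formula. Independent of the
# package's blocked kNN path.
oracle_lochness <- function(coords, labels, k) {
  n <- nrow(coords)
  d2 <- as.matrix(stats::dist(coords))^2
  labels <- factor(labels)
  nm <- table(labels)
  raw <- matrix(NA_real_, n, nlevels(labels),
                dimnames = list(rownames(coords), levels(labels)))
  for (i in seq_len(n)) {
    row <- d2[i, ]
    row[i] <- Inf
    nn <- order(row, seq_len(n))[seq_len(k)]
    cnt <- table(factor(labels[nn], levels = levels(labels)))
    raw[i, ] <- (as.numeric(cnt) / k) / (as.numeric(nm) / n)
  }
  raw[, as.numeric(nm) == 0] <- NA_real_
  raw
}

# Brute-force peak-gene pairing oracle: plain arithmetic over all pairs.
oracle_pairs <- function(peaks, genes, window = 150000) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      gap <- max(0, peaks$start[i] - genes$promoter_end[j],
                 genes$promoter_start[j] - peaks$end[i])
      if (gap > window) next
      tss <- genes$tss[j]
      s <- peaks$start[i]; e <- peaks$end[i]
      genomic <- if (tss >= s && tss < e) 0L
                 else if (tss >= e) (e - 1L) - tss
                 else s - tss
      signed <- if (genes$strand[j] == "+") genomic else -genomic
      out[[length(out) + 1]] <- tibble::tibble(
        gene_id = genes$gene_id[j], peak_id = peaks$peak_id[i],
        signed_distance = as.integer(signed))
    }
  }
  if (!length(out)) {
    return(tibble::tibble(gene_id = character(), peak_id = character(),
                          signed_distance = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), gene_id, peak_id)
}

# Random peak/gene tables on a couple of chromosomes (integer coords).
random_intervals <- function(n_peaks, n_genes, span = 1e6, seed = 1) {
  withr::with_seed(seed, {
    pk_start <- sample.int(span, n_peaks)
    gs <- sample.int(span, n_genes)
    list(
      peaks = tibble::tibble(
        peak_id = paste0("pk", seq_len(n_peaks)),
        chrom = sample(c("chr1", "chr2"), n_peaks, replace = TRUE),
        start = pk_start,
        end = pk_start + sample(50:2000, n_peaks, replace = TRUE)),
      genes = add_promoters(tibble::tibble(
        gene_id = paste0("gn", seq_len(n_genes)),
        chrom = sample(c("chr1", "chr2"), n_genes, replace = TRUE),
        strand = sample(c("+", "-"), n_genes, replace = TRUE),
        tss = gs))
    )
  })
}

# Small label-independent embedding + metadata for lochNESS tests.
null_embedding <- function(n, regions = c("A", "B"), d = 3, seed = 1) {
  withr::with_seed(seed, {
    coords <- matrix(rnorm(n * d), n, d,
                     dimnames = list(sprintf("c%03d", seq_len(n)), NULL))
    meta <- tibble::tibble(cell_id = rownames(coords),
                           region = sample(regions, n, replace = TRUE))
    list(coords = coords, meta = meta)
  })
}

# lochNESS object built directly from a raw matrix (unit test scaffolding).
lochness_from_raw <- function(raw, k = 5) {
  structure(list(cells = rownames(raw), regions = colnames(raw), raw = raw,
                 normalized = NULL, k = k, N = nrow(raw)),
            class = "sc_lochness")
}
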