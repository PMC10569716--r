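embedding_matrix <- function(embedding) {
  if (is.matrix(embedding)) {
    if (is.null(rownames(embedding))) abort("embedding matrix needs cell_id rownames.")
    return(embedding)
  }
  if (!is.data.frame(embedding) || !"cell_id" %in% names(embedding)) {
    abort("embedding must be a matrix with rownames or a tibble with a cell_id column.")
  }
  num <- embedding |> select(-cell_id)
  m <- as.matrix(num)
  if (!is.numeric(m) || ncol(m) < 1) abort("embedding needs numeric coordinate columns.")
  if (any(!is.finite(m))) abort("embedding coordinates must be finite.")
  rownames(m) <- embedding$cell_id
  m
}

# Exact k-nearest neighbours by Euclidean distance, excluding self.
# Ties at equal distance are broken by ascending cell index, so the result
# is deterministic and reproducible by a brute-force all-pairs sort.
knn_indices <- function(coords, k, block = 512L) {
  n <- nrow(coords)
  if (k >= n) abort("`k` must be smaller than the number of cells.")
  norms <- rowSums(coords^2)
  out <- matrix(0L, n, k)
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    idx <- s:e
    d2 <- outer(norms[idx], norms, "+") - 2 * tcrossprod(coords[idx, , drop = FALSE], coords)
    for (r in seq_along(idx)) {
      row <- d2[r, ]
      row[idx[r]] <- Inf
      out[idx[r], ] <- order(row, seq_len(n))[seq_len(k)]
    }
  }
  out
}

#' Per-cell regional neighbourhood enrichment (lochNESS)
#'
#' For every cell `n` and region `m`, computes
#' `lochNESS(n, m) = (#region-m cells among the k nearest neighbours of n / k)
#' / (#region-m cells in the cell type / N)`,
#' where `N` is the number of cells supplied (one cell type at a time).
#' Values of 1 mean the cell's transcriptional neighbourhood mirrors the
#' region's overall share; values above 1 mean local enrichment.
#' Neighbourhoods are exact Euclidean k-nearest neighbours on the embedding,
#' excluding the cell itself, with distance ties broken by ascending cell
#' index for determinism.
#'
#' @param embedding Cell embedding: a tibble with `cell_id` plus numeric
#'   coordinate columns, or a numeric matrix with cell-id rownames.
#' @param meta Per-cell metadata tibble with `cell_id` and the region label
#'   column; must cover every embedded cell.
#' @param k Number of nearest neighbours (`1 <= k < N`).
#' @param region_col Name of the region label column (default `"region"`).
#' @return An object of class `sc_lochness`: list with `cells`, `regions`,
#'   `raw` (cells x regions matrix), `normalized` (`NULL` until
#'   [normalize_lochness()]), `k`, `N`. Regions present as factor levels but
#'   absent from the data yield an `NA` column with a warning.
#' @seealso [normalize_lochness()], [argmax_region()], [lochness_glm()]
#' @examples
#' set.seed(1)
#' emb <- tibble::tibble(cell_id = paste0("c", 1:60),
#'                       e1 = rnorm(60), e2 = rnorm(60))
#' meta <- tibble::tibble(cell_id = emb$cell_id,
#'                        region = sample(c("A", "B"), 60, replace = TRUE))
#' L <- compute_lochness(emb, meta, k = 10)
#' colMeans(L$raw) # ~1 under label-independent embeddings
#' @export
compute_lochness <- function(embedding, meta, k = 25, region_col = "region") {
  coords <- embedding_matrix(embedding)
  n <- nrow(coords)
  if (k < 1 || k >= n) abort("`k` must satisfy 1 <= k < N.")
  lab <- meta[[region_col]][match(rownames(coords), meta$cell_id)]
  if (anyNA(lab)) abort("every embedded cell needs a region label in `meta`.")
  lab <- factor(lab)
  regions <- levels(lab)
  nm <- tabulate(lab, nbins = length(regions))
  if (any(nm == 0)) {
    warn(sprintf("region(s) with no cells yield NA columns: %s",
                 paste(regions[nm == 0], collapse = ", ")))
  }
  nn <- knn_indices(coords, k)
  lab_int <- as.integer(lab)
  # neighbour region counts per cell: k x n lookup then tabulate per row
  counts <- matrix(0L, n, length(regions))
  nb_lab <- matrix(lab_int[nn], nrow = n)
  for (m in seq_along(regions)) {
    counts[, m] <- rowSums(nb_lab == m)
  }
  expected <- nm / n
  raw <- sweep(counts / k, 2, expected, "/")
  raw[, nm == 0] <- NA_real_
  dimnames(raw) <- list(rownames(coords), regions)
  structure(list(cells = rownames(coords), regions = regions, raw = raw,
                 normalized = NULL, k = as.integer(k), N = n),
            class = "sc_lochness")
}

#' @export
print.sc_lochness <- function(x, ...) {
  cat(sprintf("<sc_lochness> %d cells x %d regions (k = %d)%s\n",
              x$N, length(x$regions), x$k,
              if (is.null(x$normalized)) "" else ", normalized"))
  invisible(x)
}

#' Normalize lochNESS over a set of regions of interest
#'
#' Rescales each cell's raw scores over the chosen regions to sum to 1
#' (`lochNESS*`), making scores comparable across that region subset.
#'
#' @param L An [compute_lochness()] result.
#' @param regions_of_interest Character subset of `L$regions`; default all.
#' @return `L` with `normalized` filled (cells x subset matrix, unit row
#'   sums). Cells whose raw scores are all zero over the subset get an `NA`
#'   row with a warning.
#' @export
normalize_lochness <- function(L, regions_of_interest = NULL) {
  stopifnot(inherits(L, "sc_lochness"))
  if (is.null(regions_of_interest)) regions_of_interest <- L$regions
  if (!length(regions_of_interest)) abort("empty region subset.")
  if (!all(regions_of_interest %in% L$regions)) {
    abort("unknown region(s) in `regions_of_interest`.")
  }
  sub <- L$raw[, regions_of_interest, drop = FALSE]
  rs <- rowSums(sub)
  zero <- !is.na(rs) & rs == 0
  if (any(zero)) {
    warn(sprintf("%d cell(s) with all-zero scores over the subset -> NA rows.",
                 sum(zero)))
    rs[zero] <- NA_real_
  }
  L$normalized <- sub / rs
  L
}

#' Dominant region per cell
#'
#' Labels each cell by the region with the largest raw lochNESS. Ties are
#' broken by region order (first wins) and reported via the `tie` flag.
#'
#' @param L An [compute_lochness()] result.
#' @return A tibble with `cell_id`, `region` (`NA` for all-`NA` rows),
#'   `tie`.
#' @export
argmax_region <- function(L) {
  stopifnot(inherits(L, "sc_lochness"))
  raw <- L$raw
  res <- apply(raw, 1, function(row) {
    if (all(is.na(row))) return(c(NA_integer_, NA))
    mx <- max(row, na.rm = TRUE)
    hits <- which(!is.na(row) & row == mx)
    c(hits[1], length(hits) > 1)
  })
  tibble(cell_id = L$cells,
         region = L$regions[res[1, ]],
         tie = as.logical(res[2, ]))
}

#' Region-bias gene regression on lochNESS covariates
#'
#' Fits, per gene, a log-link Poisson regression of UMI counts on the cell's
#' lochNESS scores for each region, with a `log(size factor)` offset and
#' overdispersion-robust (HC0 sandwich) standard errors:
#' `log E[count] = b0 + b1 lochNESS_region1 + ... + log(sf)`.
#' Because the region-share-weighted sum of raw lochNESS scores is exactly 1
#' for every cell, the full design is collinear with the intercept; the last
#' region column (in region order) is dropped, with a message, and
#' coefficients are reported for the remaining regions. Wald p-values are
#' Benjamini-Hochberg adjusted across all gene x region coefficients as one
#' family.
#'
#' @param counts An [sc_counts] RNA object; rows must cover `L$cells`.
#' @param L An [compute_lochness()] result.
#' @param size_factors Optional positive per-cell size factors aligned with
#'   `L$cells`; default `total UMI / median(total UMI)`.
#' @param genes Optional character vector restricting the genes tested.
#' @return A tibble of class `lochness_glm` with columns `gene_id`, `term`
#'   (region name or `"(Intercept)"`), `estimate`, `std_error`, `statistic`,
#'   `p`, `p_adj` (`NA` for the intercept rows). Genes with zero total count
#'   are skipped with `NA` rows.
#' @export
lochness_glm <- function(counts, L, size_factors = NULL, genes = NULL) {
  stopifnot(inherits(counts, "sc_counts"), inherits(L, "sc_lochness"))
  mat <- counts$counts
  if (!all(L$cells %in% rownames(mat))) {
    abort("counts must cover every cell in `L`.")
  }
  mat <- mat[L$cells, , drop = FALSE]
  if (!is.null(genes)) mat <- mat[, genes, drop = FALSE]
  tot <- Matrix::rowSums(mat)
  if (is.null(size_factors)) {
    size_factors <- tot / stats::median(tot)
  }
  if (any(size_factors <= 0)) abort("size factors must be positive.")

  X <- L$raw[, !apply(is.na(L$raw), 2, any), drop = FALSE]
  keep_regions <- colnames(X)
  # drop trailing collinear columns (the weighted row-sum identity makes
  # intercept + all regions rank-deficient by construction)
  repeat {
    d <- cbind(1, X)
    if (qr(d)$rank == ncol(d) || ncol(X) == 1) break
    inform(sprintf("dropping collinear lochNESS column '%s'.",
                   colnames(X)[ncol(X)]))
    X <- X[, -ncol(X), drop = FALSE]
  }
  terms <- c("(Intercept)", colnames(X))
  off <- log(size_factors)
  df0 <- as.data.frame(X)
  fit_one <- function(y) {
    fit <- tryCatch(
      suppressWarnings(stats::glm(y ~ ., data = cbind(data.frame(y = y), df0),
                                  family = poisson(), offset = off)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    est <- coef(fit)
    vc <- sandwich::vcovHC(fit, type = "HC0")
    d <- diag(vc)
    d[d < 0] <- NA_real_  # degenerate near-perfect fits
    se <- sqrt(d)
    z <- est / se
    tibble(term = terms, estimate = unname(est), std_error = unname(se),
           statistic = unname(z), p = 2 * pnorm(-abs(unname(z))))
  }
  res <- map(colnames(mat), function(g) {
    y <- as.numeric(mat[, g])
    if (sum(y) == 0) {
      return(tibble(term = terms, estimate = NA_real_, std_error = NA_real_,
                    statistic = NA_real_, p = NA_real_) |>
               mutate(gene_id = g, .before = 1))
    }
    out <- fit_one(y)
    if (is.null(out)) {
      out <- tibble(term = terms, estimate = NA_real_, std_error = NA_real_,
                    statistic = NA_real_, p = NA_real_)
    }
    mutate(out, gene_id = g, .before = 1)
  }) |> list_rbind()
  # one BH family across all gene x region tests (intercepts excluded)
  is_reg <- res$term != "(Intercept)"
  res$p_adj <- NA_real_
  res$p_adj[is_reg] <- p.adjust(res$p[is_reg], method = "BH")
  structure(res, class = c("lochness_glm", class(res)),
            regions_tested = colnames(X), regions_used = keep_regions)
}
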