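#' Number of metacells for a target occupancy
#'
#' `floor(n_cells / target)`: the metacell count that targets a mean of
#' roughly `target` transcriptomes per metacell (e.g. 2,583,967 cells at a
#' target of 250 gives 10,335 metacells).
#'
#' @param n_cells Number of RNA cells.
#' @param target Target mean cells per metacell (default 250).
#' @return An integer metacell count.
#' @examples
#' choose_n_meta(2583967, 250) # 10335
#' @export
choose_n_meta <- function(n_cells, target = 250) {
  if (target < 1) abort("`target` must be >= 1.")
  if (n_cells < target) abort("`n_cells` must be at least `target`.")
  as.integer(floor(n_cells / target))
}

#' Build metacells by k-means on a cell embedding
#'
#' Clusters cells into `n_meta` metacells with k-means on the (integrated)
#' embedding, using k-means++-style seeding for stability and a fixed RNG
#' seed for determinism. Empty clusters are re-seeded to the most distant
#' unassigned points.
#'
#' @param embedding Tibble with `cell_id` + numeric columns, or a matrix
#'   with cell-id rownames.
#' @param n_meta Number of metacells (`< n_cells`); see [choose_n_meta()].
#' @param seed Integer RNG seed.
#' @return A list of class `sc_metacells`: `cells`, `metacell_id` (integer
#'   in `[0, n_meta)` aligned with `cells`), `n_meta`.
#' @export
build_metacells <- function(embedding, n_meta, seed = 1) {
  coords <- embedding_matrix(embedding)
  n <- nrow(coords)
  if (n_meta >= n) abort("`n_meta` must be smaller than the number of cells.")
  if (n_meta < 1) abort("`n_meta` must be >= 1.")
  withr::with_seed(seed, {
    if (n_meta == 1) {
      assign <- rep(0L, n)
    } else {
      centers <- kmeanspp_centers(coords, n_meta)
      km <- tryCatch(
        suppressWarnings(kmeans(coords, centers = centers, iter.max = 100)),
        error = function(e) suppressWarnings(
          kmeans(coords, centers = n_meta, iter.max = 100, nstart = 5)))
      assign <- km$cluster - 1L
      # re-seed empties (rare with ++ seeding): give each empty id the point
      # farthest from its current center
      empties <- setdiff(seq_len(n_meta) - 1L, unique(assign))
      for (e in empties) {
        far <- which.max(rowSums((coords - km$centers[assign + 1L, ])^2))
        assign[far] <- e
      }
    }
    structure(list(cells = rownames(coords), metacell_id = as.integer(assign),
                   n_meta = as.integer(n_meta)),
              class = "sc_metacells")
  })
}

kmeanspp_centers <- function(coords, k) {
  n <- nrow(coords)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums((coords - coords[rep(idx[1], n), , drop = FALSE])^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      idx[j + 1] <- sample.int(n, 1)
    } else {
      idx[j + 1] <- sample.int(n, 1, prob = d2)
    }
    nd <- rowSums((coords - coords[rep(idx[j + 1], n), , drop = FALSE])^2)
    d2 <- pmin(d2, nd)
  }
  coords[idx, , drop = FALSE]
}

#' @export
print.sc_metacells <- function(x, ...) {
  cat(sprintf("<sc_metacells> %d cells in %d metacells\n",
              length(x$cells), x$n_meta))
  invisible(x)
}

#' Pseudobulk log2(CPM + 1) per metacell
#'
#' Sums counts over each metacell, converts to counts per million within the
#' metacell, and returns `log2(CPM + 1)`.
#'
#' @param counts An [sc_counts] RNA object.
#' @param assign An [build_metacells()] assignment covering the counted
#'   cells.
#' @return A metacells x genes numeric matrix, rows ordered (and named) by
#'   metacell id `0..n_meta-1`. Metacells with zero total count get `NA`
#'   rows with a warning.
#' @export
pseudobulk_log2cpm <- function(counts, assign) {
  stopifnot(inherits(counts, "sc_counts"), inherits(assign, "sc_metacells"))
  mat <- counts$counts
  mc <- assign$metacell_id[match(rownames(mat), assign$cells)]
  if (anyNA(mc)) abort("assignment must cover every counted cell.")
  f <- factor(mc, levels = seq_len(assign$n_meta) - 1L)
  summed <- rowsum(as.matrix(mat), f)  # levels present as rows in order
  full <- matrix(0, assign$n_meta, ncol(mat),
                 dimnames = list(levels(f), colnames(mat)))
  full[rownames(summed), ] <- summed
  tot <- rowSums(full)
  if (any(tot == 0)) {
    warn(sprintf("%d metacell(s) with zero total count -> NA rows.",
                 sum(tot == 0)))
  }
  cpm <- full / ifelse(tot == 0, NA_real_, tot) * 1e6
  log2(cpm + 1)
}

#' Pair peaks with genes within a promoter window
#'
#' Retains a (gene, peak) pair iff the genomic gap between the peak interval
#' and the gene's promoter interval (strand-aware TSS extended 2 kb
#' upstream) is at most `window` bp, inclusive (overlap counts as gap 0).
#' The reported `signed_distance` is the minimal distance from the peak to
#' the TSS point, negative when the peak lies upstream of the gene
#' (strand-aware), 0 when the peak covers the TSS.
#'
#' @param peaks Tibble with `peak_id`, `chrom`, `start`, `end` (0-based
#'   half-open), as from [read_intervals()].
#' @param genes Tibble with `gene_id`, `chrom`, `strand`, `tss`,
#'   `promoter_start`, `promoter_end`, as from [read_gene_table()].
#' @param window Maximum promoter-to-peak gap in bp (default 150000,
#'   inclusive).
#' @return A tibble with `gene_id`, `peak_id`, `signed_distance`, sorted by
#'   gene then peak. Chromosomes present in only one input are skipped with
#'   a warning.
#' @export
pair_peaks_genes <- function(peaks, genes, window = 150000L) {
  shared <- intersect(unique(peaks$chrom), unique(genes$chrom))
  lonely <- setdiff(union(unique(peaks$chrom), unique(genes$chrom)), shared)
  if (length(lonely)) {
    warn(paste("chromosome(s) present in only one input skipped:",
               paste(lonely, collapse = ", ")))
  }
  peaks <- filter(peaks, chrom %in% shared)
  genes <- filter(genes, chrom %in% shared)
  if (!nrow(peaks) || !nrow(genes)) {
    return(tibble(gene_id = character(), peak_id = character(),
                  signed_distance = integer()))
  }
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  pr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$promoter_start + 1L,
                                                genes$promoter_end))
  hits <- GenomicRanges::findOverlaps(pk, pr, maxgap = as.integer(window))
  i <- S4Vectors::queryHits(hits)
  j <- S4Vectors::subjectHits(hits)
  if (!length(i)) {
    return(tibble(gene_id = character(), peak_id = character(),
                  signed_distance = integer()))
  }
  tss <- genes$tss[j]
  s <- peaks$start[i]
  e <- peaks$end[i]
  genomic <- ifelse(tss >= s & tss < e, 0L,
                    ifelse(tss >= e, (e - 1L) - tss, s - tss))
  signed <- ifelse(genes$strand[j] == "+", genomic, -genomic)
  tibble(gene_id = genes$gene_id[j], peak_id = peaks$peak_id[i],
         signed_distance = as.integer(signed)) |>
    arrange(gene_id, peak_id)
}

#' Logistic regression of single-cell peak accessibility on metacell
#' expression
#'
#' Fits, by maximum likelihood, `open ~ log2CPM` where `open` is the binary
#' accessibility of one peak in each ATAC cell and the predictor is the
#' pseudobulk log2CPM of one gene in the cell's metacell. Because cells of a
#' metacell share the predictor value, the fit is computed on
#' metacell-aggregated binomial counts, which gives the identical maximum
#' likelihood estimate and tests. The slope p-value is the likelihood-ratio
#' (deviance) test, which stays informative where the Wald statistic
#' degrades for near-saturating slopes (the Hauck-Donner effect). Constant
#' responses or predictors and quasi-separated fits are reported with reason
#' codes instead of estimates.
#'
#' @param atac_open Binary accessibility vector, one entry per ATAC cell
#'   (aligned with `assign$cells`).
#' @param assign An [build_metacells()] assignment.
#' @param gene_expr Per-metacell log2CPM vector ordered by metacell id
#'   (a column of [pseudobulk_log2cpm()]).
#' @param max_abs_beta Magnitude cap signalling quasi-separation
#'   (default 25): larger fitted slopes are capped and `p` set `NA` with
#'   reason `"separation"`.
#' @return A one-row tibble: `beta`, `p`, `reason` (`NA` when clean).
#' @export
fit_link_logistic <- function(atac_open, assign, gene_expr,
                              max_abs_beta = 25) {
  stopifnot(inherits(assign, "sc_metacells"))
  if (length(atac_open) != length(assign$cells)) {
    abort("`atac_open` must align with the assignment's cells.")
  }
  mc <- assign$metacell_id
  keep <- !is.na(gene_expr[mc + 1L])
  if (!all(keep)) abort("every cell's metacell needs non-missing expression.")
  open_by_mc <- tapply(atac_open, mc, sum)
  n_by_mc <- tapply(rep(1L, length(mc)), mc, sum)
  ids <- as.integer(names(open_by_mc))
  x <- gene_expr[ids + 1L]
  succ <- as.numeric(open_by_mc)
  fail <- as.numeric(n_by_mc) - succ
  if (sum(succ) == 0 || sum(fail) == 0) {
    return(tibble(beta = NA_real_, p = NA_real_, reason = "constant_response"))
  }
  if (length(unique(x)) < 2) {
    return(tibble(beta = NA_real_, p = NA_real_, reason = "constant_predictor"))
  }
  fit <- tryCatch(
    suppressWarnings(glm(cbind(succ, fail) ~ x, family = binomial(),
                         control = list(maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(tibble(beta = NA_real_, p = NA_real_, reason = "fit_failed"))
  }
  b <- unname(coef(fit)[2])
  # quasi-separation: a runaway slope or a perfect fit (zero residual
  # deviance) means the slope is not identified beyond its sign
  separated <- !is.finite(b) || abs(b) > max_abs_beta ||
    fit$deviance < 1e-7
  if (separated) {
    return(tibble(beta = sign(b) * min(abs(b), max_abs_beta), p = NA_real_,
                  reason = "separation"))
  }
  lrt <- stats::pchisq(fit$null.deviance - fit$deviance, df = 1,
                       lower.tail = FALSE)
  tibble(beta = b, p = lrt, reason = NA_character_)
}

#' Fit the metacell logistic regression for a table of peak-gene pairs
#'
#' Runs [fit_link_logistic()] for every pair and Benjamini-Hochberg-adjusts
#' the Wald p-values across all tested pairs as one family.
#'
#' @param atac An ATAC [sc_counts] (binary).
#' @param assign An [build_metacells()] assignment covering the ATAC cells.
#' @param log2cpm A [pseudobulk_log2cpm()] matrix for the RNA side.
#' @param pairs Tibble with `gene_id`, `peak_id` (and optionally
#'   `signed_distance`) as from [pair_peaks_genes()].
#' @return `pairs` with `beta`, `p`, `reason`, `p_adj` appended.
#' @export
fit_peak_gene_links <- function(atac, assign, log2cpm, pairs) {
  stopifnot(inherits(atac, "sc_counts"), atac$modality == "atac")
  mat <- atac$counts[match(assign$cells, rownames(atac$counts)), ,
                     drop = FALSE]
  if (anyNA(rownames(mat))) abort("ATAC matrix must cover assigned cells.")
  res <- map(seq_len(nrow(pairs)), function(i) {
    g <- pairs$gene_id[i]
    pkid <- pairs$peak_id[i]
    if (!g %in% colnames(log2cpm) || !pkid %in% colnames(mat)) {
      return(tibble(beta = NA_real_, p = NA_real_, reason = "unknown_id"))
    }
    fit_link_logistic(as.numeric(mat[, pkid]), assign, log2cpm[, g])
  }) |> list_rbind()
  out <- dplyr::bind_cols(pairs, res)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

#' Combine logistic and external evidence into candidate calls
#'
#' A pair is a candidate cis-regulatory link iff both adjusted p-values are
#' below `alpha`; candidates are classified `"positive"` or `"negative"` by
#' the sign of the logistic coefficient. Pairs lacking external evidence are
#' left `NA` (untestable), not declared non-candidates.
#'
#' @param links Tibble with `beta`, `p_adj` and `external_p_adj` columns
#'   (each stream already BH-adjusted across its tested pairs).
#' @param alpha Significance cutoff (default 0.05).
#' @return `links` with `candidate` (logical) and `direction` columns.
#' @export
combine_evidence <- function(links, alpha = 0.05) {
  need <- c("beta", "p_adj", "external_p_adj")
  if (!all(need %in% names(links))) {
    abort(paste("need columns:", paste(need, collapse = ", ")))
  }
  links |>
    mutate(
      candidate = dplyr::if_else(
        is.na(external_p_adj), NA,
        !is.na(p_adj) & p_adj < alpha & external_p_adj < alpha),
      direction = dplyr::if_else(
        !is.na(candidate) & candidate,
        dplyr::if_else(beta > 0, "positive", "negative"),
        NA_character_))
}

#' Empirical p-values for an external pair score
#'
#' Turns any user-supplied peak-gene pair score into upper-tail empirical
#' p-values against a null score distribution, with BH adjustment across the
#' table; a utility for making external evidence streams comparable to the
#' logistic stream. When no null scores are supplied, the table's own score
#' distribution is used as the reference (a conservative rank-based p).
#'
#' @param pairs Tibble containing the score column.
#' @param score_col Name of the score column (default `"external_score"`).
#' @param null_scores Optional numeric vector of scores under the null
#'   (e.g. scores of permuted pairings).
#' @return `pairs` with `external_p` and `external_p_adj` appended.
#' @export
external_score_pvalues <- function(pairs, score_col = "external_score",
                                   null_scores = NULL) {
  s <- pairs[[score_col]]
  ref <- null_scores %||% s
  p <- vapply(s, function(v) (1 + sum(ref >= v)) / (1 + length(ref)),
              numeric(1))
  pairs |>
    mutate(external_p = p, external_p_adj = p.adjust(p, method = "BH"))
}

# Univariate L2 (ridge) logistic regression by IRLS; intercept unpenalized.
ridge_logistic <- function(x, y, lambda, max_iter = 100, tol = 1e-8) {
  X <- cbind(1, x)
  b <- c(0, 0)
  pen <- diag(c(0, lambda))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    H <- crossprod(X, X * w) + pen
    g <- crossprod(X, y - mu) - pen %*% b
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    b <- b + drop(step)
    if (max(abs(step)) < tol) break
  }
  b
}

#' One-vs-rest differential accessibility marker calling
#'
#' For every peak and cell class, tests accessibility in the class against
#' all other cells: (i) an L2-regularized one-vs-rest logistic regression
#' coefficient of class membership on the peak's accessibility, (ii) the
#' log2 fold change of mean open fraction (class vs rest, pseudocount
#' `1e-9` on both means), and (iii) a Welch t-test with BH adjustment
#' across peaks within each class. A peak is a marker iff the regularized
#' coefficient is positive, the log2 FC is positive, and the adjusted t-test
#' p is below 0.05.
#'
#' @param atac An ATAC [sc_counts] (binary).
#' @param meta Per-cell metadata tibble with `cell_id` and `cell_class`
#'   covering the ATAC cells (or a character vector of classes aligned with
#'   the matrix rows).
#' @param lambda Ridge penalty for the regularized coefficient; default
#'   `1/n_cells` (mirrors an unscaled C = 1 penalty).
#' @param alpha Marker significance cutoff on the adjusted t-test p.
#' @return A tibble with `peak_id`, `cell_class`, `reg_lr_coef`, `log2fc`,
#'   `t_p_adj`, `is_marker`. Classes with fewer than 2 cells are skipped
#'   with a warning.
#' @export
differential_accessibility <- function(atac, meta, lambda = NULL,
                                       alpha = 0.05) {
  stopifnot(inherits(atac, "sc_counts"), atac$modality == "atac")
  mat <- atac$counts
  classes <- if (is.data.frame(meta)) {
    meta$cell_class[match(rownames(mat), meta$cell_id)]
  } else {
    meta
  }
  if (anyNA(classes)) abort("every ATAC cell needs a cell_class label.")
  tab <- table(classes)
  if (length(tab) < 2) abort("need at least 2 cell classes.")
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warn(paste("skipping class(es) with < 2 cells:",
               paste(small, collapse = ", ")))
  }
  use <- setdiff(names(tab), small)
  n <- nrow(mat)
  lambda <- lambda %||% (1 / n)
  eps <- 1e-9
  map(use, function(cl) {
    inside <- classes == cl
    res <- map(colnames(mat), function(pkid) {
      xx <- as.numeric(mat[, pkid])
      m_in <- mean(xx[inside])
      m_out <- mean(xx[!inside])
      coef2 <- ridge_logistic(xx, as.numeric(inside), lambda)[2]
      tp <- tryCatch(stats::t.test(xx[inside], xx[!inside])$p.value,
                     error = function(e) NA_real_)
      tibble(peak_id = pkid, cell_class = cl, reg_lr_coef = coef2,
             log2fc = log2((m_in + eps) / (m_out + eps)), t_p = tp)
    }) |> list_rbind()
    res$t_p_adj <- p.adjust(res$t_p, method = "BH")
    res
  }) |>
    list_rbind() |>
    mutate(is_marker = !is.na(t_p_adj) & reg_lr_coef > 0 & log2fc > 0 &
             t_p_adj < alpha) |>
    select(peak_id, cell_class, reg_lr_coef, log2fc, t_p_adj, is_marker)
}
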