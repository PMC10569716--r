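#' Jensen-Shannon divergence between two probability vectors
#'
#' Computes `JSD(p, q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2`.
#' With base-2 logarithms (the default) the score is bounded in `[0, 1]`:
#' 0 when the distributions coincide, 1 when their supports are disjoint.
#' Terms with `p_i = 0` contribute nothing (`0 * log 0 = 0`).
#'
#' @param p,q Numeric probability vectors of equal length; entries must be
#'   non-negative and each vector must sum to 1 (tolerance `1e-9`).
#' @param base Logarithm base; 2 (default) gives the `[0, 1]` range, use
#'   `exp(1)` for nats.
#' @return A single number in `[0, 1]` (for base 2).
#' @examples
#' jsd(c(0.5, 0.5), c(0.75, 0.25))
#' jsd(c(1, 0), c(0, 1)) # disjoint support -> 1
#' @export
jsd <- function(p, q, base = 2) {
  if (length(p) != length(q)) abort("`p` and `q` must have equal length.")
  if (any(p < 0) || any(q < 0)) abort("probabilities must be non-negative.")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    abort("`p` and `q` must each sum to 1 (tolerance 1e-9).")
  }
  m <- (p + q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * (log(a[i], base = base) - log(m[i], base = base)))
  }
  unname((kl(p) + kl(q)) / 2)
}

#' Build a group x category composition table
#'
#' Cross-tabulates two label columns of a per-cell metadata table into the
#' count matrix used by [regional_specificity()] and
#' [composition_log_ratio()].
#'
#' @param meta Per-cell metadata tibble.
#' @param group,category Column names (strings) holding the grouping label
#'   (e.g. cell subtype) and the category label (e.g. region).
#' @return A list of class `sc_composition` with `counts` (groups x
#'   categories integer matrix), `groups`, and `categories`.
#' @export
composition_table <- function(meta, group, category) {
  g <- factor(meta[[group]])
  c_ <- factor(meta[[category]])
  keep <- !is.na(g) & !is.na(c_)
  counts <- unclass(table(g[keep], c_[keep], dnn = NULL))
  structure(list(counts = counts, groups = rownames(counts),
                 categories = colnames(counts)),
            class = "sc_composition")
}

#' @export
print.sc_composition <- function(x, ...) {
  cat(sprintf("<sc_composition> %d groups x %d categories, %d cells\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

as_composition_counts <- function(comp) {
  if (inherits(comp, "sc_composition")) return(comp$counts)
  if (is.matrix(comp)) return(comp)
  abort("expected an `sc_composition` or a counts matrix.")
}

#' Regional specificity scores (Jensen-Shannon divergence)
#'
#' For each group (cell class or subtype), compares the group's count
#' distribution across categories (brain regions) to the category
#' distribution of the whole dataset pooled, using base-2 Jensen-Shannon
#' divergence. A score of 0 means the group mirrors the global regional
#' make-up; scores near 1 mean the group is confined to regions the rest of
#' the data does not occupy.
#'
#' @param comp An [composition_table()] result (or a groups x categories
#'   count matrix).
#' @param base Log base passed to [jsd()].
#' @return A tibble with columns `group`, `n_cells`, `score`. Groups with
#'   zero total count get `NA` scores with a warning.
#' @export
regional_specificity <- function(comp, base = 2) {
  counts <- as_composition_counts(comp)
  if (ncol(counts) < 2) abort("need at least 2 categories.")
  totals <- rowSums(counts)
  global <- colSums(counts)
  global <- global / sum(global)
  if (any(totals == 0)) {
    warn(sprintf("%d group(s) with zero cells scored NA.", sum(totals == 0)))
  }
  score <- vapply(seq_len(nrow(counts)), function(i) {
    if (totals[i] == 0) return(NA_real_)
    jsd(counts[i, ] / totals[i], global, base = base)
  }, numeric(1))
  tibble(group = rownames(counts), n_cells = as.integer(totals),
         score = score)
}

#' Capped log2 composition enrichment ratios
#'
#' The within-region composition statistic: for subtype `s` and region `r`,
#' `log2( prop(s in r) / mean_r' prop(s in r') )`, capped at `+/- cap`.
#' Proportions are within-region compositions (each region's cells sum
#' to 1). The denominator is by default the unweighted mean of the per-region
#' proportions; set `denominator = "pooled"` to use the pooled overall
#' proportion instead. Subtypes with fewer than `min_cells` cells in total
#' are dropped (display rule). A zero within-region proportion is replaced
#' by half the smallest nonzero proportion observed for that subtype before
#' taking the log; the cap bounds its influence.
#'
#' @param comp A regions x subtypes orientation is not required: supply an
#'   [composition_table()] result with groups = regions, categories =
#'   subtypes, or a count matrix in that orientation.
#' @param cap Cap on the absolute log2 ratio (default 2).
#' @param min_cells Minimum total cells for a subtype to be scored
#'   (default 100).
#' @param denominator `"mean"` (unweighted mean of per-region proportions,
#'   default) or `"pooled"`.
#' @return A tibble with columns `region`, `subtype`, `prop`, `ratio`
#'   (capped log2 ratio). Regions with zero cells yield `NA` rows.
#' @export
composition_log_ratio <- function(comp, cap = 2, min_cells = 100,
                                  denominator = c("mean", "pooled")) {
  denominator <- match.arg(denominator)
  counts <- as_composition_counts(comp)
  keep <- colSums(counts) >= min_cells
  counts <- counts[, keep, drop = FALSE]
  if (!ncol(counts)) abort("no subtype passes `min_cells`.")
  region_tot <- rowSums(counts)
  prop <- counts / ifelse(region_tot == 0, NA_real_, region_tot)
  ref <- switch(denominator,
    mean = colMeans(prop, na.rm = TRUE),
    pooled = colSums(counts) / sum(counts))
  ratio <- prop
  for (j in seq_len(ncol(prop))) {
    pj <- prop[, j]
    nz <- pj[!is.na(pj) & pj > 0]
    floor_j <- if (length(nz)) min(nz) / 2 else NA_real_
    pj[!is.na(pj) & pj == 0] <- floor_j
    ratio[, j] <- pmin(pmax(log2(pj / ref[j]), -cap), cap)
  }
  tibble(
    region = rep(rownames(counts), times = ncol(counts)),
    subtype = rep(colnames(counts), each = nrow(counts)),
    prop = as.vector(prop),
    ratio = as.vector(ratio)
  )
}
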