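#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a lochNESS matrix into a long tibble
#'
#' @param x An `sc_lochness` object.
#' @param normalized Return the normalized (`lochNESS*`) scores instead of
#'   the raw ones (requires [normalize_lochness()] first).
#' @param ... Unused.
#' @return A tibble with `cell_id`, `region`, `score`.
#' @exportS3Method generics::tidy
tidy.sc_lochness <- function(x, normalized = FALSE, ...) {
  m <- if (normalized) {
    if (is.null(x$normalized)) abort("run normalize_lochness() first.")
    x$normalized
  } else {
    x$raw
  }
  tibble(cell_id = rep(rownames(m), times = ncol(m)),
         region = rep(colnames(m), each = nrow(m)),
         score = as.vector(m))
}

#' One-row summary of a lochNESS matrix
#'
#' @param x An `sc_lochness` object.
#' @param ... Unused.
#' @return A tibble with `n_cells`, `n_regions`, `k`, `mean_raw`.
#' @exportS3Method generics::glance
glance.sc_lochness <- function(x, ...) {
  tibble(n_cells = x$N, n_regions = length(x$regions), k = x$k,
         mean_raw = mean(x$raw, na.rm = TRUE))
}

#' Tidy the region-bias regression table
#'
#' The fit table is already tidy (one row per gene x term); this method
#' simply strips the class and optionally drops intercept rows.
#'
#' @param x A [lochness_glm()] result.
#' @param keep_intercept Keep `"(Intercept)"` rows (default `FALSE`).
#' @param ... Unused.
#' @return A tibble with `gene_id`, `term`, `estimate`, `std_error`,
#'   `statistic`, `p`, `p_adj`.
#' @exportS3Method generics::tidy
tidy.lochness_glm <- function(x, keep_intercept = FALSE, ...) {
  out <- as_tibble(x)
  if (!keep_intercept) out <- filter(out, term != "(Intercept)")
  out
}

#' One-row summary of the region-bias regression
#'
#' @param x A [lochness_glm()] result.
#' @param alpha Significance cutoff on the adjusted p (default 0.05).
#' @param ... Unused.
#' @return A tibble with `n_genes`, `n_regions`, `n_tests`,
#'   `n_significant`.
#' @exportS3Method generics::glance
glance.lochness_glm <- function(x, alpha = 0.05, ...) {
  reg <- filter(as_tibble(x), term != "(Intercept)")
  tibble(n_genes = dplyr::n_distinct(reg$gene_id),
         n_regions = dplyr::n_distinct(reg$term),
         n_tests = sum(!is.na(reg$p)),
         n_significant = sum(reg$p_adj < alpha, na.rm = TRUE))
}
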