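#' @importFrom ggplot2 ggplot aes geom_point geom_tile geom_col geom_hline
#'   scale_fill_gradient2 scale_color_viridis_c labs theme_minimal autoplot
#'   facet_wrap coord_flip
NULL

#' @export
ggplot2::autoplot

#' Plot per-cell lochNESS on an embedding
#'
#' Scatter of the first two embedding coordinates coloured by the raw
#' lochNESS score for one region, the usual way regional neighbourhood
#' enrichment is inspected.
#'
#' @param object An `sc_lochness` object.
#' @param embedding The embedding used to compute it (tibble with `cell_id`
#'   + coordinates).
#' @param region Region whose scores to show; default the first.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.sc_lochness <- function(object, embedding, region = NULL, ...) {
  region <- region %||% object$regions[1]
  if (!region %in% object$regions) abort("unknown region.")
  coords <- embedding_matrix(embedding)[object$cells, 1:2, drop = FALSE]
  df <- tibble(x = coords[, 1], y = coords[, 2],
               score = object$raw[, region])
  ggplot(df, aes(x = .data$x, y = .data$y, color = score)) +
    geom_point(size = 0.4) +
    scale_color_viridis_c() +
    labs(title = paste("lochNESS:", region), x = "dim 1", y = "dim 2",
         color = "lochNESS") +
    theme_minimal()
}

#' Heatmap of capped log2 composition enrichment ratios
#'
#' Displays the [composition_log_ratio()] table as a region x subtype
#' heatmap, blue for enrichment and red for depletion, on the capped log2
#' scale.
#'
#' @param ratios A [composition_log_ratio()] tibble.
#' @param cap Cap used (sets the fill limits; default 2).
#' @return A ggplot.
#' @export
plot_composition_ratio <- function(ratios, cap = 2) {
  ggplot(ratios, aes(x = subtype, y = region, fill = ratio)) +
    geom_tile() +
    scale_fill_gradient2(low = "firebrick", mid = "white", high = "steelblue",
                         limits = c(-cap, cap)) +
    labs(x = NULL, y = NULL, fill = "log2 ratio") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Bar plot of regional specificity scores
#'
#' @param spec A [regional_specificity()] tibble.
#' @return A ggplot of groups ordered by score.
#' @export
plot_specificity <- function(spec) {
  spec |>
    filter(!is.na(score)) |>
    mutate(group = stats::reorder(group, score)) |>
    ggplot(aes(x = group, y = score)) +
    geom_col(fill = "grey30") +
    coord_flip() +
    labs(x = NULL, y = "regional specificity (JSD)") +
    theme_minimal()
}

#' Signed distance vs coefficient plot for peak-gene links
#'
#' Scatter of the logistic coefficient against the signed peak-TSS
#' distance, candidates highlighted; the standard diagnostic for
#' cis-regulatory link tables.
#'
#' @param links A [combine_evidence()] tibble with `signed_distance`,
#'   `beta`, `candidate`.
#' @return A ggplot.
#' @export
plot_link_distance <- function(links) {
  ggplot(links, aes(x = signed_distance / 1000, y = beta,
                    color = !is.na(candidate) & candidate)) +
    geom_point(alpha = 0.6, size = 0.8) +
    geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey70",
                                           `TRUE` = "firebrick")) +
    labs(x = "signed distance to TSS (kb)", y = "logistic coefficient",
         color = "candidate") +
    theme_minimal()
}

#' TF activity-sign plot
#'
#' TFs ordered by the correlation between motif accessibility and cognate
#' gene expression; activators positive, repressors negative.
#'
#' @param tf_table A [tf_correlation_table()] tibble.
#' @return A ggplot.
#' @export
plot_tf_activity <- function(tf_table) {
  tf_table |>
    filter(!is.na(r)) |>
    mutate(tf_id = stats::reorder(tf_id, r)) |>
    ggplot(aes(x = tf_id, y = r, fill = classification)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "Pearson r (motif accessibility vs expression)") +
    theme_minimal()
}
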