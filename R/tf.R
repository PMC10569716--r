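#' Correlate TF motif accessibility with TF expression
#'
#' Pearson correlation, across cell class x region subclass groups, between
#' the accessibility of a TF's binding motif and the expression of the
#' cognate gene. Positive correlation classifies the TF as an activator,
#' negative as a repressor; constant vectors give `"undetermined"` rather
#' than a sign claim.
#'
#' @param accessibility,expression Aligned numeric group summaries (>= 3
#'   groups, finite values). Group aggregation is the caller's
#'   responsibility.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A one-row tibble: `r`, `classification` (`"activator"`,
#'   `"repressor"`, or `"undetermined"`), `n_groups`.
#' @examples
#' tf_correlation(c(1, 2, 3, 4), c(2.1, 3.9, 6.2, 8.0)) # activator
#' @export
tf_correlation <- function(accessibility, expression,
                           method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(accessibility) != length(expression)) {
    abort("vectors must be aligned on the same groups.")
  }
  if (length(accessibility) < 3) abort("need at least 3 groups.")
  if (any(!is.finite(accessibility)) || any(!is.finite(expression))) {
    abort("values must be finite.")
  }
  if (sd(accessibility) == 0 || sd(expression) == 0) {
    return(tibble(r = NA_real_, classification = "undetermined",
                  n_groups = length(accessibility)))
  }
  r <- cor(accessibility, expression, method = method)
  tibble(r = r,
         classification = if (r > 0) "activator"
                          else if (r < 0) "repressor"
                          else "undetermined",
         n_groups = length(accessibility))
}

#' TF activity-sign classification for a panel of TFs
#'
#' Applies [tf_correlation()] to every TF in a long table of per-group motif
#' accessibility and expression summaries.
#'
#' @param profiles Long tibble with columns `tf_id`, `group`,
#'   `accessibility`, `expression`.
#' @param method Correlation method, as in [tf_correlation()].
#' @return A tibble with one row per TF: `tf_id`, `r`, `classification`,
#'   `n_groups`.
#' @export
tf_correlation_table <- function(profiles,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  need <- c("tf_id", "group", "accessibility", "expression")
  if (!all(need %in% names(profiles))) {
    abort(paste("need columns:", paste(need, collapse = ", ")))
  }
  profiles |>
    dplyr::group_split(tf_id) |>
    map(function(d) {
      tf_correlation(d$accessibility, d$expression, method = method) |>
        mutate(tf_id = d$tf_id[1], .before = 1)
    }) |>
    list_rbind()
}
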