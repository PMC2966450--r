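#' Plot a tolerance curve
#'
#' Shows how far a screener with a given tolerance threshold gets: recall at
#' the stopping point (left panel) and the rank at which the threshold was
#' violated (right panel), both as functions of the threshold.
#'
#' @param object A [tolerance_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tolerance_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(
      object,
      `recall at stop` = .data$recall_at_stop,
      `violating rank` = as.numeric(.data$violating_rank)
    ),
    cols = c("recall at stop", "violating rank"),
    names_to = "panel", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tau, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(
      x = "tolerance threshold (consecutive non-relevant items)",
      y = NULL,
      title = "Tolerance-threshold stopping behavior"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the score profile of a ranked list
#'
#' @param object A `ranked_list` tibble.
#' @param relevant Optional character vector of relevant ids to highlight.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ranked_list <- function(object, relevant = NULL, ...) {
  df <- dplyr::mutate(
    as_tibble(object),
    relevant = if (is.null(relevant)) NA else .data$doc_id %in% relevant
  )
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$score))
  if (is.null(relevant)) {
    gg <- gg + ggplot2::geom_line()
  } else {
    gg <- gg +
      ggplot2::geom_line(color = "grey60") +
      ggplot2::geom_point(
        data = dplyr::filter(df, .data$relevant),
        color = "firebrick", size = 1.5
      )
  }
  gg +
    ggplot2::labs(x = "rank", y = "BM25 score", title = "Ranked retrieval run") +
    ggplot2::theme_minimal()
}

#' Precision-recall curve over a ranked list
#'
#' Computes interpolated-free precision and recall after each rank and plots
#' the trajectory, mirroring the standard way ranked systematic-review runs
#' are inspected.
#'
#' @param ranked Ranked doc ids or a `ranked_list`.
#' @param relevant Character vector of relevant doc ids.
#' @return A ggplot object; the underlying tibble is attached as attribute
#'   `"data"`.
#' @export
plot_precision_recall <- function(ranked, relevant) {
  ids <- ranked_ids(ranked)
  if (length(relevant) == 0) {
    abort_boolrank("relevant set must be non-empty", "boolrank_eval_error")
  }
  hits <- cumsum(ids %in% relevant)
  df <- tibble(
    rank = seq_along(ids),
    precision = hits / seq_along(ids),
    recall = hits / length(relevant)
  )
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "recall", y = "precision", title = "Recall versus precision") +
    ggplot2::theme_minimal()
  attr(gg, "data") <- df
  gg
}
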