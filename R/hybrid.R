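#' Hybrid Boolean-then-ranked retrieval
#'
#' The combined system uses a (by default simplified) Boolean strategy to
#' bound the candidate set — inheriting the Boolean search's recall at full
#' depth — and then orders that set by BM25 similarity to the topic's TRC
#' query. Documents in the Boolean set that score zero are not dropped: they
#' are appended at the tail in document-id order, so the output is always a
#' permutation of the Boolean result set and reviewers who exhaust the list
#' see exactly what the Boolean search returned.
#'
#' @param strategy A [parse_strategy()] result.
#' @param topic A [review_topic()] carrying TRC fields.
#' @param index A [build_index()] result.
#' @param thesaurus Optional [mesh_thesaurus()] (needed for `exp` lines).
#' @param simplify Use the simplified strategy to bound the set (default
#'   `TRUE`); set `FALSE` to rank the raw strategy's output.
#' @param config A [simplify_config()].
#' @param scheme Ranked-query scheme used for ordering (default `"TRC"`).
#' @return A `ranked_list` tibble (`doc_id`, `score`, `rank`) whose doc-id
#'   set equals the Boolean result set; empty (with a warning) when the
#'   Boolean set is empty.
#' @export
hybrid_search <- function(strategy, topic, index, thesaurus = NULL,
                          simplify = TRUE, config = simplify_config(),
                          scheme = "TRC") {
  stopifnot(inherits(strategy, "search_strategy"), inherits(topic, "review_topic"))
  bool_strategy <- if (simplify) simplify_strategy(strategy, config) else strategy
  boolean_set <- result_set(evaluate_strategy(bool_strategy, index, thesaurus))
  if (length(boolean_set) == 0) {
    warn("Boolean result set is empty; hybrid ranking has nothing to order",
         class = "boolrank_empty_result")
    out <- tibble(doc_id = character(), score = numeric(), rank = integer())
    class(out) <- c("ranked_list", class(out))
    return(out)
  }
  query <- build_query(topic, scheme)
  scores <- bm25_all_scores(query, index)
  scores <- scores[boolean_set]
  scores[is.na(scores)] <- 0
  names(scores) <- boolean_set
  ord <- order(-scores, doc_id_rank(boolean_set), method = "radix")
  out <- tibble(
    doc_id = boolean_set[ord],
    score = unname(scores[ord]),
    rank = seq_along(boolean_set)
  )
  attr(out, "query") <- list(
    topic_id = topic$topic_id, scheme = scheme, expansion = "none",
    system = if (simplify) "hybrid_simplified" else "hybrid_raw"
  )
  class(out) <- c("ranked_list", class(out))
  out
}
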