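#' Read and write ranked runs in TREC format
#'
#' One line per retrieved document:
#' `topic_id Q0 doc_id rank score run_tag`.
#'
#' @param ranked A `ranked_list` tibble (or any tibble with `doc_id`,
#'   `score`, `rank`).
#' @param topic_id Topic identifier for the run lines.
#' @param run_tag Run tag naming the system that produced the list.
#' @param path Optional output file path.
#' @return `write_trec_run()` returns the lines invisibly; `read_trec_run()`
#'   a tibble `topic_id`, `doc_id`, `rank`, `score`, `run_tag` ordered by
#'   rank.
#' @export
write_trec_run <- function(ranked, topic_id = NULL, run_tag = "boolrank", path = NULL) {
  q <- attr(ranked, "query") %||% list()
  topic_id <- topic_id %||% q$topic_id %||% "topic"
  lines <- sprintf(
    "%s Q0 %s %d %.6f %s",
    topic_id, ranked$doc_id, ranked$rank, ranked$score, run_tag
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' @rdname write_trec_run
#' @param x File path or character vector of run lines.
#' @export
read_trec_run <- function(x) {
  lines <- read_input_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(parts, length, integer(1)) != 6)
  if (length(bad) > 0) {
    abort_boolrank(sprintf("malformed run line %d", bad[1]), "boolrank_format_error")
  }
  tibble(
    topic_id = vapply(parts, `[`, character(1), 1),
    doc_id = vapply(parts, `[`, character(1), 3),
    rank = as.integer(vapply(parts, `[`, character(1), 4)),
    score = as.numeric(vapply(parts, `[`, character(1), 5)),
    run_tag = vapply(parts, `[`, character(1), 6)
  ) |>
    dplyr::arrange(.data$topic_id, .data$rank)
}
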