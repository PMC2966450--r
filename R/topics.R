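#' Review topics and tiered relevance judgments
#'
#' A review topic carries the structured text a systematic review publishes
#' before searching starts — the title, the detailed research questions and
#' the inclusion criteria — plus, optionally, the published Boolean search
#' strategy. These fields are the sources for the ranked query schemes
#' (title-only, title+research questions, title+questions+criteria, and the
#' Boolean-derived bag of words).
#'
#' Judgments are tiered: tier 0 holds documents retrieved by the original
#' strategy, tier 1 those kept after title/abstract screening, and tier 2 the
#' studies included in the final review. Tier 2 must be a subset of tier 1;
#' tier 1 is usually a subset of tier 0 but published counts sometimes violate
#' that (reviewers find documents outside the search), so evaluation code
#' never assumes it.
#'
#' @param topic_id Identifier string.
#' @param title Review title (non-empty).
#' @param research_questions,inclusion_criteria Free text (may be empty).
#' @param boolean_strategy Optional [parse_strategy()] result or strategy text.
#' @return `review_topic()` returns a `review_topic` list; `tier_judgments()`
#'   a `tier_judgments` list.
#' @export
review_topic <- function(topic_id,
                         title,
                         research_questions = "",
                         inclusion_criteria = "",
                         boolean_strategy = NULL) {
  if (!nzchar(trimws(title))) {
    abort_boolrank("topic title must be non-empty", "boolrank_format_error")
  }
  if (is.character(boolean_strategy)) {
    boolean_strategy <- parse_strategy(boolean_strategy)
  }
  structure(
    list(
      topic_id = as.character(topic_id),
      title = title,
      research_questions = research_questions,
      inclusion_criteria = inclusion_criteria,
      boolean_strategy = boolean_strategy
    ),
    class = "review_topic"
  )
}

#' @export
print.review_topic <- function(x, ...) {
  cat("<review_topic ", x$topic_id, "> ", x$title, "\n", sep = "")
  invisible(x)
}

#' @rdname review_topic
#' @param tier0,tier1,tier2 Character vectors of doc ids.
#' @export
tier_judgments <- function(topic_id, tier0, tier1, tier2) {
  tier0 <- unique(as.character(tier0))
  tier1 <- unique(as.character(tier1))
  tier2 <- unique(as.character(tier2))
  if (!all(tier2 %in% tier1)) {
    abort_boolrank(
      "tier 2 judgments must be a subset of tier 1",
      "boolrank_format_error"
    )
  }
  structure(
    list(
      topic_id = as.character(topic_id),
      tier0 = order_doc_ids(tier0),
      tier1 = order_doc_ids(tier1),
      tier2 = order_doc_ids(tier2)
    ),
    class = "tier_judgments"
  )
}

#' @export
print.tier_judgments <- function(x, ...) {
  cat(
    "<tier_judgments ", x$topic_id, "> tier0=", length(x$tier0),
    " tier1=", length(x$tier1), " tier2=", length(x$tier2), "\n",
    sep = ""
  )
  invisible(x)
}

# Select the judged-relevant set for a target tier (0, 1 or 2).
judged_set <- function(judgments, tier) {
  stopifnot(inherits(judgments, "tier_judgments"), tier %in% 0:2)
  judgments[[paste0("tier", tier)]]
}

#' @exportS3Method generics::tidy
tidy.tier_judgments <- function(x, ...) {
  tibble(
    doc_id = x$tier0,
    tier = 0L
  ) |>
    dplyr::bind_rows(
      tibble(doc_id = x$tier1, tier = 1L),
      tibble(doc_id = x$tier2, tier = 2L)
    ) |>
    dplyr::group_by(.data$doc_id) |>
    dplyr::summarise(highest_tier = max(.data$tier), .groups = "drop") |>
    dplyr::arrange(match(.data$doc_id, order_doc_ids(.data$doc_id)))
}

# ---- JSON I/O --------------------------------------------------------------

#' Read and write topics and judgments as JSON
#'
#' @param x Object to write (a `review_topic` or `tier_judgments`) or, for
#'   readers, a file path or JSON string.
#' @param path Optional output file path.
#' @return Readers return the reconstructed object; writers return the JSON
#'   text invisibly.
#' @export
write_topic_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "review_topic"))
  obj <- list(
    topic_id = x$topic_id,
    title = x$title,
    research_questions = x$research_questions,
    inclusion_criteria = x$inclusion_criteria,
    boolean_strategy = if (!is.null(x$boolean_strategy)) {
      format_strategy(x$boolean_strategy)
    }
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (!is.null(path)) writeLines(json, path)
  invisible(as.character(json))
}

#' @rdname write_topic_json
#' @export
read_topic_json <- function(x) {
  obj <- read_json_payload(x)
  review_topic(
    topic_id = obj$topic_id,
    title = obj$title,
    research_questions = obj$research_questions %||% "",
    inclusion_criteria = obj$inclusion_criteria %||% "",
    boolean_strategy = obj$boolean_strategy
  )
}

#' @rdname write_topic_json
#' @export
write_judgments_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "tier_judgments"))
  obj <- list(
    topic_id = x$topic_id,
    tier0 = as.list(x$tier0),
    tier1 = as.list(x$tier1),
    tier2 = as.list(x$tier2)
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) writeLines(json, path)
  invisible(as.character(json))
}

#' @rdname write_topic_json
#' @export
read_judgments_json <- function(x) {
  obj <- read_json_payload(x)
  tier_judgments(
    obj$topic_id,
    as.character(unlist(obj$tier0)),
    as.character(unlist(obj$tier1)),
    as.character(unlist(obj$tier2))
  )
}

read_json_payload <- function(x) {
  txt <- if (length(x) == 1 && !grepl("[{\\[]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else {
    paste(x, collapse = "\n")
  }
  jsonlite::fromJSON(txt, simplifyVector = FALSE)
}

# ---- TREC qrels ------------------------------------------------------------

#' Export and import judgments in TREC qrels format
#'
#' One line per judged document: `topic 0 doc_id rel`, where `rel` is the
#' highest tier the document reaches plus one (tier-0-only documents get 1,
#' tier-1 documents 2, tier-2 documents 3).
#'
#' @param judgments A [tier_judgments()] object.
#' @param path Optional output file path.
#' @return `write_qrels()` returns the lines invisibly; `read_qrels()` a
#'   `tier_judgments` object.
#' @export
write_qrels <- function(judgments, path = NULL) {
  stopifnot(inherits(judgments, "tier_judgments"))
  td <- tidy(judgments)
  lines <- sprintf("%s 0 %s %d", judgments$topic_id, td$doc_id, td$highest_tier + 1L)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' @rdname write_qrels
#' @param x File path or character vector of qrels lines.
#' @export
read_qrels <- function(x) {
  lines <- read_input_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort_boolrank("empty qrels input", "boolrank_format_error")
  }
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(parts, length, integer(1)) != 4)
  if (length(bad) > 0) {
    abort_boolrank(
      sprintf("malformed qrels line %d", bad[1]),
      "boolrank_format_error"
    )
  }
  topic <- parts[[1]][1]
  doc <- vapply(parts, `[`, character(1), 3)
  rel <- as.integer(vapply(parts, `[`, character(1), 4))
  tier_judgments(
    topic,
    tier0 = doc[rel >= 1],
    tier1 = doc[rel >= 2],
    tier2 = doc[rel >= 3]
  )
}
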