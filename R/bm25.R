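#' Build a ranked (bag-of-words) query from a review topic
#'
#' Four formulation schemes, in increasing order of information:
#'
#' * `"T"` — tokens of the review title only.
#' * `"TR"` — title plus the detailed research questions.
#' * `"TRC"` — title, research questions, plus inclusion criteria.
#' * `"B"` — every content string of the topic's Boolean strategy (terms,
#'   phrases and MeSH heading names) with operators, line numbers, field
#'   codes and truncation markers stripped (stems kept); `limit` clauses and
#'   entry-date filters contribute nothing.
#'
#' The query is an unstructured bag of words: no order, no operators. No
#' stopword removal is applied by default (set `stoplist` to a character
#' vector to enable it).
#'
#' @param topic A [review_topic()].
#' @param scheme `"T"`, `"TR"`, `"TRC"` or `"B"`.
#' @param stoplist Optional character vector of tokens to drop.
#' @return A `ranked_query`: tokens with field tags (`"any"` until re-tagged
#'   with [tag_tokens()]), plus the token sequences the tokens came from
#'   (used by [expand_query_mesh()] to form candidate phrases).
#' @export
build_query <- function(topic, scheme = c("TRC", "T", "TR", "B"), stoplist = NULL) {
  stopifnot(inherits(topic, "review_topic"))
  scheme <- match.arg(scheme)
  segments <- switch(
    scheme,
    T = list(tokenize(topic$title)),
    TR = list(tokenize(topic$title), tokenize(topic$research_questions)),
    TRC = list(
      tokenize(topic$title),
      tokenize(topic$research_questions),
      tokenize(topic$inclusion_criteria)
    ),
    B = {
      if (is.null(topic$boolean_strategy)) {
        abort_boolrank(
          "scheme B requires the topic to carry a Boolean strategy",
          "boolrank_format_error"
        )
      }
      lapply(strategy_content_strings(topic$boolean_strategy), tokenize)
    }
  )
  tokens <- unlist(segments)
  if (!is.null(stoplist)) {
    stoplist <- tolower(stoplist)
    tokens <- tokens[!(tokens %in% stoplist)]
    segments <- lapply(segments, function(s) s[!(s %in% stoplist)])
  }
  if (length(tokens) == 0) {
    abort_boolrank("query has no tokens", "boolrank_empty_query")
  }
  structure(
    list(
      terms = tibble(token = tokens, tag = "any"),
      token_seq = segments,
      scheme = scheme,
      expansion = "none",
      topic_id = topic$topic_id
    ),
    class = "ranked_query"
  )
}

#' @export
print.ranked_query <- function(x, ...) {
  cat(
    "<ranked_query ", x$topic_id, "> scheme=", x$scheme,
    " expansion=", x$expansion, " tokens=", nrow(x$terms), "\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ranked_query <- function(x, ...) x$terms

# Content strings of a strategy AST: term stems, phrase surfaces, heading
# names; operators, references, limits and date filters are dropped.
strategy_content_strings <- function(strategy) {
  out <- character()
  walk <- function(node) {
    switch(
      node$type,
      term = {
        if (!("ed" %in% resolve_fields(node$fields))) out <<- c(out, node$pattern)
      },
      phrase = out <<- c(out, paste(
        vapply(node$slots, function(s) s$pattern, character(1)),
        collapse = " "
      )),
      mesh = out <<- c(out, node$name),
      adj = ,
      not = {
        walk(node$lhs); walk(node$rhs)
      },
      and = ,
      or = for (a in node$args) walk(a),
      invisible(NULL)
    )
  }
  for (l in strategy$lines) walk(l$node)
  out
}

#' Re-tag query tokens for fielded (metadata-aware) ranking
#'
#' @param query A `ranked_query`.
#' @param metadata,text Character vectors of tokens to tag as
#'   metadata-matching or text-matching; everything else keeps tag `"any"`.
#' @return The re-tagged `ranked_query`.
#' @export
tag_tokens <- function(query, metadata = character(), text = character()) {
  stopifnot(inherits(query, "ranked_query"))
  query$terms$tag <- ifelse(
    query$terms$token %in% tolower(metadata), "metadata",
    ifelse(query$terms$token %in% tolower(text), "text", query$terms$tag)
  )
  query
}

# ---- Okapi BM25 ------------------------------------------------------------

# Named-vector addition preserving all names.
nv_add <- function(a, b) {
  if (length(a) == 0) return(b)
  if (length(b) == 0) return(a)
  keys <- union(names(a), names(b))
  av <- a[keys]; av[is.na(av)] <- 0
  bv <- b[keys]; bv[is.na(bv)] <- 0
  setNames(as.numeric(av) + as.numeric(bv), keys)
}

tf_from_postings <- function(index, field, token) {
  p <- index$postings[[field]][[token]]
  if (is.null(p)) return(setNames(numeric(), character()))
  vapply(p, length, numeric(1))
}

# tf vector (doc -> tf) of a token in a named scope, plus the matching
# document-length vector and its average.
scope_stats <- function(index, token, scope) {
  switch(
    scope,
    text = list(
      tf = nv_add(
        tf_from_postings(index, "title", token),
        tf_from_postings(index, "abstract", token)
      ),
      len = index$doc_len$text,
      avg = index$avg_len$text
    ),
    metadata = list(
      tf = nv_add(
        as.numeric_named(tf_vec(index$mesh_tf, token)),
        as.numeric_named(tf_vec(index$pubtype_token_tf, token))
      ),
      len = index$doc_len$metadata,
      avg = index$avg_len$metadata
    ),
    any = list(
      tf = nv_add(
        nv_add(
          tf_from_postings(index, "title", token),
          tf_from_postings(index, "abstract", token)
        ),
        nv_add(
          as.numeric_named(tf_vec(index$mesh_tf, token)),
          as.numeric_named(tf_vec(index$pubtype_token_tf, token))
        )
      ),
      len = index$doc_len$text + index$doc_len$metadata,
      avg = index$avg_len$text + index$avg_len$metadata
    ),
    folded = {
      tf <- tf_from_postings(index, "folded", token)
      w <- unname(index$weight_map["metadata"] %||% 1)
      meta <- as.numeric_named(tf_vec(index$folded_meta_tf, token))
      list(
        tf = nv_add(tf, meta * (w - 1)),
        len = index$doc_len$folded,
        avg = index$avg_len$folded
      )
    },
    abort_boolrank(paste0("unknown scoring scope ", scope), "boolrank_eval_error")
  )
}

as.numeric_named <- function(x) setNames(as.numeric(x), names(x))

#' Score documents with Okapi BM25
#'
#' For a query `q` and document `d`, the score is
#' \deqn{\sum_{t \in q} \ln\!\Big(\frac{N - df_t + 0.5}{df_t + 0.5} + 1\Big)
#'       \cdot \frac{tf_{t,d}\,(k_1 + 1)}{tf_{t,d} + k_1\,(1 - b + b\,|d|/avgdl)}}
#' summed over *distinct* query tokens (repeating a token does not change the
#' score). The `+1` inside the logarithm keeps the idf non-negative for very
#' common terms. Defaults `k1 = 1.2`, `b = 0.75`.
#'
#' Two metadata treatments are supported. `method = "A"` (requires a
#' `separate_fields` index) scores metadata-tagged tokens against the MeSH
#' and publication-type fields only, text-tagged tokens against
#' title+abstract, and untagged tokens against everything.
#' `method = "B_folded"` (requires a `folded` index) scores every token
#' against the folded stream, with metadata-origin occurrences weighted by
#' the index's `weight_map`.
#'
#' @param query A `ranked_query` (see [build_query()]).
#' @param doc_id Document identifier (must be indexed).
#' @param index A [build_index()] result.
#' @param method `"A"` or `"B_folded"`; defaults to the method matching the
#'   index mode.
#' @param k1,b BM25 constants.
#' @return `bm25_score()` a single non-negative number; `rank_bm25()` a
#'   tibble `doc_id`, `score`, `rank` sorted by decreasing score with ties
#'   broken by ascending document id, restricted to documents matching at
#'   least one query token, truncated to `cutoff`.
#' @export
bm25_score <- function(query, doc_id, index, method = NULL, k1 = 1.2, b = 0.75) {
  scores <- bm25_all_scores(query, index, method, k1, b)
  if (!(doc_id %in% index$doc_ids)) {
    abort_boolrank(paste0("document not indexed: ", doc_id), "boolrank_eval_error")
  }
  out <- unname(scores[doc_id])
  if (is.na(out)) 0 else out
}

bm25_all_scores <- function(query, index, method = NULL, k1 = 1.2, b = 0.75) {
  stopifnot(inherits(query, "ranked_query"), inherits(index, "citation_index"))
  if (nrow(query$terms) == 0) {
    abort_boolrank("empty query", "boolrank_empty_query")
  }
  method <- method %||% if (index$mode == "folded") "B_folded" else "A"
  if (method == "B_folded" && index$mode != "folded") {
    abort_boolrank(
      "method B_folded requires an index built with mode = 'folded'",
      "boolrank_eval_error"
    )
  }
  if (method == "A" && index$mode != "separate_fields") {
    abort_boolrank(
      "method A requires an index built with mode = 'separate_fields'",
      "boolrank_eval_error"
    )
  }
  n <- index$n_docs
  scores <- setNames(numeric(n), names(index$doc_len$text))
  distinct <- dplyr::distinct(query$terms, .data$token, .data$tag)
  for (i in seq_len(nrow(distinct))) {
    token <- distinct$token[i]
    scope <- if (method == "B_folded") {
      "folded"
    } else {
      switch(distinct$tag[i], metadata = "metadata", text = "text", "any")
    }
    st <- scope_stats(index, token, scope)
    if (length(st$tf) == 0) next
    df <- length(st$tf)
    idf <- log((n - df + 0.5) / (df + 0.5) + 1)
    docs <- names(st$tf)
    len <- st$len[docs]
    denom_norm <- 1 - b + b * (if (st$avg > 0) len / st$avg else 1)
    contrib <- idf * st$tf * (k1 + 1) / (st$tf + k1 * denom_norm)
    scores[docs] <- scores[docs] + contrib
  }
  scores
}

#' @rdname bm25_score
#' @param cutoff Maximum list depth (`Inf` for all matching documents).
#' @export
rank_bm25 <- function(query, index, method = NULL, cutoff = Inf,
                      k1 = 1.2, b = 0.75) {
  scores <- bm25_all_scores(query, index, method, k1, b)
  scores <- scores[scores > 0]
  if (length(scores) == 0) {
    out <- tibble(doc_id = character(), score = numeric(), rank = integer())
  } else {
    ids <- names(scores)
    ord <- order(-scores, doc_id_rank(ids), method = "radix")
    ids <- ids[ord]
    sc <- unname(scores[ord])
    k <- min(length(ids), cutoff)
    out <- tibble(
      doc_id = ids[seq_len(k)],
      score = sc[seq_len(k)],
      rank = seq_len(k)
    )
  }
  attr(out, "query") <- list(
    topic_id = query$topic_id, scheme = query$scheme, expansion = query$expansion
  )
  class(out) <- c("ranked_list", class(out))
  out
}

#' @exportS3Method generics::glance
glance.ranked_list <- function(x, ...) {
  q <- attr(x, "query") %||% list()
  tibble(
    topic_id = q$topic_id %||% NA_character_,
    scheme = q$scheme %||% NA_character_,
    expansion = q$expansion %||% NA_character_,
    depth = nrow(x),
    max_score = if (nrow(x) > 0) max(x$score) else NA_real_
  )
}

# ---- MeSH query expansion --------------------------------------------------

#' Expand a ranked query with thesaurus terms
#'
#' Candidate phrases from the query (by default every unigram and contiguous
#' bigram/trigram within each source segment; supply `matcher` to plug in a
#' different phrase extractor, e.g. noun phrases from a POS tagger) are
#' looked up in the thesaurus by exact phrase match against descriptor names
#' and entry terms. Each hit contributes, per variant:
#'
#' * `"v1"` — the descriptor's qualifiers (sub-headings);
#' * `"v2"` — qualifiers plus concept (entry) terms;
#' * `"v3"` — qualifiers, concept terms, abbreviations and supplementary
#'   concept terms.
#'
#' Contributed phrases are tokenized with hyphens as separators (a compound
#' entry term such as `"electro-acupuncture"` contributes its constituent
#' words) and appended to the bag; original tokens are always retained. A
#' query with no thesaurus match is returned unchanged.
#'
#' @param query A `ranked_query`.
#' @param thesaurus A [mesh_thesaurus()].
#' @param variant `"v1"`, `"v2"` or `"v3"`.
#' @param matcher Optional function taking the query and returning candidate
#'   phrases (character vector).
#' @return The expanded `ranked_query`.
#' @export
expand_query_mesh <- function(query, thesaurus,
                              variant = c("v1", "v2", "v3"),
                              matcher = NULL) {
  stopifnot(inherits(query, "ranked_query"), inherits(thesaurus, "mesh_thesaurus"))
  variant <- match.arg(variant)
  matcher <- matcher %||% default_phrase_matcher
  candidates <- unique(matcher(query))
  phrase_map <- mesh_phrase_map(thesaurus)
  added <- character()
  for (cand in candidates) {
    key <- phrase_map[[normalize_phrase(cand)]]
    if (is.null(key)) next
    node <- thesaurus$nodes[[key]]
    phrases <- node$qualifiers
    if (variant %in% c("v2", "v3")) phrases <- c(phrases, node$entry_terms)
    if (variant == "v3") {
      phrases <- c(phrases, node$abbreviations, node$supplementary_terms)
    }
    added <- c(added, unlist(lapply(phrases, tokenize, split_hyphens = TRUE)))
  }
  if (length(added) > 0) {
    query$terms <- dplyr::bind_rows(
      query$terms,
      tibble(token = added, tag = "any")
    )
    query$token_seq <- c(query$token_seq, list(added))
  }
  query$expansion <- variant
  query
}

default_phrase_matcher <- function(query) {
  out <- character()
  for (seg in query$token_seq) {
    n <- length(seg)
    if (n == 0) next
    out <- c(out, seg)
    if (n >= 2) out <- c(out, vapply(seq_len(n - 1), function(i) {
      paste(seg[i:(i + 1)], collapse = " ")
    }, character(1)))
    if (n >= 3) out <- c(out, vapply(seq_len(n - 2), function(i) {
      paste(seg[i:(i + 2)], collapse = " ")
    }, character(1)))
  }
  out
}
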