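#' Build a field-aware inverted index over a citation corpus
#'
#' The index stores positional postings for the running-text streams (title,
#' abstract, and in folded mode a combined text stream), term-frequency maps
#' for MeSH and publication-type tokens, a verbatim-heading sub-index for
#' exact descriptor lookup (used by `/`, `exp`, `*` and `.sh.`), qualifier
#' tokens for `.fs.`, plus language and entry-date columns. It also carries
#' the collection statistics BM25 consumes: document count, per-term document
#' frequency, per-field document lengths and average lengths.
#'
#' Two indexing modes mirror the two metadata treatments studied for ranked
#' retrieval: with `mode = "separate_fields"` metadata (MeSH, publication
#' types) is only reachable through its own fields; with `mode = "folded"`
#' metadata tokens are additionally appended to a freely searchable text
#' stream, so untagged query terms can match them, with a configurable weight
#' multiplier on metadata-origin occurrences.
#'
#' @param corpus A corpus tibble (see [citation_corpus()]).
#' @param mode `"separate_fields"` or `"folded"`.
#' @param weight_map Named positive numeric, currently `c(metadata = w)`:
#'   multiplier applied to metadata-origin term frequencies in folded-mode
#'   ranking.
#' @return An object of class `citation_index`.
#' @export
build_index <- function(corpus,
                        mode = c("separate_fields", "folded"),
                        weight_map = c(metadata = 2)) {
  mode <- match.arg(mode)
  corpus <- validate_corpus(corpus)
  if (any(weight_map <= 0)) {
    abort_boolrank("weight_map entries must be strictly positive", "boolrank_format_error")
  }
  n <- nrow(corpus)
  doc_ids <- order_doc_ids(corpus$doc_id)

  post <- list(
    title = new.env(parent = emptyenv()),
    abstract = new.env(parent = emptyenv())
  )
  if (mode == "folded") post$folded <- new.env(parent = emptyenv())
  tf_envs <- list(
    mesh = new.env(parent = emptyenv()),
    qualifier = new.env(parent = emptyenv()),
    pubtype_token = new.env(parent = emptyenv()),
    folded_meta = new.env(parent = emptyenv())
  )
  heading_docs <- new.env(parent = emptyenv())
  heading_major <- new.env(parent = emptyenv())
  heading_token <- new.env(parent = emptyenv())
  pubtype_docs <- new.env(parent = emptyenv())

  doc_len <- list(
    title = setNames(integer(n), corpus$doc_id),
    abstract = setNames(integer(n), corpus$doc_id),
    text = setNames(integer(n), corpus$doc_id),
    metadata = setNames(integer(n), corpus$doc_id),
    folded = setNames(integer(n), corpus$doc_id)
  )

  add_positions <- function(env, term, doc, positions) {
    cur <- env[[term]]
    if (is.null(cur)) cur <- list()
    cur[[doc]] <- positions
    env[[term]] <- cur
  }
  add_tf <- function(env, tokens, doc) {
    if (length(tokens) == 0) return(invisible())
    tab <- table(tokens)
    for (term in names(tab)) {
      cur <- env[[term]]
      if (is.null(cur)) cur <- integer()
      cur[doc] <- as.integer(tab[[term]]) + (if (is.na(cur[doc])) 0L else cur[doc])
      env[[term]] <- cur
    }
  }
  add_doc <- function(env, key, doc) {
    env[[key]] <- c(env[[key]], doc)
  }

  for (i in seq_len(n)) {
    doc <- corpus$doc_id[i]
    ti <- tokenize(corpus$title[i])
    ab <- tokenize(corpus$abstract[i])
    for (term in unique(ti)) add_positions(post$title, term, doc, which(ti == term))
    for (term in unique(ab)) add_positions(post$abstract, term, doc, which(ab == term))
    doc_len$title[doc] <- length(ti)
    doc_len$abstract[doc] <- length(ab)
    doc_len$text[doc] <- length(ti) + length(ab)

    mh <- corpus$mesh_headings[[i]]
    mesh_tok <- character()
    qual_tok <- character()
    if (nrow(mh) > 0) {
      for (j in seq_len(nrow(mh))) {
        key <- tolower(mh$descriptor[j])
        add_doc(heading_docs, key, doc)
        if (mh$major[j]) add_doc(heading_major, key, doc)
        dtok <- tokenize(mh$descriptor[j])
        for (tk in unique(dtok)) add_doc(heading_token, tk, doc)
        qtok <- unlist(lapply(mh$qualifiers[[j]], tokenize))
        mesh_tok <- c(mesh_tok, dtok, qtok)
        qual_tok <- c(qual_tok, qtok, tolower(mh$qualifiers[[j]]))
      }
    }
    add_tf(tf_envs$mesh, mesh_tok, doc)
    add_tf(tf_envs$qualifier, qual_tok, doc)

    pts <- corpus$publication_types[[i]]
    pt_tok <- character()
    for (pt in pts) {
      add_doc(pubtype_docs, tolower(pt), doc)
      pt_tok <- c(pt_tok, tokenize(pt))
    }
    add_tf(tf_envs$pubtype_token, pt_tok, doc)
    doc_len$metadata[doc] <- length(mesh_tok) + length(pt_tok)

    if (mode == "folded") {
      # Text tokens first, then metadata tokens after a positional gap so
      # adjacency cannot match across the seam.
      gap <- 100L
      stream <- c(ti, ab, mesh_tok, pt_tok)
      offs <- c(
        seq_along(ti),
        length(ti) + gap + seq_along(ab),
        length(ti) + length(ab) + 2L * gap + seq_along(c(mesh_tok, pt_tok))
      )
      for (term in unique(stream)) {
        add_positions(post$folded, term, doc, offs[stream == term])
      }
      add_tf(tf_envs$folded_meta, c(mesh_tok, pt_tok), doc)
      doc_len$folded[doc] <- length(stream)
    }
  }

  env_dedup <- function(env) {
    out <- as.list(env)
    lapply(out, function(v) order_doc_ids(unique(v)))
  }

  structure(
    list(
      mode = mode,
      weight_map = weight_map,
      doc_ids = doc_ids,
      n_docs = n,
      postings = lapply(post, as.list),
      mesh_tf = as.list(tf_envs$mesh),
      qualifier_tf = as.list(tf_envs$qualifier),
      pubtype_token_tf = as.list(tf_envs$pubtype_token),
      folded_meta_tf = as.list(tf_envs$folded_meta),
      heading_docs = env_dedup(heading_docs),
      heading_major = env_dedup(heading_major),
      heading_token_docs = env_dedup(heading_token),
      pubtype_docs = env_dedup(pubtype_docs),
      language = setNames(tolower(corpus$language), corpus$doc_id),
      entry_date = setNames(corpus$entry_date, corpus$doc_id),
      doc_len = doc_len,
      avg_len = lapply(doc_len, function(v) if (n > 0) mean(v) else 0)
    ),
    class = "citation_index"
  )
}

#' @export
print.citation_index <- function(x, ...) {
  cat(
    "<citation_index> ", x$n_docs, " docs, mode=", x$mode,
    ", vocabulary: title=", length(x$postings$title),
    " abstract=", length(x$postings$abstract), "\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method generics::glance
glance.citation_index <- function(x, ...) {
  tibble(
    n_docs = x$n_docs,
    mode = x$mode,
    vocab_title = length(x$postings$title),
    vocab_abstract = length(x$postings$abstract),
    n_headings = length(x$heading_docs),
    avg_len_text = x$avg_len$text
  )
}

# ---- accessors used by the Boolean evaluator and BM25 ----------------------

# Documents containing `term` in a positional stream.
stream_docs <- function(index, field, term) {
  p <- index$postings[[field]][[term]]
  if (is.null(p)) character() else names(p)
}

stream_positions <- function(index, field, term, doc) {
  p <- index$postings[[field]][[term]]
  if (is.null(p)) integer() else p[[doc]] %||% integer()
}

stream_vocab <- function(index, field) {
  names(index$postings[[field]]) %||% character()
}

# tf of `term` for every doc in a tf map (named int vector), empty if absent.
tf_vec <- function(map, term) {
  map[[term]] %||% setNames(integer(), character())
}

# ---- persistence -----------------------------------------------------------

#' Save and load an index
#'
#' The index is persisted as a single versioned JSON document.
#'
#' @param index A `citation_index`.
#' @param path File path.
#' @return `read_index()` returns the `citation_index`; `write_index()` its
#'   input, invisibly.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "citation_index"))
  payload <- unclass(index)
  payload$format_version <- 1L
  # named atomic vectors would serialize as nameless arrays; store as objects
  payload$doc_len <- lapply(payload$doc_len, as.list)
  payload$language <- as.list(payload$language)
  payload$entry_date <- as.list(payload$entry_date)
  payload$weight_map <- as.list(payload$weight_map)
  for (nm in c("mesh_tf", "qualifier_tf", "pubtype_token_tf", "folded_meta_tf")) {
    payload[[nm]] <- lapply(payload[[nm]], as.list)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       na = "null", digits = NA)
  invisible(index)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(payload$format_version %||% 0L, 1L) &&
      !identical(payload$format_version %||% 0, 1)) {
    abort_boolrank("unsupported index format version", "boolrank_format_error")
  }
  payload$format_version <- NULL
  relist_int <- function(x) lapply(x, function(d) lapply(d, function(v) as.integer(unlist(v))))
  payload$postings <- lapply(payload$postings, relist_int)
  for (nm in c("mesh_tf", "qualifier_tf", "pubtype_token_tf", "folded_meta_tf")) {
    payload[[nm]] <- lapply(payload[[nm]], function(v) {
      setNames(as.integer(unlist(v)), names(v))
    })
  }
  for (nm in c("heading_docs", "heading_major", "heading_token_docs", "pubtype_docs")) {
    payload[[nm]] <- lapply(payload[[nm]], function(v) as.character(unlist(v)))
  }
  payload$language <- setNames(as.character(unlist(payload$language)), names(payload$language))
  payload$entry_date <- setNames(
    vapply(payload$entry_date, function(v) if (is.null(v)) NA_integer_ else as.integer(v), integer(1)),
    names(payload$entry_date)
  )
  payload$doc_len <- lapply(payload$doc_len, function(v) {
    setNames(as.integer(unlist(v)), names(v))
  })
  payload$avg_len <- lapply(payload$avg_len, as.numeric)
  payload$doc_ids <- as.character(unlist(payload$doc_ids))
  payload$weight_map <- setNames(as.numeric(unlist(payload$weight_map)), names(payload$weight_map))
  payload$n_docs <- as.integer(payload$n_docs)
  structure(payload, class = "citation_index")
}
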