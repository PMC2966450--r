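#' Evaluate a parsed strategy against an index
#'
#' Executes every numbered line in order, producing one unordered document
#' set per line; the final line's set is the strategy result. Semantics:
#'
#' * Terms match any token in their fielded scope; truncation (`$`/`:`) is a
#'   prefix match, `#`/`?` match exactly one character. Scopes: `.mp.` =
#'   title, abstract and MeSH tokens; `.tw.` = title + abstract; `.ti.`,
#'   `.ab.` single streams; `.sh.` subject-heading words; `.fs.` qualifier
#'   (sub-heading) terms; `.pt.` publication types; `.ed.` entry date. Bare
#'   terms default to `.mp.`.
#' * Phrases require consecutive token positions in a running-text stream; in
#'   `.mp.` scope an un-truncated phrase additionally matches citations
#'   indexed with a MeSH heading whose name equals the phrase.
#' * `adjN` requires both operands to occur within token distance `n` in the
#'   same stream; order-independent under the default `adj_mode = "window"`
#'   dialect, left-then-right under `"ordered"`.
#' * MeSH heading lines (`/`) use the verbatim-heading index; `exp` unions
#'   the heading with its full subtree (requires `thesaurus`; unknown
#'   exploded headings are errors, unknown plain headings yield an empty set
#'   with a warning); `*` keeps only major-topic indexing.
#' * `and` / `or` / `not` are set intersection, union, difference; `or/1-8`
#'   folds lines 1 to 8; `limit N to ...` filters line `N` by language,
#'   publication type or entry-date range (records without an entry date are
#'   excluded by date constraints).
#'
#' All sets iterate in deterministic document-id order.
#'
#' @param strategy A [parse_strategy()] result.
#' @param index A [build_index()] result.
#' @param thesaurus Optional [mesh_thesaurus()]; required for `exp`.
#' @param adj_mode Adjacency dialect: `"window"` (default) or `"ordered"`.
#' @return An `ovid_results` object; `tidy()` gives a per-line tibble and
#'   [result_set()] the final set.
#' @export
evaluate_strategy <- function(strategy, index, thesaurus = NULL,
                              adj_mode = c("window", "ordered")) {
  stopifnot(inherits(strategy, "search_strategy"), inherits(index, "citation_index"))
  adj_mode <- match.arg(adj_mode)
  ctx <- list(index = index, thesaurus = thesaurus, adj_mode = adj_mode)
  sets <- list()
  for (line in strategy$lines) {
    # range folds tolerate interior gaps (simplification may remove lines);
    # plain references and limit targets must resolve
    refs <- node_refs_required(line$node)
    missing <- refs[!(as.character(refs) %in% names(sets))]
    if (length(missing) > 0) {
      abort_boolrank(
        sprintf("line %d references undefined line %d", line$line_no, missing[1]),
        "boolrank_eval_error"
      )
    }
    sets[[as.character(line$line_no)]] <-
      order_doc_ids(eval_node(line$node, ctx, sets))
  }
  final_line <- strategy$lines[[length(strategy$lines)]]$line_no
  structure(
    list(sets = sets, final_line = final_line, strategy = strategy),
    class = "ovid_results"
  )
}

#' @rdname evaluate_strategy
#' @param results An `ovid_results` object.
#' @param line Line number; default the strategy's final line.
#' @export
result_set <- function(results, line = NULL) {
  stopifnot(inherits(results, "ovid_results"))
  line <- line %||% results$final_line
  results$sets[[as.character(line)]]
}

#' @export
print.ovid_results <- function(x, ...) {
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ovid_results <- function(x, ...) {
  lines <- as.integer(names(x$sets))
  tibble(
    line_no = lines,
    clause = vapply(x$strategy$lines, function(l) deparse_node(l$node), character(1)),
    n_docs = vapply(x$sets, length, integer(1), USE.NAMES = FALSE),
    doc_ids = unname(x$sets)
  )
}

# ---- node evaluation -------------------------------------------------------

eval_node <- function(node, ctx, sets) {
  switch(
    node$type,
    term = eval_term(node, ctx$index),
    phrase = eval_phrase(node, ctx$index),
    mesh = eval_mesh(node, ctx),
    adj = eval_adj(node, ctx),
    and = Reduce(intersect, lapply(node$args, eval_node, ctx = ctx, sets = sets)),
    or = Reduce(union, lapply(node$args, eval_node, ctx = ctx, sets = sets)),
    not = setdiff(
      eval_node(node$lhs, ctx, sets),
      eval_node(node$rhs, ctx, sets)
    ),
    lineref = sets[[as.character(node$n)]],
    rangeop = {
      keep <- as.character(seq(node$from, node$to))
      keep <- keep[keep %in% names(sets)]
      if (length(keep) == 0) {
        abort_boolrank(
          sprintf("range %s/%d-%d covers no defined lines", node$op, node$from, node$to),
          "boolrank_eval_error"
        )
      }
      Reduce(
        if (node$op == "or") union else intersect,
        sets[keep]
      )
    },
    limit = eval_limit(node, ctx$index, sets),
    abort_boolrank(paste0("cannot evaluate node type ", node$type), "boolrank_eval_error")
  )
}

pattern_regex <- function(pattern, truncated) {
  esc <- gsub("([.\\^$*+(){}\\[\\]|\\\\])", "\\\\\\1", pattern, perl = TRUE)
  esc <- gsub("[#?]", ".", esc)
  paste0("^", esc, if (!truncated) "$" else "")
}

match_vocab <- function(vocab, pattern, truncated) {
  if (length(vocab) == 0) return(character())
  if (!truncated && !grepl("[#?]", pattern)) {
    return(vocab[vocab == pattern])
  }
  vocab[grepl(pattern_regex(pattern, truncated), vocab, perl = TRUE)]
}

resolve_fields <- function(fields) {
  if (identical(fields, "default")) "mp" else fields
}

eval_term <- function(node, index) {
  docs <- character()
  for (field in resolve_fields(node$fields)) {
    docs <- c(docs, term_field_docs(index, node$pattern, node$truncated, field))
  }
  unique(docs)
}

term_field_docs <- function(index, pattern, truncated, field) {
  stream_hits <- function(stream) {
    terms <- match_vocab(stream_vocab(index, stream), pattern, truncated)
    unique(unlist(lapply(terms, function(t) stream_docs(index, stream, t))))
  }
  tf_hits <- function(map) {
    terms <- match_vocab(names(map) %||% character(), pattern, truncated)
    unique(unlist(lapply(terms, function(t) names(map[[t]]))))
  }
  switch(
    field,
    ti = stream_hits("title"),
    ab = stream_hits("abstract"),
    tw = unique(c(stream_hits("title"), stream_hits("abstract"))),
    mp = unique(c(stream_hits("title"), stream_hits("abstract"), tf_hits(index$mesh_tf))),
    sh = {
      toks <- match_vocab(names(index$heading_token_docs) %||% character(), pattern, truncated)
      unique(unlist(index$heading_token_docs[toks]))
    },
    fs = tf_hits(index$qualifier_tf),
    pt = {
      full <- match_vocab(names(index$pubtype_docs) %||% character(), pattern, truncated)
      toks <- tf_hits(index$pubtype_token_tf)
      unique(c(unlist(index$pubtype_docs[full]), toks))
    },
    ed = {
      dates <- index$entry_date
      keep <- !is.na(dates)
      chr <- as.character(dates[keep])
      hit <- if (truncated) startsWith(chr, pattern) else chr == pattern
      names(dates[keep])[hit]
    },
    abort_boolrank(paste0("unknown field scope '", field, "'"), "boolrank_eval_error")
  ) %||% character()
}

phrase_streams <- function(fields) {
  fields <- resolve_fields(fields)
  streams <- character()
  if (any(fields %in% c("ti", "tw", "mp"))) streams <- c(streams, "title")
  if (any(fields %in% c("ab", "tw", "mp"))) streams <- c(streams, "abstract")
  streams
}

# Per-document positions of a phrase's first token where the full phrase
# matches consecutively in `stream`.
phrase_match_positions <- function(index, slots, stream) {
  vocab <- stream_vocab(index, stream)
  slot_terms <- lapply(slots, function(s) match_vocab(vocab, s$pattern, s$truncated))
  if (any(vapply(slot_terms, length, integer(1)) == 0)) return(list())
  slot_docs <- lapply(slot_terms, function(terms) {
    unique(unlist(lapply(terms, function(t) stream_docs(index, stream, t))))
  })
  docs <- Reduce(intersect, slot_docs)
  out <- list()
  for (doc in docs) {
    pos_sets <- lapply(slot_terms, function(terms) {
      sort(unique(unlist(lapply(terms, function(t) stream_positions(index, stream, t, doc)))))
    })
    starts <- pos_sets[[1]]
    for (k in seq_along(pos_sets)[-1]) {
      starts <- starts[(starts + k - 1L) %in% pos_sets[[k]]]
      if (length(starts) == 0) break
    }
    if (length(starts) > 0) out[[doc]] <- starts
  }
  out
}

eval_phrase <- function(node, index) {
  docs <- character()
  for (stream in phrase_streams(node$fields)) {
    docs <- c(docs, names(phrase_match_positions(index, node$slots, stream)))
  }
  fields <- resolve_fields(node$fields)
  plain <- !any(vapply(node$slots, function(s) {
    s$truncated || grepl("[#?]", s$pattern)
  }, logical(1)))
  if (plain && any(fields %in% c("mp", "sh"))) {
    norm <- paste(vapply(node$slots, function(s) s$pattern, character(1)), collapse = " ")
    for (heading in names(index$heading_docs)) {
      if (normalize_phrase(heading) == norm) {
        docs <- c(docs, index$heading_docs[[heading]])
      }
    }
  }
  unique(docs)
}

eval_mesh <- function(node, ctx) {
  index <- ctx$index
  names_lc <- if (node$exploded) {
    if (is.null(ctx$thesaurus)) {
      abort_boolrank(
        paste0("exp ", node$name, "/ requires a thesaurus"),
        "boolrank_eval_error"
      )
    }
    tolower(mesh_explode(ctx$thesaurus, node$name))
  } else {
    key <- tolower(node$name)
    known <- !is.null(index$heading_docs[[key]]) ||
      (!is.null(ctx$thesaurus) && !is.null(mesh_lookup(ctx$thesaurus, key)))
    if (!known) {
      warn(
        paste0("MeSH heading not found: ", node$name, " (empty result)"),
        class = "boolrank_unknown_heading"
      )
    }
    key
  }
  source <- if (node$major) index$heading_major else index$heading_docs
  unique(unlist(source[names_lc])) %||% character()
}

# Position maps for adjacency operands: named list doc -> integer positions.
adj_positions <- function(node, index, stream) {
  switch(
    node$type,
    term = {
      terms <- match_vocab(stream_vocab(index, stream), node$pattern, node$truncated)
      out <- list()
      for (t in terms) {
        p <- index$postings[[stream]][[t]]
        for (doc in names(p)) out[[doc]] <- c(out[[doc]], p[[doc]])
      }
      out
    },
    phrase = phrase_match_positions(index, node$slots, stream),
    or = {
      maps <- lapply(node$args, adj_positions, index = index, stream = stream)
      out <- list()
      for (m in maps) {
        for (doc in names(m)) out[[doc]] <- c(out[[doc]], m[[doc]])
      }
      out
    },
    adj = {
      # nested adjacency: positions of the left operand where the pair matches
      hits <- adj_pair_positions(node, index, stream)
      hits
    },
    abort_boolrank(
      paste0("adj operands must be terms, phrases or or-groups, not ", node$type),
      "boolrank_eval_error"
    )
  )
}

adj_pair_positions <- function(node, index, stream, mode = "window") {
  lhs <- adj_positions(node$lhs, index, stream)
  rhs <- adj_positions(node$rhs, index, stream)
  out <- list()
  for (doc in intersect(names(lhs), names(rhs))) {
    lp <- sort(unique(lhs[[doc]]))
    rp <- sort(unique(rhs[[doc]]))
    keep <- vapply(lp, function(p) {
      if (mode == "window") {
        any(abs(rp - p) <= node$n & rp != p)
      } else {
        any(rp - p >= 1 & rp - p <= node$n)
      }
    }, logical(1))
    if (any(keep)) out[[doc]] <- lp[keep]
  }
  out
}

adj_streams <- function(node) {
  leaves_fields <- function(n) {
    switch(
      n$type,
      term = ,
      phrase = list(n$fields),
      adj = c(leaves_fields(n$lhs), leaves_fields(n$rhs)),
      or = ,
      and = unlist(lapply(n$args, leaves_fields), recursive = FALSE),
      list()
    )
  }
  streams <- unique(unlist(lapply(leaves_fields(node), phrase_streams)))
  if (length(streams) == 0) c("title", "abstract") else streams
}

eval_adj <- function(node, ctx) {
  docs <- character()
  for (stream in adj_streams(node)) {
    hits <- adj_pair_positions(node, ctx$index, stream, mode = ctx$adj_mode)
    docs <- c(docs, names(hits))
  }
  unique(docs)
}

eval_limit <- function(node, index, sets) {
  base <- sets[[as.character(node$target)]]
  if (is.null(base)) {
    abort_boolrank(
      sprintf("limit references undefined line %d", node$target),
      "boolrank_eval_error"
    )
  }
  cons <- node$constraint
  keep <- switch(
    cons$kind,
    language = index$language[base] == cons$value,
    pubtype = base %in% (index$pubtype_docs[[cons$value]] %||% character()),
    entry_date = {
      d <- index$entry_date[base]
      !is.na(d) & d >= cons$value[1] & d <= cons$value[2]
    },
    abort_boolrank(paste0("unknown limit kind ", cons$kind), "boolrank_eval_error")
  )
  keep[is.na(keep)] <- FALSE
  base[keep]
}
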