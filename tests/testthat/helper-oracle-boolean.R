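# Independent linear-scan oracle for the Ovid dialect. It never touches the
# inverted index: every node is evaluated by scanning per-document token
# lists, and token patterns are matched character by character rather than
# through regular expressions.

oracle_tok_match <- function(tok, pattern, truncated) {
  pc <- strsplit(pattern, "")[[1]]
  tc <- strsplit(tok, "")[[1]]
  if (truncated) {
    if (length(tc) < length(pc)) return(FALSE)
  } else {
    if (length(tc) != length(pc)) return(FALSE)
  }
  for (i in seq_along(pc)) {
    if (!(pc[i] %in% c("#", "?")) && pc[i] != tc[i]) return(FALSE)
  }
  TRUE
}

oracle_doc_view <- function(corpus) {
  lapply(seq_len(nrow(corpus)), function(i) {
    mh <- corpus$mesh_headings[[i]]
    mesh_tokens <- character()
    heading_tokens <- character()
    qualifier_tokens <- character()
    headings <- character()
    majors <- character()
    if (nrow(mh) > 0) {
      for (j in seq_len(nrow(mh))) {
        dtok <- tokenize(mh$descriptor[j])
        qtok <- unlist(lapply(mh$qualifiers[[j]], tokenize))
        mesh_tokens <- c(mesh_tokens, dtok, qtok)
        heading_tokens <- c(heading_tokens, dtok)
        qualifier_tokens <- c(qualifier_tokens, qtok, tolower(mh$qualifiers[[j]]))
        headings <- c(headings, tolower(mh$descriptor[j]))
        if (mh$major[j]) majors <- c(majors, tolower(mh$descriptor[j]))
      }
    }
    pts <- corpus$publication_types[[i]]
    list(
      id = corpus$doc_id[i],
      title = tokenize(corpus$title[i]),
      abstract = tokenize(corpus$abstract[i]),
      mesh_tokens = mesh_tokens,
      heading_tokens = heading_tokens,
      qualifier_tokens = qualifier_tokens,
      headings = headings,
      majors = majors,
      pubtypes = tolower(pts),
      pubtype_tokens = unlist(lapply(pts, tokenize)),
      language = tolower(corpus$language[i]),
      entry_date = corpus$entry_date[i]
    )
  })
}

oracle_scope_tokens <- function(doc, field) {
  switch(
    field,
    ti = doc$title,
    ab = doc$abstract,
    tw = c(doc$title, doc$abstract),
    mp = c(doc$title, doc$abstract, doc$mesh_tokens),
    sh = doc$heading_tokens,
    fs = doc$qualifier_tokens,
    pt = c(doc$pubtypes, doc$pubtype_tokens),
    ed = if (is.na(doc$entry_date)) character() else as.character(doc$entry_date),
    stop("oracle: unknown field ", field)
  )
}

oracle_term_match <- function(node, doc) {
  fields <- if (identical(node$fields, "default")) "mp" else node$fields
  for (f in fields) {
    toks <- oracle_scope_tokens(doc, f)
    for (tok in toks) {
      if (oracle_tok_match(tok, node$pattern, node$truncated)) return(TRUE)
    }
  }
  FALSE
}

oracle_stream_names <- function(fields) {
  fields <- if (identical(fields, "default")) "mp" else fields
  streams <- character()
  if (any(fields %in% c("ti", "tw", "mp"))) streams <- c(streams, "title")
  if (any(fields %in% c("ab", "tw", "mp"))) streams <- c(streams, "abstract")
  streams
}

# Start positions at which the phrase matches consecutively in `toks`.
oracle_phrase_starts <- function(slots, toks) {
  k <- length(slots)
  n <- length(toks)
  if (n < k) return(integer())
  starts <- integer()
  for (s in seq_len(n - k + 1)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!oracle_tok_match(toks[s + j - 1], slots[[j]]$pattern, slots[[j]]$truncated)) {
        ok <- FALSE
        break
      }
    }
    if (ok) starts <- c(starts, s)
  }
  starts
}

oracle_phrase_match <- function(node, doc) {
  for (stream in oracle_stream_names(node$fields)) {
    if (length(oracle_phrase_starts(node$slots, doc[[stream]])) > 0) return(TRUE)
  }
  fields <- if (identical(node$fields, "default")) "mp" else node$fields
  plain <- !any(vapply(node$slots, function(s) {
    s$truncated || grepl("[#?]", s$pattern)
  }, logical(1)))
  if (plain && any(fields %in% c("mp", "sh"))) {
    norm <- paste(vapply(node$slots, function(s) s$pattern, character(1)),
                  collapse = " ")
    for (h in doc$headings) {
      if (paste(tokenize(h), collapse = " ") == norm) return(TRUE)
    }
  }
  FALSE
}

# Positions of an adjacency operand in one stream (term, phrase, or or-group).
oracle_adj_positions <- function(node, doc, stream) {
  toks <- doc[[stream]]
  switch(
    node$type,
    term = which(vapply(toks, oracle_tok_match, logical(1),
                        pattern = node$pattern, truncated = node$truncated,
                        USE.NAMES = FALSE)),
    phrase = oracle_phrase_starts(node$slots, toks),
    or = sort(unique(unlist(lapply(node$args, oracle_adj_positions,
                                   doc = doc, stream = stream)))),
    stop("oracle: bad adj operand ", node$type)
  )
}

oracle_adj_match <- function(node, doc) {
  streams <- unique(unlist(lapply(
    boolrank:::collect_leaves(node),
    function(l) oracle_stream_names(l$fields)
  )))
  if (length(streams) == 0) streams <- c("title", "abstract")
  for (stream in streams) {
    lp <- oracle_adj_positions(node$lhs, doc, stream)
    rp <- oracle_adj_positions(node$rhs, doc, stream)
    for (p in lp) {
      for (q in rp) {
        if (p != q && abs(p - q) <= node$n) return(TRUE)
      }
    }
  }
  FALSE
}

# Transitive closure of the child relation, computed iteratively (no shared
# code with mesh_explode's recursive walk).
oracle_explode <- function(thesaurus, heading) {
  key <- tolower(trimws(heading))
  if (is.null(thesaurus$nodes[[key]])) stop("oracle: unknown heading ", heading)
  frontier <- key
  seen <- character()
  while (length(frontier) > 0) {
    nxt <- frontier[1]
    frontier <- frontier[-1]
    if (nxt %in% seen) next
    seen <- c(seen, nxt)
    frontier <- c(frontier, thesaurus$nodes[[nxt]]$children)
  }
  vapply(seen, function(k) thesaurus$nodes[[k]]$name, character(1), USE.NAMES = FALSE)
}

oracle_mesh_match <- function(node, doc, thesaurus) {
  names_lc <- if (node$exploded) {
    tolower(oracle_explode(thesaurus, node$name))
  } else {
    tolower(node$name)
  }
  pool <- if (node$major) doc$majors else doc$headings
  any(names_lc %in% pool)
}

oracle_eval_strategy <- function(strategy, corpus, thesaurus = NULL) {
  docs <- oracle_doc_view(corpus)
  ids <- vapply(docs, function(d) d$id, character(1))
  sets <- list()
  by_pred <- function(pred) ids[vapply(docs, pred, logical(1))]
  eval_node <- function(node) {
    switch(
      node$type,
      term = by_pred(function(d) oracle_term_match(node, d)),
      phrase = by_pred(function(d) oracle_phrase_match(node, d)),
      mesh = by_pred(function(d) oracle_mesh_match(node, d, thesaurus)),
      adj = by_pred(function(d) oracle_adj_match(node, d)),
      and = Reduce(intersect, lapply(node$args, eval_node)),
      or = Reduce(union, lapply(node$args, eval_node)),
      not = setdiff(eval_node(node$lhs), eval_node(node$rhs)),
      lineref = sets[[as.character(node$n)]],
      rangeop = {
        keep <- as.character(seq(node$from, node$to))
        keep <- keep[keep %in% names(sets)]
        Reduce(if (node$op == "or") union else intersect, sets[keep])
      },
      limit = {
        base <- sets[[as.character(node$target)]]
        base[vapply(base, function(id) {
          d <- docs[[match(id, ids)]]
          switch(
            node$constraint$kind,
            language = identical(d$language, node$constraint$value),
            pubtype = node$constraint$value %in% d$pubtypes,
            entry_date = !is.na(d$entry_date) &&
              d$entry_date >= node$constraint$value[1] &&
              d$entry_date <= node$constraint$value[2]
          )
        }, logical(1))]
      },
      stop("oracle: cannot evaluate ", node$type)
    )
  }
  for (l in strategy$lines) {
    sets[[as.character(l$line_no)]] <- sort(eval_node(l$node))
  }
  sets
}
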