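#' Lint a search strategy for common authoring errors
#'
#' Published search strategies frequently contain mechanical errors —
#' incorrect line references, misspelled or obsolete MeSH headings, dead
#' lines. `lint_strategy()` reports the mechanically checkable classes:
#'
#' * `BAD_LINE_REF` — reference to a missing line (e.g. a range fold spanning
#'   a gap).
#' * `UNKNOWN_MESH` — heading absent from the thesaurus.
#' * `UNREFERENCED_LINE` — line never used by a later line and not the final
#'   line.
#' * `MIXED_LINE` — MeSH heading and free-text term combined in one clause.
#' * `REDUNDANT_LINE` — clause identical (as an AST) to an earlier line.
#' * `SHORT_STEM` — truncation stem shorter than 2 characters, which matches
#'   excessively and is demoted to a literal match.
#' * `PARSE_ERROR` — reported when raw text is passed and does not parse;
#'   lint never raises on a valid parse.
#'
#' @param strategy A [parse_strategy()] result, or raw strategy text.
#' @param thesaurus Optional [mesh_thesaurus()] used for `UNKNOWN_MESH`.
#' @return A tibble with columns `line_no`, `code`, `message` (zero rows for
#'   a clean strategy).
#' @export
lint_strategy <- function(strategy, thesaurus = NULL) {
  if (!inherits(strategy, "search_strategy")) {
    strategy <- tryCatch(
      suppressWarnings(parse_strategy(strategy)),
      error = function(e) e
    )
    if (inherits(strategy, "error")) {
      return(tibble(
        line_no = NA_integer_,
        code = "PARSE_ERROR",
        message = conditionMessage(strategy)
      ))
    }
  }
  issues <- list()
  add <- function(line_no, code, message) {
    issues[[length(issues) + 1]] <<- tibble(
      line_no = as.integer(line_no), code = code, message = message
    )
  }

  line_nos <- vapply(strategy$lines, function(l) l$line_no, integer(1))
  final <- max(line_nos)
  referenced <- integer()

  seen_clauses <- character()
  for (l in strategy$lines) {
    refs <- node_refs(l$node)
    referenced <- c(referenced, refs)
    bad <- setdiff(refs, line_nos[line_nos < l$line_no])
    for (b in bad) {
      add(l$line_no, "BAD_LINE_REF",
          sprintf("reference to missing or later line %d", b))
    }
    walk_lint_node(l$node, l$line_no, thesaurus, add)
    kinds <- node_kinds(l$node)
    if ("mesh" %in% kinds && any(c("term", "phrase") %in% kinds)) {
      add(l$line_no, "MIXED_LINE",
          "MeSH heading and free-text term combined in one clause")
    }
    clause <- deparse_node(l$node)
    if (clause %in% seen_clauses) {
      add(l$line_no, "REDUNDANT_LINE",
          sprintf("clause identical to an earlier line: %s", clause))
    }
    seen_clauses <- c(seen_clauses, clause)
  }
  for (no in setdiff(line_nos, c(referenced, final))) {
    add(no, "UNREFERENCED_LINE", "line is never referenced and is not the final line")
  }

  if (length(issues) == 0) {
    return(tibble(line_no = integer(), code = character(), message = character()))
  }
  dplyr::arrange(dplyr::bind_rows(issues), .data$line_no, .data$code)
}

walk_lint_node <- function(node, line_no, thesaurus, add) {
  switch(
    node$type,
    mesh = {
      if (!is.null(thesaurus) && is.null(mesh_lookup(thesaurus, node$name))) {
        add(line_no, "UNKNOWN_MESH",
            sprintf("heading not found in thesaurus: %s", node$name))
      }
    },
    term = {
      if (isTRUE(node$short_stem)) {
        add(line_no, "SHORT_STEM",
            sprintf("truncation stem '%s' shorter than 2 characters", node$pattern))
      }
    },
    phrase = {
      for (s in node$slots) walk_lint_node(s, line_no, thesaurus, add)
    },
    adj = ,
    not = {
      walk_lint_node(node$lhs, line_no, thesaurus, add)
      walk_lint_node(node$rhs, line_no, thesaurus, add)
    },
    and = ,
    or = {
      for (a in node$args) walk_lint_node(a, line_no, thesaurus, add)
    },
    invisible(NULL)
  )
  invisible(NULL)
}

node_kinds <- function(node) {
  switch(
    node$type,
    term = "term",
    phrase = "phrase",
    mesh = "mesh",
    adj = ,
    not = unique(c(node_kinds(node$lhs), node_kinds(node$rhs))),
    and = ,
    or = unique(unlist(lapply(node$args, node_kinds))),
    node$type
  )
}
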