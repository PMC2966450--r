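# AST node constructors for the Ovid-dialect query language, plus the
# deparser. Nodes are plain lists tagged with `type`:
#   term     pattern (lowercase), truncated, trunc_char, wildcard ("#"/"?"
#            kept inside pattern), fields (chr vector, "default" when unset),
#            raw (surface form for deparsing), quoted
#   phrase   slots (list of term nodes), fields, raw, quoted
#   mesh     name, exploded, major
#   adj      n, lhs, rhs
#   and/or   args (list)
#   not      lhs, rhs (binary left-associative difference)
#   lineref  n
#   rangeop  op ("and"/"or"), from, to
#   limit    target, constraint (kind = language/pubtype/entry_date, value)
# Compound nodes parsed as "( ... ).mp." additionally carry group_fields so
# the deparser can reproduce the group suffix form.

qn_term <- function(pattern, truncated = FALSE, trunc_char = "$",
                    fields = "default", raw = pattern, quoted = FALSE) {
  list(
    type = "term", pattern = tolower(pattern), truncated = truncated,
    trunc_char = trunc_char, fields = fields, raw = raw, quoted = quoted
  )
}

qn_phrase <- function(slots, fields = "default", raw = NULL, quoted = FALSE) {
  list(type = "phrase", slots = slots, fields = fields, raw = raw, quoted = quoted)
}

qn_mesh <- function(name, exploded = FALSE, major = FALSE) {
  list(type = "mesh", name = name, exploded = exploded, major = major)
}

qn_adj <- function(n, lhs, rhs) {
  stopifnot(n >= 1)
  list(type = "adj", n = as.integer(n), lhs = lhs, rhs = rhs)
}

qn_and <- function(args) list(type = "and", args = args)
qn_or <- function(args) list(type = "or", args = args)
qn_not <- function(lhs, rhs) list(type = "not", lhs = lhs, rhs = rhs)
qn_lineref <- function(n) list(type = "lineref", n = as.integer(n))

qn_rangeop <- function(op, from, to) {
  list(type = "rangeop", op = op, from = as.integer(from), to = as.integer(to))
}

qn_limit <- function(target, constraint) {
  list(type = "limit", target = as.integer(target), constraint = constraint)
}

node_type <- function(node) node$type

# Line numbers referenced by a node (for validation, lint and repair).
node_refs <- function(node) {
  switch(
    node$type,
    lineref = node$n,
    rangeop = seq(node$from, node$to),
    limit = node$target,
    adj = c(node_refs(node$lhs), node_refs(node$rhs)),
    not = c(node_refs(node$lhs), node_refs(node$rhs)),
    and = ,
    or = unlist(lapply(node$args, node_refs)),
    integer(0)
  )
}

# References that must resolve at evaluation time: everything node_refs
# reports except the interior of a range fold, which may legitimately span
# removed lines after simplification.
node_refs_required <- function(node) {
  switch(
    node$type,
    rangeop = integer(0),
    adj = ,
    not = c(node_refs_required(node$lhs), node_refs_required(node$rhs)),
    and = ,
    or = unlist(lapply(node$args, node_refs_required)),
    node_refs(node)
  )
}

# Recursively attach a field spec to leaves that have none.
set_fields <- function(node, fields) {
  switch(
    node$type,
    term = ,
    phrase = {
      if (identical(node$fields, "default")) node$fields <- fields
      node
    },
    adj = {
      node$lhs <- set_fields(node$lhs, fields)
      node$rhs <- set_fields(node$rhs, fields)
      node
    },
    not = {
      node$lhs <- set_fields(node$lhs, fields)
      node$rhs <- set_fields(node$rhs, fields)
      node
    },
    and = ,
    or = {
      node$args <- lapply(node$args, set_fields, fields = fields)
      node
    },
    node
  )
}

# ---- deparser --------------------------------------------------------------

node_precedence <- function(node) {
  switch(node$type, or = 1L, and = 2L, not = 3L, adj = 4L, 5L)
}

deparse_operand <- function(node, parent_prec, suppress_fields) {
  txt <- deparse_node(node, suppress_fields = suppress_fields)
  if (node_precedence(node) < parent_prec) paste0("(", txt, ")") else txt
}

field_suffix <- function(fields) {
  if (identical(fields, "default")) "" else paste0(".", paste(fields, collapse = ","), ".")
}

deparse_term_core <- function(node) {
  body <- if (node$quoted) paste0('"', node$raw, '"') else node$raw
  if (node$truncated) paste0(body, node$trunc_char) else body
}

deparse_node <- function(node, suppress_fields = FALSE) {
  suffix <- function(fields) if (suppress_fields) "" else field_suffix(fields)
  switch(
    node$type,
    term = paste0(deparse_term_core(node), suffix(node$fields)),
    phrase = {
      body <- if (!is.null(node$raw)) node$raw else {
        paste(vapply(node$slots, deparse_term_core, character(1)), collapse = " ")
      }
      if (node$quoted) body <- paste0('"', body, '"')
      paste0(body, suffix(node$fields))
    },
    mesh = paste0(
      if (node$exploded) "exp " else "",
      if (node$major) "*" else "",
      node$name, "/"
    ),
    adj = {
      prec <- node_precedence(node)
      inner_suppress <- suppress_fields || !is.null(node$group_fields)
      txt <- paste(
        deparse_operand(node$lhs, prec, inner_suppress),
        paste0("adj", node$n),
        deparse_operand(node$rhs, prec, inner_suppress)
      )
      wrap_group(node, txt, suppress_fields)
    },
    not = {
      prec <- node_precedence(node)
      inner_suppress <- suppress_fields || !is.null(node$group_fields)
      txt <- paste(
        deparse_operand(node$lhs, prec, inner_suppress),
        "not",
        deparse_operand(node$rhs, prec, inner_suppress)
      )
      wrap_group(node, txt, suppress_fields)
    },
    and = ,
    or = {
      prec <- node_precedence(node)
      inner_suppress <- suppress_fields || !is.null(node$group_fields)
      txt <- paste(
        vapply(node$args, deparse_operand, character(1),
               parent_prec = prec, suppress_fields = inner_suppress),
        collapse = paste0(" ", node$type, " ")
      )
      wrap_group(node, txt, suppress_fields)
    },
    lineref = as.character(node$n),
    rangeop = paste0(node$op, "/", node$from, "-", node$to),
    limit = paste0("limit ", node$target, " to ", node$constraint$raw),
    abort_boolrank(paste0("cannot deparse node type ", node$type), "boolrank_internal")
  )
}

wrap_group <- function(node, txt, suppress_fields) {
  if (!suppress_fields && !is.null(node$group_fields)) {
    paste0("(", txt, ")", field_suffix(node$group_fields))
  } else {
    txt
  }
}

#' Format a parsed strategy back to strategy text
#'
#' Produces one numbered clause per line in the canonical surface syntax; the
#' output reparses to an equivalent strategy.
#'
#' @param strategy A [parse_strategy()] result.
#' @return Character scalar of newline-separated numbered lines.
#' @export
format_strategy <- function(strategy) {
  stopifnot(inherits(strategy, "search_strategy"))
  paste(
    vapply(strategy$lines, function(l) {
      paste0(l$line_no, " ", deparse_node(l$node))
    }, character(1)),
    collapse = "\n"
  )
}

#' @export
print.search_strategy <- function(x, ...) {
  cat(format_strategy(x), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.search_strategy <- function(x, ...) {
  tibble(
    line_no = vapply(x$lines, function(l) l$line_no, integer(1)),
    clause = vapply(x$lines, function(l) deparse_node(l$node), character(1)),
    node_type = vapply(x$lines, function(l) l$node$type, character(1)),
    references = lapply(x$lines, function(l) node_refs(l$node))
  )
}
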