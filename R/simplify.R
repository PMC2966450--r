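#' Simplification configuration
#'
#' Controls the rewrite system that broadens a strategy into a superset of
#' itself. The defaults reproduce the canonical worked example: field scopes
#' `.ti.`/`.tw.`/`.fs.`/`.sh.` widen to `.mp.`, `adjN` operands become a
#' disjunction, `limit` lines, entry-date filters and explicit
#' publication-type filter lines are removed, truncation and `exp` are left
#' unchanged, and plain MeSH heading lines become `.mp.` text searches.
#'
#' @param convert_and_to_or `"never"`, `"concept_lines_only"` (default:
#'   convert an `and` only when every operand is a term or phrase on the same
#'   line, keeping cross-line facet intersections intact) or `"always"`.
#' @param mesh_line_action `"replace_with_mp"` (default) or
#'   `"remove_if_conjunct"` (drop a plain heading used conjunctively instead
#'   of widening it).
#' @param drop_limits Remove `limit` lines and publication-type filter lines
#'   (default `TRUE`).
#' @param drop_entry_dates Remove `.ed.` entry-date filters (default `TRUE`).
#' @return A `simplify_config` list.
#' @export
simplify_config <- function(convert_and_to_or = c("concept_lines_only", "never", "always"),
                            mesh_line_action = c("replace_with_mp", "remove_if_conjunct"),
                            drop_limits = TRUE,
                            drop_entry_dates = TRUE) {
  structure(
    list(
      convert_and_to_or = match.arg(convert_and_to_or),
      mesh_line_action = match.arg(mesh_line_action),
      drop_limits = isTRUE(drop_limits),
      drop_entry_dates = isTRUE(drop_entry_dates)
    ),
    class = "simplify_config"
  )
}

#' Simplify a Boolean search strategy into a broader superset
#'
#' Applies the rewrite rules described in [simplify_config()] and repairs
#' line references: a range fold spanning a removed line contracts, a
#' conjunction drops removed operands, and a line whose entire definition was
#' removed is itself removed, cascading. Original line numbers are preserved
#' (gaps allowed) so the output stays diffable against the source; the result
#' line is the highest surviving line. The output is re-parseable with
#' [parse_strategy()].
#'
#' When filters appear conjunctively (their universal use in published
#' strategies) the result set of the simplified strategy is a superset of the
#' original's; a publication-type filter found inside a disjunction is
#' widened to `.mp.` rather than dropped so the guarantee still holds there.
#' The right-hand side of a `not` is deliberately left unmodified: widening
#' an excluded set would shrink the result.
#'
#' @param strategy A [parse_strategy()] result.
#' @param config A [simplify_config()].
#' @return A `search_strategy`.
#' @examples
#' s <- parse_strategy(c(
#'   "21 exp pyridoxine/",
#'   "22 pyridoxal.ti.",
#'   '23 (vitamin adj1 ("B6" or "B 6")).mp.',
#'   "24 or/21-23",
#'   "25 random:.sh,pt.",
#'   "26 limit 25 to English language"
#' ))
#' cat(format_strategy(simplify_strategy(s)))
#' @export
simplify_strategy <- function(strategy, config = simplify_config()) {
  stopifnot(inherits(strategy, "search_strategy"))
  if (!inherits(config, "simplify_config")) config <- do.call(simplify_config, config)

  line_nos <- vapply(strategy$lines, function(l) l$line_no, integer(1))
  nodes <- setNames(lapply(strategy$lines, function(l) l$node), as.character(line_nos))

  # Lines reachable from the result under an odd (or mixed) number of
  # negations are frozen: widening an excluded set would shrink the result,
  # so those lines keep their original definitions and are never removed.
  frozen <- negative_polarity_lines(nodes, line_nos)
  # Lines consumed disjunctively (or-operands, or-range members, chased
  # through limit chains): a metadata filter there is widened to .mp.
  # instead of removed, keeping the superset guarantee.
  or_consumed <- or_context_lines(nodes, line_nos, frozen)

  rewritten <- nodes
  for (no in line_nos) {
    key <- as.character(no)
    if (no %in% frozen) next
    rewritten[[key]] <- simplify_node(
      nodes[[key]], config,
      context = if (no %in% or_consumed) "disjunctive" else "conjunctive"
    )
    if (is.null(rewritten[[key]])) rewritten[key] <- list(NULL)
  }

  removed <- line_nos[vapply(line_nos, function(no) {
    is.null(rewritten[[as.character(no)]])
  }, logical(1))]

  # References to a removed limit line pass through to its target, so a
  # disjunction over a dropped limit widens to the unfiltered line instead
  # of losing it.
  redirect <- function(no) {
    while (no %in% removed) {
      node <- nodes[[as.character(no)]]
      if (!is.null(node) && node$type == "limit") no <- node$target else return(NULL)
    }
    no
  }

  # Cascade: repair references; a line whose definition empties out joins
  # the removed set.
  repeat {
    changed <- FALSE
    for (no in setdiff(line_nos, removed)) {
      node <- rewritten[[as.character(no)]]
      repaired <- repair_refs(node, removed, setdiff(line_nos, removed), redirect)
      if (is.null(repaired)) {
        removed <- c(removed, no)
        changed <- TRUE
      } else {
        rewritten[[as.character(no)]] <- repaired
      }
    }
    if (!changed) break
  }

  surviving <- setdiff(line_nos, removed)
  if (length(surviving) == 0) {
    abort_boolrank(
      "strategy degenerates under simplification",
      "boolrank_degenerate_strategy"
    )
  }
  structure(
    list(lines = lapply(surviving, function(no) {
      list(line_no = no, node = rewritten[[as.character(no)]])
    })),
    class = "search_strategy"
  )
}

# Fixpoint propagation of reference polarity from the strategy's result
# line. Returns the line numbers reached with negative (or mixed) polarity.
negative_polarity_lines <- function(nodes, line_nos) {
  pos <- setNames(logical(length(line_nos)), as.character(line_nos))
  neg <- pos
  signed_refs <- function(node, flip) {
    switch(
      node$type,
      lineref = list(list(ref = node$n, neg = flip)),
      limit = list(list(ref = node$target, neg = flip)),
      rangeop = lapply(seq(node$from, node$to), function(r) list(ref = r, neg = flip)),
      not = c(signed_refs(node$lhs, flip), signed_refs(node$rhs, !flip)),
      adj = c(signed_refs(node$lhs, flip), signed_refs(node$rhs, flip)),
      and = ,
      or = unlist(lapply(node$args, signed_refs, flip = flip), recursive = FALSE),
      list()
    )
  }
  final <- max(line_nos)
  pos[as.character(final)] <- TRUE
  worklist <- list(list(line = final, neg = FALSE))
  while (length(worklist) > 0) {
    item <- worklist[[1]]
    worklist <- worklist[-1]
    node <- nodes[[as.character(item$line)]]
    if (is.null(node)) next
    for (sr in signed_refs(node, item$neg)) {
      key <- as.character(sr$ref)
      if (!(key %in% names(pos))) next
      already <- if (sr$neg) neg[key] else pos[key]
      if (!already) {
        if (sr$neg) neg[key] <- TRUE else pos[key] <- TRUE
        worklist[[length(worklist) + 1]] <- list(line = sr$ref, neg = sr$neg)
      }
    }
  }
  as.integer(names(neg)[neg])
}

# Line numbers referenced in a disjunctive position by a non-frozen line,
# with limit chains chased down to their targets.
or_context_lines <- function(nodes, line_nos, frozen) {
  found <- integer()
  collect <- function(node, in_or) {
    switch(
      node$type,
      lineref = if (in_or) found <<- c(found, node$n),
      rangeop = if (node$op == "or") found <<- c(found, seq(node$from, node$to)),
      not = {
        collect(node$lhs, in_or)
        collect(node$rhs, TRUE)
      },
      adj = {
        collect(node$lhs, TRUE)
        collect(node$rhs, TRUE)
      },
      or = for (a in node$args) collect(a, TRUE),
      and = for (a in node$args) collect(a, FALSE),
      invisible(NULL)
    )
  }
  for (no in setdiff(line_nos, frozen)) {
    collect(nodes[[as.character(no)]], FALSE)
  }
  # chase limit chains: a disjunctive reference to a limit protects its target
  out <- integer()
  for (r in unique(found)) {
    while (TRUE) {
      out <- c(out, r)
      node <- nodes[[as.character(r)]]
      if (!is.null(node) && node$type == "limit") r <- node$target else break
    }
  }
  unique(out)
}

# Map a field vector under the widening rules; NULL when the scope reduces to
# a pure metadata filter (publication type / entry date).
simplify_fields <- function(fields, config) {
  fields <- resolve_fields(fields)
  if (config$drop_limits && "pt" %in% fields) return(NULL)
  if (config$drop_entry_dates && "ed" %in% fields) return(NULL)
  mapped <- unique(ifelse(fields %in% c("ti", "tw", "fs", "sh"), "mp", fields))
  mapped
}

# Rewrite a node. Returns NULL when the node is removed. `context` is
# "conjunctive" for standalone lines and operands of and/not-lhs, and
# "disjunctive" inside or/adj where dropping an operand would shrink the set.
simplify_node <- function(node, config, context) {
  switch(
    node$type,
    term = ,
    phrase = {
      fields <- simplify_fields(node$fields, config)
      if (is.null(fields)) {
        if (context == "conjunctive") return(NULL)
        fields <- "mp"
      }
      node$fields <- fields
      node
    },
    mesh = {
      if (node$exploded) return(node)
      if (config$mesh_line_action == "remove_if_conjunct" && context == "conjunctive") {
        return(NULL)
      }
      make_text_node(tolower(gsub(",", "", node$name)), fields = "mp", quoted = FALSE)
    },
    adj = {
      args <- flatten_or(list(
        simplify_node(node$lhs, config, "disjunctive"),
        simplify_node(node$rhs, config, "disjunctive")
      ))
      out <- qn_or(args)
      out$group_fields <- node$group_fields %||% shared_leaf_fields(args)
      out
    },
    and = {
      args <- purrr::compact(lapply(node$args, simplify_node, config = config,
                                    context = "conjunctive"))
      if (length(args) == 0) return(NULL)
      if (length(args) == 1) return(args[[1]])
      convert <- config$convert_and_to_or == "always" ||
        (config$convert_and_to_or == "concept_lines_only" &&
           all(vapply(args, function(a) a$type %in% c("term", "phrase"), logical(1))))
      out <- if (convert) qn_or(args) else qn_and(args)
      out$group_fields <- node$group_fields
      out
    },
    or = {
      args <- flatten_or(purrr::compact(
        lapply(node$args, simplify_node, config = config, context = "disjunctive")
      ))
      if (length(args) == 0) return(NULL)
      if (length(args) == 1) return(args[[1]])
      out <- qn_or(args)
      out$group_fields <- node$group_fields
      out
    },
    not = {
      lhs <- simplify_node(node$lhs, config, context)
      if (is.null(lhs)) return(NULL)
      # rhs untouched: widening an excluded set would shrink the result
      qn_not(lhs, node$rhs)
    },
    lineref = node,
    rangeop = {
      if (config$convert_and_to_or == "always" && node$op == "and") {
        node$op <- "or"
      }
      node
    },
    limit = if (config$drop_limits) NULL else node,
    node
  )
}

flatten_or <- function(args) {
  out <- list()
  for (a in args) {
    if (!is.null(a) && a$type == "or" && is.null(a$group_fields)) {
      out <- c(out, a$args)
    } else if (!is.null(a)) {
      out <- c(out, list(a))
    }
  }
  out
}

shared_leaf_fields <- function(args) {
  fields <- unique(lapply(args, function(a) {
    if (a$type %in% c("term", "phrase")) list(a$fields) else
      lapply(collect_leaves(a), function(l) l$fields)
  }))
  fields <- unique(unlist(fields, recursive = FALSE))
  if (length(fields) == 1 && !identical(fields[[1]], "default")) fields[[1]] else NULL
}

collect_leaves <- function(node) {
  switch(
    node$type,
    term = ,
    phrase = list(node),
    adj = ,
    not = c(collect_leaves(node$lhs), collect_leaves(node$rhs)),
    and = ,
    or = unlist(lapply(node$args, collect_leaves), recursive = FALSE),
    list()
  )
}

# Repair references to removed lines. References to removed limit lines are
# redirected to their (unfiltered) targets; dead references are dropped from
# their surrounding conjunction/disjunction. Returns NULL when the node's
# whole definition disappears.
repair_refs <- function(node, removed, surviving, redirect) {
  switch(
    node$type,
    lineref = {
      target <- redirect(node$n)
      if (is.null(target)) NULL else qn_lineref(target)
    },
    rangeop = {
      members <- unique(unlist(lapply(
        intersect(seq(node$from, node$to), c(surviving, removed)),
        redirect
      )))
      if (length(members) == 0) return(NULL)
      members <- sort(members)
      if (length(members) == 1) return(qn_lineref(members))
      span <- intersect(seq(min(members), max(members)), surviving)
      if (setequal(span, members)) {
        node$from <- min(members)
        node$to <- max(members)
        node
      } else {
        refs <- lapply(members, qn_lineref)
        if (node$op == "or") qn_or(refs) else qn_and(refs)
      }
    },
    limit = {
      target <- redirect(node$target)
      if (is.null(target)) return(NULL)
      node$target <- target
      node
    },
    and = ,
    or = {
      args <- purrr::compact(lapply(node$args, repair_refs, removed = removed,
                                    surviving = surviving, redirect = redirect))
      if (length(args) == 0) return(NULL)
      if (length(args) == 1) return(args[[1]])
      node$args <- args
      node
    },
    not = {
      lhs <- repair_refs(node$lhs, removed, surviving, redirect)
      rhs <- repair_refs(node$rhs, removed, surviving, redirect)
      if (is.null(lhs)) return(NULL)
      if (is.null(rhs)) return(lhs)
      qn_not(lhs, rhs)
    },
    adj = {
      lhs <- repair_refs(node$lhs, removed, surviving, redirect)
      rhs <- repair_refs(node$rhs, removed, surviving, redirect)
      if (is.null(lhs) || is.null(rhs)) return(lhs %||% rhs)
      node$lhs <- lhs
      node$rhs <- rhs
      node
    },
    node
  )
}
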