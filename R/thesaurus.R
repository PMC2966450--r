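#' MeSH-like thesaurus
#'
#' A thesaurus is a rooted forest of descriptors. Each descriptor carries a
#' name, optional qualifiers (sub-headings), entry terms (synonym concept
#' terms), abbreviations and supplementary concept terms. Descriptor names are
#' unique case-insensitively; matching everywhere in the package is
#' case-insensitive but punctuation-preserving, so `"Acupuncture, Ear"` keeps
#' its comma.
#'
#' `mesh_thesaurus()` builds one from a nested list of descriptor nodes, each
#' a list with fields `name`, and optionally `qualifiers`, `entry_terms`,
#' `abbreviations`, `supplementary_terms` and `children` (a nested list of the
#' same shape).
#'
#' @param forest Nested list of descriptor nodes.
#' @return An object of class `mesh_thesaurus`.
#' @examples
#' th <- mesh_thesaurus(list(
#'   list(name = "Acupuncture Therapy", children = list(
#'     list(name = "Electroacupuncture"),
#'     list(name = "Moxibustion")
#'   ))
#' ))
#' mesh_explode(th, "acupuncture therapy")
#' @export
mesh_thesaurus <- function(forest) {
  nodes <- list()
  add_node <- function(node, parent_key) {
    if (is.null(node$name) || !nzchar(node$name)) {
      abort_boolrank("descriptor node without a name", "boolrank_format_error")
    }
    key <- tolower(node$name)
    if (!is.null(nodes[[key]])) {
      abort_boolrank(
        paste0("duplicate descriptor name (case-insensitive): ", node$name),
        "boolrank_duplicate_id"
      )
    }
    nodes[[key]] <<- list(
      name = node$name,
      parent = parent_key,
      children = character(),
      qualifiers = as.character(unlist(node$qualifiers)),
      entry_terms = as.character(unlist(node$entry_terms)),
      abbreviations = as.character(unlist(node$abbreviations)),
      supplementary_terms = as.character(unlist(node$supplementary_terms))
    )
    for (child in node$children %||% list()) {
      child_key <- add_node(child, key)
      nodes[[key]]$children <<- c(nodes[[key]]$children, child_key)
    }
    key
  }
  roots <- vapply(forest, add_node, character(1), parent_key = NA_character_)
  structure(
    list(nodes = nodes, roots = roots),
    class = "mesh_thesaurus"
  )
}

#' @export
print.mesh_thesaurus <- function(x, ...) {
  cat(
    "<mesh_thesaurus> ", length(x$nodes), " descriptors, ",
    length(x$roots), " roots\n",
    sep = ""
  )
  invisible(x)
}

#' @export
format.mesh_thesaurus <- function(x, ...) {
  paste0("<mesh_thesaurus: ", length(x$nodes), " descriptors>")
}

mesh_lookup <- function(thesaurus, heading) {
  thesaurus$nodes[[tolower(trimws(heading))]]
}

#' Explode a MeSH heading
#'
#' Returns the descriptor itself plus every more-specific descendant
#' descriptor name — the full subtree, unbounded depth — mirroring the Ovid
#' `exp` operator. `max_depth` limits how many levels below the heading are
#' included (the `exp` operator's depth is not standardized across systems;
#' the full subtree is the default).
#'
#' @param thesaurus A [mesh_thesaurus()].
#' @param heading Descriptor name (case-insensitive).
#' @param max_depth Non-negative integer or `Inf` (default): levels of
#'   descendants to include; `0` returns just the heading.
#' @return Character vector of descriptor names in preorder.
#' @export
mesh_explode <- function(thesaurus, heading, max_depth = Inf) {
  node <- mesh_lookup(thesaurus, heading)
  if (is.null(node)) {
    abort_boolrank(
      paste0("unknown MeSH descriptor: ", heading),
      "boolrank_unknown_descriptor"
    )
  }
  walk <- function(key, depth) {
    n <- thesaurus$nodes[[key]]
    out <- n$name
    if (depth < max_depth) {
      for (child in n$children) {
        out <- c(out, walk(child, depth + 1))
      }
    }
    out
  }
  walk(tolower(trimws(heading)), 0)
}

# Map of normalized phrase -> descriptor key, over descriptor names and entry
# terms; used by ranked-query MeSH expansion (exact phrase match).
mesh_phrase_map <- function(thesaurus) {
  out <- list()
  for (key in names(thesaurus$nodes)) {
    node <- thesaurus$nodes[[key]]
    for (phrase in c(node$name, node$entry_terms)) {
      norm <- normalize_phrase(phrase)
      if (nzchar(norm) && is.null(out[[norm]])) out[[norm]] <- key
    }
  }
  out
}

# ---- JSON I/O --------------------------------------------------------------

#' Read and write a thesaurus as nested JSON
#'
#' @param x For `write_mesh_json()`, a [mesh_thesaurus()]; for
#'   `read_mesh_json()`, a file path or JSON string.
#' @param path Optional output file path.
#' @return `read_mesh_json()` returns a `mesh_thesaurus`; `write_mesh_json()`
#'   returns the JSON text invisibly.
#' @export
write_mesh_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "mesh_thesaurus"))
  as_nested <- function(key) {
    node <- x$nodes[[key]]
    list(
      name = node$name,
      qualifiers = as.list(node$qualifiers),
      entry_terms = as.list(node$entry_terms),
      abbreviations = as.list(node$abbreviations),
      supplementary_terms = as.list(node$supplementary_terms),
      children = lapply(node$children, as_nested)
    )
  }
  json <- jsonlite::toJSON(
    lapply(x$roots, as_nested),
    auto_unbox = TRUE, pretty = TRUE
  )
  if (!is.null(path)) writeLines(json, path)
  invisible(as.character(json))
}

#' @rdname write_mesh_json
#' @export
read_mesh_json <- function(x) {
  txt <- if (length(x) == 1 && !grepl("[{\\[]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else {
    paste(x, collapse = "\n")
  }
  mesh_thesaurus(jsonlite::fromJSON(txt, simplifyVector = FALSE))
}

#' @exportS3Method generics::tidy
tidy.mesh_thesaurus <- function(x, ...) {
  keys <- names(x$nodes)
  tibble(
    name = vapply(keys, function(k) x$nodes[[k]]$name, character(1), USE.NAMES = FALSE),
    parent = vapply(keys, function(k) {
      p <- x$nodes[[k]]$parent
      if (is.na(p)) NA_character_ else x$nodes[[p]]$name
    }, character(1), USE.NAMES = FALSE),
    n_children = vapply(keys, function(k) length(x$nodes[[k]]$children), integer(1), USE.NAMES = FALSE),
    n_entry_terms = vapply(keys, function(k) length(x$nodes[[k]]$entry_terms), integer(1), USE.NAMES = FALSE)
  )
}
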