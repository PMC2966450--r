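# Internal helpers shared across modules.

# Deterministic ordering for document identifiers: numeric order when every id
# parses as a number (so "5" sorts before "17"), C-locale lexicographic
# otherwise. Every set-valued result in the package iterates in this order.
order_doc_ids <- function(ids) {
  if (length(ids) == 0) return(character())
  nums <- suppressWarnings(as.numeric(ids))
  if (!anyNA(nums)) {
    ids[order(nums, ids, method = "radix")]
  } else {
    ids[order(ids, method = "radix")]
  }
}

# Rank permutation of doc ids under the same ordering (used for tie-breaks).
doc_id_rank <- function(ids) {
  match(ids, order_doc_ids(unique(ids)))
}

abort_boolrank <- function(message, class, ...) {
  abort(message, class = c(class, "boolrank_error"), ...)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)
}

compact_chr <- function(x) x[nzchar(x)]
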