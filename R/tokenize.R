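#' Tokenize citation text
#'
#' Splits free text into the token stream used for indexing and ranked
#' querying: everything is lower-cased, tokens are maximal runs of letters and
#' digits, and hyphens joining two alphanumeric characters are kept inside a
#' token (`"electro-acupuncture"` stays whole, `"vitamin B6"` yields
#' `c("vitamin", "b6")`). No stemming is applied: in the Ovid dialect,
#' truncation is written explicitly in the query (`hyperactiv$`), so the
#' indexed vocabulary must preserve surface forms.
#'
#' @param text Character vector; each element is tokenized independently.
#' @param split_hyphens If `TRUE`, hyphens separate tokens instead of joining
#'   them. Used when tokenizing thesaurus-contributed expansion phrases, where
#'   compound entry terms should contribute their constituent words.
#' @return For length-1 input, a character vector of tokens; otherwise a list
#'   of character vectors.
#' @examples
#' tokenize("Attention Deficit Disorder")
#' tokenize("vitamin B6")
#' @export
tokenize <- function(text, split_hyphens = FALSE) {
  pattern <- if (split_hyphens) {
    "[a-z0-9]+"
  } else {
    "[a-z0-9]+(?:-[a-z0-9]+)*"
  }
  out <- lapply(tolower(as.character(text)), function(x) {
    if (is.na(x) || !nzchar(x)) return(character())
    m <- regmatches(x, gregexpr(pattern, x, perl = TRUE))[[1]]
    as.character(m)
  })
  if (length(out) == 1) out[[1]] else out
}

# Normalize a phrase for exact-match comparisons (thesaurus lookup):
# lower-case tokens joined by single spaces, hyphen-preserving.
normalize_phrase <- function(text) {
  vapply(
    as.character(text),
    function(x) paste(tokenize(x), collapse = " "),
    character(1),
    USE.NAMES = FALSE
  )
}
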