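# Random-case generators for property tests. All callers set the seed.

random_test_thesaurus <- function() {
  mesh_thesaurus(list(
    list(
      name = "Alpha Disease",
      qualifiers = c("therapy", "diagnosis"),
      entry_terms = "alpha syndrome",
      children = list(
        list(name = "Beta Disease", qualifiers = "therapy",
             children = list(list(name = "Gamma Disease"))),
        list(name = "Delta Disease")
      )
    ),
    list(
      name = "Needle Therapy",
      qualifiers = "methods",
      entry_terms = "needle treatment",
      children = list(list(name = "Ear Needle Therapy"))
    )
  ))
}

random_test_corpus <- function(n_docs, vocab = paste0("w", 1:20)) {
  headings <- c(
    "Alpha Disease", "Beta Disease", "Gamma Disease", "Delta Disease",
    "Needle Therapy", "Ear Needle Therapy"
  )
  quals <- c("therapy", "diagnosis", "methods")
  pts <- c("Journal Article", "Randomized Controlled Trial", "Review")
  rows <- lapply(seq_len(n_docs), function(i) {
    n_mh <- sample(0:3, 1)
    mh <- if (n_mh > 0) {
      picks <- sample(headings, n_mh)
      mesh_tibble_helper(
        picks, stats::runif(n_mh) < 0.3,
        lapply(picks, function(x) sample(quals, sample(0:2, 1)))
      )
    } else {
      mesh_tibble_helper(character(), logical(), list())
    }
    tibble::tibble(
      doc_id = as.character(i),
      title = paste(sample(vocab, sample(2:5, 1), replace = TRUE), collapse = " "),
      abstract = paste(sample(vocab, sample(6:25, 1), replace = TRUE), collapse = " "),
      mesh_headings = list(mh),
      publication_types = list(sample(pts, sample(1:2, 1))),
      language = sample(c("eng", "ger"), 1, prob = c(0.8, 0.2)),
      entry_date = if (stats::runif(1) < 0.9) {
        as.integer(sample(1990:2008, 1) * 10000 + sample(1:12, 1) * 100 + sample(1:28, 1))
      } else {
        NA_integer_
      },
      extra = list(character())
    )
  })
  validate_corpus(dplyr::bind_rows(rows))
}

# Random strategy text over the shared vocabulary/headings. Metadata filters
# (publication type, entry date, limit) are only ever used conjunctively or
# standalone, matching how published strategies use them.
random_test_strategy <- function(n_lines, vocab = paste0("w", 1:20)) {
  headings <- c("Alpha Disease", "Beta Disease", "Needle Therapy", "Gamma Disease")
  mutate_word <- function(w) {
    # inject a single-character wildcard
    cands <- seq(2, nchar(w))
    i <- cands[sample.int(length(cands), 1)]
    paste0(substr(w, 1, i - 1), "#", substr(w, i + 1, nchar(w)))
  }
  leaf_clause <- function() {
    w <- sample(vocab, 1)
    type <- sample(c(
      "term", "trunc", "wild", "phrase", "quoted", "field", "mesh",
      "exp", "adj", "sh", "fs"
    ), 1)
    switch(
      type,
      term = w,
      trunc = paste0(substr(w, 1, max(2, nchar(w) - 1)), "$"),
      wild = mutate_word(w),
      phrase = paste(sample(vocab, 2), collapse = " "),
      quoted = paste0('"', paste(sample(vocab, 2), collapse = " "), '"'),
      field = paste0(w, ".", sample(c("ti", "ab", "tw", "mp"), 1), "."),
      mesh = paste0(sample(headings, 1), "/"),
      exp = paste0("exp ", sample(headings, 1), "/"),
      adj = sprintf("(%s adj%d %s)", sample(vocab, 1), sample(1:3, 1), sample(vocab, 1)),
      sh = paste0(sample(c("alpha", "beta", "needle"), 1), ".sh."),
      fs = paste0(sample(c("therapy", "methods"), 1), ".fs.")
    )
  }
  combo_clause <- function(prev) {
    type <- sample(c("ref2", "range", "not", "filter", "limit"), 1,
                   prob = c(0.35, 0.25, 0.15, 0.1, 0.15))
    switch(
      type,
      ref2 = paste(sample(prev, 1), sample(c("and", "or"), 1), sample(prev, 1)),
      range = {
        a <- sample(prev, 1)
        larger <- prev[prev > a]
        if (length(larger) == 0) {
          paste(a, "or", a)
        } else {
          b <- larger[sample.int(length(larger), 1)]
          sprintf("%s/%d-%d", sample(c("or", "and"), 1), a, b)
        }
      },
      not = paste(sample(prev, 1), "not", sample(prev, 1)),
      filter = paste(sample(prev, 1), "and", sample(c(
        "trial.pt.", "review.pt.", "journal article.pt."
      ), 1)),
      limit = sprintf("limit %d to English language", max(prev))
    )
  }
  lines <- character(n_lines)
  for (i in seq_len(n_lines)) {
    clause <- if (i <= 2 || stats::runif(1) < 0.5) {
      leaf_clause()
    } else {
      combo_clause(seq_len(i - 1))
    }
    lines[i] <- paste(i, clause)
  }
  # make sure the final line ties the strategy together
  if (n_lines >= 3 && !grepl("^\\d+ (limit|or/|and/|\\d)", lines[n_lines])) {
    lines[n_lines] <- sprintf("%d or/1-%d", n_lines, n_lines - 1)
  }
  lines
}

# Random ranked lists and relevance sets for metric property tests.
random_ranked_case <- function(max_len = 60) {
  n <- sample(1:max_len, 1)
  ids <- as.character(sample(1000, n))
  relevant <- sample(ids, sample(1:max(1, n %/% 3), 1))
  list(ranked = ids, relevant = relevant)
}
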