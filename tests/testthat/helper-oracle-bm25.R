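# Naive per-document BM25 oracle: recomputes tf, df, lengths and averages by
# scanning raw citation text, with no inverted index. Mirrors the "any"
# scope (title + abstract + MeSH + publication-type tokens).

oracle_bm25_scores <- function(query_tokens, corpus, k1 = 1.2, b = 0.75) {
  docs <- lapply(seq_len(nrow(corpus)), function(i) {
    mh <- corpus$mesh_headings[[i]]
    mesh_tokens <- character()
    if (nrow(mh) > 0) {
      for (j in seq_len(nrow(mh))) {
        mesh_tokens <- c(
          mesh_tokens,
          tokenize(mh$descriptor[j]),
          unlist(lapply(mh$qualifiers[[j]], tokenize))
        )
      }
    }
    c(
      tokenize(corpus$title[i]), tokenize(corpus$abstract[i]),
      mesh_tokens, unlist(lapply(corpus$publication_types[[i]], tokenize))
    )
  })
  n <- nrow(corpus)
  lens <- vapply(docs, length, numeric(1))
  avg <- mean(lens)
  scores <- setNames(numeric(n), corpus$doc_id)
  for (token in unique(query_tokens)) {
    tf <- vapply(docs, function(toks) sum(toks == token), numeric(1))
    df <- sum(tf > 0)
    if (df == 0) next
    idf <- log((n - df + 0.5) / (df + 0.5) + 1)
    contrib <- idf * tf * (k1 + 1) / (tf + k1 * (1 - b + b * lens / avg))
    contrib[tf == 0] <- 0
    scores <- scores + contrib
  }
  scores
}
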