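query_of <- function(...) {
  build_query(review_topic("t", paste(...)), "T")
}

test_that("bm25 matches the closed form on a single-document corpus", {
  idx <- build_index(citation_corpus("1", title = "", abstract = "acupuncture"))
  q <- query_of("acupuncture")
  # N=1, df=1, tf=1, len=avglen: idf = ln(0.5/1.5 + 1), tf part = 2.2/2.2
  expect_equal(
    bm25_score(q, "1", idx),
    log(0.5 / 1.5 + 1) * (1 * 2.2) / (1 + 1.2)
  )
  expect_equal(bm25_score(query_of("absent"), "1", idx), 0)
  # duplicated query tokens contribute once
  expect_equal(
    bm25_score(query_of("acupuncture acupuncture"), "1", idx),
    bm25_score(q, "1", idx)
  )
  expect_error(
    bm25_score(structure(list(terms = tibble::tibble()), class = "ranked_query"),
               "1", idx),
    class = "boolrank_empty_query"
  )
})

test_that("ranking is tf-monotone at equal length and breaks ties by id", {
  corpus <- citation_corpus(
    doc_id = c("5", "17", "2"),
    abstract = c(
      "acupuncture acupuncture filler filler",
      "acupuncture filler filler filler",
      "filler filler filler filler"
    )
  )
  idx <- build_index(corpus)
  r <- rank_bm25(query_of("acupuncture"), idx)
  expect_equal(r$doc_id, c("5", "17"))

  # equal-score documents order by ascending (numeric) id
  corpus2 <- citation_corpus(
    doc_id = c("17", "5"),
    abstract = c("acupuncture filler", "acupuncture filler")
  )
  r2 <- rank_bm25(query_of("acupuncture"), build_index(corpus2))
  expect_equal(r2$doc_id, c("5", "17"))

  # cutoff larger than the matching set shortens the list
  expect_equal(nrow(rank_bm25(query_of("acupuncture"), idx, cutoff = 10)), 2)
})

test_that("rank output is deterministic, duplicate-free and score-sorted", {
  set.seed(51)
  for (rep in 1:10) {
    corpus <- random_test_corpus(sample(10:60, 1))
    idx <- build_index(corpus)
    q <- query_of(paste(sample(paste0("w", 1:20), 4), collapse = " "))
    r1 <- rank_bm25(q, idx)
    r2 <- rank_bm25(q, idx)
    expect_equal(r1, r2)
    expect_false(any(duplicated(r1$doc_id)))
    expect_true(all(diff(r1$score) <= 1e-12))
  }
})

test_that("bm25 equals the naive per-document oracle on random corpora", {
  set.seed(52)
  for (rep in 1:30) {
    corpus <- random_test_corpus(sample(5:60, 1))
    idx <- build_index(corpus)
    tokens <- sample(c(paste0("w", 1:20), "alpha", "therapy"), sample(2:6, 1))
    q <- query_of(paste(tokens, collapse = " "))
    want <- oracle_bm25_scores(q$terms$token, corpus)
    got <- vapply(corpus$doc_id, function(d) bm25_score(q, d, idx), numeric(1))
    expect_equal(got, want[names(got)], tolerance = 1e-12)
  }
})

test_that("adding a matching term at fixed length cannot lower the score", {
  corpus <- citation_corpus(
    doc_id = c("1", "2"),
    abstract = c(
      "acupuncture pain filler filler",
      "acupuncture pain pain filler"
    )
  )
  idx <- build_index(corpus)
  q <- query_of("acupuncture pain")
  expect_gte(bm25_score(q, "2", idx), bm25_score(q, "1", idx))
})

test_that("query schemes nest and scheme B strips operators from strategies", {
  strategy <- parse_strategy(fixture_path("adhd_strategy.txt"))
  topic <- review_topic(
    "adhd", "Acupuncture for ADHD",
    research_questions = "does acupuncture reduce hyperactivity",
    inclusion_criteria = "randomized trials in children",
    boolean_strategy = strategy
  )
  t_q <- build_query(topic, "T")
  expect_setequal(t_q$terms$token, c("acupuncture", "for", "adhd"))
  tr_q <- build_query(topic, "TR")
  trc_q <- build_query(topic, "TRC")
  expect_true(all(t_q$terms$token %in% tr_q$terms$token))
  expect_true(all(tr_q$terms$token %in% trc_q$terms$token))

  b_q <- build_query(topic, "B")
  expect_true(all(c("adhd", "addh", "adhs", "hyperactiv", "hyperkin") %in%
                    b_q$terms$token))
  expect_false(any(c("or", "and", "limit") %in% b_q$terms$token))
  expect_false(any(grepl("\\$", b_q$terms$token)))
  expect_error(build_query(review_topic("x", "title only"), "B"),
               class = "boolrank_format_error")
})

test_that("metadata method A honors tags and method B needs a folded index", {
  corpus <- meta_corpus()
  sep <- build_index(corpus, mode = "separate_fields")
  fold <- build_index(corpus, mode = "folded")

  q <- tag_tokens(query_of("electroacupuncture"), metadata = "electroacupuncture")
  # tagged metadata: only doc 1 carries the heading
  r <- rank_bm25(q, sep, method = "A")
  expect_equal(r$doc_id, "1")

  q_text <- tag_tokens(query_of("electroacupuncture"), text = "electroacupuncture")
  r_text <- rank_bm25(q_text, sep, method = "A")
  expect_equal(r_text$doc_id, "1") # title/abstract mention

  expect_error(rank_bm25(q, sep, method = "B_folded"), class = "boolrank_eval_error")
  expect_error(rank_bm25(q, fold, method = "A"), class = "boolrank_eval_error")
  expect_gt(nrow(rank_bm25(q, fold, method = "B_folded")), 0)
})

test_that("mesh expansion variants nest and match the rule-application fixture", {
  th <- fixture_thesaurus()
  q <- query_of("electroacupuncture relief")

  none <- expand_query_mesh(query_of("nomatchword"), th, "v3")
  expect_equal(none$terms$token, "nomatchword")

  v1 <- expand_query_mesh(q, th, "v1")
  expect_true("methods" %in% v1$terms$token)
  expect_false("electro" %in% v1$terms$token)

  v2 <- expand_query_mesh(q, th, "v2")
  expect_true(all(c("methods", "electro", "acupuncture") %in% v2$terms$token))

  v3 <- expand_query_mesh(q, th, "v3")
  expect_true(all(c("ea", "percutaneous") %in% v3$terms$token))
  expect_true(all(v1$terms$token %in% v2$terms$token))
  expect_true(all(v2$terms$token %in% v3$terms$token))

  # multiword descriptor matched through contiguous bigrams
  q2 <- expand_query_mesh(query_of("needle acupuncture therapy trial"), th, "v2")
  expect_true("treatment" %in% q2$terms$token ||
                "acupuncture treatment" %in% q2$terms$token)
})
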