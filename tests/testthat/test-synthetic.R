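test_that("bundles respect the requested tier structure", {
  bundle <- generate_bundle(generator_config(
    seed = 5, n_background = 60, tier_sizes = c(50, 10, 4),
    vocab_size = 300, doc_length = 30, mesh_tree_size = 15
  ))
  j <- bundle$judgments
  expect_equal(length(j$tier0), 50)
  expect_equal(length(j$tier1), 10)
  expect_equal(length(j$tier2), 4)
  expect_true(all(j$tier2 %in% j$tier1))
  expect_true(all(j$tier1 %in% j$tier0))
  expect_equal(nrow(bundle$corpus), 110)
})

test_that("infeasible generator configurations fail before generation", {
  expect_error(generator_config(tier_sizes = c(10, 20, 5)),
               class = "boolrank_infeasible_config")
  expect_error(generator_config(n_background = 2),
               class = "boolrank_infeasible_config")
  expect_error(
    generator_config(topic_term_emission = c(
      background = 0.02, tier0 = 0.15, tier1 = 2, tier2 = 0.6
    )),
    class = "boolrank_infeasible_config"
  )
})

test_that("the same seed reproduces a byte-identical bundle", {
  b1 <- generate_bundle(small_bundle_config(42))
  b2 <- generate_bundle(small_bundle_config(42))
  expect_identical(write_jsonl(b1$corpus), write_jsonl(b2$corpus))
  expect_identical(format_strategy(b1$strategy), format_strategy(b2$strategy))
  expect_identical(write_mesh_json(b1$thesaurus), write_mesh_json(b2$thesaurus))
  expect_identical(write_qrels(b1$judgments), write_qrels(b2$judgments))

  b3 <- generate_bundle(small_bundle_config(43))
  expect_false(identical(write_jsonl(b1$corpus), write_jsonl(b3$corpus)))
})

test_that("mean abstract length concentrates near its target", {
  bundle <- generate_bundle(generator_config(
    seed = 9, n_background = 1000, tier_sizes = c(10, 5, 2),
    doc_length = 120
  ))
  lens <- lengths(lapply(bundle$corpus$abstract, tokenize))
  expect_lt(abs(mean(lens) - 120) / 120, 0.1)
})

test_that("the generated strategy retrieves every tier-1 document", {
  for (seed in c(1, 2, 3)) {
    bundle <- generate_bundle(small_bundle_config(seed))
    idx <- build_index(bundle$corpus)
    hits <- result_set(evaluate_strategy(bundle$strategy, idx, bundle$thesaurus))
    expect_true(all(bundle$judgments$tier1 %in% hits))
  }
})

test_that("bundle files are written in every interchange format", {
  dir <- withr::local_tempdir()
  bundle <- generate_bundle(small_bundle_config(3))
  write_bundle(bundle, dir)
  expect_setequal(
    list.files(dir),
    c("corpus.nbib", "corpus.jsonl", "thesaurus.json", "topic.json",
      "strategy.txt", "qrels.txt")
  )
  expect_equal(read_jsonl(file.path(dir, "corpus.jsonl")), bundle$corpus)
  topic <- read_topic_json(file.path(dir, "topic.json"))
  expect_equal(topic$title, bundle$topic$title)
  expect_equal(
    format_strategy(topic$boolean_strategy),
    format_strategy(bundle$strategy)
  )
})

test_that("ranked retrieval finds tier-2 documents far above chance", {
  bundle <- generate_bundle(generator_config(seed = 42))
  idx <- build_index(bundle$corpus)
  n0 <- length(bundle$judgments$tier0)
  trc <- rank_bm25(build_query(bundle$topic, "TRC"), idx, cutoff = n0)
  r_trc <- recall_at(trc, bundle$judgments$tier2, n0)
  base <- random_order_baseline(
    result_set(evaluate_strategy(bundle$strategy, idx, bundle$thesaurus)),
    bundle$judgments$tier2, seed = 1, repeats = 100,
    metrics = list(r = function(rk, rel) recall_at(rk, rel, n0))
  )
  expect_gt(r_trc, base$mean)
})
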