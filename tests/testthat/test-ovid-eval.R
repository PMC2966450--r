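test_that("toy-corpus strategies evaluate to brute-force verified sets", {
  idx <- build_index(toy_corpus())

  res <- evaluate_strategy(
    parse_strategy(c("1 adhd", "2 child$", "3 1 and 2")), idx
  )
  expect_equal(result_set(res), "A")

  res2 <- evaluate_strategy(
    parse_strategy(c("1 adhd", "2 child$", "3 or/1-2")), idx
  )
  expect_equal(result_set(res2), c("A", "B", "C"))
})

test_that("adjacency respects the token-distance window", {
  idx <- build_index(citation_corpus(
    doc_id = "D", title = "x", abstract = "vitamin b6 supplementation"
  ))
  hit <- evaluate_strategy(parse_strategy("1 (vitamin adj1 b6).mp."), idx)
  expect_equal(result_set(hit), "D")
  miss <- evaluate_strategy(parse_strategy("1 (vitamin adj1 supplementation).mp."), idx)
  expect_equal(result_set(miss), character())
  # distance two is reachable with adj2
  hit2 <- evaluate_strategy(parse_strategy("1 (vitamin adj2 supplementation).mp."), idx)
  expect_equal(result_set(hit2), "D")
  # ordered dialect: right operand must follow the left
  rev <- evaluate_strategy(parse_strategy("1 (b6 adj1 vitamin).mp."), idx,
                           adj_mode = "ordered")
  expect_equal(result_set(rev), character())
})

test_that("limit lines filter by language, pubtype and entry date", {
  idx <- build_index(meta_corpus())
  # line 1 matches every document: 1 via "trial", 2 via "acupuncture",
  # 3 via "meridians", 4 via "review"
  universe <- "1 trial.mp. or acupuncture.mp. or meridians.mp. or review.mp."
  expect_equal(
    result_set(evaluate_strategy(parse_strategy(universe), idx)),
    as.character(1:4)
  )

  eng <- evaluate_strategy(
    parse_strategy(c(universe, "2 limit 1 to English language")), idx
  )
  expect_equal(result_set(eng), c("1", "2", "4"))

  rct <- evaluate_strategy(
    parse_strategy(c(universe, "2 limit 1 to randomized controlled trial")), idx
  )
  expect_equal(result_set(rct), "1")

  dated <- evaluate_strategy(
    parse_strategy(c(universe, "2 limit 1 to yr=2000-2008")), idx
  )
  # doc 3 has no entry date, doc 4 predates the window; both are excluded
  expect_equal(result_set(dated), c("1", "2"))
})

test_that("heading operators distinguish verbatim, major and exploded matches", {
  idx <- build_index(meta_corpus())
  th <- fixture_thesaurus()

  plain <- evaluate_strategy(parse_strategy("1 Electroacupuncture/"), idx, th)
  expect_equal(result_set(plain), "1")

  major <- evaluate_strategy(parse_strategy("1 *Electroacupuncture/"), idx, th)
  expect_equal(result_set(major), "1")
  major2 <- evaluate_strategy(parse_strategy("1 *Child/"), idx, th)
  expect_equal(result_set(major2), character())

  exploded <- evaluate_strategy(parse_strategy("1 exp Acupuncture Therapy/"), idx, th)
  expect_equal(result_set(exploded), c("1", "2", "3"))

  expect_error(
    evaluate_strategy(parse_strategy("1 exp Missing Heading/"), idx, th),
    class = "boolrank_unknown_descriptor"
  )
  expect_warning(
    res <- evaluate_strategy(parse_strategy("1 Missing Heading/"), idx, th),
    class = "boolrank_unknown_heading"
  )
  expect_equal(result_set(res), character())
})

test_that("field scopes nest monotonically from title to whole citation", {
  set.seed(31)
  for (rep in 1:10) {
    corpus <- random_test_corpus(sample(10:60, 1))
    idx <- build_index(corpus)
    w <- sample(paste0("w", 1:20), 1)
    sets <- lapply(c("ti", "tw", "mp"), function(f) {
      result_set(evaluate_strategy(
        parse_strategy(paste0("1 ", w, ".", f, ".")), idx
      ))
    })
    expect_true(all(sets[[1]] %in% sets[[2]]))
    expect_true(all(sets[[2]] %in% sets[[3]]))
  }
})

test_that("De Morgan and idempotence identities hold over random corpora", {
  set.seed(32)
  for (rep in 1:10) {
    corpus <- random_test_corpus(sample(10:80, 1))
    idx <- build_index(corpus)
    a <- sample(paste0("w", 1:20), 1)
    b <- sample(paste0("w", 1:20), 1)
    # universe line: every vocabulary token is "w" plus one or two digits
    lhs <- result_set(evaluate_strategy(parse_strategy(c(
      paste("1", a), paste("2", b), "3 1 or 2", "4 w# or w##", "5 4 not 3"
    )), idx))
    rhs <- result_set(evaluate_strategy(parse_strategy(c(
      paste("1", a), paste("2", b), "3 w# or w##",
      "4 3 not 1", "5 3 not 2", "6 4 and 5"
    )), idx))
    expect_equal(lhs, rhs)

    idem <- evaluate_strategy(parse_strategy(c(paste("1", a), "2 1 or 1")), idx)
    expect_equal(result_set(idem, 2), result_set(idem, 1))
  }
})

test_that("indexed evaluation matches the linear-scan oracle on random cases", {
  set.seed(33)
  th <- random_test_thesaurus()
  for (rep in 1:40) {
    corpus <- random_test_corpus(sample(8:60, 1))
    idx <- build_index(corpus)
    strategy <- parse_strategy(random_test_strategy(sample(3:12, 1)))
    got <- evaluate_strategy(strategy, idx, th)
    want <- oracle_eval_strategy(strategy, corpus, th)
    for (line in names(want)) {
      expect_equal(sort(got$sets[[line]]), want[[line]],
                   info = paste("line", line, "of:\n", format_strategy(strategy)))
    }
  }
})
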