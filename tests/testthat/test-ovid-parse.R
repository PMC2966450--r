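test_that("printed strategy syntax parses into the expected shapes", {
  s <- parse_strategy(fixture_path("adhd_strategy.txt"))
  td <- tidy(s)
  expect_equal(nrow(td), 17)

  expect_equal(td$node_type[td$line_no == 9], "rangeop")
  expect_equal(s$lines[[9]]$node$op, "or")
  expect_equal(s$lines[[9]]$node$from, 1L)
  expect_equal(s$lines[[9]]$node$to, 8L)

  n5 <- s$lines[[5]]$node
  expect_equal(n5$type, "term")
  expect_equal(n5$pattern, "hyperactiv")
  expect_true(n5$truncated)

  # line 14 chains three heading lookups with or
  n14 <- s$lines[[14]]$node
  expect_equal(n14$type, "or")
  expect_equal(
    vapply(n14$args, function(a) a$name, character(1)),
    c("acupuncture therapy", "acupuncture, ear", "electroacupuncture")
  )

  n17 <- s$lines[[17]]$node
  expect_equal(n17$type, "and")
  expect_equal(vapply(n17$args, function(a) a$n, integer(1)), c(9L, 13L, 16L))
})

test_that("adjacency groups with field suffixes parse and deparse faithfully", {
  s <- parse_strategy('23 (vitamin adj1 ("B6" or "B 6")).mp.')
  node <- s$lines[[1]]$node
  expect_equal(node$type, "adj")
  expect_equal(node$n, 1L)
  expect_equal(node$lhs$pattern, "vitamin")
  expect_equal(node$lhs$fields, "mp")
  expect_equal(node$rhs$type, "or")
  expect_equal(node$rhs$args[[2]]$slots[[2]]$pattern, "6")
  expect_equal(format_strategy(s), '23 (vitamin adj1 ("B6" or "B 6")).mp.')
})

test_that("compound field suffixes and truncation synonyms are understood", {
  s <- parse_strategy("25 random:.sh,pt.")
  node <- s$lines[[1]]$node
  expect_equal(node$fields, c("sh", "pt"))
  expect_true(node$truncated)
  expect_equal(node$trunc_char, ":")
  expect_equal(format_strategy(s), "25 random:.sh,pt.")
})

test_that("parse errors carry line information", {
  expect_error(parse_strategy(c("1 adhd", "1 child")),
               "strictly increasing", class = "boolrank_parse_error")
  expect_error(parse_strategy(c("1 adhd", "2 5 and 1")),
               "undefined or later line 5", class = "boolrank_parse_error")
  expect_error(parse_strategy(c("1 adhd", "2 child", "3 and/4-5")),
               "forward range", class = "boolrank_parse_error")
  expect_error(parse_strategy(c("1 adhd", "2 child", "3 foo and/1-2")),
               class = "boolrank_parse_error")
  expect_error(parse_strategy("1 adhd.xx."), "unknown field code",
               class = "boolrank_parse_error")
  expect_error(parse_strategy("1 (adhd"), "expected", class = "boolrank_parse_error")
  expect_warning(parse_strategy("1 a$"), class = "boolrank_short_stem")
})

test_that("limit clauses parse language, pubtype and date constraints", {
  s <- parse_strategy(c("1 adhd", "2 limit 1 to English language"))
  expect_equal(s$lines[[2]]$node$constraint,
               list(kind = "language", value = "eng", raw = "English language"))
  s2 <- parse_strategy(c("1 adhd", "2 limit 1 to randomized controlled trial"))
  expect_equal(s2$lines[[2]]$node$constraint$kind, "pubtype")
  s3 <- parse_strategy(c("1 adhd", "2 limit 1 to yr=1990-2000"))
  expect_equal(s3$lines[[2]]$node$constraint$value, c(19900000, 20009999))
})

test_that("format/parse round trip is stable on random strategies", {
  set.seed(21)
  for (rep in 1:30) {
    txt <- random_test_strategy(sample(3:12, 1))
    s <- parse_strategy(txt)
    s2 <- parse_strategy(format_strategy(s))
    expect_equal(format_strategy(s2), format_strategy(s))
  }
})
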