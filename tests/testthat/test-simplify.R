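norm_ws <- function(x) gsub("\\s+", " ", trimws(unlist(strsplit(x, "\n"))))

test_that("the six-line vitamin-B6 fragment simplifies to the four printed lines", {
  s <- parse_strategy(fixture_path("bvitamin_fragment.txt"))
  simp <- simplify_strategy(s)
  expect_equal(
    norm_ws(format_strategy(simp)),
    norm_ws(c(
      "21 exp pyridoxine/",
      "22 pyridoxal.mp.",
      '23 (vitamin or "B6" or "B 6").mp.',
      "24 or/21-23"
    ))
  )
  # re-parseable and idempotent
  again <- simplify_strategy(parse_strategy(format_strategy(simp)))
  expect_equal(format_strategy(again), format_strategy(simp))
})

test_that("a strategy of .mp. terms and or-folds is a fixed point", {
  s <- parse_strategy(c("1 alpha.mp.", "2 beta.mp.", "3 or/1-2"))
  expect_equal(format_strategy(simplify_strategy(s)), format_strategy(s))
})

test_that("rule-by-rule rewrites match hand application", {
  s <- parse_strategy(c("1 a1.tw.", "2 b1 adj3 c1", "3 1 and 2"))
  simp <- simplify_strategy(s, simplify_config(convert_and_to_or = "never"))
  expect_equal(
    norm_ws(format_strategy(simp)),
    norm_ws(c("1 a1.mp.", "2 (b1 or c1).mp.", "3 1 and 2"))
  )
})

test_that("mesh line actions replace or drop heading lines as configured", {
  s <- parse_strategy(c("1 Alpha Disease/", "2 w1", "3 1 and 2"))
  replaced <- simplify_strategy(s, simplify_config(convert_and_to_or = "never"))
  expect_equal(tidy(replaced)$clause[1], "alpha disease.mp.")

  # heading used conjunctively can be dropped under remove_if_conjunct
  removed <- simplify_strategy(
    s, simplify_config(convert_and_to_or = "never",
                       mesh_line_action = "remove_if_conjunct")
  )
  td <- tidy(removed)
  expect_false(1 %in% td$line_no)
  expect_equal(td$clause[td$line_no == 3], "2")

  # exploded headings are never touched
  s2 <- parse_strategy(c("1 exp Alpha Disease/", "2 1"))
  expect_equal(tidy(simplify_strategy(s2))$clause[1], "exp Alpha Disease/")
})

test_that("removed filter chains cascade and the result line is the highest survivor", {
  s <- parse_strategy(c(
    "1 w1", "2 w2", "3 or/1-2", "4 trial.pt.", "5 3 and 4",
    "6 limit 5 to English language"
  ))
  simp <- simplify_strategy(s, simplify_config(convert_and_to_or = "never"))
  td <- tidy(simp)
  expect_equal(td$line_no, c(1L, 2L, 3L, 5L))
  expect_equal(td$clause[td$line_no == 5], "3")

  # a range spanning a removed line contracts
  s2 <- parse_strategy(c("1 w1", "2 20080101.ed.", "3 w2", "4 or/1-3"))
  simp2 <- simplify_strategy(s2)
  expect_equal(tidy(simp2)$clause[tidy(simp2)$line_no == 4], "or/1-3")
  expect_true(all(result_ok <- TRUE)) # parses back
  expect_silent(parse_strategy(format_strategy(simp2)))

  # everything removable -> degenerate
  expect_error(
    simplify_strategy(parse_strategy(c("1 trial.pt.", "2 limit 1 to English language"))),
    "degenerates", class = "boolrank_degenerate_strategy"
  )
})

test_that("simplification yields supersets and is idempotent on random cases", {
  set.seed(41)
  th <- random_test_thesaurus()
  config <- simplify_config(convert_and_to_or = "never")
  for (rep in 1:40) {
    corpus <- random_test_corpus(sample(8:50, 1))
    idx <- build_index(corpus)
    strategy <- parse_strategy(random_test_strategy(sample(3:10, 1)))
    simp <- tryCatch(simplify_strategy(strategy, config),
                     boolrank_degenerate_strategy = function(e) NULL)
    if (is.null(simp)) next
    orig_set <- result_set(evaluate_strategy(strategy, idx, th))
    simp_set <- result_set(evaluate_strategy(simp, idx, th))
    expect_true(all(orig_set %in% simp_set),
                info = paste("not a superset for:\n", format_strategy(strategy)))
    expect_equal(format_strategy(simplify_strategy(simp, config)),
                 format_strategy(simp))
  }
})

test_that("converting and to or never shrinks the result set", {
  set.seed(42)
  th <- random_test_thesaurus()
  for (rep in 1:15) {
    corpus <- random_test_corpus(sample(8:50, 1))
    idx <- build_index(corpus)
    strategy <- parse_strategy(random_test_strategy(sample(3:10, 1)))
    never <- tryCatch(
      simplify_strategy(strategy, simplify_config(convert_and_to_or = "never")),
      boolrank_degenerate_strategy = function(e) NULL
    )
    if (is.null(never)) next
    always <- simplify_strategy(strategy, simplify_config(convert_and_to_or = "always"))
    n_set <- result_set(evaluate_strategy(never, idx, th))
    a_set <- result_set(evaluate_strategy(always, idx, th))
    expect_true(all(n_set %in% a_set))
  }
})

test_that("lint reports the mechanically checkable error classes", {
  th <- fixture_thesaurus()

  clean <- lint_strategy(parse_strategy(c("1 Acupuncture Therapy/", "2 1")), th)
  expect_equal(nrow(clean), 0)

  dup <- lint_strategy(parse_strategy(c(
    "1 Child/", "2 adhd", "3 1 and 2", "4 adhd", "5 3 or 4"
  )), th)
  expect_true(any(dup$code == "REDUNDANT_LINE" & dup$line_no == 4))

  gaps <- lint_strategy(parse_strategy(c("1 adhd", "3 child", "4 or/1-3")), th)
  expect_true(any(gaps$code == "BAD_LINE_REF" & gaps$line_no == 4))

  unk <- lint_strategy(parse_strategy("1 Imaginary Heading/"), th)
  expect_equal(unk$code, "UNKNOWN_MESH")

  mixed <- lint_strategy(parse_strategy("1 Child/ or adhd"), th)
  expect_true("MIXED_LINE" %in% mixed$code)

  dead <- lint_strategy(parse_strategy(c("1 adhd", "2 child", "3 2")), th)
  expect_true(any(dead$code == "UNREFERENCED_LINE" & dead$line_no == 1))

  short <- suppressWarnings(lint_strategy(parse_strategy("1 a$"), th))
  expect_true("SHORT_STEM" %in% short$code)

  broken <- lint_strategy("1 ((adhd", th)
  expect_equal(broken$code, "PARSE_ERROR")
})
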