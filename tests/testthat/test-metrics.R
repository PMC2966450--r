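test_that("precision and recall at depth follow their definitions", {
  ranked <- as.character(1:20)
  relevant <- as.character(1:10)
  expect_equal(precision_at(ranked, relevant, 10), 1.0)
  expect_equal(recall_at(ranked, relevant, 10), 1.0)
  expect_equal(precision_at(ranked, relevant, 20), 0.5)

  # list shorter than N: precision denominator is the list length
  expect_equal(precision_at(as.character(1:4), as.character(1:2), 10), 0.5)
  expect_error(recall_at(ranked, character(), 5), class = "boolrank_eval_error")
})

test_that("the P/R identity holds over random lists", {
  set.seed(61)
  for (rep in 1:200) {
    case <- random_ranked_case()
    n <- sample(1:80, 1)
    p <- precision_at(case$ranked, case$relevant, n)
    r <- recall_at(case$ranked, case$relevant, n)
    expect_equal(r, p * min(n, length(case$ranked)) / length(case$relevant))
  }
})

test_that("unordered set precision reproduces the screening-burden arithmetic", {
  retrieved <- as.character(seq_len(1643))
  relevant <- as.character(seq_len(9))
  p <- set_precision(retrieved, relevant)
  expect_equal(p, 9 / 1643)
  expect_equal(round(100 * p, 1), 0.5)
  expect_equal(set_recall(retrieved, relevant), 1)
})

test_that("rank-biased precision matches closed forms", {
  expect_equal(as.numeric(rbp(character(), "x", 0.5)), 0)
  expect_equal(as.numeric(rbp(c("n1", "n2"), "x", 0.9)), 0)
  for (p in c(0.5, 0.9, 0.99)) {
    expect_equal(as.numeric(rbp(c("r", "n"), "r", p)), 1 - p)
  }
  expect_equal(as.numeric(rbp(c("a", "b"), c("a", "b"), 0.99)),
               0.01 * (1 + 0.99))
  expect_equal(attr(rbp(c("a", "b"), "a", 0.99), "residual"), 0.99^2)
  expect_error(rbp("a", "a", 1), class = "boolrank_eval_error")
  expect_error(rbp("a", "a", 0), class = "boolrank_eval_error")
})

test_that("rbp is bounded and non-decreasing in list depth", {
  set.seed(62)
  for (rep in 1:100) {
    case <- random_ranked_case()
    p <- sample(c(0.5, 0.9, 0.99), 1)
    full <- as.numeric(rbp(case$ranked, case$relevant, p))
    expect_gte(full, 0)
    expect_lte(full, 1 - p^length(case$ranked) + 1e-12)
    cut <- sample(seq_along(case$ranked), 1)
    expect_lte(as.numeric(rbp(case$ranked[seq_len(cut)], case$relevant, p)),
               full + 1e-12)
  }
})

test_that("the tolerance counter stops exactly where hand simulation says", {
  all_rel <- tolerance_run(c("a", "b", "c"), c("a", "b", "c"), tau = 0)
  expect_equal(all_rel$recall_at_stop, 1.0)
  expect_true(all_rel$exhausted)

  # [R,N,N,R,N,N,N] with tau = 2: third consecutive non-relevant at rank 7
  lst <- c("r1", "n1", "n2", "r2", "n3", "n4", "n5")
  run <- tolerance_run(lst, c("r1", "r2"), tau = 2)
  expect_equal(run$stop_rank, 7L)
  expect_equal(run$violating_rank, 7L)
  expect_equal(run$recall_at_stop, 1.0)

  # [N,N,N,R] with tau = 2 stops at rank 3 before reaching the relevant item
  run2 <- tolerance_run(c("n1", "n2", "n3", "r1"), "r1", tau = 2)
  expect_equal(run2$stop_rank, 3L)
  expect_equal(run2$recall_at_stop, 0.0)

  # non-strict reading stops one item earlier
  run3 <- tolerance_run(c("n1", "n2", "n3", "r1"), "r1", tau = 2, strict = FALSE)
  expect_equal(run3$stop_rank, 2L)
})

test_that("tolerance curves are monotone in the threshold", {
  curve <- tolerance_curve(c("n", "r"), "r", 0)
  expect_equal(curve$recall_at_stop, 0)

  lst <- c("r1", "n1", "n2", "r2", "n3", "n4", "n5")
  curve2 <- tolerance_curve(lst, c("r1", "r2"), c(1, 2, 3))
  expect_equal(curve2$recall_at_stop, c(0.5, 1.0, 1.0))
  expect_equal(curve2$stop_rank, c(3L, 7L, 7L))

  set.seed(63)
  for (rep in 1:100) {
    case <- random_ranked_case()
    curve <- tolerance_curve(case$ranked, case$relevant, 0:10)
    expect_true(all(diff(curve$recall_at_stop) >= 0))
    expect_true(all(diff(curve$stop_rank) >= 0))
  }
})

test_that("the random-order baseline is seeded and matches its expectation", {
  single <- random_order_baseline("only", "only", seed = 1, repeats = 5)
  expect_equal(unique(unlist(single$values[single$metric == "recall"])), 1)

  a <- random_order_baseline(as.character(1:50), as.character(1:5),
                             seed = 99, repeats = 20)
  b <- random_order_baseline(as.character(1:50), as.character(1:5),
                             seed = 99, repeats = 20)
  expect_equal(a, b)

  # E[R@N] of a random permutation = min(N, |S|)/|S| * R_full
  s <- as.character(1:40)
  rel <- as.character(1:8)
  n <- 10
  base <- random_order_baseline(
    s, rel, seed = 7, repeats = 1000,
    metrics = list(r_at_n = function(ranked, relevant) recall_at(ranked, relevant, n))
  )
  expect_equal(base$mean, n / 40 * 1.0, tolerance = 0.05)
})

test_that("evaluate_run produces the tiered metric table layout", {
  j <- tier_judgments("t", tier0 = as.character(1:30),
                      tier1 = as.character(1:10), tier2 = as.character(1:4))
  tab <- evaluate_run(as.character(1:20), j, tier = 2, cutoffs = c(5, 20))
  expect_named(tab, c("tier", "rbp", "p_at_5", "r_at_5", "p_at_20", "r_at_20"))
  expect_equal(tab$r_at_5, 1)
  expect_equal(tab$p_at_5, 4 / 5)
})

test_that("trec run and qrels files round trip", {
  j <- tier_judgments("t1", tier0 = c("9", "5", "3"), tier1 = c("5", "3"),
                      tier2 = "3")
  qr <- write_qrels(j)
  expect_setequal(qr, c("t1 0 9 1", "t1 0 5 2", "t1 0 3 3"))
  j2 <- read_qrels(qr)
  expect_equal(j2$tier0, j$tier0)
  expect_equal(j2$tier2, j$tier2)

  ranked <- tibble::tibble(doc_id = c("5", "9"), score = c(2.5, 1.0), rank = 1:2)
  lines <- write_trec_run(ranked, topic_id = "t1", run_tag = "test")
  back <- read_trec_run(lines)
  expect_equal(back$doc_id, c("5", "9"))
  expect_equal(back$score, c(2.5, 1.0))
  expect_error(read_trec_run("bad line"), class = "boolrank_format_error")
})
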