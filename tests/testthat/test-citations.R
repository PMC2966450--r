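test_that("nbib parsing handles records, headings, and both tag spacings", {
  expect_equal(nrow(read_nbib("")), 0)

  rec <- c(
    "PMID- 1",
    "TI  - Acupuncture for ADHD",
    "AB  - a trial",
    "MH  - *Electroacupuncture",
    "MH- Child/therapy",
    "PT  - Randomized Controlled Trial",
    "LA  - eng"
  )
  corpus <- read_nbib(rec)
  expect_equal(nrow(corpus), 1)
  expect_equal(corpus$doc_id, "1")
  expect_equal(corpus$title, "Acupuncture for ADHD")
  mh <- corpus$mesh_headings[[1]]
  expect_equal(mh$descriptor, c("Electroacupuncture", "Child"))
  expect_equal(mh$major, c(TRUE, FALSE))
  expect_equal(mh$qualifiers, list(character(), "therapy"))
  expect_equal(corpus$publication_types[[1]], "Randomized Controlled Trial")
})

test_that("nbib continuation lines and unknown tags are preserved", {
  rec <- c(
    "PMID- 9",
    "TI  - A long",
    "      title continued",
    "AD  - Some Affiliation"
  )
  corpus <- read_nbib(rec)
  expect_equal(corpus$title, "A long title continued")
  expect_equal(unname(corpus$extra[[1]]["AD"]), "Some Affiliation")

  roundtrip <- read_nbib(strsplit(write_nbib(corpus), "\n")[[1]])
  expect_equal(roundtrip$extra[[1]], corpus$extra[[1]])
})

test_that("nbib errors name the offending record", {
  expect_error(read_nbib(c("TI  - no id")), "record 1 has no PMID",
               class = "boolrank_format_error")
  expect_error(
    read_nbib(c("PMID- 7", "", "PMID- 7")),
    "duplicate doc_id",
    class = "boolrank_duplicate_id"
  )
})

test_that("jsonl round trip is the identity and errors cite line numbers", {
  expect_equal(nrow(read_jsonl(write_jsonl(citation_corpus(character())))), 0)

  corpus <- meta_corpus()
  expect_equal(read_jsonl(write_jsonl(corpus)), corpus)

  lines <- c(write_jsonl(corpus)[1:2], "not json")
  expect_error(read_jsonl(lines), "line 3", class = "boolrank_format_error")
})

test_that("nbib round trip preserves all citation fields", {
  corpus <- meta_corpus()
  rt <- read_nbib(strsplit(write_nbib(corpus), "\n")[[1]])
  expect_equal(rt$doc_id, corpus$doc_id)
  expect_equal(rt$title, corpus$title)
  expect_equal(rt$abstract, corpus$abstract)
  expect_equal(rt$mesh_headings, corpus$mesh_headings)
  expect_equal(rt$language, corpus$language)
  expect_equal(rt$entry_date, corpus$entry_date)
})

test_that("round trips hold on randomly generated corpora", {
  set.seed(101)
  for (rep in 1:10) {
    corpus <- random_test_corpus(sample(1:30, 1))
    expect_equal(read_jsonl(write_jsonl(corpus)), corpus)
    rt <- read_nbib(strsplit(write_nbib(corpus), "\n")[[1]])
    expect_equal(rt$mesh_headings, corpus$mesh_headings)
    expect_equal(rt$abstract, corpus$abstract)
  }
})

test_that("tokenizer lowercases, keeps digits and intra-token hyphens", {
  expect_equal(tokenize("Attention Deficit Disorder"),
               c("attention", "deficit", "disorder"))
  expect_equal(tokenize("vitamin B6"), c("vitamin", "b6"))
  expect_equal(tokenize(""), character())
  expect_equal(tokenize("electro-acupuncture"), "electro-acupuncture")
  expect_equal(tokenize("electro-acupuncture", split_hyphens = TRUE),
               c("electro", "acupuncture"))
})
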