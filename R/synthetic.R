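#' Configuration for the synthetic review-search generator
#'
#' The generator emulates the structure of a systematic-review test
#' collection at desk scale: a background corpus of citations with Zipfian
#' vocabulary, a review topic with nested tiers of relevant documents
#' (screening candidates, title/abstract keeps, final includes), a small
#' MeSH-like thesaurus whose topic-linked descriptors tag the relevant
#' documents, and a three-facet Ovid strategy whose result set contains every
#' tier-1 document by construction.
#'
#' Topic signal is controlled by per-tier emission probabilities: each
#' content token of an abstract is drawn from the topic term pool with the
#' tier's probability, otherwise from the Zipfian background vocabulary.
#'
#' @param seed Integer seed; the whole bundle is a deterministic function of
#'   it.
#' @param n_background Background (non-candidate) corpus size.
#' @param tier_sizes Integer triple `(n0, n1, n2)` with `n2 <= n1 <= n0`.
#' @param vocab_size Background vocabulary size.
#' @param zipf_exponent Zipf exponent of the background term distribution.
#' @param topic_term_emission Named probabilities for `background`, `tier0`,
#'   `tier1`, `tier2`.
#' @param doc_length Mean abstract length in tokens (Poisson).
#' @param mesh_tree_size Number of thesaurus descriptors.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 42,
                             n_background = 400,
                             tier_sizes = c(50, 12, 5),
                             vocab_size = 2000,
                             zipf_exponent = 1.1,
                             topic_term_emission = c(
                               background = 0.02, tier0 = 0.15,
                               tier1 = 0.35, tier2 = 0.6
                             ),
                             doc_length = 120,
                             mesh_tree_size = 60) {
  stopifnot(length(tier_sizes) == 3)
  tier_sizes <- as.integer(tier_sizes)
  if (tier_sizes[3] > tier_sizes[2] || tier_sizes[2] > tier_sizes[1]) {
    abort_boolrank(
      "tier sizes must be nested: n2 <= n1 <= n0",
      "boolrank_infeasible_config"
    )
  }
  if (tier_sizes[1] < 1 || n_background < 10 || vocab_size < 50 ||
      mesh_tree_size < 10 || doc_length < 10) {
    abort_boolrank("generator sizes too small to be feasible", "boolrank_infeasible_config")
  }
  if (any(topic_term_emission < 0) || any(topic_term_emission > 1)) {
    abort_boolrank("emission probabilities must lie in [0, 1]", "boolrank_infeasible_config")
  }
  structure(
    list(
      seed = as.integer(seed),
      n_background = as.integer(n_background),
      tier_sizes = tier_sizes,
      vocab_size = as.integer(vocab_size),
      zipf_exponent = zipf_exponent,
      topic_term_emission = topic_term_emission,
      doc_length = doc_length,
      mesh_tree_size = as.integer(mesh_tree_size)
    ),
    class = "generator_config"
  )
}

#' Generate a complete synthetic review-search bundle
#'
#' @param config A [generator_config()].
#' @return A `synthetic_bundle`: list with `corpus` (citation tibble),
#'   `thesaurus`, `topic`, `strategy` (parsed), `judgments`, and the
#'   `config`. The same seed always yields a byte-identical bundle.
#' @export
generate_bundle <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  vocab <- make_vocabulary(config$vocab_size)
  zipf_w <- 1 / seq_len(config$vocab_size)^config$zipf_exponent

  # Topic term pool: condition, intervention, and outcome facets, disjoint
  # from the background vocabulary so emission probabilities fully control
  # the signal.
  pool <- list(
    condition = make_vocabulary(4, prefix = "cond"),
    intervention = make_vocabulary(4, prefix = "intv"),
    outcome = make_vocabulary(4, prefix = "outc")
  )
  topic_terms <- unlist(pool, use.names = FALSE)

  thesaurus <- make_synthetic_thesaurus(pool, vocab, config$mesh_tree_size)
  cond_root <- paste0(title_case(pool$condition[1]), " Disorder")
  intv_root <- paste0(title_case(pool$intervention[1]), " Therapy")
  intv_children <- paste0(title_case(pool$intervention[2:3]), " Therapy")

  n0 <- config$tier_sizes[1]; n1 <- config$tier_sizes[2]; n2 <- config$tier_sizes[3]
  n_total <- config$n_background + n0
  doc_ids <- as.character(seq_len(n_total))
  labels <- rep("background", n_total)
  cand <- sample(doc_ids, n0)
  labels[match(cand, doc_ids)] <- "tier0"
  keep1 <- sample(cand, n1)
  labels[match(keep1, doc_ids)] <- "tier1"
  keep2 <- sample(keep1, n2)
  labels[match(keep2, doc_ids)] <- "tier2"

  emission <- config$topic_term_emission
  generic_headings <- setdiff(
    vapply(names(thesaurus$nodes), function(k) thesaurus$nodes[[k]]$name, character(1)),
    c(cond_root, intv_root, intv_children)
  )
  qualifier_pool <- c("therapy", "diagnosis", "epidemiology", "methods")
  pubtype_pool <- c("Journal Article", "Review", "Randomized Controlled Trial", "Letter")

  draw_tokens <- function(n, p_topic) {
    topic_mask <- runif(n) < p_topic
    out <- character(n)
    n_topic <- sum(topic_mask)
    if (n_topic > 0) out[topic_mask] <- sample(topic_terms, n_topic, replace = TRUE)
    if (n - n_topic > 0) {
      out[!topic_mask] <- sample(vocab, n - n_topic, replace = TRUE, prob = zipf_w)
    }
    out
  }

  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    label <- labels[i]
    p_topic <- unname(emission[if (label == "background") "background" else label])
    abs_len <- max(20L, rpois(1, config$doc_length))
    abstract <- paste(draw_tokens(abs_len, p_topic), collapse = " ")
    title <- paste(draw_tokens(8L, p_topic), collapse = " ")

    descriptors <- sample(generic_headings, sample(2:4, 1))
    if (label %in% c("tier0", "tier1", "tier2")) {
      descriptors <- c(cond_root, descriptors)
    }
    if (label %in% c("tier1", "tier2")) {
      descriptors <- c(sample(c(intv_root, intv_children), 1), descriptors)
    } else if (label == "tier0" && runif(1) < 0.3) {
      # some screening candidates mention the intervention only in text
      abstract <- paste(abstract, pool$intervention[1])
    }
    mh <- mesh_tibble(
      descriptors,
      runif(length(descriptors)) < 0.2,
      lapply(descriptors, function(d) {
        sample(qualifier_pool, sample(0:2, 1))
      })
    )
    language <- if (label %in% c("tier1", "tier2")) {
      "eng"
    } else {
      sample(c("eng", "ger", "fre"), 1, prob = c(0.9, 0.06, 0.04))
    }
    pt <- if (label == "tier2") {
      "Randomized Controlled Trial"
    } else {
      sample(pubtype_pool, 1, prob = c(0.6, 0.15, 0.15, 0.1))
    }
    rows[[i]] <- tibble(
      doc_id = doc_ids[i],
      title = title,
      abstract = abstract,
      mesh_headings = list(mh),
      publication_types = list(pt),
      language = language,
      entry_date = as.integer(sample(1995:2008, 1) * 10000 +
                                sample(1:12, 1) * 100 + sample(1:28, 1)),
      extra = list(character())
    )
  }
  corpus <- validate_corpus(dplyr::bind_rows(rows))

  title_txt <- paste(
    pool$intervention[1], "for", pool$condition[1], "disorder in",
    pool$condition[2], "patients"
  )
  rq_txt <- paste(
    c(
      "does", pool$intervention[1], "improve", pool$outcome[1], "and",
      pool$outcome[2], "in patients with", pool$condition[1], "disorder",
      "compared with", pool$intervention[2], "or placebo",
      draw_tokens(12L, 0.3)
    ),
    collapse = " "
  )
  ic_txt <- paste(
    c(
      "randomized controlled trials of", pool$intervention[1], "or",
      pool$intervention[3], "in", pool$condition[1], "disorder measuring",
      pool$outcome[1], pool$outcome[2], "or", pool$outcome[3],
      "published in english",
      draw_tokens(30L, 0.3)
    ),
    collapse = " "
  )

  strategy_text <- c(
    paste0("1 ", cond_root, "/"),
    paste0("2 ", pool$condition[1]),
    paste0("3 ", substr(pool$condition[2], 1, nchar(pool$condition[2]) - 1), "$"),
    "4 or/1-3",
    paste0("5 exp ", intv_root, "/"),
    paste0("6 ", substr(pool$intervention[1], 1, nchar(pool$intervention[1]) - 1), "$"),
    "7 or/5-6",
    "8 4 and 7",
    "9 limit 8 to English language"
  )
  strategy <- parse_strategy(strategy_text)

  topic <- review_topic(
    topic_id = paste0("synth-", config$seed),
    title = title_txt,
    research_questions = rq_txt,
    inclusion_criteria = ic_txt,
    boolean_strategy = strategy
  )
  judgments <- tier_judgments(
    topic$topic_id,
    tier0 = doc_ids[labels %in% c("tier0", "tier1", "tier2")],
    tier1 = doc_ids[labels %in% c("tier1", "tier2")],
    tier2 = doc_ids[labels == "tier2"]
  )

  structure(
    list(
      corpus = corpus,
      thesaurus = thesaurus,
      topic = topic,
      strategy = strategy,
      judgments = judgments,
      config = config,
      generator_version = "1"
    ),
    class = "synthetic_bundle"
  )
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(
    "<synthetic_bundle seed=", x$config$seed, "> ",
    nrow(x$corpus), " citations, tiers ",
    paste(x$config$tier_sizes, collapse = "/"), "\n",
    sep = ""
  )
  invisible(x)
}

# Pronounceable deterministic pseudo-words (consonant-vowel syllables).
make_vocabulary <- function(n, prefix = NULL) {
  consonants <- strsplit("bcdfglmnprstvz", "")[[1]]
  vowels <- strsplit("aeiou", "")[[1]]
  words <- character(n)
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    repeat {
      k <- sample(2:4, 1)
      w <- paste0(sample(consonants, k, replace = TRUE),
                  sample(vowels, k, replace = TRUE), collapse = "")
      if (!is.null(prefix)) w <- paste0(prefix, w)
      if (is.null(seen[[w]])) {
        seen[[w]] <- TRUE
        words[i] <- w
        break
      }
    }
  }
  words
}

title_case <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

make_synthetic_thesaurus <- function(pool, vocab, size) {
  cond_root <- list(
    name = paste0(title_case(pool$condition[1]), " Disorder"),
    qualifiers = c("diagnosis", "epidemiology", "therapy"),
    entry_terms = c(
      paste(pool$condition[1], "syndrome"),
      paste0(pool$condition[1], "-", pool$condition[2])
    ),
    children = list(
      list(
        name = paste0(title_case(pool$condition[3]), " Disorder"),
        qualifiers = c("diagnosis", "therapy")
      )
    )
  )
  intv_root <- list(
    name = paste0(title_case(pool$intervention[1]), " Therapy"),
    qualifiers = c("methods", "adverse effects"),
    entry_terms = c(
      paste0(pool$intervention[1], "-", pool$intervention[2]),
      paste(pool$intervention[1], "treatment")
    ),
    abbreviations = toupper(substr(pool$intervention[1], 1, 3)),
    children = list(
      list(
        name = paste0(title_case(pool$intervention[2]), " Therapy"),
        qualifiers = "methods"
      ),
      list(
        name = paste0(title_case(pool$intervention[3]), " Therapy"),
        qualifiers = "methods",
        supplementary_terms = paste(pool$intervention[3], "agents")
      )
    )
  )
  n_generic <- max(0L, size - 5L)
  generic_names <- unique(title_case(make_vocabulary(n_generic * 2, prefix = "g")))
  generic_names <- head(generic_names, n_generic)
  generic <- lapply(generic_names, function(nm) {
    list(name = nm, qualifiers = sample(c("therapy", "methods", "diagnosis"), 1))
  })
  # Random shallow forest over the generic descriptors.
  roots <- list(cond_root, intv_root)
  i <- 1
  while (i <= length(generic)) {
    n_children <- min(sample(0:3, 1), length(generic) - i)
    node <- generic[[i]]
    if (n_children > 0) {
      node$children <- generic[(i + 1):(i + n_children)]
    }
    roots[[length(roots) + 1]] <- node
    i <- i + n_children + 1
  }
  mesh_thesaurus(roots)
}

#' Write a synthetic bundle to disk
#'
#' Writes `corpus.nbib`, `corpus.jsonl`, `thesaurus.json`, `topic.json`,
#' `strategy.txt` and `qrels.txt` into `dir`.
#'
#' @param bundle A [generate_bundle()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_nbib(bundle$corpus, file.path(dir, "corpus.nbib"))
  write_jsonl(bundle$corpus, file.path(dir, "corpus.jsonl"))
  write_mesh_json(bundle$thesaurus, file.path(dir, "thesaurus.json"))
  write_topic_json(bundle$topic, file.path(dir, "topic.json"))
  writeLines(format_strategy(bundle$strategy), file.path(dir, "strategy.txt"))
  write_qrels(bundle$judgments, file.path(dir, "qrels.txt"))
  invisible(dir)
}
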