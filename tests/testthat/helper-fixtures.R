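# Shared fixtures built in code.

fixture_path <- function(name) {
  system.file("extdata", name, package = "boolrank")
}

fixture_thesaurus <- function() {
  read_mesh_json(fixture_path("acupuncture_subtree.json"))
}

# Three-document toy corpus used across Boolean evaluator tests.
toy_corpus <- function() {
  citation_corpus(
    doc_id = c("A", "B", "C"),
    title = c("adhd in children", "adult adhd", "asthma in children"),
    abstract = c(
      "a trial of acupuncture for adhd",
      "vitamin b6 supplementation in adults",
      "asthma management guidance"
    ),
    language = c("eng", "ger", "eng")
  )
}

# Corpus with controlled MeSH headings, languages, dates and pubtypes.
meta_corpus <- function() {
  citation_corpus(
    doc_id = as.character(1:4),
    title = c(
      "electroacupuncture trial", "acupuncture for pain",
      "meridian mapping", "drug therapy review"
    ),
    abstract = c(
      "electroacupuncture in children",
      "ear acupuncture analgesia",
      "meridians and acupuncture points",
      "pharmacological management"
    ),
    mesh_headings = list(
      mesh_tibble_helper("Electroacupuncture", TRUE, list("methods")),
      mesh_tibble_helper(c("Acupuncture, Ear", "Child"), c(FALSE, FALSE),
                         list(character(), "therapy")),
      mesh_tibble_helper("Meridians", FALSE, list(character())),
      mesh_tibble_helper("Child", FALSE, list("drug effects"))
    ),
    publication_types = list(
      "Randomized Controlled Trial", "Journal Article",
      "Journal Article", "Review"
    ),
    language = c("eng", "eng", "ger", "eng"),
    entry_date = c(20080115L, 20050601L, NA, 19991231L)
  )
}

mesh_tibble_helper <- function(descriptor, major, qualifiers) {
  tibble::tibble(
    descriptor = descriptor,
    major = major,
    qualifiers = qualifiers
  )
}

small_bundle_config <- function(seed) {
  generator_config(
    seed = seed, n_background = 40, tier_sizes = c(15, 6, 3),
    vocab_size = 200, doc_length = 40, mesh_tree_size = 12
  )
}
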