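Package: boolrank
Title: Boolean and Ranked Retrieval Workbench for Systematic-Review Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained workbench for studying search strategies used in
    biomedical systematic reviews. Parses and evaluates Ovid-dialect Boolean
    search strategies (numbered lines, truncation, wildcards, field codes,
    adjacency, MeSH heading explosion, limits) over MEDLINE-like citation
    corpora; rewrites strategies into broadened "simplified" supersets and
    lints them for common authoring errors; ranks citations with Okapi BM25
    under several query-formulation schemes and MeSH-based expansion variants;
    combines Boolean filtering with ranked ordering into a hybrid retriever;
    and evaluates runs against nested tiers of relevance judgments with
    precision/recall at depth, rank-biased precision, and a tolerance-threshold
    stopping model. A seeded synthetic-data generator produces corpora,
    thesauri, topics, strategies and judgments so every stage is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
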