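# boolrank

Boolean and ranked retrieval workbench for biomedical systematic-review
search.

Systematic-review teams find candidate studies by running long Boolean
search strategies — numbered Ovid-dialect lines mixing free-text terms,
truncation (`hyperactiv$`), proximity (`adj1`), MeSH headings
(`exp Acupuncture Therapy/`) and metadata limits — against citation
databases, then screening every returned record by hand. `boolrank`
implements that whole ecosystem at desk scale so the trade-offs can be
studied end to end, offline:

* a parser and set-semantics evaluator for the Ovid Boolean dialect over
  MEDLINE-like citation corpora (nbib or JSON-lines), backed by a
  field-aware positional inverted index;
* a rule-based **simplifier** that broadens a strategy into a superset of
  itself (`.ti.`/`.tw.`/`.fs.` → `.mp.`, `adjN` → `or`, limits and date or
  publication-type filters removed, with polarity-aware reference repair),
  plus a strategy **linter**;
* Okapi **BM25** ranked retrieval with topic-derived query schemes (title /
  +research questions / +inclusion criteria / Boolean-derived bag of
  words), two metadata-indexing treatments, and three MeSH query-expansion
  variants;
* a **hybrid** retriever: simplified-Boolean candidate set, BM25-ordered;
* tiered evaluation: P@N, R@N, set precision/recall, rank-biased precision

  `RBP = (1 − p) Σ r_i p^(i−1)` (default persistence `p = 0.99`),

  a tolerance-threshold stopping model (screener quits after more than τ
  consecutive non-relevant documents; the counter resets on each relevant
  one), and a seeded random-order baseline for unordered Boolean sets;
* a seeded synthetic generator producing corpus + thesaurus + topic +
  strategy + nested tier-0/1/2 judgments, so every pipeline stage is
  testable with no downloads.

## Worked example

Simplifying a published strategy fragment:

```r
library(boolrank)
frag <- parse_strategy(system.file("extdata", "bvitamin_fragment.txt", package = "boolrank"))
simplify_strategy(frag)
#> 21 exp pyridoxine/
#> 22 pyridoxal.mp.
#> 23 (vitamin or "B6" or "B 6").mp.
#> 24 or/21-23
```

The `.ti.` scope widened to `.mp.`, the `adj1` proximity became a
disjunction, and the publication-type filter line plus the language limit
were removed with their references repaired — the strategy now retrieves a
superset of its original output. Exploding a MeSH heading on the bundled
fixture thesaurus:

```r
th <- read_mesh_json(system.file("extdata", "acupuncture_subtree.json", package = "boolrank"))
mesh_explode(th, "Acupuncture Therapy")
#> [1] "Acupuncture Therapy"   "Acupuncture Analgesia" "Acupuncture, Ear"
#> [4] "Electroacupuncture"    "Meridians"             "Acupuncture Points"
#> [7] "Moxibustion"
```

A full synthetic study — generate a collection, run the Boolean strategy,
rank its output with the topic's title + research questions + inclusion
criteria (TRC) query, and evaluate against the final included studies
(tier 2):

```r
bundle <- generate_bundle(generator_config(seed = 42))   # 450 citations, tiers 50/12/5
idx <- build_index(bundle$corpus)

boolean_set <- result_set(evaluate_strategy(bundle$strategy, idx, bundle$thesaurus))
length(boolean_set)                                  #> 64
set_recall(boolean_set, bundle$judgments$tier2)      #> 1

hybrid <- hybrid_search(bundle$strategy, bundle$topic, idx, bundle$thesaurus)
head(hybrid, 3)
#>   doc_id score  rank
#> 1 14      34.6     1
#> 2 293     31.7     2
#> 3 396     30.7     3

evaluate_run(hybrid, bundle$judgments, tier = 2, cutoffs = c(10, 50))
#>    tier    rbp p_at_10 r_at_10 p_at_50 r_at_50
#> 1     2 0.0486     0.5       1     0.1       1

tolerance_run(hybrid, bundle$judgments$tier2, tau = 10)
#>   tau stop_rank recall_at_stop violating_rank exhausted
#> 1  10        17              1             17 FALSE
```

Read: the Boolean strategy returned 64 of 450 documents including all 5
final includes; the hybrid ranking put all of them in the top 10
(`r_at_10 = 1`, so precision at 10 is 0.5); a screener tolerating 10
consecutive misses would stop at rank 17 having already seen every include.
RBP at `p = 0.99` is small because only 5 of the list's documents are
relevant and the modeled user credits the whole depth.

A thin command-line front end wraps the same functions
(`system.file("cli", "boolrank.R", package = "boolrank")`) with commands
`index`, `boolean`, `simplify`, `lint`, `rank`, `hybrid`, `eval`,
`tolerance`, `generate`, reading and writing nbib/JSON-lines corpora,
thesaurus JSON, strategy text, TREC runs and qrels.

## Documentation

The methods vignette (`vignettes/boolrank-methods.Rmd`) describes the
retrieval models, the simplification rewrite system and its superset
guarantee, the stopping model, the synthetic generator's assumptions, and
the package's numerical and degenerate-input conventions.
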