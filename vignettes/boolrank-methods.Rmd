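---
title: "Boolean and ranked retrieval for systematic-review search: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean and ranked retrieval for systematic-review search: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolrank)
```

# The problem

Teams writing biomedical systematic reviews locate candidate studies with
complex Boolean search strategies run against citation databases such as
MEDLINE through the Ovid interface. These strategies — numbered lines
combining free-text terms, truncation, proximity operators, MeSH headings
and metadata limits — are published as part of the review, and their quality
determines both the recall of the evidence base and the screening workload.
Two practical difficulties motivate this package:

1. Boolean output is an unordered set: reviewers must screen everything, and
   there is no signal about whether a strategy draft is any good until they
   do.
2. Published strategies are hard to re-run faithfully: they accumulate
   restrictive operators, stale headings and outright errors, and re-executed
   strategies often miss studies the review ultimately included.

`boolrank` is a desk-scale workbench for studying these phenomena. It
implements the Ovid-dialect Boolean language over MEDLINE-like citations, an
Okapi BM25 ranked retriever with several query-formulation schemes, a
rule-based strategy *simplifier* that broadens a strategy into a superset of
itself, a *hybrid* retriever that ranks within a Boolean result set, a tiered
evaluation framework with a stopping model, and a seeded synthetic-data
generator so that every stage is testable without any external service.

# Data model

A **corpus** is a tibble of citations: identifier, title, abstract, MeSH
headings (descriptor, major-topic flag, qualifiers), publication types,
language and entry date. Corpora read and write both the MEDLINE nbib tagged
flat format and JSON-lines; unknown nbib tags are carried through untouched.

A **thesaurus** (`mesh_thesaurus()`) is a rooted forest of descriptors with
qualifiers, entry terms, abbreviations and supplementary concept terms.
Descriptor matching is case-insensitive but punctuation-preserving
(`"Acupuncture, Ear"` keeps its comma, as printed in MeSH). `mesh_explode()`
implements the explosion operator: the heading plus its full subtree.
Which levels an interface's `exp` actually adds is not standardized, so
explosion depth is exposed as `max_depth` with the full subtree as default.

**Judgments** are tiered: tier 0 is the set retrieved by the original
strategy, tier 1 the documents kept after title/abstract screening, tier 2
the studies included in the final review. Tier 2 ⊆ tier 1 is enforced;
tier 1 ⊆ tier 0 is *not* assumed by any evaluation code, because published
per-review counts sometimes violate it (screening can admit documents found
outside the search). The shipped `ahrq_tier_counts.tsv` reproduces one
published collection's per-review counts; of its printed per-tier averages
only the drug-review tier-2 mean (56.4) recomputes exactly from its own
column, so that is the only average the tests rely on.

# The Boolean dialect

`parse_strategy()` accepts strategy text exactly as printed in reviews.
Design choices where the dialect is genuinely ambiguous:

* **Adjacency.** `adjN` is read as order-independent co-occurrence within a
  token distance of `n` in one running-text stream (title or abstract).
  Interface documentation variously says "directly adjacent" and "separated
  by maximum *n* words"; the window reading is the default and
  `adj_mode = "ordered"` selects the directed reading. Two operands never
  match on the *same* token occurrence.
* **Truncation.** `$` and `:` are synonyms. A truncation stem shorter than
  two characters would match absurdly many tokens, so it is demoted to a
  literal match with a warning (and flagged by the linter).
* **Scopes.** Bare terms default to `.mp.` (title + abstract + MeSH tokens),
  matching how numbered term lines behave with term mapping off. `.sh.`
  matches subject-heading words; `.fs.` matches qualifier terms, both as
  full names and as their word tokens, since published strategies write
  both. Compound suffixes (`.sh,pt.`) are scope unions.
* **NOT** is binary left-associative set difference.
* **Determinism.** Every result set iterates in document-id order (numeric
  when ids are numeric).

The evaluator runs against a field-aware positional inverted index
(`build_index()`). Positions are stored only for running-text streams, since
adjacency and phrases are meaningful only over running text; headings get a
verbatim sub-index used by `/`, `exp`, `*` and `.sh.`. The index also
carries the collection statistics BM25 needs. In `mode = "folded"` the
metadata tokens are appended to a freely searchable stream (with a
positional gap so adjacency cannot match across the seam), which is the
second of the two metadata treatments below.

The test suite validates the evaluator against an independent linear-scan
oracle — per-document token lists, character-by-character wildcard matching,
no shared code with the index path — over hundreds of random corpus ×
strategy cases, plus algebraic identities (De Morgan, idempotence, scope
monotonicity `ti ⊆ tw ⊆ mp`).

# Simplification

The simplifier broadens a strategy so that its result set contains the
original's — useful both for diagnosing why a re-run strategy lost studies
and for bounding a candidate set for ranking. The rewrite table:

| construct | action |
|---|---|
| `.ti.`, `.tw.`, `.fs.`, `.sh.` | widen to `.mp.` |
| `adj n` | operands joined by `or` |
| `limit … to …` | remove line |
| `.ed.` entry-date filters | remove line |
| publication-type filter lines (`.pt.`) | remove line |
| plain MeSH heading lines | replace with `.mp.` text search (configurable removal) |
| `and` | optionally convert to `or` |
| `$`, `exp`, `or` | unchanged |

Three points required actual design work:

**Within-line versus cross-line AND.** Converting every `and` to `or` would
collapse a strategy to near-whole-corpus output; converting none leaves
within-line conjunctions narrower than necessary. The default policy
(`concept_lines_only`) converts an `and` only when all its operands are
terms or phrases on the same line, preserving cross-line facet
intersections. `never` and `always` are available.

**Reference repair.** Removing lines must not leave dangling references.
References to a removed `limit` line pass through to the limit's target (so
a disjunction over a dropped limit widens to the unfiltered set rather than
losing it); a range fold spanning removed lines contracts, or is rewritten
as an explicit disjunction when contraction would change its meaning; a
conjunction drops removed operands; a line whose definition empties out is
itself removed, cascading. Original line numbers are preserved (gaps
allowed) so diffs against the source stay readable, and the result line is
the highest surviving line.

**Negation polarity.** Widening a line that feeds the right-hand side of a
`not` — directly or through any chain of references — would *shrink* the
final result. The simplifier therefore computes each line's polarity with
respect to the result line and freezes every line reachable under an odd or
mixed number of negations: frozen lines keep their original definitions and
are never removed. Similarly, a metadata filter consumed disjunctively is
widened to `.mp.` instead of being dropped. With these rules the superset
property `eval(simplify(s)) ⊇ eval(s)` holds for every strategy the test
generator can produce (verified on hundreds of random corpus × strategy
cases), including strategies with `not` and with filters in unusual
positions. The property is checked rather than proven: a pathological
strategy that hides a filter inside a frozen negative region simply keeps
that region unchanged, which is always safe.

Simplification is idempotent: a second pass finds nothing left to rewrite.

The companion linter flags the mechanically checkable error classes observed
in published strategies: bad line references, headings missing from the
thesaurus, unreferenced lines, clauses mixing headings with free text,
duplicated clauses, and over-short truncation stems.

# Ranked retrieval

`bm25_score()` implements Okapi BM25,

$$\mathrm{score}(q, d) = \sum_{t \in q}
  \ln\!\left(\frac{N - df_t + 0.5}{df_t + 0.5} + 1\right)
  \frac{tf_{t,d}\,(k_1 + 1)}{tf_{t,d} + k_1\,(1 - b + b\,|d|/\mathrm{avgdl})}$$

summed over distinct query tokens. The `+1` form keeps the idf non-negative
for terms appearing in most documents, which matters for the long
inclusion-criteria queries below. The constants default to the widely used
`k1 = 1.2`, `b = 0.75`; the upstream experimental system is described only
as using "default settings", so these are exposed as arguments rather than
hidden. No stemming and no stopword removal are applied by default: the
Boolean dialect makes truncation explicit, and the ranked queries are
deliberately raw bags of words (`stoplist` exists and is off). Ties in
ranking break by ascending document id, so runs are reproducible to the
byte.

**Query schemes.** A review topic publishes its title, research questions
and inclusion criteria before searching starts, so ranked queries are formed
from exactly those fields: title only (`T`), title + research questions
(`TR`), all three (`TRC`), or the bag of content terms extracted from the
published Boolean strategy with operators and field codes stripped (`B`).

**Metadata treatments.** Method A indexes metadata separately: query tokens
tagged `metadata` score only against MeSH/publication-type fields, `text`
tokens against title+abstract, untagged tokens against everything. Method B
folds metadata tokens into the searchable text stream with a weight
multiplier (default 2, configurable — the upstream description says only
"higher weighting") on metadata-origin occurrences.

**MeSH expansion.** Candidate phrases (all unigrams and contiguous
bigrams/trigrams of the query; a phrase-extractor function can be plugged
in, e.g. a POS-based noun-phrase chunker) are matched exactly against
descriptor names and entry terms. Variant 1 appends the matched
descriptor's qualifiers, variant 2 adds entry terms, variant 3 adds
abbreviations and supplementary concept terms. Contributed phrases are
tokenized with hyphens as separators, so a compound entry term like
`electro-acupuncture` contributes the words its target documents actually
contain; the document tokenizer itself keeps intra-token hyphens.

# Evaluation and the stopping model

`precision_at()`/`recall_at()` are computed over the top
`min(N, |ranked|)` items; for a list shorter than `N`, precision divides by
the list length, preserving the identity
`R@N = P@N · min(N, |ranked|) / |relevant|`. Rank-biased precision
`rbp()` reports the finite-list base value with the residual `p^depth`
attached as an attribute, making the truncation uncertainty explicit;
`p = 0.99` models the very patient screener typical of review teams.

The **tolerance model** (`tolerance_run()`) simulates a screener who
abandons a ranked list after too many consecutive non-relevant documents:
the counter resets on every relevant document, increments otherwise, and
the user stops when it *exceeds* the threshold τ (strict reading; the
`>= τ` reading is a flag). `tolerance_curve()` sweeps a τ grid; recall and
violating rank are provably non-decreasing in τ, and the tests verify this
on a thousand random lists.

Because a Boolean set is unordered, rank-based comparisons against it use
`random_order_baseline()`: seeded uniform shuffles of the set, metrics
averaged over repeats. The expected `R@N` of a shuffle has the closed form
`min(N,|S|)/|S| · R_full`, which the tests verify within Monte-Carlo error.

The **hybrid** system (`hybrid_search()`) evaluates the simplified strategy
to bound the candidate set, then orders that set by BM25 score against the
TRC query. Zero-scoring documents are kept at the tail in id order rather
than dropped: reviewers who exhaust the list see exactly the Boolean set,
so recall at full depth equals the Boolean recall by construction. Ranking
against the *raw* strategy's output is available via `simplify = FALSE`.

# The synthetic generator

`generate_bundle()` produces a corpus, thesaurus, topic, strategy and
judgments as a deterministic function of one seed. It emulates the
*structure* of a review test collection, not medical language:

* Background text is drawn from a Zipf(1.1) pseudo-word vocabulary
  (2,000 words by default); abstracts are Poisson-length around 120 tokens.
* A topic pool of condition/intervention/outcome terms is injected into
  documents with per-tier emission probabilities — 0.02 for background,
  0.15 / 0.35 / 0.6 for tiers 0/1/2 — so relevance signal increases toward
  the final includes, and the pool is disjoint from the background
  vocabulary so the probabilities fully control the signal.
* Topic terms are planted both as surface tokens and as MeSH descriptors,
  because real strategies mix free-text and heading lines; tier-1 documents
  carry the condition descriptor, an intervention descriptor and English
  language, which makes the generated three-facet strategy (condition
  OR-block, intervention OR-block with an `exp` line, final AND, a `limit`
  line) retrieve every tier-1 document by construction.
* Default sizes — 400 background documents, tiers of 50/12/5 — are a
  desk-scale reduction of the drug-review collection's magnitudes
  (thousands retrieved, hundreds screened in, tens included). The test
  suite uses 40/15/6/3 bundles where it needs many seeds.

What passing tests on this generator do **not** show: anything about real
medical vocabulary overlap (synonymy, abbreviation noise), about Ovid's
automatic term mapping, or about absolute effectiveness numbers on MEDLINE.
The generator supports *relative* and *structural* claims — superset
behavior, permutation identities, ranking beating a shuffled baseline —
which is what the package's tests assert.

# Numerical and degenerate-input choices

* BM25 on an empty query is an error; a query token absent everywhere
  contributes zero. Scores of zero are excluded from ranked lists (but kept
  in hybrid output, which must cover the Boolean set).
* Recall against an empty relevant set is an error, not `NaN`.
* Records without an entry date are excluded by date limits — the
  restrictive reading, consistent with how limits behave in practice.
* `exp` over a heading missing from the thesaurus is an error; a plain `/`
  lookup of an unknown heading warns and returns the empty set, matching
  the forgiving behavior needed to re-run old strategies.
* The explosion fixture thesaurus shipped in `inst/extdata` is hand-built
  for tests and examples; it is not an excerpt of the real MeSH files.

# Reproducing the headline numbers

`scripts/acceptance.R --seed <s> --out <path>` regenerates everything from
scratch: the worked simplification example, the explosion fixture, the
arithmetic over the shipped per-review counts, and a full synthetic study
(Boolean vs simplified vs TRC-ranked vs hybrid, with the random-order
baseline and the tolerance model) at the default bundle size of 450
citations. Problem sizes throughout the tests — corpora up to 300 documents
for oracle sweeps, 500 random cases for the Boolean and superset
properties, 200 for BM25, 100 bundles for the hybrid identity — were chosen
so the whole suite exercises every code path many times while staying
comfortably runnable on a laptop.

# Known limitations

* No Ovid term mapping, frequency operators, or proximity across sentence
  boundaries; `and`/`or` inside MeSH heading names require quoting.
* Phrase matching inside `.pt.` scope is not positional (publication types
  are short controlled strings; use a single token or the full string).
* Significance testing between systems is out of scope.
* The simplifier's superset guarantee is conditional on the polarity
  analysis described above; it freezes rather than broadens negative
  regions, so a strategy that is mostly negation gains little from
  simplification.
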