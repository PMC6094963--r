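---
title: "Methods: lexicon enrichment, indexing and misuse categorization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lexicon enrichment, indexing and misuse categorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misuselex)
```

## The problem and the pipeline

Drug misuse — intake errors, over- and under-dosage, brutal quitting,
self-medication, use for unintended effects — is rarely reported to
physicians, but is described spontaneously in health fora. Mining those
messages raises three coupled problems that this package addresses as one
pipeline:

1. patients do not use terminology: *anxiété* appears as *anxieuse*,
   *anxiete*, *angoisse*, misspellings and inflections included, so the
   disorder vocabulary must be **enriched** from seed terms;
2. messages must be **indexed** with the disorders (ICD-10-style codes) and
   drugs (ATC codes) they mention;
3. messages must be **categorized** into *no use*, *normal use* and
   *misuse*, with so few misuse examples (about 7% in annotated reference
   data) that class balancing and careful experiment design matter.

## Text preprocessing

`normalize_text()` lowercases, strips diacritics by Unicode NFKD
decomposition followed by combining-mark removal (*Anxiété → anxiete*), and
replaces every maximal digit run with the reserved token `NUM`. Three
deliberate non-actions: no spell-checking (misspellings are data here),
no stopword removal (function words carry misuse signal: *je ne le prends
pas*), no statistical tagging. Lemmatization is a deterministic lookup
table (`lemma_table()`); forms outside the table map to themselves. This
keeps the whole chain reproducible and testable, at the cost of missing
unknown inflections — which is precisely the gap the lexicon-enrichment
routes are there to cover.

Sentence splitting is rule-based (terminal `.!?;` + whitespace, punctuation
runs collapsed); tokens are maximal alphanumeric runs with an optional
trailing apostrophe, so French elisions stay separate (*d'angoisse → d'*,
*angoisse*). Reserved feature tokens (`NUM`, `DRUG`, `DISORDER`, `ATC_*`,
`ICD_*`) are uppercase-with-underscore, a shape normalization can never
produce, so they cannot collide with corpus words; `normalize_text()`
protects them and is therefore idempotent.

## Lexicon enrichment

All routes start from a seed table: disorder terms with a fine-grained code
and a simplified `group` code (close diagnoses that lay writers do not
distinguish, e.g. F40.0 agoraphobia grouped under F40). Lexica are sets of
`(term, code, source)` entries and always contain the seeds.

- **Morphological family** (`expand_morphology`): every word of a
  morphology table sharing the seed's lemma or family root.
- **Knowledge-base aliases** (`extract_aliases`): labels attached to the
  seed's code; labels differing only by diacritics collapse after
  normalization, inflectional variants are kept on purpose (they survive
  lemmatizer failures).
- **Graph neighbors** (`extract_graph_neighbors`): the top-30 heaviest
  neighbors per seed in a weighted relation graph, optionally restricted to
  morphological relations. The weight order is completed lexicographically:
  "first 30" presupposes a total order, and ties must break
  deterministically.
- **Brown clusters** (`brown_cluster` + `lexicon_from_clusters`): words
  sharing a cluster with a seed.
- **Embedding neighbors** (`train_embeddings` + `embedding_neighbors`):
  top-30 cosine neighbors of each query, with two query sets — seeds only,
  or seeds plus their morphological family, which counteracts the tendency
  of distributional neighborhoods to stay inside one syntactic category.
- **Combinations**: `combine_total` (set union) and `combine_vote` (seeds
  plus every term proposed by at least two distinct resources).

Distributional routes run on a topical sub-corpus — messages that seeds-only
indexing tags with at least one code (`subcorpus_sequences`) — because
clusters computed on the full corpus are too coarse to isolate disorder
vocabulary; this mirrors how such models behave on real fora.

### Brown clustering

`brown_cluster()` is a from-scratch implementation of greedy agglomerative
class-bigram clustering: the quality of a word clustering is the average
mutual information (AMI) between adjacent classes,
$\sum_{c,c'} p(c,c') \log_2 \frac{p(c,c')}{p_l(c)\,p_r(c')}$, and each step
merges the pair of clusters whose merge loses the least AMI. The exact
algorithm is intractable beyond toy sizes, so the standard windowed variant
is used: words enter by decreasing frequency (ties lexicographic) and a
merge is triggered whenever more than `window` clusters (default
`n_clusters + 1`) are active. Bigram statistics are recomputed from the
token stream at each step; words not yet inserted are skipped with
adjacency closed over the gap. Setting `window ≥ |V|` recovers the plain
agglomerative algorithm, which the tests pin against an exhaustive
minimal-loss oracle on small vocabularies. Within clusters, the "relevance"
ordering is corpus frequency (descending, ties lexicographic): the notion
is not standardized, and frequency is deterministic and inspectable.

The default of 500 clusters is the published operating point for a
119k-message corpus; on the synthetic corpora used in tests and in the
acceptance script the vocabulary is only a few hundred words, so those runs
use 20–40 clusters to keep clusters non-trivial (problem sizes: 2,000
messages, vocabulary ≈ 300, stated here once as the package's own choice).

### CBOW embeddings

`train_embeddings()` implements continuous-bag-of-words with negative
sampling: the mean of the context vectors in a 10-word window predicts the
center word against 5 noise words drawn from the unigram distribution
raised to 3/4; vectors are updated by SGD (rate 0.05). Before training,
`merge_bigrams()` joins adjacent pairs with positive PMI and count ≥ 5 into
single tokens, so multiword expressions (*crise d'angoisse*, *cercle
vicieux*) can receive vectors; PMI is the chosen collocation score because
it is the simplest standard choice and is testable by hand. Training is
fully seeded and single-threaded: the same corpus, parameters and seed give
byte-identical vectors, which the determinism contract in the tests relies
on. Embedding dimension defaults to 40 in `build_lexica()` — small, because
the synthetic vocabularies are small; for real corpora one would raise it.

## Indexing and its evaluation

A unit (message or sentence) is indexed with a code iff some lexicon term
for that code occurs as a contiguous token sequence; at each position the
term token may match the surface token or its lemma. Matching is exact
after normalization — no fuzzy matching, because "occurrence" is the
contract, and fuzzy matching would make the recall gaps the enrichment
routes exist to close invisible. All matches are recorded as spans with
0-based half-open token offsets; overlapping matches are all kept since the
prediction is a set.

Evaluation pools TP/FP/FN over (unit, code) pairs — micro counting — and
reports P/R/F plus a per-code breakdown with its macro average. Degenerate
0/0 ratios return 0 with a `degenerate` flag rather than erroring: empty
folds and empty prediction sets occur in practice. Scores are rounded
half-up to 3 decimals at reporting time only.

Cohen's kappa is computed from the confusion matrix as
$\kappa = (p_o - p_e)/(1 - p_e)$ and interpreted on the Landis–Koch bands,
closed on the upper end (0.60 is still "moderate"); $p_e = 1$ (perfectly
skewed marginals) yields an explicit `undefined` flag.

## Categorization

Naive Bayes is implemented in-repo. The multinomial variant is primary:
$P(t\mid c) = (n_{tc} + \alpha)/(n_c + \alpha V)$ with $\alpha = 1$;
out-of-vocabulary tokens at prediction time receive the count-zero smoothed
probability with the same denominator (dropping them silently would make
posterior mass depend on the training vocabulary in an opaque way). The
Bernoulli variant models per-class presence probabilities and stands in for
the Gaussian-on-counts flavour of "classic" Naive Bayes, which is ill-posed
on sparse counts. Ties break on the model's fixed label order
(`NO_USE < NORMAL_USE < MISUSE`) for determinism.

Balancing follows the study designs at their published proportions:
misuse-vs-rest takes every misuse message and as many from the rest (133 +
133 at the reference counts); no-use-vs-rest takes half the no-use class
against the same number (300 + 300); normal-use-vs-misuse and three-way
balance at the minority size. `UNDECIDED` messages are excluded
everywhere. The evaluation protocol is stratified 10-fold cross-validation
with a recorded seed — chosen because the underlying experiments name only
a toolkit and "default parameters", and 10-fold is that toolkit's
convention; the cascade design trains both binary models inside each fold
and composes them, so no test message ever influences either stage of its
own prediction.

Features are bags of lemmas (all words kept by default, counts rather than
binary presence — binary is a flag), optionally augmented with `ATC_*`
3-character drug-class tokens and `ICD_*` disorder-group tokens. The five
ablation modes rewrite entity mentions in the token stream (replace by
code, append code, placeholder, delete), remapping all span offsets;
mode `code` inserts the code *at* the span position rather than appending
it, so positional extensions remain possible, while featureset
augmentation appends counts — two distinct mechanisms on purpose.

## The synthetic-corpus generator

`generate_corpus()` builds pseudo-French messages from a closed template
vocabulary (~150 words) rather than natural-language generation, because
gold labels must be exact by construction: every planted drug mention,
disorder surface form and class cue is recorded with token offsets, and the
generator returns the exact term table it used, so indexing with that table
has message-level recall 1.0 by construction — the anchor the indexing
tests are built on.

What it emulates: the 60/32/7 class mix of annotated reference data (the
default `class_mix` is exactly 1117/600/133 over 1850); drug-class skew
(~60% birth-control G03, ~15% psychotropic N05/N06) via ~30 real drug
names with correct ATC codes; disorder surface variation (canonical form
or inflected variant, then diacritic drop / adjacent swap / single
deletion at `misspelling_rate`, default 0.1); a ten-leaf misuse typology
(non-intentional: intake error, dosage error, contraindication;
intentional: overlooked prescription, fear-of-ADR underuse,
self-medication, psychotropic effect, weight loss, suicide attempt,
addiction), uniform by default since subtype frequencies are not
published.

`cue_strength` (default 0.9) is the probability that a message carries its
class's characteristic cue sentence — the subtype cue for misuse (*j'ai
avale 3 boites de …*), an intake statement for normal use, negated
intake/prescription questions/third-person mentions for no use. One design
point is worth spelling out: the cue gate applies to **every** class, not
only to misuse. If no-use messages kept always-on distinctive phrasing, the
rest half of a balanced misuse-vs-rest sample would leak that signal and a
Bayes-optimal classifier would sit near macro-F 0.64 even with no misuse
cues at all; gating all classes makes `cue_strength = 0` a true no-signal
control (macro-F ≈ 0.5) and makes detection quality increase monotonically
with cue strength, which the property tests assert.

What it does **not** emulate — and hence what passing tests do not show
about real data: grammatical French, discourse structure, thread/reply
context, vocabulary drift, abbreviations (*AD* for antidepressant),
class-dependent message length, annotator noise. Results on the synthetic
corpora validate the machinery (the planted signal is recovered, the
invariants hold), not the absolute performance on real fora.

## Numerical choices and degenerate inputs

- Merge ties in Brown clustering break on the lexicographically smallest
  cluster-id pair; `n_clusters ≥ |V|` returns singletons without error.
- Graph and embedding neighbor ties break lexicographically after
  weight/similarity; out-of-vocabulary embedding queries are skipped with a
  warning.
- Empty messages yield empty token lists and empty count documents; they
  are classified by the prior.
- Overlapping ablation spans resolve leftmost-longest with a warning.
- All sampling (class labels, balancing, folds, negative samples) is
  plain base-R RNG under explicit seeds; no parallelism, so every reported
  number is exactly reproducible.

## Known limitations

- Table-driven lemmatization cannot generalize to unseen inflections; on
  real French a tagger would replace it behind the same interface.
- The Brown implementation recomputes bigram statistics per merge: fine up
  to a few thousand vocabulary items, not for 100k-word corpora.
- Pure-R CBOW is orders of magnitude slower than optimized
  implementations; it is sized for the corpora used here.
- Only Naive Bayes classifiers are implemented in-repo; tree/forest/
  logistic baselines can be slotted in through the same document/label
  interface but are out of scope.
- The published absolute indexing and classification scores depend on a
  non-redistributable annotated corpus and resource snapshots; this package
  reproduces the method and its qualitative behaviour, and pins the
  arithmetic of every published quantity that is computable from printed
  inputs.
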