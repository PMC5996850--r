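---
title: "Mining coherent phrases: model, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining coherent phrases: model, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phraseminer)
```

## The problem

Biomedical concepts are very often multi-word units: a search for *zinc
finger* is not served well by documents that mention zinc in one sentence
and fingers in another. Controlled vocabularies cover only part of this
phrase inventory and age quickly, so this package takes a purely
statistical route with two independent gates:

1. **Coherence**: do the words of a string co-occur *contiguously* far
   more often than independence predicts?
2. **Retrieval utility**: does treating the string as a single query unit
   actually rank relevant documents better than treating it as a bag of
   words?

Both gates are unsupervised. The only supervision-like signal is the
structure of scientific writing itself: titles summarize abstracts, so
"all query words in the title" is used as an automatic (pseudo-relevance)
positive label.

## Stage 1: chained hypergeometric segmentation

For two units with sentence counts $N_s$ and $N_t$ out of $N$ sentences,
the number of sentences containing both under independence is
hypergeometric,

$$P(Y = y) \;=\; \frac{\binom{N_t}{y}\binom{N-N_t}{N_s-y}}{\binom{N}{N_s}},$$

and the evidence for association is the upper tail
$p = \sum_{y=N'_{st}}^{\min(N_s,N_t)} P(y)$. The crucial strictness device
is the substitution of $N'_{st}$, the number of sentences containing the
words *adjacent and in order*, for the plain co-occurrence count: a pair
like *early*/*lung* may share many sentences, but only its contiguous
count can make it look like a phrase. Because contiguous counts are a
subset of co-occurrence counts while the marginals $N_s, N_t$ stay intact,
the test is deliberately conservative for scattered pairs — this is what
makes the false-positive rate on independent background text essentially
zero rather than the nominal 1%.

Candidates longer than two words are tested left to right: the chunk
$w_1\ldots w_i$ (as a contiguous string, with its own sentence count
playing the role of $N_s$) is tested against the next word $w_{i+1}$, and
the chain stops at the first failure. All step p-values are recorded; the
candidate is accepted only if every step has $p \le \alpha$.

Since one candidate entails up to $k-1$ tests, a Benjamini–Hochberg
step-up correction is applied *within each candidate's family* of step
p-values (rate `bh_q`). Correcting per candidate rather than corpus-wide
is intentional: the procedure is explicitly willing to accept a small
error rate across candidates, and a corpus-wide correction over millions
of tests would be both anti-conservative in spirit and scale-dependent.
Note that when `bh_q` equals `alpha`, a candidate whose every step already
passed `alpha` also passes the step-up check (the largest p-value is at
the $k q/m = q$ boundary), so the correction only bites when `bh_q` is set
below `alpha`. In the pipeline the correction is applied to
segmentation-accepted candidates; applied to an already-discarded trace it
would merely relabel it.

### Counting conventions

* All text is lowercased; counting is case-insensitive.
* Sentence counts pool titles and abstracts. The alternative (abstracts
  only) was considered; titles are genuine sentences of the corpus and
  excluding them would discard exactly the occurrences that the retrieval
  stage treats as the strongest signal.
* A sentence containing a string twice still contributes 1 to its
  *sentence count*; BM25 term frequencies, by contrast, count every
  contiguous occurrence (overlaps allowed).
* Contiguity never crosses a boundary-punctuation marker. Stopwords do
  *not* break contiguity for tracked strings — only for harvesting — so
  externally supplied phrases such as *activin a* can be counted and
  chained over all their tokens, including the stopword.
* Boundary comparisons are inclusive (`p <= alpha` passes,
  `p(k) <= k*q/m` rejects), stated for bit-reproducibility.

### Tokenization

Tokens are lowercased, split on whitespace and boundary punctuation, with
hyphens and apostrophes kept word-internal (`3'-utr`, `zinc-finger`).
Boundary punctuation positions are preserved inline as a marker token so
later stages can respect them. Sentences split at `.`, `?` or `!` followed
by whitespace and an uppercase letter or digit — a deliberately simple
rule; the statistics are robust to modest splitting noise. Titles are one
sentence. The default stopword list is the ~130-word PubMed/NLM list
shipped in `inst/extdata/`, overridable per run. Numerals and single
characters are legal tokens (*high resolution 3d*).

### Candidate harvesting

Harvesting takes every maximal run of non-stopword tokens between
boundaries **and every contiguous sub-run of length ≥ 2**, because real
phrase inventories are nested (*heavy oil* and *super heavy* alongside
*super heavy oil*); only harvesting maximal runs would miss the parts.
Single words are never candidates, there is no upper length bound, and a
minimum of `min_count = 5` contiguous occurrences applies. External
lexicon phrases are exempt from the minimum count but dropped if they
never occur contiguously (both later stages need nonzero counts).

## Stage 2: BM25 retrieval filtering

Each accepted phrase is a query. The judged set is every document whose
*abstract* contains all query words; a document is positive iff its
*title* also contains all of them, and a title containing only some of
the words stays negative (conservative labeling — the computed AP is a
lower bound). Abstracts are ranked by Okapi BM25,

$$\mathrm{score}(d) = \sum_{t \in q} \mathrm{idf}(t)\,
\frac{tf_{t,d}\,(k_1+1)}{tf_{t,d} + k_1\,(1-b+b\,|d|/\mathrm{avgdl})},
\qquad \mathrm{idf}(t) = \max\!\left(\mathrm{idf}_{\min},\,
\ln\frac{D-df_t+0.5}{df_t+0.5}\right),$$

under two term models: the query's individual words, and the phrase as a
single term whose $tf$/$df$ count contiguous matches only. Both scorers
use identical constants, so the comparison is between term models, not
parameterizations. `df` and `avgdl` come from the whole collection (as a
real search index would), not just the judged set, and the full judged set
is ranked (no top-$k$ truncation). Ties are broken by ascending document
id so average precision — which is tie-order sensitive — is
deterministic.

The four selection criteria: at least `min_pos = 5` positives; phrase AP
strictly above word AP; phrase AP above the expected AP of a uniformly
random ranking; word AP above `ap_word_floor = 0.01` (too low an AP means
the judged set carries no usable relevance signal). The random baseline is
enumerated exactly for judged sets of up to 8 documents (every arrangement
of positive positions is equally likely) and otherwise estimated by seeded
Monte Carlo with `baseline_reps = 1000` permutations, cached per
$(|T|, |A \cup T|)$ pair. A final `min_improvement` bound on
$(AP_{phrase}-AP_{word})/AP_{word}$ carves out the stricter subset
(0 keeps the full set; 0.10 is the conventional stricter choice).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.01 | per-step tail-probability threshold (probability) |
| `bh_q` | 0.01 | per-candidate FDR for the step-up correction |
| `min_count` | 5 | minimum contiguous occurrences of a harvested candidate |
| `k1` | 1.2 | BM25 tf saturation (dimensionless) |
| `b` | 0.75 | BM25 length normalization (0–1) |
| `idf_floor` | 0 | lower bound on idf |
| `min_pos` | 5 | criterion-1 minimum positives |
| `ap_word_floor` | 0.01 | criterion-4 floor on word-based AP |
| `min_improvement` | 0 | relative-improvement bound for selection |
| `baseline_reps` | 1000 | Monte-Carlo permutations for the random baseline |
| `seed` | 1 | seed for all stochastic components |

The BM25 constants are the standard Okapi defaults; they are exposed
because absolute scores depend on them, but the *comparison* between the
two scorers is robust to their exact values.

## Numerical choices

The hypergeometric pmf is evaluated in log space via `lchoose` and the
tail by log-sum-exp, so p-values of order $10^{-300}$ keep full relative
accuracy; the tests check agreement with an independent survival-function
evaluation to $10^{-10}$ relative error and with exact integer arithmetic
at small $N$ where binomial coefficients are exactly representable in
doubles. Degenerate inputs are defined, not exceptional: a tail starting
at or below the support minimum is 1; a zero contiguous count for the full
string yields $p = 1$ and a discard. Output files print numbers with 6
significant digits, fixed for reproducibility; reruns are byte-identical.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` describes the standard validation corpus: 2,000
documents, a 500-word background vocabulary with power-law unigram
probabilities (exponent 1.1 — a uniform background would make the
co-occurrence test unrealistically easy), stopwords at rate 0.25 acting as
natural harvest boundaries, 50 planted phrases inserted contiguously at
0.008 per sentence (roughly 20 sentences per thousand carry some planted
phrase), titles that repeat each phrase their abstract carries with
probability 0.6, and a scatter mechanism (rate 0.004) that writes a
phrase's words into one sentence with background words between them.
Scatter serves two purposes: applied to dedicated control phrases it is
the negative control (words that co-occur but never form a phrase must
never be selected), and applied to planted phrases it creates the
word-match-but-not-phrase documents that make word-based retrieval
genuinely worse than phrase-based retrieval — the very contrast criterion
2 measures.

Planted phrases default to two tokens drawn from a reserved vocabulary
block. Two deliberate choices: reserved tokens make ground truth
unambiguous (an overlap with background words would make "correct"
ill-defined), and bigram defaults keep recovery scoring exact — the
contiguous sub-pairs of a planted trigram are themselves real collocations
that the method *correctly* extracts, which an exact set comparison
against the planted list would miscount as errors. Longer planted phrases
are supported and exercised in the chained-segmentation tests.

What passing these tests does **not** show about real corpora: the
generator has no grammar, no topical correlation between words, no
burstiness within documents, no synonymy, and its titles are random words
plus carried phrases rather than composed sentences. It validates the
statistical machinery and the implementation, not linguistic coverage.
Conversely, the generator's title-carry structure is an idealization of
the title-summarization assumption; on real data that assumption is an
approximation whose failure modes (e.g. rhetorical titles) the pipeline
inherits.

## Problem sizes used in the shipped tests

The test suite validates oracles on hundreds of randomized small cases
(hypergeometric statistics at $N \le 200$, AP vectors up to length 40,
500 Benjamini–Hochberg families) and runs the full pipeline on corpora of
120–2,000 documents; the standard 2,000-document corpus is used for
recovery (F1 ≥ 0.9, zero scatter controls), directionality of the AP
comparison, and byte-level determinism. These sizes were chosen as the
smallest at which every effect is comfortably away from its decision
boundary.

## Known limitations

* Sentence splitting is rule-based; abbreviation-heavy text will
  occasionally merge sentences. The counts degrade gracefully.
* The external-lexicon path expects a flat phrase list; parsing UMLS
  distributions is out of scope.
* Part-of-speech tagging of phrases is not bundled; the output format
  supports a `.pos` companion only through a user-supplied tagger.
* Reproducing a full-corpus phrase inventory requires the full corpus;
  the package is validated on synthetic and toy corpora and scales to
  corpora that fit in memory, not to hundreds of millions of sentences.
* Synonym expansion is excluded by design: matching is exact, which keeps
  the pseudo-relevance standard unambiguous at the cost of
  under-counting relevance.
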