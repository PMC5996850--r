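# phraseminer

Statistical mining of coherent multi-word phrases from title/abstract
corpora (MEDLINE/PubMed XML or plain TSV), for text-mining and information
retrieval work where queries and concepts are multi-word units — "zinc
finger protein", "central venous pressure" — rather than bags of words.
The package decides, for every frequent multi-word string in a corpus,
(1) whether its words co-occur contiguously far beyond chance, and
(2) whether treating it as a *single retrieval unit* actually improves
search, and keeps only the strings that pass both gates.

## Method

**Stage 1 — segmentation by chained hypergeometric tests.** Candidate
strings are all multi-word runs bounded by punctuation or stopwords that
occur at least 5 times (plus an optional external lexicon, which may
contain stopwords). For two units with sentence counts
*N<sub>s</sub>* and *N<sub>t</sub>* out of *N* sentences, the number of
shared sentences under independence is hypergeometric:

P(Y = y) = C(N<sub>t</sub>, y) · C(N − N<sub>t</sub>, N<sub>s</sub> − y) / C(N, N<sub>s</sub>)

The test statistic substitutes the *contiguous* phrase count
*N′<sub>st</sub>* (sentences containing "word₁ word₂" adjacently, a subset
of plain co-occurrence) and takes the upper tail
p = Σ<sub>y = N′st</sub><sup>min(Ns, Nt)</sup> P(y). A candidate of k words
is tested left to right — chunk "w₁…wᵢ" against word wᵢ₊₁ — and accepted
only if all k − 1 steps have p ≤ 0.01, with a per-candidate
Benjamini–Hochberg step-up correction over the step p-values.

**Stage 2 — retrieval filtering under title pseudo-relevance.** Each
accepted phrase becomes a query over the documents whose abstracts contain
all its words. Documents whose *titles* also contain every word are
pseudo-relevant positives (set T); the rest are negatives (set A). The
abstracts are ranked twice by Okapi BM25 — once summing individual word
weights, once treating the phrase as a single term (contiguous-match tf/df)
— and compared by average precision (AP). A phrase is kept iff:

1. |T| ≥ 5,
2. AP(phrase) > AP(words),
3. AP(phrase) > AP(random ranking),
4. AP(words) > 0.01.

Restricting criterion 2 to a ≥ 10 % relative improvement gives a stricter
subset. Everything is deterministic for a fixed corpus, configuration and
seed.

## Worked example

The built-in generator produces corpora with known planted phrases, titles
that preferentially repeat a phrase their abstract carries, and
"scatter controls" whose words co-occur but are never adjacent:

```r
library(phraseminer)
sim <- generate_corpus(synthetic_spec())   # 2,000 docs, 50 planted phrases
run <- run_pipeline(sim$collection, phrase_config(seed = 1))
run
summary(run)
recovery_report(run$selected, sim$truth)
```

```
<phrase_run>
  documents:            2000
  candidates:           3151 (3151 harvested, 0 external)
  segmentation accepted:50 (3101 discarded, 0 BH-eliminated)
  selected phrases:     50 (small subset: 50)
Selected phrases: 50
Mean AP (word-based):   0.4425
Mean AP (phrase-based): 0.6073  (+38.1% mean per-phrase)
Mean AP (random):       0.4204
precision 1.00, recall 1.00, F1 1.00
```

All 3,151 frequent background word pairs are discarded by the chained test,
the 50 planted phrases are accepted and all pass the four retrieval
criteria; phrase-as-unit ranking beats word ranking (0.607 vs 0.443 mean
AP), which in turn beats random ranking (0.420). No scatter control is ever
selected: their words share sentences but never sit adjacent, so their
contiguous count N′ keeps the tail probability at 1.

`run_pipeline(..., out_dir = "out")` additionally writes the four released
file formats — `all_dictionary.txt` (phrases), `.group` (in-set
subphrases), `.pmid` (documents per phrase) and `.sco`
(`phrase|p-values|word AP,phrase AP`) — plus a stage-count run report.

A thin command line sits over the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/phraseminer.R", package="phraseminer"))') \
    simulate --out corpus.tsv --truth truth.tsv --seed 42
Rscript ... run --corpus corpus.tsv --out-dir out --alpha 0.01 --min-count 5
```

## Vignette

`vignettes/phrase-mining.Rmd` documents the model and its assumptions, the
tunable parameters, the numerical conventions (log-space combinatorics,
tie-breaking, boundary inclusivity), what the synthetic generator does and
does not emulate, and known limitations.
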