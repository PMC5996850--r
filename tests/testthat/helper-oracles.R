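# Brute-force oracles and tiny fixtures, independent of the package's
# implementation paths.

# sliding-window occurrence count of a token sequence in one sentence;
# windows containing the boundary marker can never match (phrases hold no
# markers), so plain equality is the whole contiguity rule
bf_occurrences_in_sentence <- function(sentence, tokens) {
  k <- length(tokens)
  n <- length(sentence)
  if (n < k) return(0L)
  hits <- 0L
  for (i in seq_len(n - k + 1L)) {
    if (all(sentence[i:(i + k - 1L)] == tokens)) hits <- hits + 1L
  }
  hits
}

bf_sentences_of <- function(collection) {
  unlist(lapply(collection, function(d) c(d$title, d$abstract)),
         recursive = FALSE, use.names = FALSE)
}

# sentences (titles + abstracts) containing the unit; unit is a token vector
bf_sentence_count <- function(collection, tokens) {
  sum(vapply(bf_sentences_of(collection), function(s) {
    if (length(tokens) == 1L) tokens %in% s[s != "|"]
    else bf_occurrences_in_sentence(s, tokens) > 0L
  }, logical(1)))
}

bf_abstract_tf <- function(doc, tokens) {
  if (length(tokens) == 1L) {
    sum(vapply(doc$abstract, function(s) sum(s[s != "|"] == tokens),
               integer(1)))
  } else {
    sum(vapply(doc$abstract, bf_occurrences_in_sentence, integer(1),
               tokens = tokens))
  }
}

bf_doc_freq <- function(collection, tokens) {
  sum(vapply(collection, function(d) bf_abstract_tf(d, tokens) > 0L,
             logical(1)))
}

# exact rational tail sum; choose() is exact in doubles for the small N used
bf_pvalue_exact <- function(n_total, n_s, n_t, n_st) {
  lo <- max(0, n_s + n_t - n_total)
  hi <- min(n_s, n_t)
  if (n_st <= lo) return(1)
  ys <- n_st:hi
  sum(choose(n_t, ys) * choose(n_total - n_t, n_s - ys)) /
    choose(n_total, n_s)
}

# average precision computed rank by rank, after an explicit stable sort
bf_average_precision <- function(doc_id, score, positive) {
  ord <- order(-score, doc_id, method = "radix")
  positive <- positive[ord]
  found <- 0L
  precisions <- numeric(0)
  for (r in seq_along(positive)) {
    if (positive[r]) {
      found <- found + 1L
      precisions <- c(precisions, found / r)
    }
  }
  mean(precisions)
}

# naive BH step-up via stats::p.adjust: every member of the family rejected?
bf_bh_all_rejected <- function(p, q) {
  all(stats::p.adjust(p, method = "BH") <= q)
}

# a deterministic six-document toy collection used across module tests;
# planted structure: "zinc finger" always contiguous, "gene therapy" in
# titles of the docs carrying it, "x y" scattered in doc 6 only
toy_collection <- function() {
  document_collection(list(
    document("1001",
             title = list(c("zinc", "finger", "proteins")),
             abstract = list(c("zinc", "finger", "proteins", "bind", "dna"),
                             c("the", "zinc", "finger", "domain"))),
    document("1002",
             title = list(c("gene", "therapy", "advances")),
             abstract = list(c("gene", "therapy", "for", "cancer"),
                             c("vector", "design", "|", "gene", "therapy"))),
    document("1003",
             title = list(c("protein", "structure")),
             abstract = list(c("zinc", "finger", "motif", "analysis"),
                             c("structure", "of", "dna"))),
    document("1004",
             title = list(c("dna", "repair")),
             abstract = list(c("repair", "of", "dna", "damage"),
                             c("gene", "therapy", "is", "promising"))),
    document("1005",
             title = list(c("cancer", "biology")),
             abstract = list(c("cancer", "cells", "divide"),
                             c("zinc", "and", "finger", "separately"))),
    document("1006",
             title = list(c("x", "and", "y", "study")),
             abstract = list(c("x", "q", "y", "q", "x", "y")))
  ))
}
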