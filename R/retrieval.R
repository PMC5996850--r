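# BM25 retrieval filtering under title-based pseudo-relevance.
#
# Each segmentation-accepted phrase is used as a query over the documents
# whose abstracts contain all its words. Titles only assign labels: a
# document is positive (set T) when its title also contains every query word,
# negative (set A) otherwise -- including titles carrying only some of the
# words (conservative rule). Abstracts are then ranked twice with BM25, once
# summing the individual word weights and once treating the phrase as a
# single multi-word term, and the two rankings are compared by average
# precision.

#' BM25 parameters
#'
#' Standard Okapi constants. The phrase filter compares two scorers under the
#' same constants, so the qualitative contrast is robust to their exact
#' values.
#'
#' @param k1 Term-frequency saturation constant (> 0). Default 1.2.
#' @param b Length-normalization constant in \[0, 1\]. Default 0.75.
#' @param idf_floor Minimum allowed inverse document frequency (>= 0).
#'   Default 0.
#'
#' @return An object of class `bm25_params`.
#' @export
bm25_params <- function(k1 = 1.2, b = 0.75, idf_floor = 0) {
  stopifnot(k1 > 0, b >= 0, b <= 1, idf_floor >= 0)
  structure(list(k1 = k1, b = b, idf_floor = idf_floor),
            class = "bm25_params")
}

bm25_idf <- function(n_docs, df, idf_floor) {
  pmax(idf_floor, log((n_docs - df + 0.5) / (df + 0.5)))
}

bm25_weight <- function(tf, doc_len, avgdl, k1, b) {
  tf * (k1 + 1) / (tf + k1 * (1 - b + b * doc_len / avgdl))
}

#' Build the judged document set for a phrase query
#'
#' All documents whose abstract contains every phrase word (in any
#' positions), labeled positive when the title also contains every word.
#'
#' @param phrase Space-joined phrase string or token vector.
#' @param index A [build_index()] result over the collection.
#'
#' @return A data frame of class `judged_set` with columns `doc_id` and
#'   `positive` (logical), sorted by `doc_id`.
#' @export
build_judged_set <- function(phrase, index) {
  words <- unique(if (length(phrase) > 1L) phrase
                  else strsplit(phrase, " ", fixed = TRUE)[[1]])
  in_abstract <- docs_with_all_words(index, words, where = "abstract")
  in_title <- docs_with_all_words(index, words, where = "title")
  structure(
    data.frame(doc_id = in_abstract,
               positive = in_abstract %in% in_title,
               stringsAsFactors = FALSE),
    phrase = as_unit_string(phrase),
    class = c("judged_set", "data.frame")
  )
}

#' BM25 score of a document for a bag of words
#'
#' Sum over the query words of
#' `idf(w) * tf * (k1 + 1) / (tf + k1 * (1 - b + b * len / avgdl))`, with
#' `idf(w) = max(idf_floor, ln((D - df + 0.5) / (df + 0.5)))`. Only abstract
#' text is scored; `df` and `avgdl` are taken over the whole collection.
#'
#' @param doc_id Document identifier (vectorized).
#' @param words Character vector of query words.
#' @param index A `corpus_index`.
#' @param params A [bm25_params()].
#'
#' @return Numeric score(s), one per element of `doc_id`.
#' @export
bm25_word_score <- function(doc_id, words, index, params = bm25_params()) {
  words <- unique(words)
  len <- unname(index$abstract_len[doc_id])
  score <- numeric(length(doc_id))
  for (w in words) {
    post <- index$word_postings[[w]]
    df <- length(post)
    if (df == 0L && params$idf_floor == 0) next
    tf <- unname(post[doc_id])
    tf[is.na(tf)] <- 0L
    idf <- bm25_idf(index$n_docs, df, params$idf_floor)
    score <- score + idf * bm25_weight(tf, len, index$avgdl,
                                       params$k1, params$b)
  }
  score
}

#' BM25 score of a document for a phrase treated as a single term
#'
#' The same formula with the phrase as the sole term: `tf` counts contiguous
#' occurrences of the phrase in the abstract, `df` the documents whose
#' abstracts contain it contiguously. An abstract containing the words but
#' never contiguously scores 0.
#'
#' @inheritParams bm25_word_score
#' @param phrase Space-joined phrase string or token vector; must be tracked
#'   by the index.
#'
#' @return Numeric score(s).
#' @export
bm25_phrase_score <- function(doc_id, phrase, index, params = bm25_params()) {
  u <- as_unit_string(phrase)
  if (!(u %in% index$units)) {
    stop("phrase '", u, "' was not tracked; rebuild the index with it in `units`")
  }
  post <- index$unit_postings[[u]]
  df <- length(post)
  tf <- unname(post[doc_id])
  tf[is.na(tf)] <- 0L
  idf <- bm25_idf(index$n_docs, df, params$idf_floor)
  len <- unname(index$abstract_len[doc_id])
  idf * bm25_weight(tf, len, index$avgdl, params$k1, params$b)
}

ap_from_ordered_labels <- function(positive) {
  mean((cumsum(positive) / seq_along(positive))[positive])
}

#' Rank a judged set and compute average precision
#'
#' Sorts the judged documents by score descending (ties broken by ascending
#' `doc_id`, byte order) and returns the mean, over the positive documents,
#' of precision at their ranks.
#'
#' @param judged A [build_judged_set()] result (>= 1 positive document).
#' @param scores Numeric vector aligned with `judged$doc_id`.
#'
#' @return Average precision in \[0, 1\].
#' @export
rank_and_ap <- function(judged, scores) {
  stopifnot(nrow(judged) == length(scores))
  if (!any(judged$positive)) {
    stop("average precision is undefined: the judged set has no positive document")
  }
  ord <- order(-scores, judged$doc_id, method = "radix")
  ap_from_ordered_labels(judged$positive[ord])
}

#' Expected average precision of a random ranking
#'
#' The baseline of criterion 3: the mean AP when `n_total` documents,
#' `n_pos` of them positive, are ranked uniformly at random. For
#' `n_total <= exact_limit` every arrangement of the positive positions is
#' enumerated (each equally likely under a uniform random permutation);
#' otherwise a seeded Monte-Carlo estimate over `reps` random rankings is
#' returned. The caller's RNG state is left untouched.
#'
#' @param n_pos Number of positives (>= 1).
#' @param n_total Total documents (>= `n_pos`).
#' @param reps Monte-Carlo replicates (default 1000).
#' @param seed Integer seed for the Monte-Carlo branch.
#' @param exact_limit Largest `n_total` enumerated exactly (default 8).
#'
#' @return Expected average precision.
#' @export
random_baseline_ap <- function(n_pos, n_total, reps = 1000L, seed = 1L,
                               exact_limit = 8L) {
  stopifnot(n_pos >= 1L, n_total >= n_pos)
  if (n_pos == n_total) return(1)
  if (n_total <= exact_limit) {
    pos_sets <- utils::combn(n_total, n_pos)
    return(mean(apply(pos_sets, 2L, function(pos) {
      mean(seq_along(pos) / pos)
    })))
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  set.seed(seed)
  mean(vapply(seq_len(reps), function(i) {
    pos <- sort.int(sample.int(n_total, n_pos))
    mean(seq_along(pos) / pos)
  }, numeric(1)))
}

#' Evaluate one phrase under the four retrieval criteria
#'
#' Builds the judged set, computes AP under word-based and phrase-as-unit
#' BM25 and the random baseline, and applies the criteria: (1) at least
#' `min_pos` positive documents; (2) phrase AP strictly greater than word AP;
#' (3) phrase AP greater than the random baseline; (4) word AP greater than
#' `ap_word_floor`. A phrase is selected iff all four hold.
#'
#' @param phrase Space-joined phrase string (tracked by the index).
#' @param index A `corpus_index` tracking the phrase.
#' @param params A [bm25_params()].
#' @param min_pos Criterion-1 minimum positive count (default 5).
#' @param ap_word_floor Criterion-4 floor for word-based AP (default 0.01).
#' @param baseline_reps,baseline_seed Monte-Carlo settings for the random
#'   baseline.
#' @param baseline_cache Optional environment caching baselines by
#'   `(n_pos, n_total)`.
#'
#' @return An object of class `phrase_evaluation`: a one-row data frame with
#'   columns `phrase`, `n_pos`, `n_total`, `ap_word`, `ap_phrase`,
#'   `ap_random`, `improvement`, `crit_min_pos`, `crit_phrase_gt_word`,
#'   `crit_gt_random`, `crit_word_floor`, `selected`.
#' @export
evaluate_phrase <- function(phrase, index, params = bm25_params(),
                            min_pos = 5L, ap_word_floor = 0.01,
                            baseline_reps = 1000L, baseline_seed = 1L,
                            baseline_cache = NULL) {
  judged <- build_judged_set(phrase, index)
  n_total <- nrow(judged)
  n_pos <- sum(judged$positive)
  ap_word <- ap_phrase <- ap_random <- NA_real_
  if (n_pos >= 1L) {
    words <- strsplit(phrase, " ", fixed = TRUE)[[1]]
    ap_word <- rank_and_ap(judged,
                           bm25_word_score(judged$doc_id, words, index, params))
    ap_phrase <- rank_and_ap(judged,
                             bm25_phrase_score(judged$doc_id, phrase, index,
                                               params))
    key <- paste0(n_pos, "/", n_total)
    if (!is.null(baseline_cache) && !is.null(baseline_cache[[key]])) {
      ap_random <- baseline_cache[[key]]
    } else {
      ap_random <- random_baseline_ap(n_pos, n_total, reps = baseline_reps,
                                      seed = baseline_seed)
      if (!is.null(baseline_cache)) baseline_cache[[key]] <- ap_random
    }
  }
  crit <- c(
    crit_min_pos = n_pos >= min_pos,
    crit_phrase_gt_word = isTRUE(ap_phrase > ap_word),
    crit_gt_random = isTRUE(ap_phrase > ap_random),
    crit_word_floor = isTRUE(ap_word > ap_word_floor)
  )
  structure(
    data.frame(phrase = phrase, n_pos = n_pos, n_total = n_total,
               ap_word = ap_word, ap_phrase = ap_phrase,
               ap_random = ap_random,
               improvement = relative_improvement(ap_word, ap_phrase),
               crit_min_pos = crit[[1]], crit_phrase_gt_word = crit[[2]],
               crit_gt_random = crit[[3]], crit_word_floor = crit[[4]],
               selected = all(crit),
               stringsAsFactors = FALSE),
    class = c("phrase_evaluation", "data.frame")
  )
}

#' Evaluate many phrases
#'
#' @param phrases Character vector of tracked phrases.
#' @inheritParams evaluate_phrase
#' @return A data frame with one [evaluate_phrase()] row per phrase.
#' @export
evaluate_phrases <- function(phrases, index, params = bm25_params(),
                             min_pos = 5L, ap_word_floor = 0.01,
                             baseline_reps = 1000L, baseline_seed = 1L) {
  cache <- new.env(parent = emptyenv())
  rows <- lapply(phrases, evaluate_phrase, index = index, params = params,
                 min_pos = min_pos, ap_word_floor = ap_word_floor,
                 baseline_reps = baseline_reps, baseline_seed = baseline_seed,
                 baseline_cache = cache)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select phrases by minimum relative improvement
#'
#' Keeps the phrases passing all four criteria whose relative improvement
#' `(ap_phrase - ap_word) / ap_word` is at least `min_improvement`.
#' `min_improvement = 0` reproduces the full selected set; 0.10 gives the
#' stricter "at least 10% better as a phrase" subset.
#'
#' @param evaluations A data frame of [evaluate_phrase()] rows.
#' @param min_improvement Fractional lower bound (default 0).
#'
#' @return Character vector of selected phrases (sorted, byte order).
#' @export
select_subset <- function(evaluations, min_improvement = 0) {
  sel <- evaluations$selected &
    !is.na(evaluations$improvement) &
    evaluations$improvement >= min_improvement
  sort(evaluations$phrase[sel], method = "radix")
}
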