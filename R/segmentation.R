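# Chained hypergeometric segmentation.
#
# For two units with sentence counts Ns and Nt out of N sentences, the number
# of sentences containing both is hypergeometric under independence. The test
# is made stricter by substituting the contiguous phrase count N'_st for the
# co-occurrence count before taking the upper tail, so that only words that
# actually sit next to each other can look significant. Multi-word candidates
# are tested left to right: chunk tokens[1..i] (as a contiguous string)
# against token i+1, until the chain ends or a step fails.

#' Hypergeometric probability mass
#'
#' P(Y = y) = C(Nt, y) C(N - Nt, Ns - y) / C(N, Ns): the probability that two
#' independent units with sentence counts `n_s` and `n_t` out of `n_total`
#' sentences share exactly `y` sentences. Evaluated in log space
#' (`lchoose`), vectorized over `y`; values of `y` outside the support give 0.
#'
#' @param y Integer vector of co-occurrence counts.
#' @param n_total Total number of sentences N.
#' @param n_s,n_t Sentence counts of the two units.
#'
#' @return Numeric vector of probabilities.
#' @export
hypergeom_pmf <- function(y, n_total, n_s, n_t) {
  stopifnot(n_total >= 0, n_s >= 0, n_t >= 0, n_s <= n_total, n_t <= n_total)
  lo <- max(0, n_s + n_t - n_total)
  hi <- min(n_s, n_t)
  out <- numeric(length(y))
  ok <- y >= lo & y <= hi & y == round(y)
  if (any(ok)) {
    out[ok] <- exp(lchoose(n_t, y[ok]) + lchoose(n_total - n_t, n_s - y[ok]) -
                     lchoose(n_total, n_s))
  }
  out
}

#' Upper-tail hypergeometric p-value with the contiguous-count substitution
#'
#' The probability, under independence, of observing `n_st_phrase` or more
#' shared sentences: `sum_{y = n_st_phrase}^{min(n_s, n_t)} P(Y = y)`.
#' `n_st_phrase` is the count of sentences containing the two units as a
#' contiguous phrase -- a subset of the plain co-occurrence count, which makes
#' the requirement stricter. Summation is done by log-sum-exp over the exact
#' tail, so tiny tails keep full relative accuracy.
#'
#' @inheritParams hypergeom_pmf
#' @param n_st_phrase Number of sentences containing the contiguous phrase.
#'
#' @return A p-value in \[0, 1\]. Degenerate inputs (`n_st_phrase` at or below
#'   the support minimum) give 1.
#' @export
hypergeom_pvalue <- function(n_total, n_s, n_t, n_st_phrase) {
  stopifnot(n_st_phrase >= 0, n_st_phrase <= min(n_s, n_t))
  lo <- max(0, n_s + n_t - n_total)
  hi <- min(n_s, n_t)
  if (n_st_phrase <= lo) return(1)
  ys <- seq.int(n_st_phrase, hi)
  lp <- lchoose(n_t, ys) + lchoose(n_total - n_t, n_s - ys) -
    lchoose(n_total, n_s)
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))
}

#' Segment one candidate by chained hypergeometric tests
#'
#' Tests the candidate left to right: step i tests the contiguous chunk
#' `tokens[1..i]` (its contiguous sentence count is Ns; for i = 1 this is the
#' first word's count) against the next token (word sentence count Nt), with
#' N'_st the contiguous sentence count of `tokens[1..i+1]`. Every step
#' p-value is recorded; the candidate is accepted iff every step p-value is
#' <= `alpha` (a p-value exactly at the threshold passes). The index must
#' have been built with every prefix of the candidate tracked (see
#' [candidate_prefix_units()]).
#'
#' @param candidate A space-joined phrase string or token vector (>= 2
#'   tokens).
#' @param index A [build_index()] result tracking the candidate's prefixes.
#' @param alpha Per-step p-value threshold, in (0, 1). Default 0.01.
#'
#' @return An object of class `segmentation_trace`: the phrase, a data frame
#'   of steps (`prefix`, `next_word`, `n_s`, `n_t`, `n_st`, `p_value`), the
#'   `outcome` (`"accepted"` or `"discarded"`) and `fail_step` (first failing
#'   step, or `NA`).
#' @export
segment_candidate <- function(candidate, index, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  tokens <- if (length(candidate) == 1L) {
    strsplit(candidate, " ", fixed = TRUE)[[1]]
  } else {
    candidate
  }
  L <- length(tokens)
  if (L < 2L) stop("a candidate must have at least 2 tokens")
  N <- n_sentences(index)
  prefix <- character(L - 1L)
  next_word <- character(L - 1L)
  n_s <- integer(L - 1L)
  n_t <- integer(L - 1L)
  n_st <- integer(L - 1L)
  p <- numeric(L - 1L)
  for (i in seq_len(L - 1L)) {
    prefix[i] <- paste(tokens[seq_len(i)], collapse = " ")
    next_word[i] <- tokens[i + 1L]
    n_s[i] <- sentence_count(index, prefix[i])
    n_t[i] <- sentence_count(index, next_word[i])
    n_st[i] <- sentence_count(index, paste(tokens[seq_len(i + 1L)],
                                           collapse = " "))
    p[i] <- hypergeom_pvalue(N, n_s[i], n_t[i], n_st[i])
  }
  fails <- which(p > alpha)
  structure(list(
    phrase = paste(tokens, collapse = " "),
    tokens = tokens,
    steps = data.frame(prefix = prefix, next_word = next_word,
                       n_s = n_s, n_t = n_t, n_st = n_st, p_value = p,
                       stringsAsFactors = FALSE),
    alpha = alpha,
    outcome = if (length(fails)) "discarded" else "accepted",
    fail_step = if (length(fails)) fails[1] else NA_integer_
  ), class = "segmentation_trace")
}

#' @export
print.segmentation_trace <- function(x, ...) {
  cat("<segmentation_trace> '", x$phrase, "': ", x$outcome,
      if (!is.na(x$fail_step)) paste0(" (step ", x$fail_step, ")"),
      "\n", sep = "")
  print(x$steps, ...)
  invisible(x)
}

#' Benjamini-Hochberg correction of a candidate's step p-values
#'
#' Applies the step-up false-discovery-rate procedure to the family of step
#' p-values of one candidate: with the m p-values sorted ascending, all ranks
#' up to the largest k with p(k) <= k q / m are rejected (boundary
#' inclusive). If any step is not rejected, the trace's outcome becomes
#' `"bh_eliminated"`; otherwise the trace is returned unchanged.
#'
#' @param trace A [segment_candidate()] result with >= 1 step.
#' @param q False discovery rate, in (0, 1). Default 0.01.
#'
#' @return The (possibly relabeled) `segmentation_trace`.
#' @export
bh_correct <- function(trace, q = 0.01) {
  stopifnot(q > 0, q < 1, nrow(trace$steps) >= 1L)
  p <- sort(trace$steps$p_value)
  m <- length(p)
  passed <- which(p <= seq_len(m) * q / m)
  k <- if (length(passed)) max(passed) else 0L
  if (k < m) trace$outcome <- "bh_eliminated"
  trace
}

#' All prefix units needed to segment a set of candidates
#'
#' The chained test looks up contiguous sentence counts for every prefix of
#' every candidate (lengths 2 .. L). Track these when building the index.
#'
#' @param phrases Character vector of space-joined candidate phrases.
#' @return Character vector of multi-word unit strings.
#' @export
candidate_prefix_units <- function(phrases) {
  toks <- strsplit(phrases, " ", fixed = TRUE)
  unique(unlist(lapply(toks, function(t) {
    vapply(2:length(t), function(k) paste(t[seq_len(k)], collapse = " "),
           character(1))
  }), use.names = FALSE))
}

#' Segment a whole candidate set
#'
#' Runs [segment_candidate()] on every phrase and, for candidates whose every
#' step passed the threshold, applies [bh_correct()] within the candidate's
#' own family of step p-values (the correction is per candidate, not
#' corpus-wide).
#'
#' @param candidates A `candidate_set` or character vector of phrases.
#' @param index Index tracking all candidate prefixes.
#' @param alpha Per-step threshold (default 0.01).
#' @param bh_q False discovery rate for the per-candidate correction
#'   (default 0.01).
#'
#' @return A named list of `segmentation_trace` objects.
#' @export
segment_candidates <- function(candidates, index, alpha = 0.01, bh_q = 0.01) {
  phrases <- if (is.data.frame(candidates)) candidates$phrase else candidates
  phrases <- unique(phrases)
  traces <- lapply(phrases, segment_candidate, index = index, alpha = alpha)
  traces <- lapply(traces, function(tr) {
    if (tr$outcome == "accepted") bh_correct(tr, q = bh_q) else tr
  })
  names(traces) <- phrases
  traces
}

#' Relative improvement of phrase-based over word-based retrieval
#'
#' The report arithmetic `(ap_phrase - ap_word) / ap_word`, as a fraction.
#'
#' @param ap_word,ap_phrase Average precision under word-based and
#'   phrase-as-unit scoring.
#' @return Numeric fraction (`NA` when `ap_word` is 0).
#' @export
relative_improvement <- function(ap_word, ap_phrase) {
  ifelse(ap_word > 0, (ap_phrase - ap_word) / ap_word, NA_real_)
}
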