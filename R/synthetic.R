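# Synthetic corpus with planted phrases.
#
# Emulates the structure the pipeline exploits in real title/abstract
# corpora: abstracts drawn from a skewed (power-law) background unigram
# distribution with stopwords sprinkled in as natural phrase boundaries;
# "planted" phrases inserted contiguously far above chance; titles that
# summarize, i.e. preferentially repeat a planted phrase the abstract
# contains; and a scatter mechanism that places a phrase's words in one
# sentence *non*-contiguously -- the negative control that separates phrase
# co-occurrence from mere word co-occurrence.

#' Specification of a synthetic corpus
#'
#' Defaults describe the standard validation corpus: 2,000 documents over a
#' 500-word background vocabulary with 50 planted two-word phrases and a 0.6
#' title-carry probability. Planted and scatter-control phrases use reserved
#' token blocks (`zz...`, `qq...`) disjoint from the background vocabulary so
#' ground truth is unambiguous.
#'
#' @param n_docs Number of documents.
#' @param sentences_per_abstract Inclusive range (length-2 integer vector) of
#'   abstract sentence counts.
#' @param vocab_size Background vocabulary size.
#' @param power_exponent Exponent of the power-law background unigram
#'   distribution (P(rank r) proportional to r^-exponent).
#' @param n_planted Number of planted phrases.
#' @param planted_length Token length of each planted phrase (scalar or
#'   vector recycled over phrases). Default 2: contiguous sub-pairs of a
#'   longer planted phrase are themselves coherent collocations, which would
#'   blur exact-set recovery scoring.
#' @param planted_phrases Optional list of explicit token vectors, overriding
#'   `n_planted`/`planted_length`.
#' @param insertion_probability Per-sentence probability that a given planted
#'   phrase is inserted contiguously.
#' @param title_carry_probability Probability that a document containing a
#'   planted phrase (contiguously) repeats it in its title.
#' @param scatter_probability Per-sentence probability that a given phrase's
#'   words are inserted non-contiguously (with background words between).
#'   Applies to planted phrases (creating word-match-only documents) and to
#'   the scatter controls.
#' @param n_scatter_controls Number of control phrases inserted *only* in
#'   scattered form; the pipeline must never select them.
#' @param stopword_rate Probability that a background token position carries
#'   a stopword instead of a vocabulary word.
#' @param sentence_length,title_length Inclusive token-count ranges.
#' @param seed Integer RNG seed; generation is deterministic given the spec.
#'
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_docs = 2000L,
                           sentences_per_abstract = c(4L, 8L),
                           vocab_size = 500L,
                           power_exponent = 1.1,
                           n_planted = 50L,
                           planted_length = 2L,
                           planted_phrases = NULL,
                           insertion_probability = 0.008,
                           title_carry_probability = 0.6,
                           scatter_probability = 0.004,
                           n_scatter_controls = 10L,
                           stopword_rate = 0.25,
                           sentence_length = c(6L, 12L),
                           title_length = c(3L, 5L),
                           seed = 42L) {
  if (is.null(planted_phrases)) {
    lens <- rep_len(planted_length, n_planted)
    tok_id <- 0L
    planted_phrases <- lapply(lens, function(L) {
      out <- sprintf("zz%04d", tok_id + seq_len(L))
      tok_id <<- tok_id + L
      out
    })
  }
  probs <- c(insertion_probability, title_carry_probability,
             scatter_probability, stopword_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (length(planted_phrases) &&
      max(lengths(planted_phrases)) > sentence_length[1]) {
    stop("infeasible spec: a planted phrase is longer than the shortest sentence")
  }
  structure(list(
    n_docs = as.integer(n_docs),
    sentences_per_abstract = as.integer(sentences_per_abstract),
    vocab_size = as.integer(vocab_size),
    power_exponent = power_exponent,
    planted_phrases = planted_phrases,
    insertion_probability = insertion_probability,
    title_carry_probability = title_carry_probability,
    scatter_probability = scatter_probability,
    n_scatter_controls = as.integer(n_scatter_controls),
    stopword_rate = stopword_rate,
    sentence_length = as.integer(sentence_length),
    title_length = as.integer(title_length),
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

sample_range <- function(range, n) {
  if (range[1] == range[2]) rep.int(range[1], n)
  else range[1] + sample.int(range[2] - range[1] + 1L, n, replace = TRUE) - 1L
}

#' Generate a synthetic corpus with known ground truth
#'
#' Deterministic for a fixed spec (the caller's RNG state is preserved).
#'
#' @param spec A [synthetic_spec()].
#'
#' @return A list with `collection` (a [document_collection()]) and `truth`
#'   (class `synthetic_ground_truth`: `planted` and `scatter_controls` as
#'   space-joined phrase strings, `occurrences` -- a data frame of contiguous
#'   insertions per document -- and the spec echo).
#' @export
generate_corpus <- function(spec) {
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
  set.seed(spec$seed)

  vocab <- sprintf("w%04d", seq_len(spec$vocab_size))
  vprob <- seq_len(spec$vocab_size)^(-spec$power_exponent)
  vprob <- vprob / sum(vprob)
  stop_pool <- c("of", "in", "the", "and", "with", "for", "to", "on", "by",
                 "from")
  planted <- spec$planted_phrases
  n_p <- length(planted)
  controls <- if (spec$n_scatter_controls > 0L) {
    lapply(seq_len(spec$n_scatter_controls), function(i) {
      sprintf("qq%04d", 2L * i - c(1L, 0L))
    })
  } else {
    list()
  }
  n_c <- length(controls)
  scatterable <- c(planted, controls)

  bg_tokens <- function(n) {
    if (n == 0L) return(character(0))
    is_stop <- stats::runif(n) < spec$stopword_rate
    out <- character(n)
    if (any(is_stop)) {
      out[is_stop] <- sample(stop_pool, sum(is_stop), replace = TRUE)
    }
    if (any(!is_stop)) {
      out[!is_stop] <- sample(vocab, sum(!is_stop), replace = TRUE,
                              prob = vprob)
    }
    out
  }
  # place whole blocks at slots between background tokens, so no inserted
  # block can ever split another (planted phrases stay contiguous)
  assemble_sentence <- function(base, blocks) {
    if (!length(blocks)) return(base)
    slots <- sample.int(length(base) + 1L, length(blocks),
                        replace = TRUE) - 1L
    ord <- order(slots)
    out <- vector("list", 2L * length(blocks) + 1L)
    prev <- 0L
    j <- 1L
    for (b in ord) {
      out[[j]] <- base[seq_len(slots[b] - prev) + prev]
      out[[j + 1L]] <- blocks[[b]]
      prev <- slots[b]
      j <- j + 2L
    }
    out[[j]] <- if (prev < length(base)) base[(prev + 1L):length(base)]
                else character(0)
    unlist(out, use.names = FALSE)
  }
  scatter_block <- function(words) {
    n_fill <- length(words) - 1L
    fill <- sample(vocab, n_fill, replace = TRUE, prob = vprob)
    out <- character(2L * length(words) - 1L)
    out[seq_along(words) * 2L - 1L] <- words
    if (n_fill) out[seq_len(n_fill) * 2L] <- fill
    out
  }

  docs <- vector("list", spec$n_docs)
  occ_doc <- list()
  occ_phrase <- list()
  occ_n <- list()
  for (d in seq_len(spec$n_docs)) {
    doc_id <- sprintf("%07d", 1000000L + d)
    n_sent <- sample_range(spec$sentences_per_abstract, 1L)
    lens <- sample_range(spec$sentence_length, n_sent)
    counts <- integer(n_p)
    abstract <- vector("list", n_sent)
    for (s in seq_len(n_sent)) {
      base <- bg_tokens(lens[s])
      blocks <- list()
      if (n_p) {
        ins <- which(stats::runif(n_p) < spec$insertion_probability)
        for (i in ins) {
          blocks[[length(blocks) + 1L]] <- planted[[i]]
          counts[i] <- counts[i] + 1L
        }
      }
      if (length(scatterable) && spec$scatter_probability > 0) {
        sc <- which(stats::runif(length(scatterable)) <
                      spec$scatter_probability)
        for (i in sc) {
          blocks[[length(blocks) + 1L]] <- scatter_block(scatterable[[i]])
        }
      }
      abstract[[s]] <- assemble_sentence(base, blocks)
    }
    title_base <- bg_tokens(sample_range(spec$title_length, 1L))
    present <- which(counts > 0L)
    carried <- present[stats::runif(length(present)) <
                         spec$title_carry_probability]
    title <- assemble_sentence(title_base, planted[carried])
    if (any(counts > 0L)) {
      hit <- which(counts > 0L)
      occ_doc[[length(occ_doc) + 1L]] <- rep(doc_id, length(hit))
      occ_phrase[[length(occ_phrase) + 1L]] <-
        vapply(planted[hit], paste, character(1), collapse = " ")
      occ_n[[length(occ_n) + 1L]] <- counts[hit]
    }
    docs[[d]] <- document(doc_id, title = list(title), abstract = abstract)
  }

  truth <- structure(list(
    planted = vapply(planted, paste, character(1), collapse = " "),
    scatter_controls = vapply(controls, paste, character(1), collapse = " "),
    occurrences = data.frame(
      doc_id = unlist(occ_doc, use.names = FALSE),
      phrase = unlist(occ_phrase, use.names = FALSE),
      n = unlist(occ_n, use.names = FALSE),
      stringsAsFactors = FALSE
    ),
    spec = spec
  ), class = "synthetic_ground_truth")

  list(collection = document_collection(docs), truth = truth)
}

#' Write the ground truth sidecar file
#'
#' A plain TSV (`phrase TAB role`) listing planted phrases and scatter
#' controls, for use next to the TSV corpus emitted by [write_tsv_corpus()].
#'
#' @param truth A `synthetic_ground_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  writeLines(c(paste(truth$planted, "planted", sep = "\t"),
               paste(truth$scatter_controls, "scatter_control", sep = "\t")),
             path, useBytes = TRUE)
  invisible(path)
}

#' Score recovery of planted phrases
#'
#' Exact set-based precision, recall and F1 of an extracted phrase set
#' against the planted ground truth. An empty extracted set has precision 1
#' by convention (no false claims), recall 0, F1 0.
#'
#' @param extracted Character vector of extracted phrases.
#' @param truth A `synthetic_ground_truth` (or character vector of planted
#'   phrases).
#'
#' @return A list with `precision`, `recall`, `f1`, `n_extracted`,
#'   `n_planted`, `n_correct`.
#' @export
recovery_report <- function(extracted, truth) {
  planted <- if (inherits(truth, "synthetic_ground_truth")) truth$planted
             else truth
  extracted <- unique(extracted)
  n_correct <- sum(extracted %in% planted)
  precision <- if (length(extracted) == 0L) 1 else n_correct / length(extracted)
  recall <- if (length(planted) == 0L) 1 else n_correct / length(planted)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  list(precision = precision, recall = recall, f1 = f1,
       n_extracted = length(extracted), n_planted = length(planted),
       n_correct = n_correct)
}
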