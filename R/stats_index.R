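# Corpus counting index.
#
# Precomputes every statistic the two pipeline stages query: per-unit sentence
# counts (words and tracked contiguous strings), per-document abstract term
# frequencies, document frequencies, abstract lengths. Sentence counts pool
# title and abstract sentences; document-level statistics (tf, df, length)
# are abstract-only, since retrieval scores abstracts and titles serve only
# as relevance labels.

flatten_collection <- function(collection) {
  tseq <- lapply(collection, `[[`, "title")
  aseq <- lapply(collection, `[[`, "abstract")
  nt <- vapply(tseq, length, integer(1))
  na <- vapply(aseq, length, integer(1))
  sentences <- c(unlist(tseq, recursive = FALSE, use.names = FALSE),
                 unlist(aseq, recursive = FALSE, use.names = FALSE))
  list(
    sentences = sentences,
    sent_doc = c(rep.int(seq_along(collection), nt),
                 rep.int(seq_along(collection), na)),
    sent_abstract = rep(c(FALSE, TRUE), c(sum(nt), sum(na)))
  )
}

# Enumerate contiguous k-gram occurrences over tokenized sentences, never
# crossing a boundary marker (nor any token in `extra_breaks`). Returns one
# row per occurrence: the space-joined gram and its sentence index.
ngram_occurrences <- function(sentences, ks, filter_by_k = NULL,
                              extra_breaks = NULL) {
  empty <- list(gram = character(0), sent = integer(0))
  tok <- unlist(sentences, use.names = FALSE)
  n <- length(tok)
  if (n == 0L) return(empty)
  sid <- rep.int(seq_along(sentences), lengths(sentences))
  brk <- tok == boundary_marker()
  if (!is.null(extra_breaks)) brk <- brk | tok %in% extra_breaks
  newseg <- c(TRUE, sid[-1L] != sid[-n]) | brk | c(FALSE, brk[-n])
  seg <- cumsum(newseg)
  grams <- list()
  sents <- list()
  for (k in ks) {
    if (n < k) next
    i <- seq_len(n - k + 1L)
    i <- i[seg[i] == seg[i + k - 1L]]
    if (!length(i)) next
    g <- tok[i]
    for (j in seq_len(k - 1L)) g <- paste(g, tok[i + j])
    if (!is.null(filter_by_k)) {
      keep <- g %in% filter_by_k[[as.character(k)]]
      g <- g[keep]
      i <- i[keep]
    }
    if (length(i)) {
      grams[[length(grams) + 1L]] <- g
      sents[[length(sents) + 1L]] <- sid[i]
    }
  }
  if (!length(grams)) return(empty)
  list(gram = unlist(grams, use.names = FALSE),
       sent = unlist(sents, use.names = FALSE))
}

max_segment_length <- function(sentences, extra_breaks = NULL) {
  tok <- unlist(sentences, use.names = FALSE)
  if (!length(tok)) return(0L)
  sid <- rep.int(seq_along(sentences), lengths(sentences))
  brk <- tok == boundary_marker()
  if (!is.null(extra_breaks)) brk <- brk | tok %in% extra_breaks
  seg <- cumsum(c(TRUE, sid[-1L] != sid[-length(sid)]) | brk |
                  c(FALSE, brk[-length(brk)]))
  max(tabulate(seg[!brk] - min(seg) + 1L), 0L)
}

split_units_by_length <- function(units) {
  toks <- strsplit(units, " ", fixed = TRUE)
  k <- lengths(toks)
  split(units, as.character(k))
}

#' Build the corpus counting index
#'
#' Computes, in one pass, every count both pipeline stages need: the total
#' sentence count N (titles and abstracts pooled), per-word sentence counts,
#' contiguous sentence counts and per-document abstract occurrence counts for
#' each tracked multi-word unit, per-document abstract term frequencies,
#' document frequencies, abstract lengths and their mean. A sentence
#' containing a unit twice contributes 1 to its sentence count; term
#' frequencies count every contiguous occurrence (overlaps allowed).
#'
#' @param collection A non-empty [document_collection()].
#' @param units Character vector of multi-word strings (space-joined tokens)
#'   to track contiguously. Word statistics are always built.
#'
#' @return An object of class `corpus_index`.
#' @export
build_index <- function(collection, units = character(0)) {
  if (!inherits(collection, "document_collection") || length(collection) == 0L) {
    stop("collection must be a non-empty document_collection")
  }
  units <- unique(units)
  if (length(units) && any(!grepl(" ", units, fixed = TRUE))) {
    stop("tracked units must be multi-word (space-joined) strings")
  }
  mark <- boundary_marker()
  doc_ids <- names(collection)
  fl <- flatten_collection(collection)
  N <- length(fl$sentences)

  # word sentence counts (titles + abstracts, presence per sentence)
  uniq <- lapply(fl$sentences, function(s) unique(s[s != mark]))
  wsc_tab <- table(unlist(uniq, use.names = FALSE))
  word_sc <- stats::setNames(as.integer(wsc_tab), names(wsc_tab))

  # abstract word postings: tf per (word, document)
  abs_tok <- lapply(collection, function(d) {
    v <- unlist(d$abstract, use.names = FALSE)
    v[v != mark]
  })
  abstract_len <- stats::setNames(vapply(abs_tok, length, integer(1)), doc_ids)
  if (any(abstract_len == 0L)) stop("every document must have a non-empty abstract")
  word_postings <- invert_postings(
    unlist(abs_tok, use.names = FALSE),
    rep.int(seq_along(collection), lengths(abs_tok)),
    doc_ids
  )

  # title membership: documents whose title contains a word
  ttl_words <- lapply(collection, function(d) {
    v <- unique(unlist(d$title, use.names = FALSE))
    v[v != mark]
  })
  title_word_docs <- split(
    doc_ids[rep.int(seq_along(collection), lengths(ttl_words))],
    unlist(ttl_words, use.names = FALSE)
  )

  # tracked multi-word units: contiguous matches (stopwords do not break
  # contiguity; only boundary markers do)
  unit_sc <- stats::setNames(integer(length(units)), units)
  unit_postings <- stats::setNames(vector("list", length(units)), units)
  if (length(units)) {
    by_k <- split_units_by_length(units)
    occ <- ngram_occurrences(fl$sentences,
                             ks = as.integer(names(by_k)),
                             filter_by_k = by_k)
    if (length(occ$gram)) {
      pres <- !duplicated(paste0(occ$gram, "\r", occ$sent))
      sc_tab <- table(occ$gram[pres])
      unit_sc[names(sc_tab)] <- as.integer(sc_tab)
      in_abs <- fl$sent_abstract[occ$sent]
      if (any(in_abs)) {
        up <- invert_postings(occ$gram[in_abs],
                              fl$sent_doc[occ$sent[in_abs]],
                              doc_ids)
        unit_postings[names(up)] <- up
      }
    }
  }

  sc_env <- list2env(as.list(c(word_sc, unit_sc)), parent = emptyenv())
  structure(list(
    N = N,
    n_docs = length(collection),
    doc_ids = doc_ids,
    abstract_len = abstract_len,
    avgdl = mean(abstract_len),
    word_postings = word_postings,
    title_word_docs = title_word_docs,
    units = units,
    unit_postings = unit_postings,
    sc_env = sc_env
  ), class = "corpus_index")
}

# tf per (term, document) from parallel term / doc-index vectors
invert_postings <- function(term, doc_idx, doc_ids) {
  if (!length(term)) return(list())
  key_tab <- table(paste0(term, "\r", doc_idx))
  parts <- strsplit(names(key_tab), "\r", fixed = TRUE)
  kt <- vapply(parts, `[[`, character(1), 1L)
  kd <- as.integer(vapply(parts, `[[`, character(1), 2L))
  tf <- as.integer(key_tab)
  lapply(split(seq_along(kt), kt), function(ix) {
    stats::setNames(tf[ix], doc_ids[kd[ix]])
  })
}

#' @export
print.corpus_index <- function(x, ...) {
  cat("<corpus_index> ", x$n_docs, " documents, ", x$N, " sentences, ",
      length(x$units), " tracked units\n", sep = "")
  invisible(x)
}

as_unit_string <- function(unit) {
  if (length(unit) > 1L) paste(unit, collapse = " ") else unit
}

#' Sentence count of a unit
#'
#' Number of sentences (titles and abstracts) containing a word, or containing
#' a multi-word string contiguously. Multi-word strings must have been listed
#' in `units` when the index was built.
#'
#' @param index A `corpus_index`.
#' @param unit A word, a space-joined string, or a token vector.
#'
#' @return Integer count (0 for a word absent from the corpus).
#' @export
sentence_count <- function(index, unit) {
  u <- as_unit_string(unit)
  if (grepl(" ", u, fixed = TRUE) && !(u %in% index$units)) {
    stop("unit '", u, "' was not tracked; rebuild the index with it in `units`")
  }
  val <- get0(u, envir = index$sc_env, inherits = FALSE)
  if (is.null(val)) 0L else val
}

#' Document frequency of a unit
#'
#' Number of documents whose abstract contains the unit (contiguously, for
#' multi-word strings).
#'
#' @inheritParams sentence_count
#' @return Integer count.
#' @export
doc_freq <- function(index, unit) {
  u <- as_unit_string(unit)
  if (grepl(" ", u, fixed = TRUE)) {
    if (!(u %in% index$units)) {
      stop("unit '", u, "' was not tracked; rebuild the index with it in `units`")
    }
    length(index$unit_postings[[u]])
  } else {
    length(index$word_postings[[u]])
  }
}

#' Term frequency of a unit in a document's abstract
#'
#' Occurrences of the unit in the abstract (contiguous occurrences for
#' multi-word strings, overlaps allowed).
#'
#' @inheritParams sentence_count
#' @param doc_id Document identifier.
#' @return Integer count.
#' @export
term_freq <- function(index, doc_id, unit) {
  u <- as_unit_string(unit)
  p <- if (grepl(" ", u, fixed = TRUE)) {
    if (!(u %in% index$units)) {
      stop("unit '", u, "' was not tracked; rebuild the index with it in `units`")
    }
    index$unit_postings[[u]]
  } else {
    index$word_postings[[u]]
  }
  v <- p[doc_id]
  if (length(v) != 1L || is.na(v)) 0L else as.integer(v)
}

#' Abstract length and its corpus mean
#'
#' @inheritParams term_freq
#' @return `abstract_length()`: token count of the document's abstract;
#'   `avg_doc_length()`: the mean over the collection.
#' @export
abstract_length <- function(index, doc_id) {
  v <- index$abstract_len[doc_id]
  if (is.na(v)) stop("unknown document id: ", doc_id)
  as.integer(v)
}

#' @rdname abstract_length
#' @export
avg_doc_length <- function(index) index$avgdl

#' Total sentence count
#'
#' @param index A `corpus_index`.
#' @return N, the number of sentences (titles + abstracts) in the corpus.
#' @export
n_sentences <- function(index) index$N

#' Documents containing all given words
#'
#' @param index A `corpus_index`.
#' @param words Character vector of words.
#' @param where `"abstract"` (term occurs anywhere in the abstract) or
#'   `"title"`.
#'
#' @return Sorted character vector of document ids.
#' @export
docs_with_all_words <- function(index, words, where = c("abstract", "title")) {
  where <- match.arg(where)
  words <- unique(words)
  sets <- lapply(words, function(w) {
    if (where == "abstract") names(index$word_postings[[w]])
    else index$title_word_docs[[w]]
  })
  if (any(lengths(sets) == 0L)) return(character(0))
  sort(Reduce(intersect, sets), method = "radix")
}

#' Membership predicates for a document
#'
#' @inheritParams docs_with_all_words
#' @param doc_id Document identifier.
#' @return Logical: does the document's title (resp. abstract) contain every
#'   word in `words`?
#' @export
title_contains_all <- function(index, doc_id, words) {
  all(vapply(unique(words),
             function(w) doc_id %in% index$title_word_docs[[w]], logical(1)))
}

#' @rdname title_contains_all
#' @export
abstract_contains_all <- function(index, doc_id, words) {
  all(vapply(unique(words),
             function(w) doc_id %in% names(index$word_postings[[w]]),
             logical(1)))
}

#' Count contiguous occurrences of phrases in a collection
#'
#' Total number of contiguous occurrences of each phrase across all sentences
#' (titles and abstracts), and the number of distinct sentences containing it.
#' Contiguity never crosses a boundary marker; stopwords do not break it.
#'
#' @param collection A [document_collection()].
#' @param phrases Character vector of space-joined multi-word strings.
#'
#' @return A data frame with columns `phrase`, `occurrences`,
#'   `sentence_count`.
#' @export
count_contiguous <- function(collection, phrases) {
  phrases <- unique(phrases)
  fl <- flatten_collection(collection)
  by_k <- split_units_by_length(phrases)
  occ <- ngram_occurrences(fl$sentences, ks = as.integer(names(by_k)),
                           filter_by_k = by_k)
  n_occ <- stats::setNames(integer(length(phrases)), phrases)
  n_sent <- n_occ
  if (length(occ$gram)) {
    ot <- table(occ$gram)
    n_occ[names(ot)] <- as.integer(ot)
    st <- table(occ$gram[!duplicated(paste0(occ$gram, "\r", occ$sent))])
    n_sent[names(st)] <- as.integer(st)
  }
  data.frame(phrase = phrases,
             occurrences = as.integer(n_occ),
             sentence_count = as.integer(n_sent),
             row.names = NULL, stringsAsFactors = FALSE)
}
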