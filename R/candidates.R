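# Candidate phrase harvesting and external lexicon merge.

#' Harvest candidate strings from a corpus
#'
#' Collects every multi-word text string bounded by punctuation or stopwords:
#' within each sentence, maximal runs of non-stopword tokens between boundary
#' markers are enumerated together with every contiguous sub-run of length
#' >= 2 (nested phrases such as "heavy oil" inside "super heavy oil" are
#' candidates in their own right). Candidates occurring fewer than
#' `min_count` times are dropped; single words are never candidates.
#'
#' @param collection A [document_collection()].
#' @param config The [tokenizer_config()] whose stopword set bounds the runs.
#' @param min_count Minimum number of contiguous occurrences (default 5).
#'
#' @return A `candidate_set`: a data frame with columns `phrase`
#'   (space-joined tokens), `length` (token count), `frequency` (total
#'   contiguous occurrences) and `source` (`"harvested"`).
#' @export
harvest_candidates <- function(collection, config = tokenizer_config(),
                               min_count = 5L) {
  stopifnot(min_count >= 1L)
  fl <- flatten_collection(collection)
  kmax <- max_segment_length(fl$sentences, extra_breaks = config$stopwords)
  if (kmax < 2L) {
    return(candidate_set(character(0), integer(0), character(0)))
  }
  occ <- ngram_occurrences(fl$sentences, ks = 2:kmax,
                           extra_breaks = config$stopwords)
  if (!length(occ$gram)) {
    return(candidate_set(character(0), integer(0), character(0)))
  }
  tab <- table(occ$gram)
  tab <- tab[tab >= min_count]
  phrases <- names(tab)
  ord <- order(phrases, method = "radix")
  candidate_set(phrases[ord], as.integer(tab)[ord],
                rep("harvested", length(tab)))
}

candidate_set <- function(phrase, frequency, source) {
  structure(
    data.frame(phrase = phrase,
               length = lengths(strsplit(phrase, " ", fixed = TRUE)),
               frequency = frequency,
               source = source,
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("candidate_set", "data.frame")
  )
}

#' Merge an external candidate lexicon
#'
#' Adds phrases from a flat lexicon file (UTF-8, one phrase per line) to a
#' harvested candidate set. Lexicon phrases are lowercased and tokenized; they
#' may contain stopwords (the way "activin a" does) and are exempt from the
#' harvesting minimum count, but a phrase that never occurs contiguously in
#' the corpus carries no evidence and is dropped (with a message). A lexicon
#' phrase identical to a harvested candidate keeps `source = "harvested"`.
#'
#' @param candidates A `candidate_set` from [harvest_candidates()].
#' @param lexicon_path Path to the phrase list.
#' @param collection The corpus the candidates came from (needed to count
#'   occurrences of the new phrases).
#' @param config A [tokenizer_config()].
#'
#' @return The merged `candidate_set`; dropped zero-frequency phrases are
#'   recorded in `attr(, "dropped")`.
#' @export
merge_external_lexicon <- function(candidates, lexicon_path, collection,
                                   config = tokenizer_config()) {
  lines <- readLines(lexicon_path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  toks <- lapply(lines, function(x) {
    unlist(tokenize_and_split(x, config, split_sentences = FALSE),
           use.names = FALSE)
  })
  toks <- lapply(toks, function(t) t[t != boundary_marker()])
  keep <- lengths(toks) >= 2L
  phrases <- unique(vapply(toks[keep], paste, character(1), collapse = " "))
  phrases <- setdiff(phrases, candidates$phrase)
  if (!length(phrases)) {
    attr(candidates, "dropped") <- character(0)
    return(candidates)
  }
  counts <- count_contiguous(collection, phrases)
  present <- counts$occurrences > 0L
  dropped <- counts$phrase[!present]
  if (length(dropped)) {
    message(length(dropped),
            " external phrase(s) absent from the corpus were dropped")
  }
  ext <- candidate_set(counts$phrase[present],
                       counts$occurrences[present],
                       rep("external", sum(present)))
  out <- rbind(candidates, ext)
  out <- out[order(out$phrase, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_set", "data.frame")
  attr(out, "dropped") <- dropped
  out
}
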