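# Corpus readers, tokenization and the document container.
#
# Text is represented, after reading, as lists of token vectors: one character
# vector per sentence, lowercased, with boundary punctuation preserved inline
# as the marker token "|". The marker is what keeps candidate harvesting and
# contiguous phrase matching from crossing a punctuation boundary.

#' Boundary marker token
#'
#' The reserved token used to record the position of boundary punctuation
#' inside a tokenized sentence. Phrases never contain it; contiguous matches
#' never cross it.
#'
#' @return A length-one character string.
#' @export
boundary_marker <- function() "|"

#' Default stopword list
#'
#' The ~130-word PubMed/NLM stopword list shipped with the package. Stopwords
#' delimit candidate strings during harvesting (a harvested phrase contains no
#' stopword), but remain ordinary tokens for counting and retrieval so that
#' externally supplied phrases containing stopwords (e.g. "activin a") can
#' still be matched contiguously.
#'
#' @return Character vector of lowercase words.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "pubmed_stopwords.txt", package = "phraseminer")
  readLines(path, encoding = "UTF-8")
}

#' Tokenizer configuration
#'
#' @param stopwords Character vector of lowercase stopwords. Defaults to the
#'   shipped PubMed list.
#' @param boundary_punctuation Characters that delimit candidate strings.
#'   Hyphen and apostrophe are never allowed here: they are word-internal
#'   (so "3'-utr" and "zinc-finger" are single tokens).
#' @param intra_token_characters Characters retained inside tokens.
#'
#' @return An object of class `tokenizer_config`.
#' @export
tokenizer_config <- function(stopwords = default_stopwords(),
                             boundary_punctuation = default_boundary_punctuation(),
                             intra_token_characters = c("-", "'")) {
  if (!all(c("-", "'") %in% intra_token_characters)) {
    stop("hyphen and apostrophe must be intra-token characters")
  }
  if (any(intra_token_characters %in% boundary_punctuation)) {
    stop("intra-token characters cannot also be boundary punctuation")
  }
  cfg <- list(
    stopwords = unique(tolower(stopwords)),
    boundary_punctuation = boundary_punctuation,
    intra_token_characters = intra_token_characters
  )
  cfg$boundary_regex <- paste0(
    "[", gsub("([][\\\\^-])", "\\\\\\1", paste(boundary_punctuation, collapse = "")), "]"
  )
  class(cfg) <- "tokenizer_config"
  cfg
}

default_boundary_punctuation <- function() {
  c(".", ",", ";", ":", "!", "?", "(", ")", "[", "]", "{", "}",
    "\"", "|", "/", "\\", "<", ">", "=", "+", "*", "&", "%", "$",
    "#", "@", "^", "~", "_", "`")
}

# Sentence split rule: terminal punctuation, whitespace, then an uppercase
# letter or digit. Deliberately simple; applied before lowercasing.
split_raw_sentences <- function(text) {
  if (!nzchar(trimws(text))) return(character(0))
  strsplit(text, "(?<=[.?!])\\s+(?=[A-Z0-9])", perl = TRUE)[[1]]
}

tokenize_sentence <- function(sentence, config) {
  s <- tolower(sentence)
  s <- gsub(config$boundary_regex, paste0(" ", boundary_marker(), " "), s,
            perl = TRUE)
  toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return(character(0))
  # tokens made only of intra-token characters carry no word content; they
  # act as boundaries
  only_intra <- grepl("^['-]+$", toks)
  toks[only_intra] <- boundary_marker()
  # collapse runs of markers, strip leading/trailing markers
  m <- toks == boundary_marker()
  toks <- toks[!(m & c(FALSE, m[-length(m)]))]
  while (length(toks) && toks[1] == boundary_marker()) toks <- toks[-1]
  while (length(toks) && toks[length(toks)] == boundary_marker()) {
    toks <- toks[-length(toks)]
  }
  toks
}

#' Tokenize text into sentences of tokens
#'
#' Lowercases, optionally splits into sentences (at `.`, `?` or `!` followed
#' by whitespace and an uppercase letter or digit), splits tokens on
#' whitespace and boundary punctuation, and records boundary punctuation
#' positions as the marker token [boundary_marker()]. Hyphens and apostrophes
#' stay inside tokens. Titles should be tokenized with
#' `split_sentences = FALSE` (a title is one sentence).
#'
#' @param text A single string (UTF-8).
#' @param config A [tokenizer_config()].
#' @param split_sentences Apply the sentence-split rule? Default `TRUE`.
#'
#' @return A list of character vectors, one per non-empty sentence.
#' @export
tokenize_and_split <- function(text, config = tokenizer_config(),
                               split_sentences = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  sentences <- if (split_sentences) split_raw_sentences(text) else text
  out <- lapply(sentences, tokenize_sentence, config = config)
  out[lengths(out) > 0L]
}

#' Construct a document
#'
#' @param doc_id Non-empty identifier string (PMID-like).
#' @param title,abstract Lists of token vectors (sentences), as produced by
#'   [tokenize_and_split()].
#'
#' @return An object of class `document`.
#' @export
document <- function(doc_id, title, abstract) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  structure(list(doc_id = doc_id, title = title, abstract = abstract),
            class = "document")
}

#' Assemble documents into a collection
#'
#' @param docs List of [document()] objects.
#' @param skipped Number of input records skipped (e.g. abstract-less).
#'
#' @return An object of class `document_collection` (a named list of
#'   documents; `attr(x, "skipped")` reports the skip count).
#' @export
document_collection <- function(docs, skipped = 0L) {
  ids <- vapply(docs, function(d) d$doc_id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate document id(s): ", paste(unique(dup), collapse = ", "))
  }
  names(docs) <- ids
  structure(docs, skipped = as.integer(skipped),
            class = c("document_collection", "list"))
}

#' @export
print.document_collection <- function(x, ...) {
  ns <- sum(vapply(x, function(d) length(d$title) + length(d$abstract),
                   integer(1)))
  cat("<document_collection> ", length(x), " documents, ", ns, " sentences",
      if (attr(x, "skipped") > 0L)
        paste0(" (", attr(x, "skipped"), " records skipped on read)"),
      "\n", sep = "")
  invisible(x)
}

make_document <- function(id, title_text, abstract_text, config) {
  document(
    doc_id = id,
    title = tokenize_and_split(title_text, config, split_sentences = FALSE),
    abstract = tokenize_and_split(abstract_text, config, split_sentences = TRUE)
  )
}

#' Read a TSV corpus
#'
#' Reads the plain corpus dialect: UTF-8 lines of `id TAB title TAB abstract`,
#' no header. Records with an empty abstract are skipped and counted in the
#' collection's skip report. Embedded tabs are illegal.
#'
#' @param path File path.
#' @param config A [tokenizer_config()].
#'
#' @return A [document_collection()].
#' @export
read_tsv_corpus <- function(path, config = tokenizer_config()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  # count columns by tabs so trailing empty fields are not lost
  n_col <- vapply(gregexpr("\t", lines, fixed = TRUE), function(m) {
    if (m[1] == -1L) 1L else length(m) + 1L
  }, integer(1))
  bad <- which(n_col != 3L)
  if (length(bad)) {
    stop("line ", bad[1], ": expected 3 tab-separated columns, found ",
         n_col[bad[1]])
  }
  fields <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    c(f, rep("", 3L - length(f)))
  })
  docs <- list()
  skipped <- 0L
  for (f in fields) {
    if (!nzchar(trimws(f[3]))) {
      skipped <- skipped + 1L
      next
    }
    docs[[length(docs) + 1L]] <- make_document(f[1], f[2], f[3], config)
  }
  if (!length(docs)) stop("no usable records (all lacked an abstract)")
  document_collection(docs, skipped = skipped)
}

#' Write a collection as TSV
#'
#' Inverse of [read_tsv_corpus()] up to tokenization: tokens are joined with
#' spaces, boundary markers are written as `|`, each sentence is terminated
#' with a period and its first character capitalized so that re-reading splits
#' sentences identically. Re-reading the written file reproduces the
#' collection.
#'
#' @param collection A [document_collection()].
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_tsv_corpus <- function(collection, path) {
  detok <- function(sentences) {
    paste(vapply(sentences, function(toks) {
      s <- paste(toks, collapse = " ")
      paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)), ".")
    }, character(1)), collapse = " ")
  }
  lines <- vapply(collection, function(d) {
    paste(d$doc_id, detok(d$title), detok(d$abstract), sep = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a MEDLINE/PubMed XML corpus
#'
#' Parses article records (`MedlineCitation` nodes) from PubMed XML. Each
#' usable record must carry a PMID, an `ArticleTitle` and a non-empty
#' abstract; abstract-less records are skipped and counted. Multiple
#' `AbstractText` sections are concatenated.
#'
#' @param path File path to well-formed PubMed XML.
#' @param config A [tokenizer_config()].
#'
#' @return A [document_collection()].
#' @export
read_medline_xml <- function(path, config = tokenizer_config()) {
  xml <- tryCatch(
    xml2::read_xml(path),
    error = function(e) stop("malformed XML in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  cites <- xml2::xml_find_all(xml, "//MedlineCitation")
  if (!length(cites)) stop("no MedlineCitation records found")
  docs <- list()
  skipped <- 0L
  ids <- character(0)
  for (node in cites) {
    pmid <- xml2::xml_text(xml2::xml_find_first(node, "./PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(node, ".//ArticleTitle"))
    abst <- paste(
      xml2::xml_text(xml2::xml_find_all(node, ".//Abstract/AbstractText")),
      collapse = " "
    )
    if (!nzchar(trimws(abst))) {
      skipped <- skipped + 1L
      next
    }
    if (pmid %in% ids) stop("duplicate PMID: ", pmid)
    ids <- c(ids, pmid)
    docs[[length(docs) + 1L]] <- make_document(pmid, title, abst, config)
  }
  if (!length(docs)) stop("no usable records (all lacked an abstract)")
  document_collection(docs, skipped = skipped)
}
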