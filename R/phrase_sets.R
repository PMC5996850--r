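# Final phrase-set assembly and the released companion file formats.

#' Group phrases by in-set contiguous subphrases
#'
#' For each phrase, finds every strict contiguous token subsequence of length
#' >= 2 that is itself a member of the set, ordered left-to-right by start
#' position and then by increasing length ("super heavy oil" over the set
#' containing "super heavy" and "heavy oil" gives those two, in that order).
#'
#' @param phrase_set Character vector of deduplicated space-joined phrases.
#' @return Named list mapping each phrase to its (possibly empty) character
#'   vector of subphrases.
#' @export
group_subphrases <- function(phrase_set) {
  phrase_set <- unique(phrase_set)
  toks <- strsplit(phrase_set, " ", fixed = TRUE)
  out <- lapply(toks, function(t) {
    L <- length(t)
    if (L < 3L) return(character(0))
    subs <- character(0)
    for (start in seq_len(L - 1L)) {
      for (len in 2L:(L - 1L)) {
        if (start + len - 1L > L) break
        s <- paste(t[start:(start + len - 1L)], collapse = " ")
        if (s %in% phrase_set) subs <- c(subs, s)
      }
    }
    subs
  })
  names(out) <- phrase_set
  out
}

#' Assemble phrase-set entries
#'
#' Joins, for every selected phrase, its segmentation trace, retrieval
#' evaluation, the sorted list of documents containing it contiguously in the
#' abstract, and its in-set subphrases.
#'
#' @param selected Character vector of selected phrases.
#' @param traces Named list of `segmentation_trace` objects.
#' @param evaluations Data frame of [evaluate_phrase()] rows.
#' @param index The `corpus_index` (for the document lists).
#'
#' @return A list of `phrase_set_entry` objects, sorted by phrase (byte
#'   order).
#' @export
phrase_set_entries <- function(selected, traces, evaluations, index) {
  selected <- sort(unique(selected), method = "radix")
  groups <- group_subphrases(selected)
  lapply(selected, function(p) {
    ev <- evaluations[evaluations$phrase == p, , drop = FALSE]
    structure(list(
      phrase = p,
      trace = traces[[p]],
      evaluation = ev,
      pmids = sort(names(index$unit_postings[[p]]), method = "radix"),
      subphrases = groups[[p]]
    ), class = "phrase_set_entry")
  })
}

fmt6 <- function(x) sprintf("%.6g", x)

#' Write the four phrase-set output files
#'
#' Writes, under `out_dir`, the released file formats:
#' \describe{
#'   \item{`<prefix>.txt`}{one phrase per line;}
#'   \item{`<prefix>.group`}{phrase then its in-set subphrases,
#'     tab-separated;}
#'   \item{`<prefix>.pmid`}{phrase then the ids of documents containing it,
#'     tab-separated;}
#'   \item{`<prefix>.sco`}{vertical-bar separated: phrase | comma-separated
#'     chained-test p-values | the two average precisions (word-based first,
#'     then phrase-based), comma-separated.}
#' }
#' Numbers are printed with 6 significant digits; output is UTF-8,
#' newline-terminated, and byte-identical across runs for identical input.
#'
#' @param entries List of entries from [phrase_set_entries()], sorted by
#'   phrase.
#' @param out_dir Output directory (created if needed).
#' @param prefix File name stem (default `"all_dictionary"`).
#'
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_outputs <- function(entries, out_dir, prefix = "all_dictionary") {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- file.path(out_dir, paste0(prefix, c(".txt", ".group", ".pmid",
                                               ".sco")))
  names(paths) <- c("txt", "group", "pmid", "sco")
  phrases <- vapply(entries, `[[`, character(1), "phrase")
  writeLines(phrases, paths["txt"], useBytes = TRUE)
  writeLines(vapply(entries, function(e) {
    paste(c(e$phrase, e$subphrases), collapse = "\t")
  }, character(1)), paths["group"], useBytes = TRUE)
  writeLines(vapply(entries, function(e) {
    paste(c(e$phrase, e$pmids), collapse = "\t")
  }, character(1)), paths["pmid"], useBytes = TRUE)
  writeLines(vapply(entries, function(e) {
    paste(e$phrase,
          paste(fmt6(e$trace$steps$p_value), collapse = ","),
          paste(fmt6(c(e$evaluation$ap_word, e$evaluation$ap_phrase)),
                collapse = ","),
          sep = "|")
  }, character(1)), paths["sco"], useBytes = TRUE)
  invisible(paths)
}

#' Read the four phrase-set output files back
#'
#' Round-trip companion to [write_outputs()].
#'
#' @param out_dir Directory containing the files.
#' @param prefix File name stem (default `"all_dictionary"`).
#'
#' @return A list with `phrases` (character), `groups` (named list),
#'   `pmids` (named list) and `sco` (data frame with `phrase`, `p_values`
#'   (list column), `ap_word`, `ap_phrase`).
#' @export
read_phrase_outputs <- function(out_dir, prefix = "all_dictionary") {
  rd <- function(ext) readLines(file.path(out_dir, paste0(prefix, ext)),
                                encoding = "UTF-8", warn = FALSE)
  phrases <- rd(".txt")
  parse_tab <- function(lines) {
    f <- strsplit(lines, "\t", fixed = TRUE)
    stats::setNames(lapply(f, function(x) x[-1]),
                    vapply(f, `[[`, character(1), 1L))
  }
  groups <- parse_tab(rd(".group"))
  pmids <- parse_tab(rd(".pmid"))
  sco_f <- strsplit(rd(".sco"), "|", fixed = TRUE)
  sco <- data.frame(
    phrase = vapply(sco_f, `[[`, character(1), 1L),
    stringsAsFactors = FALSE
  )
  sco$p_values <- lapply(sco_f, function(x) {
    as.numeric(strsplit(x[2], ",", fixed = TRUE)[[1]])
  })
  aps <- lapply(sco_f, function(x) {
    as.numeric(strsplit(x[3], ",", fixed = TRUE)[[1]])
  })
  sco$ap_word <- vapply(aps, `[[`, numeric(1), 1L)
  sco$ap_phrase <- vapply(aps, `[[`, numeric(1), 2L)
  list(phrases = phrases, groups = groups, pmids = pmids, sco = sco)
}
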