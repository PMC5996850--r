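# End-to-end pipeline: read -> harvest (+ lexicon) -> segment (+ BH) ->
# evaluate (four criteria) -> select -> write.

#' Pipeline configuration
#'
#' All tunables of the pipeline stages, validated against their module
#' preconditions.
#'
#' @param alpha Per-step segmentation p-value threshold (default 0.01).
#' @param bh_q Per-candidate Benjamini-Hochberg false discovery rate
#'   (default 0.01).
#' @param min_count Minimum contiguous occurrences for a harvested candidate
#'   (default 5).
#' @param k1,b,idf_floor BM25 constants, see [bm25_params()].
#' @param min_pos Criterion-1 minimum positive count (default 5).
#' @param ap_word_floor Criterion-4 floor on word-based AP (default 0.01).
#' @param min_improvement Minimum relative improvement for the selected set
#'   (default 0; 0.10 gives the small subset).
#' @param baseline_reps Monte-Carlo replicates for the random baseline.
#' @param seed Integer seed for every stochastic component (the random
#'   baseline).
#' @param stopword_path Optional stopword file (one lowercase word per
#'   line); `NULL` uses the shipped PubMed list.
#' @param lexicon_path Optional external phrase lexicon (one phrase per
#'   line).
#'
#' @return An object of class `phrase_config`.
#' @export
phrase_config <- function(alpha = 0.01, bh_q = 0.01, min_count = 5L,
                          k1 = 1.2, b = 0.75, idf_floor = 0,
                          min_pos = 5L, ap_word_floor = 0.01,
                          min_improvement = 0, baseline_reps = 1000L,
                          seed = 1L, stopword_path = NULL,
                          lexicon_path = NULL) {
  stopifnot(alpha > 0, alpha < 1, bh_q > 0, bh_q < 1, min_count >= 1,
            k1 > 0, b >= 0, b <= 1, idf_floor >= 0, min_pos >= 1,
            ap_word_floor >= 0, min_improvement >= 0, baseline_reps >= 1)
  structure(list(alpha = alpha, bh_q = bh_q, min_count = as.integer(min_count),
                 k1 = k1, b = b, idf_floor = idf_floor,
                 min_pos = as.integer(min_pos), ap_word_floor = ap_word_floor,
                 min_improvement = min_improvement,
                 baseline_reps = as.integer(baseline_reps),
                 seed = as.integer(seed),
                 stopword_path = stopword_path,
                 lexicon_path = lexicon_path),
            class = "phrase_config")
}

empty_evaluations <- function() {
  data.frame(phrase = character(0), n_pos = integer(0), n_total = integer(0),
             ap_word = numeric(0), ap_phrase = numeric(0),
             ap_random = numeric(0), improvement = numeric(0),
             crit_min_pos = logical(0), crit_phrase_gt_word = logical(0),
             crit_gt_random = logical(0), crit_word_floor = logical(0),
             selected = logical(0), stringsAsFactors = FALSE)
}

load_corpus <- function(corpus, tok_config) {
  if (inherits(corpus, "document_collection")) return(corpus)
  if (!file.exists(corpus)) stop("corpus file not found: ", corpus)
  if (grepl("\\.xml$", corpus, ignore.case = TRUE)) {
    read_medline_xml(corpus, tok_config)
  } else {
    read_tsv_corpus(corpus, tok_config)
  }
}

#' Run the full phrase-extraction pipeline
#'
#' Reads (or takes) a corpus, harvests candidate strings, merges an optional
#' external lexicon, segments candidates by the chained hypergeometric test
#' with per-candidate Benjamini-Hochberg correction, evaluates the accepted
#' phrases under the four BM25 retrieval criteria, selects the final phrase
#' set, and (optionally) writes the four output files plus a run report.
#' Deterministic for a fixed corpus and configuration.
#'
#' @param corpus A [document_collection()], or the path of a TSV corpus
#'   (`id TAB title TAB abstract`) or of a MEDLINE XML file (`.xml`).
#' @param config A [phrase_config()].
#' @param out_dir If non-`NULL`, directory to write `all_dictionary.{txt,
#'   group,pmid,sco}` and `run_report.txt` into.
#'
#' @return An object of class `phrase_run`: a list with `selected` and
#'   `small_subset` (character vectors), `entries`, `evaluations`, `traces`,
#'   `candidates`, `report` and `config`.
#' @export
run_pipeline <- function(corpus, config = phrase_config(), out_dir = NULL) {
  tok_config <- if (is.null(config$stopword_path)) {
    tokenizer_config()
  } else {
    tokenizer_config(stopwords = readLines(config$stopword_path,
                                           encoding = "UTF-8", warn = FALSE))
  }
  collection <- load_corpus(corpus, tok_config)

  candidates <- harvest_candidates(collection, tok_config,
                                   min_count = config$min_count)
  n_harvested <- nrow(candidates)
  if (!is.null(config$lexicon_path)) {
    candidates <- merge_external_lexicon(candidates, config$lexicon_path,
                                         collection, tok_config)
  }
  n_external <- sum(candidates$source == "external")

  traces <- list()
  evaluations <- empty_evaluations()
  index <- NULL
  if (nrow(candidates) > 0L) {
    units <- candidate_prefix_units(candidates$phrase)
    index <- build_index(collection, units)
    traces <- segment_candidates(candidates, index,
                                 alpha = config$alpha, bh_q = config$bh_q)
    outcomes <- vapply(traces, `[[`, character(1), "outcome")
    accepted <- names(traces)[outcomes == "accepted"]
    if (length(accepted)) {
      evaluations <- evaluate_phrases(
        accepted, index,
        params = bm25_params(config$k1, config$b, config$idf_floor),
        min_pos = config$min_pos, ap_word_floor = config$ap_word_floor,
        baseline_reps = config$baseline_reps, baseline_seed = config$seed
      )
    }
  } else {
    outcomes <- character(0)
  }

  selected <- select_subset(evaluations, config$min_improvement)
  small <- select_subset(evaluations, max(config$min_improvement, 0.10))
  entries <- if (length(selected)) {
    phrase_set_entries(selected, traces, evaluations, index)
  } else {
    list()
  }

  # attribute each non-selected accepted phrase (with a non-empty judged
  # set) to its first failing criterion
  nonempty <- evaluations[evaluations$n_total >= 1L, , drop = FALSE]
  fail_of <- function(r) {
    if (!r$crit_min_pos) "min_pos"
    else if (!r$crit_phrase_gt_word) "phrase_not_better"
    else if (!r$crit_gt_random) "not_above_random"
    else if (!r$crit_word_floor) "word_ap_floor"
    else if (!is.na(r$improvement) &&
             r$improvement < config$min_improvement) "below_min_improvement"
    else "selected"
  }
  attribution <- if (nrow(nonempty)) {
    vapply(seq_len(nrow(nonempty)),
           function(i) fail_of(nonempty[i, , drop = FALSE]), character(1))
  } else {
    character(0)
  }
  crit_names <- c("min_pos", "phrase_not_better", "not_above_random",
                  "word_ap_floor", "below_min_improvement")
  rejected_by <- vapply(crit_names,
                        function(nm) sum(attribution == nm), integer(1))

  report <- list(
    n_docs = length(collection),
    n_sentences = if (is.null(index)) NA_integer_ else n_sentences(index),
    n_harvested = n_harvested,
    n_external = n_external,
    n_candidates = nrow(candidates),
    n_accepted = sum(outcomes == "accepted"),
    n_discarded = sum(outcomes == "discarded"),
    n_bh_eliminated = sum(outcomes == "bh_eliminated"),
    n_evaluated = nrow(evaluations),
    n_empty_judged = sum(evaluations$n_total == 0L),
    rejected_by = rejected_by,
    n_selected = length(selected),
    n_small_subset = length(small)
  )

  run <- structure(list(selected = selected, small_subset = small,
                        entries = entries, evaluations = evaluations,
                        traces = traces, candidates = candidates,
                        report = report, config = config),
                   class = "phrase_run")
  if (!is.null(out_dir)) {
    write_outputs(entries, out_dir)
    write_run_report(run, file.path(out_dir, "run_report.txt"))
  }
  run
}

write_run_report <- function(run, path) {
  r <- run$report
  lines <- c(
    paste0("n_docs: ", r$n_docs),
    paste0("n_sentences: ", r$n_sentences),
    paste0("n_harvested: ", r$n_harvested),
    paste0("n_external: ", r$n_external),
    paste0("n_candidates: ", r$n_candidates),
    paste0("n_accepted: ", r$n_accepted),
    paste0("n_discarded: ", r$n_discarded),
    paste0("n_bh_eliminated: ", r$n_bh_eliminated),
    paste0("n_evaluated: ", r$n_evaluated),
    paste0("n_empty_judged: ", r$n_empty_judged),
    paste0("rejected_", names(r$rejected_by), ": ", r$rejected_by),
    paste0("n_selected: ", r$n_selected),
    paste0("n_small_subset: ", r$n_small_subset),
    "",
    paste0("config_", setdiff(names(run$config),
                              c("stopword_path", "lexicon_path")), ": ",
           unlist(run$config[setdiff(names(run$config),
                                     c("stopword_path", "lexicon_path"))]))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.phrase_run <- function(x, ...) {
  r <- x$report
  cat("<phrase_run>\n",
      "  documents:            ", r$n_docs, "\n",
      "  candidates:           ", r$n_candidates,
      " (", r$n_harvested, " harvested, ", r$n_external, " external)\n",
      "  segmentation accepted:", r$n_accepted,
      " (", r$n_discarded, " discarded, ", r$n_bh_eliminated,
      " BH-eliminated)\n",
      "  selected phrases:     ", r$n_selected,
      " (small subset: ", r$n_small_subset, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.phrase_run <- function(object, ...) {
  ev <- object$evaluations
  sel <- ev[ev$phrase %in% object$selected, , drop = FALSE]
  out <- list(
    report = object$report,
    mean_ap_word = mean(sel$ap_word),
    mean_ap_phrase = mean(sel$ap_phrase),
    mean_ap_random = mean(sel$ap_random),
    mean_improvement = mean(sel$improvement)
  )
  class(out) <- "summary.phrase_run"
  out
}

#' @export
print.summary.phrase_run <- function(x, ...) {
  cat("Selected phrases: ", x$report$n_selected, "\n",
      "Mean AP (word-based):   ", format(x$mean_ap_word, digits = 4), "\n",
      "Mean AP (phrase-based): ", format(x$mean_ap_phrase, digits = 4),
      "  (", sprintf("%+.1f%%", 100 * x$mean_improvement), " mean per-phrase)\n",
      "Mean AP (random):       ", format(x$mean_ap_random, digits = 4), "\n",
      sep = "")
  invisible(x)
}
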