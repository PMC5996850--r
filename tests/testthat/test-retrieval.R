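# A collection with controlled counts for BM25 checks: 100 documents, the
# word "q" in exactly 10 abstracts (once each), all abstracts 5 tokens long.
bm25_fixture <- function() {
  docs <- lapply(1:100, function(i) {
    toks <- c(sprintf("f%02d", i %% 7), "c1", "c2", "c3", "c4")
    if (i <= 10) toks[2] <- "q"
    document(sprintf("%03d", i), title = list(c("title", "words")),
             abstract = list(toks))
  })
  document_collection(docs)
}

test_that("word BM25 reduces to the idf under tf = 1 at average length", {
  idx <- build_index(bm25_fixture())
  p <- bm25_params()
  # D = 100, df = 10, tf = 1, len = avgdl: score = ln(90.5/10.5)
  expect_equal(bm25_word_score("001", "q", idx, p), log(90.5 / 10.5),
               tolerance = 1e-12)
  # absent word contributes 0
  expect_equal(bm25_word_score("050", "q", idx, p), 0)
  expect_equal(bm25_word_score("001", c("q", "zzz"), idx, p),
               log(90.5 / 10.5), tolerance = 1e-12)
})

test_that("phrase BM25 scores the phrase as one term and saturates in tf", {
  reps <- function(n, s) replicate(n, s, simplify = FALSE)
  coll <- document_collection(c(
    lapply(1:3, function(i) {
      document(paste0("p", i), title = list(c("zinc", "finger")),
               abstract = list(c("zinc", "finger", "x", "y", "z")))
    }),
    list(document("scat", title = list(c("other")),
                  abstract = list(c("zinc", "q", "finger", "y", "z")))),
    lapply(1:4, function(i) {
      document(paste0("bg", i), title = list(c("bg")),
               abstract = list(c("a1", "a2", "a3", "b1", "b2")))
    })
  ))
  idx <- build_index(coll, units = "zinc finger")
  p <- bm25_params()
  # words present but never contiguous: phrase score exactly 0
  expect_equal(bm25_phrase_score("scat", "zinc finger", idx, p), 0)
  expect_gt(bm25_phrase_score("p1", "zinc finger", idx, p), 0)
  # tf = 1 at len = avgdl: the score equals the phrase idf
  expect_equal(bm25_phrase_score("p1", "zinc finger", idx, p),
               log((8 - 3 + 0.5) / (3 + 0.5)), tolerance = 1e-12)
  # saturation: the weight approaches (k1 + 1) as tf grows at fixed length
  w <- function(tf) tf * (p$k1 + 1) / (tf + p$k1)
  expect_lt(w(1000), p$k1 + 1)
  expect_gt(w(1000), w(10))
})

test_that("judged sets follow the conservative title-labeling rule", {
  coll <- toy_collection()
  idx <- build_index(coll, units = "zinc finger")
  js <- build_judged_set("zinc finger", idx)
  expect_equal(js$doc_id, c("1001", "1003", "1005"))
  expect_equal(js$positive, c(TRUE, FALSE, FALSE))
  # a title with only some of the words stays negative
  idx2 <- build_index(coll, units = "x y")
  js2 <- build_judged_set("x y", idx2)
  expect_equal(js2$doc_id, "1006")
  expect_true(js2$positive)  # title "x and y study" has both words
})

test_that("average precision matches the worked example and brute force", {
  judged <- structure(
    data.frame(doc_id = c("a", "b", "c"),
               positive = c(TRUE, FALSE, TRUE)),
    class = c("judged_set", "data.frame"))
  # ranks [pos, neg, pos]: (1/1 + 2/3) / 2 = 5/6
  expect_equal(rank_and_ap(judged, c(3, 2, 1)), 5 / 6)
  # all positives first -> 1; single positive last of n -> 1/n
  judged$positive <- c(TRUE, TRUE, FALSE)
  expect_equal(rank_and_ap(judged, c(3, 2, 1)), 1)
  judged$positive <- c(FALSE, FALSE, TRUE)
  expect_equal(rank_and_ap(judged, c(3, 2, 1)), 1 / 3)
  judged$positive <- c(FALSE, FALSE, FALSE)
  expect_error(rank_and_ap(judged, c(3, 2, 1)), "no positive")

  set.seed(808)
  for (rep in 1:200) {
    n <- sample(2:30, 1)
    ids <- sprintf("d%03d", sample(1000, n))
    scores <- round(stats::runif(n), 2)  # rounded to force score ties
    pos <- stats::runif(n) < 0.4
    if (!any(pos)) pos[sample(n, 1)] <- TRUE
    judged <- structure(data.frame(doc_id = ids, positive = pos),
                        class = c("judged_set", "data.frame"))
    expect_equal(rank_and_ap(judged, scores),
                 bf_average_precision(ids, scores, pos))
  }
})

test_that("ties are broken by ascending document id", {
  judged <- structure(
    data.frame(doc_id = c("b", "a"), positive = c(TRUE, FALSE)),
    class = c("judged_set", "data.frame"))
  # equal scores: "a" (negative) ranks first by id -> AP = 1/2
  expect_equal(rank_and_ap(judged, c(1, 1)), 1 / 2)
})

test_that("random baseline: enumeration matches hand values and full permutations", {
  expect_equal(random_baseline_ap(2, 2), 1)
  # n_pos = 1, n_total = 2: (1 + 1/2) / 2
  expect_equal(random_baseline_ap(1, 2), 0.75)

  # against an explicit average over all n! orderings
  perm_ap <- function(n_pos, n_total) {
    labels <- c(rep(TRUE, n_pos), rep(FALSE, n_total - n_pos))
    perms <- function(v) {
      if (length(v) <= 1L) return(list(v))
      do.call(c, lapply(seq_along(v), function(i) {
        lapply(perms(v[-i]), function(p) c(v[i], p))
      }))
    }
    mean(vapply(perms(seq_len(n_total)), function(ord) {
      l <- labels[ord]
      mean((cumsum(l) / seq_along(l))[l])
    }, numeric(1)))
  }
  for (n_total in 2:5) {
    for (n_pos in 1:(n_total - 1)) {
      expect_equal(random_baseline_ap(n_pos, n_total),
                   perm_ap(n_pos, n_total), tolerance = 1e-12,
                   info = paste(n_pos, n_total))
    }
  }
})

test_that("Monte-Carlo baseline is seeded, reproducible, and leaves the RNG alone", {
  set.seed(1); before <- stats::runif(1)
  set.seed(1)
  a <- random_baseline_ap(3, 20, reps = 500, seed = 9)
  b <- random_baseline_ap(3, 20, reps = 500, seed = 9)
  expect_identical(a, b)
  expect_equal(stats::runif(1), before)  # caller's stream unaffected
})

test_that("phrase evaluation applies the four criteria", {
  g <- generate_corpus(synthetic_spec(
    n_docs = 150, n_planted = 3, insertion_probability = 0.06,
    scatter_probability = 0.03, n_scatter_controls = 0,
    title_carry_probability = 0.8, seed = 909
  ))
  idx <- build_index(g$collection, units = g$truth$planted)
  ev <- evaluate_phrases(g$truth$planted, idx, baseline_seed = 4L)
  # flags are exactly the stated comparisons, and selection their conjunction
  expect_equal(ev$crit_min_pos, ev$n_pos >= 5)
  expect_equal(ev$crit_phrase_gt_word, ev$ap_phrase > ev$ap_word)
  expect_equal(ev$crit_gt_random, ev$ap_phrase > ev$ap_random)
  expect_equal(ev$crit_word_floor, ev$ap_word > 0.01)
  expect_equal(ev$selected,
               ev$crit_min_pos & ev$crit_phrase_gt_word &
                 ev$crit_gt_random & ev$crit_word_floor)
  # planted phrases carry the title signal: most are selected and the mean
  # phrase-as-unit AP exceeds the mean word AP
  expect_true(mean(ev$selected) >= 2 / 3)
  expect_gt(mean(ev$ap_phrase), mean(ev$ap_word))
  expect_equal(ev$improvement, (ev$ap_phrase - ev$ap_word) / ev$ap_word)

  # criterion 1: a phrase with fewer than five positives is rejected
  few <- document_collection(c(
    lapply(1:4, function(i) {
      document(paste0("t", i), title = list(c("rare", "pair")),
               abstract = list(c("rare", "pair", "x", "y")))
    }),
    lapply(1:6, function(i) {
      document(paste0("n", i), title = list(c("other")),
               abstract = list(c("rare", "pair", "a", "b")))
    })
  ))
  idx_few <- build_index(few, units = "rare pair")
  ev_few <- evaluate_phrase("rare pair", idx_few)
  expect_equal(ev_few$n_pos, 4L)
  expect_false(ev_few$crit_min_pos)
  expect_false(ev_few$selected)
})

test_that("selection by minimum improvement is an antitone filter", {
  ev <- rbind(
    evdf <- data.frame(phrase = c("p1", "p2", "p3"),
                       n_pos = 6L, n_total = 20L,
                       ap_word = c(0.20, 0.30, 0.10),
                       ap_phrase = c(0.21, 0.45, 0.25),
                       ap_random = 0.05,
                       improvement = c(0.05, 0.50, 1.50),
                       crit_min_pos = TRUE, crit_phrase_gt_word = TRUE,
                       crit_gt_random = TRUE, crit_word_floor = TRUE,
                       selected = TRUE)
  )
  expect_equal(select_subset(ev, 0), c("p1", "p2", "p3"))
  # improvement 5% < 10%: excluded from the stricter subset
  expect_equal(select_subset(ev, 0.10), c("p2", "p3"))
  expect_equal(select_subset(ev, 1.00), "p3")
  for (m in c(0, 0.1, 0.5, 2)) {
    expect_true(all(select_subset(ev, m + 0.1) %in% select_subset(ev, m)))
  }
})
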