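test_that("hypergeometric pmf matches direct binomial-coefficient arithmetic", {
  # N=10, Ns=3, Nt=4: P(Y=2) = C(4,2) C(6,1) / C(10,3) = 36/120
  expect_equal(hypergeom_pmf(2, 10, 3, 4), 0.3, tolerance = 1e-12)
  # unit 2 in every sentence: P(Y = Ns) = 1
  expect_equal(hypergeom_pmf(3, 10, 3, 10), 1, tolerance = 1e-12)
  # outside the support: 0, not an error
  expect_equal(hypergeom_pmf(c(-1, 5), 10, 3, 4), c(0, 0))
})

test_that("pmf normalizes and agrees with dhyper over random small stats", {
  set.seed(101)
  for (rep in 1:200) {
    N <- sample(2:200, 1)
    Ns <- sample.int(N, 1)
    Nt <- sample.int(N, 1)
    ys <- max(0, Ns + Nt - N):min(Ns, Nt)
    p <- hypergeom_pmf(ys, N, Ns, Nt)
    expect_equal(sum(p), 1, tolerance = 1e-10)
    expect_equal(p, stats::dhyper(ys, Nt, N - Nt, Ns), tolerance = 1e-12)
  }
})

test_that("tail p-value matches exact rational brute force and phyper", {
  # worked example: N=10, Ns=3, Nt=4, N'_st=2 -> 36/120 + 4/120 = 1/3
  expect_equal(hypergeom_pvalue(10, 3, 4, 2), 1 / 3, tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(10, 3, 4, 0), 1)

  set.seed(202)
  for (rep in 1:200) {
    N <- sample(2:200, 1)
    Ns <- sample.int(N, 1)
    Nt <- sample.int(N, 1)
    Nst <- sample.int(min(Ns, Nt) + 1L, 1) - 1L
    got <- hypergeom_pvalue(N, Ns, Nt, Nst)
    ref <- stats::phyper(Nst - 1, Nt, N - Nt, Ns, lower.tail = FALSE)
    ref <- max(min(ref, 1), 0)
    if (Nst <= max(0, Ns + Nt - N)) ref <- 1
    expect_equal(got, ref, tolerance = 1e-10, info = paste(N, Ns, Nt, Nst))
    if (N <= 25) {
      expect_equal(got, bf_pvalue_exact(N, Ns, Nt, Nst), tolerance = 1e-12)
    }
  }
  # dedicated exact-rational sweep where choose() is exact
  set.seed(203)
  for (rep in 1:200) {
    N <- sample(2:25, 1)
    Ns <- sample.int(N, 1)
    Nt <- sample.int(N, 1)
    Nst <- sample.int(min(Ns, Nt) + 1L, 1) - 1L
    expect_equal(hypergeom_pvalue(N, Ns, Nt, Nst),
                 bf_pvalue_exact(N, Ns, Nt, Nst), tolerance = 1e-12)
  }
})

test_that("the p-value is non-increasing in the contiguous count", {
  set.seed(303)
  for (rep in 1:50) {
    N <- sample(10:150, 1)
    Ns <- sample.int(N, 1)
    Nt <- sample.int(N, 1)
    pv <- vapply(0:min(Ns, Nt), function(nst) {
      hypergeom_pvalue(N, Ns, Nt, nst)
    }, numeric(1))
    expect_true(all(diff(pv) <= 1e-12))
  }
})

chain_index <- function(coll, phrases) {
  build_index(coll, units = candidate_prefix_units(phrases))
}

test_that("chained segmentation accepts planted strings and rejects chance pairings", {
  # "x y z" planted contiguously in ~50 of 1000 sentences; x, y, z never
  # co-occur otherwise
  g <- generate_corpus(synthetic_spec(
    n_docs = 200, sentences_per_abstract = c(5, 5), n_planted = 1,
    planted_length = 3, insertion_probability = 0.05,
    title_carry_probability = 0, n_scatter_controls = 0, seed = 404
  ))
  phrase <- g$truth$planted[1]
  idx <- chain_index(g$collection, phrase)
  tr <- segment_candidate(phrase, idx, alpha = 0.01)
  expect_equal(tr$outcome, "accepted")
  expect_equal(nrow(tr$steps), 2L)  # three tokens -> two chained tests
  expect_true(all(tr$steps$p_value < 1e-6))
  # every step agrees with the brute-force tail sum on the same counts
  for (i in seq_len(nrow(tr$steps))) {
    s <- tr$steps[i, ]
    expect_equal(s$p_value,
                 stats::phyper(s$n_st - 1, s$n_t, n_sentences(idx) - s$n_t,
                               s$n_s, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("a chain fails at the first non-significant step", {
  # "early lung": frequent words adjacent once; "lung cancer": always adjacent
  mk_sent <- function(...) c(...)
  sents <- c(
    replicate(30, mk_sent("early", "results"), simplify = FALSE),
    replicate(30, mk_sent("lung", "cancer"), simplify = FALSE),
    list(mk_sent("early", "lung", "cancer", "treatment")),
    replicate(10, mk_sent("treatment", "options"), simplify = FALSE)
  )
  coll <- document_collection(list(
    document("1", title = list(c("t")), abstract = sents)
  ))
  phrase <- "early lung cancer treatment"
  idx <- chain_index(coll, phrase)
  tr <- segment_candidate(phrase, idx, alpha = 0.01)
  expect_equal(tr$outcome, "discarded")
  expect_equal(tr$fail_step, 1L)
  expect_equal(nrow(tr$steps), 3L)
})

test_that("two-token candidates have exactly one step and zero counts discard", {
  coll <- toy_collection()
  idx <- chain_index(coll, c("zinc finger", "zinc dna"))
  tr <- segment_candidate("zinc finger", idx)
  expect_equal(nrow(tr$steps), 1L)
  # "zinc dna" never occurs contiguously: p-value 1, discarded
  tr0 <- segment_candidate("zinc dna", idx)
  expect_equal(tr0$outcome, "discarded")
  expect_equal(tr0$steps$p_value, 1)
})

test_that("BH step-up matches the p.adjust reference and keeps boundary cases", {
  mk_trace <- function(p) {
    structure(list(phrase = "a b", tokens = c("a", "b"),
                   steps = data.frame(prefix = "a", next_word = "b",
                                      n_s = 1L, n_t = 1L, n_st = 1L,
                                      p_value = NA_real_)[rep(1, length(p)), ],
                   alpha = 0.01, outcome = "accepted",
                   fail_step = NA_integer_),
              class = "segmentation_trace")
  }
  set_p <- function(tr, p) { tr$steps$p_value <- p; tr }

  # hand-executed step-up: only rank 1 of [0.001, 0.008, 0.04] is rejected
  tr <- bh_correct(set_p(mk_trace(1:3), c(0.001, 0.008, 0.04)), q = 0.01)
  expect_equal(tr$outcome, "bh_eliminated")
  # m = 1 reduces BH to the plain threshold
  expect_equal(bh_correct(set_p(mk_trace(1), 0.005), q = 0.01)$outcome,
               "accepted")
  # p-values exactly at q k / m at each rank: all rejected (inclusive)
  q <- 0.01; m <- 4
  exact <- q * seq_len(m) / m
  expect_equal(bh_correct(set_p(mk_trace(1:m), exact), q = q)$outcome,
               "accepted")

  set.seed(505)
  for (rep in 1:500) {
    m <- sample(1:8, 1)
    p <- round(stats::runif(m), 3)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    got <- bh_correct(set_p(mk_trace(seq_len(m)), p), q = q)$outcome
    want <- if (bf_bh_all_rejected(p, q)) "accepted" else "bh_eliminated"
    expect_equal(got, want, info = paste(q, paste(p, collapse = ",")))
  }
})

test_that("the accepted set shrinks as alpha decreases", {
  g <- generate_corpus(synthetic_spec(
    n_docs = 150, n_planted = 8, insertion_probability = 0.03,
    n_scatter_controls = 0, seed = 606
  ))
  cand <- harvest_candidates(g$collection, tokenizer_config(), min_count = 3L)
  idx <- chain_index(g$collection, cand$phrase)
  acc <- function(alpha) {
    tr <- segment_candidates(cand, idx, alpha = alpha, bh_q = alpha)
    names(tr)[vapply(tr, `[[`, character(1), "outcome") == "accepted"]
  }
  a_loose <- acc(0.05)
  a_mid <- acc(0.01)
  a_tight <- acc(0.001)
  expect_true(all(a_tight %in% a_mid))
  expect_true(all(a_mid %in% a_loose))
})

test_that("background word pairs are accepted at no more than twice alpha", {
  g <- generate_corpus(synthetic_spec(
    n_docs = 1000, n_planted = 0, n_scatter_controls = 0, seed = 707
  ))
  cand <- harvest_candidates(g$collection, tokenizer_config(), min_count = 5L)
  bigrams <- cand$phrase[cand$length == 2L]
  expect_gte(length(bigrams), 500L)
  idx <- chain_index(g$collection, bigrams)
  traces <- segment_candidates(bigrams, idx, alpha = 0.01)
  n_acc <- sum(vapply(traces, `[[`, character(1), "outcome") == "accepted")
  expect_lte(n_acc / length(bigrams), 2 * 0.01)
})

test_that("external candidates with stopwords chain over all tokens", {
  sents <- c(
    replicate(12, c("activin", "a", "receptor"), simplify = FALSE),
    replicate(20, c("background", "noise", "words"), simplify = FALSE)
  )
  coll <- document_collection(list(
    document("1", title = list(c("t")), abstract = sents)
  ))
  idx <- chain_index(coll, "activin a")
  tr <- segment_candidate("activin a", idx, alpha = 0.01)
  expect_equal(tr$steps$next_word, "a")
  expect_equal(tr$outcome, "accepted")
})
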