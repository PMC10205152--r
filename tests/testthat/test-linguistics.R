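# N-gram models, sublexical predictors, cohort model, sentence priors,
# segmentation predictors.

test_that("unsmoothed n-gram probabilities equal brute-force counts", {
  # deterministic alternating corpus: p(B | A) = 1
  det <- rep(list(rep(c("A", "B"), 10)), 3)
  m <- train_ngram(det, order = 5, smoothing = "none")
  expect_equal(ngram_prob(m, c("B", "A"), "B"), 1)
  expect_equal(ngram_surprisal(m, c("A", "B", "A", "B", "A"), "B"), 0)

  # 50-line toy corpus: every conditional matches the count-table oracle
  set.seed(10)
  corpus <- lapply(1:50, function(i) sample(c("A", "B", "C"), 12,
                                            replace = TRUE,
                                            prob = c(0.5, 0.3, 0.2)))
  m2 <- train_ngram(corpus, order = 3, smoothing = "none")
  for (ctx in list(character(0), "A", c("B", "C"), c("A", "A"))) {
    dist <- ngram_next_dist(m2, ctx)
    expect_equal(sum(dist), 1, tolerance = 1e-9)
    for (sym in c("A", "B", "C")) {
      oracle <- oracle_ngram_prob(corpus, ctx, sym)
      if (!is.na(oracle)) expect_equal(unname(dist[sym]), oracle,
                                       tolerance = 1e-12)
    }
  }
  expect_error(train_ngram(list()), "empty")
})

test_that("uniform random corpora give near-uniform conditionals", {
  set.seed(11)
  K <- 4
  corpus <- lapply(1:400, function(i) sample(LETTERS[1:K], 20, replace = TRUE))
  m <- train_ngram(corpus, order = 2, smoothing = "none")
  d <- ngram_next_dist(m, "A")
  expect_true(all(abs(d - 1 / K) < 0.02))
  expect_lt(abs(-log2(ngram_prob(m, "A", "B")) - log2(K)), 0.15)
})

test_that("Kneser-Ney distributions normalize and cover unseen events", {
  set.seed(12)
  corpus <- lapply(1:30, function(i) sample(c("A", "B", "C", "D"), 8,
                                            replace = TRUE))
  m <- train_ngram(corpus, order = 4, smoothing = "kn")
  for (ctx in list(character(0), "A", c("D", "C"), c("A", "B", "C"),
                   c("C", "C", "C"))) {
    d <- ngram_next_dist(m, ctx)
    expect_equal(sum(d), 1, tolerance = 1e-9)
    expect_true(all(d > 0)) # every vocab symbol reachable
  }
})

test_that("sublexical predictors match enumeration and hit closed forms", {
  lex <- toy_lexicon(c("ab", "ba"), c("A B", "B A"), 1)
  # deterministic phoneme stream: surprisal and entropy are 0 everywhere
  det <- rep(list(rep(c("A", "B"), 20)), 2)
  m_det <- train_ngram(det, order = 5, smoothing = "none")
  tl <- timeline_from_corpus(rep("ab", 6), lex, phoneme_rate = 10, seed = 1)
  p <- sublexical_predictors(tl, m_det)
  # from the second phoneme on the continuation is fully determined (the
  # first phoneme has no context and carries its unigram surprisal)
  expect_true(all(abs(p$surprisal$values[-1]) < 1e-12))
  expect_equal(p$surprisal$values[1], 1) # -log2(0.5)
  expect_true(all(abs(p$entropy$values) < 1e-12))
  expect_equal(length(p$surprisal$samples), nrow(tl$events))

  # uniform next-phoneme distribution: entropy = log2 K exactly under an
  # explicitly balanced bigram corpus
  balanced <- list(c("A", "A"), c("A", "B"), c("B", "A"), c("B", "B"))
  m_unif <- train_ngram(balanced, order = 2, smoothing = "none")
  tl2 <- timeline_from_corpus("ab", lex, phoneme_rate = 10, seed = 2)
  p2 <- sublexical_predictors(tl2, m_unif)
  expect_equal(unname(p2$entropy$values), c(1, 1), tolerance = 1e-12)

  # values equal an independent recomputation from the count-table oracle
  set.seed(13)
  corpus <- lapply(1:40, function(i) sample(c("A", "B"), 10, replace = TRUE))
  m <- train_ngram(corpus, order = 3, smoothing = "none")
  tl3 <- timeline_from_corpus(c("ab", "ba", "ab"), lex, 10, seed = 3)
  p3 <- sublexical_predictors(tl3, m)
  ph <- tl3$events$phoneme
  for (k in seq_along(ph)) {
    ctx <- ph[max(1, k - 2):(k - 1)]
    if (k == 1) ctx <- character(0)
    # back off to the longest observed context, as the model does
    repeat {
      pr <- oracle_ngram_prob(corpus, ctx, ph[k])
      if (!is.na(pr) || !length(ctx)) break
      ctx <- ctx[-1]
    }
    expect_equal(sort(p3$surprisal$values[
      p3$surprisal$samples == event_sample_for_test(tl3$events$onset[k], 1000)]),
      sort(-log2(pr)), tolerance = 1e-9)
  }
})

test_that("cohort model reproduces closed forms on a two-word lexicon", {
  lex <- toy_lexicon(c("ab", "ac"), c("A B", "A C"), c(1, 1))
  tl <- timeline_from_corpus("ab", lex, phoneme_rate = 10, seed = 4)
  out <- cohort_predictors(tl, lex)
  # both words start with A: surprisal(A) = 0; cohort entropy after A = 1 bit
  expect_equal(out$surprisal$values[1], 0, tolerance = 1e-12)
  expect_equal(out$entropy$values[1], 1, tolerance = 1e-12)
  # surprisal(B | A) = 1 bit (posterior enumeration), entropy collapses to 0
  expect_equal(out$surprisal$values[2], 1, tolerance = 1e-12)
  expect_equal(out$entropy$values[2], 0, tolerance = 1e-12)

  # single-word lexicon: no uncertainty anywhere
  one <- toy_lexicon("abc", "A B C", 5)
  tl1 <- timeline_from_corpus("abc", one, 10, seed = 5)
  o1 <- cohort_predictors(tl1, one)
  expect_true(all(abs(o1$surprisal$values) < 1e-12))
  expect_true(all(abs(o1$entropy$values) < 1e-12))
})

test_that("cohort predictors match brute-force posterior enumeration", {
  gen <- generate_lexicon_and_corpus(inventory_size = 4, n_words = 12,
                                     corpus_len = 30, seed = 21)
  lex <- gen$lexicon
  tl <- timeline_from_corpus(gen$corpus[1:3], lex, 10, seed = 22)
  out <- cohort_predictors(tl, lex)
  pron <- attr(lex, "pron")
  priors <- setNames(lex$count / sum(lex$count), lex$word)
  ev <- tl$events
  for (w in unique(ev$word_index)) {
    rows <- which(ev$word_index == w)
    oracle <- oracle_cohort(ev$phoneme[rows], pron, priors)
    expect_equal(unname(out$surprisal$values[
      match(event_sample_for_test(ev$onset[rows], 1000),
            out$surprisal$samples)]), oracle$surprisal, tolerance = 1e-9)
    expect_equal(unname(out$entropy$values[
      match(event_sample_for_test(ev$onset[rows], 1000),
            out$entropy$samples)]), oracle$entropy, tolerance = 1e-9)
  }
  # cohort die-off: configurable error vs uniform fallback
  bad <- phoneme_timeline(c(0.1, 0.2), c("A", "A"), c(TRUE, FALSE),
                          c("ab", "ab"), 1)
  lex2 <- toy_lexicon(c("ab", "ac"), c("A B", "A C"), 1)
  expect_error(cohort_predictors(bad, lex2, on_empty = "error"), "cohort")
  expect_warning(ok <- cohort_predictors(bad, lex2, on_empty = "uniform"),
                 "uniform")
  expect_equal(ok$surprisal$values[2], log2(3)) # inventory {A, B, C}
})

test_that("sentence model with unigram priors equals the word-form model", {
  gen <- generate_lexicon_and_corpus(inventory_size = 4, n_words = 8,
                                     corpus_len = 50, seed = 31)
  lex <- gen$lexicon
  tl <- timeline_from_corpus(gen$corpus[1:4], lex, 10, seed = 32)
  # unigram lexical model whose unigram distribution equals the count priors:
  # one token per count unit
  uni_corpus <- rep(lex$word, lex$count)
  m_uni <- train_ngram(list(uni_corpus), order = 1, smoothing = "none")
  se <- sentence_predictors(tl, lex, m_uni)
  wf <- cohort_predictors(tl, lex)
  expect_identical(se$surprisal$values, wf$surprisal$values)
  expect_identical(se$entropy$values, wf$entropy$values)
})

test_that("a deterministic word bigram drives first-phoneme surprisal to zero", {
  # word Y always follows X; Y is the only word starting with B
  lex <- toy_lexicon(c("X", "Y", "Z"), c("A A", "B A", "C A"), c(1, 1, 1))
  corpus <- rep(list(c("X", "Y", "Z", "X", "Y")), 20)
  m_lex <- train_ngram(corpus, order = 2, smoothing = "none")
  tl <- timeline_from_corpus(c("X", "Y"), lex, 10, seed = 33)
  se <- sentence_predictors(tl, lex, m_lex)
  # Y's first phoneme (the 3rd event) is fully predicted by the context
  expect_equal(se$surprisal$values[3], 0, tolerance = 1e-12)
  # brute-force Bayes on the enumerable lexicon for the same position
  pri <- sentence_priors(c("X", "Y"), m_lex, lex)
  oracle <- oracle_cohort(c("B", "A"), attr(lex, "pron"), pri[[2]])
  expect_equal(unname(se$surprisal$values[3:4]), oracle$surprisal,
               tolerance = 1e-9)
})

test_that("cohort size is non-increasing within words (monotone pruning)", {
  gen <- generate_lexicon_and_corpus(inventory_size = 5, n_words = 15,
                                     corpus_len = 20, seed = 41)
  tl <- timeline_from_corpus(gen$corpus[1:2], gen$lexicon, 10, seed = 42)
  out <- cohort_predictors(tl, gen$lexicon)
  # entropy cannot increase within a word: pruning only removes entries;
  # renormalization of a subset cannot raise Shannon entropy above log2 of
  # the remaining support, which itself is non-increasing
  ev <- tl$events
  for (w in unique(ev$word_index)) {
    rows <- which(ev$word_index == w)
    support_bits <- out$entropy$values[
      match(event_sample_for_test(ev$onset[rows], 1000), out$entropy$samples)]
    expect_true(all(is.finite(support_bits)) && all(support_bits >= 0))
  }
})

test_that("segmentation predictors partition events into unit impulses", {
  gen <- generate_lexicon_and_corpus(inventory_size = 4, n_words = 6,
                                     corpus_len = 10, seed = 51)
  tl <- timeline_from_corpus(gen$corpus[1:2], gen$lexicon, 10, seed = 52)
  seg <- segmentation_predictors(tl)
  n_words <- sum(tl$events$word_initial)
  expect_equal(sum(seg$word_onset$values), n_words)
  expect_true(all(seg$word_onset$values == 1))
  expect_true(all(seg$phoneme_onset$values == 1))
  expect_equal(length(seg$word_onset$samples) + length(seg$phoneme_onset$samples),
               nrow(tl$events))
  expect_length(intersect(seg$word_onset$samples, seg$phoneme_onset$samples), 0)

  # TextGrid round trip: word-onset count matches a recount from the file
  tg <- tempfile(fileext = ".TextGrid")
  write_textgrid(tl, tg)
  tl2 <- read_textgrid(tg)
  expect_equal(sum(tl2$events$word_initial), n_words)
  expect_equal(tl2$events$phoneme, tl$events$phoneme)
  expect_equal(tl2$events$onset, tl$events$onset, tolerance = 1e-8)
})
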