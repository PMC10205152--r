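# Synthetic-data generators: n-back sequences, lexicon/corpus, timelines,
# and EEG simulation.

test_that("n-back sequences satisfy the load rule under exhaustive rescan", {
  for (load in c(0, 3)) {
    seq <- generate_nback_sequence(n_items = 23, n_targets = 6, load = load,
                                   item_duration = 0.5, isi = 2.5, seed = 7)
    it <- seq$items
    expect_equal(seq$total_duration, 69)
    expect_equal(sum(it$target), 6)
    # targets only among the last 20 items
    expect_true(all(which(it$target) > nrow(it) - 20))
    # independent rescan: the rule holds exactly at flagged positions and
    # fails at every unflagged position from its first applicable index
    first <- if (load == 3) 4L else 2L
    for (i in first:nrow(it)) {
      ref <- if (load == 3) it$locus[i - 3] else it$locus[1]
      expect_identical(it$locus[i] == ref, it$target[i])
    }
    # fixed inter-onset interval
    expect_true(all(abs(diff(it$onset) - 3) < 1e-12))
  }
})

test_that("n-back generation is deterministic and validates constraints", {
  a <- generate_nback_sequence(seed = 11)
  b <- generate_nback_sequence(seed = 11)
  expect_identical(a, b)
  expect_equal(sum(generate_nback_sequence(n_targets = 0, seed = 1)$items$target), 0)
  expect_error(generate_nback_sequence(n_items = 23, n_targets = 21),
               "infeasible")
  expect_error(generate_nback_sequence(n_items = 5, n_targets = 4, load = 3),
               "infeasible")
})

test_that("lexicon/corpus generator matches a recount oracle", {
  out <- generate_lexicon_and_corpus(inventory_size = 6, n_words = 10,
                                     corpus_len = 200, zipf_exponent = 1,
                                     seed = 3)
  expect_s3_class(out$lexicon, "toy_lexicon")
  toks <- unlist(out$corpus)
  expect_true(all(toks %in% out$lexicon$word))
  # determinism: an independent regeneration recounts to the same corpus
  out2 <- generate_lexicon_and_corpus(inventory_size = 6, n_words = 10,
                                      corpus_len = 200, zipf_exponent = 1,
                                      seed = 3)
  expect_identical(out2$corpus, out$corpus)
  # token counts equal an independent recount of the emitted corpus
  recount <- vapply(out$lexicon$word, function(w) sum(toks == w), integer(1))
  expect_identical(as.integer(table(factor(toks, out$lexicon$word))),
                   unname(recount))
  # zipf_exponent = 0: token frequencies uniform within binomial error
  unif <- generate_lexicon_and_corpus(inventory_size = 6, n_words = 5,
                                      corpus_len = 600, zipf_exponent = 0,
                                      seed = 4)
  n <- length(unlist(unif$corpus))
  counts <- table(factor(unlist(unif$corpus), levels = unif$lexicon$word))
  p0 <- 1 / 5
  expect_true(all(abs(counts / n - p0) < 4 * sqrt(p0 * (1 - p0) / n)))
})

test_that("timelines are ordered with word-initial flags matching the lexicon", {
  lex <- toy_lexicon(c("ab", "c"), c("A B", "C"), c(2, 1))
  tl <- timeline_from_corpus(list(c("ab", "c", "ab")), lex,
                             phoneme_rate = 10, seed = 9)
  ev <- tl$events
  expect_equal(nrow(ev), 5)
  expect_true(all(diff(ev$onset) > 0))
  expect_true(all(ev$onset < tl$total_duration))
  # recompute flags independently from the lexicon pronunciations
  pron_len <- c(ab = 2L, c = 1L)
  expected_flags <- unlist(lapply(c("ab", "c", "ab"), function(w)
    c(TRUE, rep(FALSE, pron_len[[w]] - 1L))))
  expect_identical(ev$word_initial, expected_flags)
  # rate arithmetic: 100 phonemes at 10/s last about 10 s
  lex2 <- toy_lexicon(c("x", "y"), c("A", "B"), 1)
  tl2 <- timeline_from_corpus(rep(c("x", "y"), 50), lex2, phoneme_rate = 10,
                              seed = 2)
  expect_lt(abs(tl2$total_duration - 10.1), 0.2)
  expect_error(timeline_from_corpus("zzz", lex, 10), "absent")
})

test_that("single-word timeline has one initial flag", {
  lex <- toy_lexicon(c("ab", "cd"), c("A B", "C D"), 1)
  tl <- timeline_from_corpus("ab", lex, phoneme_rate = 5, seed = 1)
  expect_equal(nrow(tl$events), 2)
  expect_identical(tl$events$word_initial, c(TRUE, FALSE))
})

test_that("synthetic EEG decomposes exactly into signal plus noise", {
  sim <- make_recovery_sim(duration = 20, n_trials = 2, noise_sigma = 0.5)
  eeg <- sim$eeg
  expect_identical(eeg$data, eeg$signal + eeg$noise)
  expect_equal(ncol(eeg$data),
               max(eeg$trial_bounds))
  # determinism: same seed, bit-identical
  eeg2 <- synthesize_eeg(list(events = sim$pred), list(events = sim$K),
                         2, 100, noise_sigma = 0.5, n_trials = 2, seed = 44)
  expect_identical(eeg$data, eeg2$data)
})

test_that("convolution respects trial boundaries", {
  fs <- 100
  basis <- lag_basis(fs = fs)
  # one impulse at the very end of trial 1 must not bleed into trial 2
  pred <- impulse_series(samples = 99, values = 1, fs = fs, n_samples = 200,
                         name = "edge")
  K <- random_smooth_kernels(1, basis$lags, 1, fs, seed = 5)
  eeg <- synthesize_eeg(list(edge = pred), list(edge = K), 1, fs,
                        noise_sigma = 0, n_trials = 2, seed = 6)
  expect_true(all(eeg$signal[1, 101:200] == 0))
})

test_that("SNR calibration gives the requested signal-to-noise variance ratio", {
  sim <- make_recovery_sim(duration = 60, n_trials = 3)
  eeg <- synthesize_eeg(list(events = sim$pred), list(events = sim$K), 2,
                        100, n_trials = 3, seed = 50, snr_db = 0)
  ratio <- mean(apply(eeg$signal, 1, var)) / mean(apply(eeg$noise, 1, var))
  expect_lt(abs(ratio - 1), 0.05)
})

test_that("all-zero kernels give pure-noise EEG", {
  basis <- lag_basis()
  pred <- random_impulse_predictor(10, 100, seed = 1)
  eeg <- synthesize_eeg(list(ev = pred),
                        list(ev = zero_kernels(1, basis$lags, 3)),
                        3, 100, noise_sigma = 1, n_trials = 1, seed = 2)
  expect_true(all(eeg$signal == 0))
  expect_identical(eeg$data, eeg$noise)
})
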