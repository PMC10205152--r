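# Synthetic study material: toy lexicons and corpora, phoneme timelines,
# n-back visual stimulus sequences, and trial-structured EEG simulated from
# known kernels. These generators exercise every downstream stage without any
# external data and make parameter-recovery validation possible.

# ---------------------------------------------------------------------------
# Lexicon and corpus

#' Construct a toy phonological lexicon
#'
#' @param word Character vector of unique word ids.
#' @param phonemes Character vector of pronunciations, each a space-separated
#'   string of phoneme labels.
#' @param count Positive integer frequency counts (the word prior mass;
#'   missing words in downstream lookups receive a count of 1).
#' @return A `toy_lexicon`: a data.frame with columns `word`, `phonemes`,
#'   `count`, plus a `pron` attribute holding pronunciations as vectors.
#' @export
toy_lexicon <- function(word, phonemes, count = 1L) {
  count <- rep_len(as.integer(count), length(word))
  if (anyDuplicated(word)) stopf("word ids must be unique")
  if (any(!nzchar(phonemes))) stopf("phoneme strings must be nonempty")
  if (any(count < 1L)) stopf("counts must be >= 1")
  pron <- strsplit(phonemes, " ", fixed = TRUE)
  inventory <- sort(unique(unlist(pron)))
  if (length(inventory) < 2L) stopf("phoneme inventory must have >= 2 symbols")
  lex <- data.frame(word = word, phonemes = phonemes, count = count,
                    stringsAsFactors = FALSE)
  attr(lex, "pron") <- stats::setNames(pron, word)
  attr(lex, "inventory") <- inventory
  class(lex) <- c("toy_lexicon", "data.frame")
  lex
}

lexicon_pron <- function(lexicon) attr(lexicon, "pron")

lexicon_inventory <- function(lexicon) attr(lexicon, "inventory")

#' Generate a toy lexicon and a Zipf-distributed corpus
#'
#' Creates `n_words` unique pronunciations (2-5 phonemes each) over a finite
#' inventory, assigns Zipfian frequency counts by rank, and samples a training
#' corpus of utterances whose token frequencies follow the same Zipf law.
#'
#' @param inventory_size Number of phoneme symbols (>= 2).
#' @param n_words Number of lexicon entries (>= 2).
#' @param corpus_len Number of utterances to sample.
#' @param zipf_exponent Zipf exponent `s` (token probability of rank-`i` word
#'   proportional to `i^-s`); 0 gives a uniform vocabulary.
#' @param seed Integer seed; fixed seeds give bit-identical output.
#' @return `list(lexicon = toy_lexicon, corpus = list of word-id vectors)`.
#' @export
generate_lexicon_and_corpus <- function(inventory_size = 12, n_words = 40,
                                        corpus_len = 500, zipf_exponent = 1,
                                        seed = NULL) {
  assert_count(inventory_size, "inventory_size", min = 2L)
  assert_count(n_words, "n_words", min = 2L)
  assert_count(corpus_len, "corpus_len", min = 1L)
  inv <- if (inventory_size <= 26L) LETTERS[seq_len(inventory_size)] else
    sprintf("P%02d", seq_len(inventory_size))
  with_seed(seed, {
    prons <- character(0)
    while (length(prons) < n_words) {
      len <- sample(2:5, n_words, replace = TRUE)
      cand <- vapply(len, function(l)
        paste(sample(inv, l, replace = TRUE), collapse = " "), character(1))
      prons <- unique(c(prons, cand))[seq_len(min(n_words, length(unique(c(prons, cand)))))]
    }
    words <- sprintf("w%03d", seq_len(n_words))
    ranks <- seq_len(n_words)
    wt <- ranks^(-zipf_exponent)
    counts <- pmax(1L, as.integer(round(1000 * wt / wt[1])))
    lex <- toy_lexicon(words, prons, counts)
    p <- wt / sum(wt)
    corpus <- lapply(seq_len(corpus_len), function(i) {
      n <- sample(3:8, 1L)
      sample(words, n, replace = TRUE, prob = p)
    })
    list(lexicon = lex, corpus = corpus)
  })
}

# ---------------------------------------------------------------------------
# Phoneme timeline (synthetic forced alignment)

#' Construct a phoneme timeline
#'
#' @param onset Strictly increasing onset times in seconds.
#' @param phoneme Phoneme labels.
#' @param word_initial Logical: is this event the first phoneme of its word?
#' @param word_id Word id of the containing word.
#' @param total_duration Total duration in seconds (> last onset).
#' @return A `phoneme_timeline`: `events` data.frame (with a `word_index`
#'   column numbering word instances) and `total_duration`.
#' @export
phoneme_timeline <- function(onset, phoneme, word_initial, word_id,
                             total_duration) {
  n <- length(onset)
  stopifnot(length(phoneme) == n, length(word_initial) == n,
            length(word_id) == n)
  if (n && any(diff(onset) <= 0)) stopf("onsets must be strictly increasing")
  if (n && onset[n] >= total_duration) {
    stopf("all onsets must lie before total_duration")
  }
  word_index <- cumsum(as.logical(word_initial))
  if (n && !word_initial[1]) stopf("first event must be word-initial")
  ev <- data.frame(onset = onset, phoneme = phoneme,
                   word_initial = as.logical(word_initial),
                   word_id = word_id, word_index = word_index,
                   stringsAsFactors = FALSE)
  structure(list(events = ev, total_duration = total_duration),
            class = "phoneme_timeline")
}

#' @export
print.phoneme_timeline <- function(x, ...) {
  cat(sprintf("<phoneme_timeline> %d phonemes / %d words over %.2f s\n",
              nrow(x$events), max(c(0L, x$events$word_index)),
              x$total_duration))
  invisible(x)
}

#' Lay out a corpus as a timed phoneme sequence
#'
#' Emulates forced-alignment output: words from `corpus` are concatenated and
#' their phonemes placed at a nominal rate, with uniform onset jitter of up to
#' 10% of the inter-phoneme interval so that downstream code cannot rely on a
#' perfectly regular grid. Jittered onsets remain strictly increasing.
#'
#' @param corpus List of word-id vectors (utterances), or one vector.
#' @param lexicon A [toy_lexicon()] supplying pronunciations.
#' @param phoneme_rate Nominal phonemes per second (> 0).
#' @param seed Integer seed for the jitter.
#' @param jitter Jitter half-width as a fraction of the interval (default 0.1).
#' @return A [phoneme_timeline()].
#' @export
timeline_from_corpus <- function(corpus, lexicon, phoneme_rate = 8,
                                 seed = NULL, jitter = 0.1) {
  assert_scalar(phoneme_rate, "phoneme_rate", min = 1e-9)
  if (!is.list(corpus)) corpus <- list(corpus)
  words <- unlist(corpus, use.names = FALSE)
  pron <- lexicon_pron(lexicon)
  missing <- setdiff(unique(words), names(pron))
  if (length(missing)) {
    stopf("word(s) absent from lexicon: %s",
          paste(missing, collapse = ", "))
  }
  phones <- unlist(pron[words], use.names = FALSE)
  lens <- lengths(pron[words])
  word_initial <- sequence(lens) == 1L
  word_id <- rep(words, lens)
  n <- length(phones)
  dt <- 1 / phoneme_rate
  jit <- with_seed(seed, stats::runif(n, -jitter, jitter))
  onset <- (seq_len(n) - 1L + 0.5) * dt + jit * dt
  phoneme_timeline(onset, phones, word_initial, word_id,
                   total_duration = (n + 1) * dt)
}

# ---------------------------------------------------------------------------
# n-back visual sequences

#' Generate an n-back visual stimulus sequence
#'
#' Items are squares at one of `n_loci` screen positions with a fixed
#' inter-onset interval of `item_duration + isi`. Targets satisfy the load
#' rule exactly: under 3-back the locus equals the locus three positions back;
#' under 0-back it equals the first item's locus. Non-target items are
#' constructed to violate the rule, and targets occur only among the last 20
#' items.
#'
#' @param n_items Number of items (23 gives a 69 s trial at the defaults).
#' @param n_targets Number of targets.
#' @param load 0 or 3 (0-back / 3-back).
#' @param item_duration Item duration in seconds.
#' @param isi Inter-stimulus interval in seconds.
#' @param n_loci Number of screen positions (default 8).
#' @param seed Integer seed.
#' @return A `visual_sequence`: `items` data.frame (`onset`, `locus`,
#'   `target`), plus `item_duration`, `isi`, `load`, `total_duration`.
#' @export
generate_nback_sequence <- function(n_items = 23, n_targets = 6, load = 3,
                                    item_duration = 0.5, isi = 2.5,
                                    n_loci = 8, seed = NULL) {
  assert_count(n_items, "n_items", min = 1L)
  assert_count(n_targets, "n_targets", min = 0L)
  if (!load %in% c(0, 3)) stopf("`load` must be 0 or 3")
  if (load == 3 && n_items < n_targets + 3) {
    stopf("infeasible: need n_items >= n_targets + 3 under 3-back")
  }
  first_applicable <- if (load == 3) 4L else 2L
  eligible <- seq(max(first_applicable, n_items - 19L), n_items)
  eligible <- eligible[eligible >= first_applicable]
  if (n_targets > length(eligible)) {
    stopf("infeasible: %d targets but only %d eligible positions",
          n_targets, length(eligible))
  }
  with_seed(seed, {
    target_pos <- sort(sample(eligible, n_targets))
    target <- logical(n_items)
    target[target_pos] <- TRUE
    locus <- integer(n_items)
    for (i in seq_len(n_items)) {
      ref <- if (load == 3 && i > 3L) locus[i - 3L]
             else if (load == 0 && i > 1L) locus[1L]
             else NA_integer_
      if (target[i]) {
        locus[i] <- ref # guaranteed non-NA: targets start at first_applicable
      } else if (is.na(ref)) {
        locus[i] <- sample.int(n_loci, 1L)
      } else {
        locus[i] <- sample(setdiff(seq_len(n_loci), ref), 1L)
      }
    }
    soa <- item_duration + isi
    items <- data.frame(onset = (seq_len(n_items) - 1) * soa,
                        locus = locus, target = target)
    structure(list(items = items, item_duration = item_duration, isi = isi,
                   load = load, n_loci = n_loci,
                   total_duration = n_items * soa),
              class = "visual_sequence")
  })
}

#' @export
print.visual_sequence <- function(x, ...) {
  cat(sprintf("<visual_sequence> %d items (%d targets), %d-back, %.1f s\n",
              nrow(x$items), sum(x$items$target), x$load, x$total_duration))
  invisible(x)
}

#' Visual onset and offset impulse predictors for a sequence
#'
#' The visual response is modeled like an evoked potential: unit impulses at
#' square onsets and at square offsets (onset + item duration), as two
#' separate predictors whose TRFs are later combined into one effective
#' response function via [combine_visual_trf()].
#'
#' @param seq A `visual_sequence`.
#' @param fs Grid rate in Hz.
#' @return `list(onset = impulse_series, offset = impulse_series)`.
#' @export
visual_impulses <- function(seq, fs = 100) {
  stopifnot(inherits(seq, "visual_sequence"))
  dur <- seq$total_duration
  list(
    onset = impulse_series(times = seq$items$onset, values = 1, fs = fs,
                           duration = dur, name = "visual_onset"),
    offset = impulse_series(times = seq$items$onset + seq$item_duration,
                            values = 1, fs = fs, duration = dur,
                            name = "visual_offset")
  )
}

# ---------------------------------------------------------------------------
# Synthetic EEG from known kernels

#' Random sparse event predictor for simulations
#'
#' Events at Poisson(rate) times with log-normal magnitudes, mimicking the
#' statistics of surprisal-style impulse predictors.
#'
#' @param duration Seconds. @param fs Grid Hz. @param rate Events per second.
#' @param seed Integer seed. @param name Predictor name.
#' @return An [impulse_series()].
#' @export
random_impulse_predictor <- function(duration, fs = 100, rate = 4,
                                     seed = NULL, name = "events") {
  with_seed(seed, {
    n <- stats::rpois(1, rate * duration)
    times <- sort(stats::runif(n, 0, duration - 1 / fs))
    values <- stats::rlnorm(n, 0, 0.5)
    impulse_series(times = times, values = values, fs = fs,
                   duration = duration, name = name)
  })
}

#' Smooth random ground-truth kernels
#'
#' Sums of two or three Hamming-windowed cosine bumps per channel, tapered to
#' zero at both ends of the lag axis, giving physiologically plausible smooth
#' response functions that the 50 ms Hamming basis can represent.
#'
#' @param n_dims Predictor dimensions. @param lags Lag axis in samples.
#' @param n_channels Channels. @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @return Array `n_dims x length(lags) x n_channels` with attribute `lags`.
#' @export
random_smooth_kernels <- function(n_dims, lags, n_channels, fs = 100,
                                  seed = NULL) {
  L <- length(lags)
  taper <- sin(pi * (seq_len(L) - 0.5) / L)^2
  with_seed(seed, {
    k <- array(0, dim = c(n_dims, L, n_channels))
    for (d in seq_len(n_dims)) for (ch in seq_len(n_channels)) {
      nb <- sample(2:3, 1L)
      v <- numeric(L)
      for (b in seq_len(nb)) {
        ctr <- stats::runif(1, 0.15, 0.85) * L
        wid <- stats::runif(1, 0.1, 0.3) * L
        amp <- stats::rnorm(1, 0, 1)
        v <- v + amp * exp(-0.5 * ((seq_len(L) - ctr) / wid)^2)
      }
      k[d, , ch] <- v * taper
    }
    structure(k, lags = as.integer(lags), fs = fs)
  })
}

#' Simulate trial-structured EEG as kernel-convolved predictors plus noise
#'
#' Each channel is the sum over predictors of the per-trial convolution of a
#' known kernel with the predictor time series, plus i.i.d. Gaussian noise
#' (optionally 1/f-shaped). Convolution is computed trial by trial with zero
#' padding, so no signal leaks across trial boundaries. The returned object
#' exposes the signal and noise parts separately; their sum is bit-identical
#' to `data`.
#'
#' @param predictors Named list; each element a `n_dims x n_samples` matrix
#'   (or an [impulse_series()] / numeric vector, treated as one dimension)
#'   sampled at `fs` and spanning all trials.
#' @param kernels Named list matching `predictors`; each an array
#'   `n_dims x n_lags x n_channels` with attribute `lags` (samples at `fs`,
#'   negative = predictor leads response), e.g. from
#'   [random_smooth_kernels()].
#' @param n_channels Number of channels.
#' @param fs Sampling rate in Hz.
#' @param noise_sigma Noise standard deviation (ignored if `snr_db` given).
#' @param n_trials Number of equal-length trials; the predictor length must
#'   be divisible by `n_trials`.
#' @param seed Integer seed; same seed gives bit-identical output.
#' @param snr_db If given, `noise_sigma` is set so that the ratio of signal
#'   variance to noise variance (averaged over channels) is `10^(snr_db/10)`.
#' @param noise Either "white" (default) or "pink" (1/f-shaped).
#' @return A `synthetic_eeg`: `data`, `signal`, `noise` (channel x time),
#'   `fs`, `trial_bounds` (n_trials x 2, 1-based inclusive), `kernels`,
#'   `noise_sigma`, `seed`, `channel_names`.
#' @export
synthesize_eeg <- function(predictors, kernels, n_channels, fs = 100,
                           noise_sigma = 1, n_trials = 1, seed = NULL,
                           snr_db = NULL, noise = c("white", "pink")) {
  noise <- match.arg(noise)
  predictors <- lapply(predictors, as_predictor_matrix)
  if (is.null(names(predictors)) || any(!nzchar(names(predictors)))) {
    stopf("predictors must be a named list")
  }
  if (!setequal(names(predictors), names(kernels))) {
    stopf("predictor and kernel names must match")
  }
  n_time <- unique(vapply(predictors, ncol, integer(1)))
  if (length(n_time) != 1L) stopf("all predictors must share one grid")
  if (n_time %% n_trials != 0L) {
    stopf("predictor length %d not divisible by n_trials = %d",
          n_time, n_trials)
  }
  bounds <- trial_bounds(n_time, n_trials)
  signal <- matrix(0, n_channels, n_time)
  for (nm in names(predictors)) {
    X <- predictors[[nm]]
    K <- kernels[[nm]]
    lags <- attr(K, "lags")
    if (is.null(lags)) stopf("kernel '%s' lacks a `lags` attribute", nm)
    if (dim(K)[1] != nrow(X)) {
      stopf("kernel '%s': %d dims but predictor has %d",
            nm, dim(K)[1], nrow(X))
    }
    if (dim(K)[3] != n_channels) stopf("kernel '%s': channel mismatch", nm)
    for (ch in seq_len(n_channels)) {
      signal[ch, ] <- signal[ch, ] +
        convolve_kernel(X, K[, , ch, drop = FALSE], lags, bounds)
    }
  }
  if (!is.null(snr_db)) {
    sig_var <- mean(apply(signal, 1, stats::var))
    noise_sigma <- sqrt(sig_var / 10^(snr_db / 10))
  }
  noise_mat <- with_seed(seed, {
    m <- matrix(stats::rnorm(n_channels * n_time, 0, 1), n_channels, n_time)
    if (noise == "pink") m <- t(apply(m, 1, pink_shape))
    m * noise_sigma
  })
  structure(
    list(data = signal + noise_mat, signal = signal, noise = noise_mat,
         fs = fs, trial_bounds = bounds, kernels = kernels,
         noise_sigma = noise_sigma, seed = seed,
         channel_names = sprintf("ch%02d", seq_len(n_channels))),
    class = "synthetic_eeg"
  )
}

#' @export
print.synthetic_eeg <- function(x, ...) {
  cat(sprintf(
    "<synthetic_eeg> %d channels x %d samples @ %g Hz, %d trials, sigma=%.3g\n",
    nrow(x$data), ncol(x$data), x$fs, nrow(x$trial_bounds), x$noise_sigma))
  invisible(x)
}

trial_bounds <- function(n_time, n_trials) {
  len <- n_time %/% n_trials
  cbind(start = (seq_len(n_trials) - 1L) * len + 1L,
        end = seq_len(n_trials) * len)
}

as_predictor_matrix <- function(x) {
  if (inherits(x, "impulse_series")) return(matrix(as_dense(x), nrow = 1))
  if (is.numeric(x) && is.null(dim(x))) return(matrix(x, nrow = 1))
  if (is.matrix(x)) return(x)
  stopf("predictors must be matrices, vectors or impulse_series")
}

# y(t) = sum_d sum_lag K[d, lag] x[d, t - lag], per trial, zero padded.
convolve_kernel <- function(X, K, lags, bounds) {
  out <- numeric(ncol(X))
  L <- length(lags)
  for (tr in seq_len(nrow(bounds))) {
    idx <- bounds[tr, 1]:bounds[tr, 2]
    Tt <- length(idx)
    for (d in seq_len(nrow(X))) {
      x <- X[d, idx]
      acc <- numeric(Tt)
      for (l in seq_len(L)) {
        h <- K[d, l, 1]
        if (h == 0) next
        lg <- lags[l]
        src <- seq_len(Tt) - lg
        ok <- src >= 1L & src <= Tt
        acc[ok] <- acc[ok] + h * x[src[ok]]
      }
      out[idx] <- out[idx] + acc
    }
  }
  out
}

# Shape white noise to an approximate 1/f amplitude spectrum, preserving the
# total variance.
pink_shape <- function(x) {
  n <- length(x)
  f <- stats::fft(x)
  freq <- c(1, seq_len(n - 1))
  freq <- pmin(freq, n - freq + 1) # symmetric
  f <- f / sqrt(freq)
  out <- Re(stats::fft(f, inverse = TRUE)) / n
  out * stats::sd(x) / stats::sd(out)
}
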