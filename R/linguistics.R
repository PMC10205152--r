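# Information-theoretic linguistic predictors: n-gram surprisal/entropy over
# phonemes (sublexical model), cohort-model word recognition with frequency
# priors (word-form model) or n-gram-conditioned priors (sentence model), and
# unit-impulse segmentation predictors.

NGRAM_SEP <- "\x1f"

ngram_key <- function(syms) paste(syms, collapse = NGRAM_SEP)

# ---------------------------------------------------------------------------
# Model training

#' Train an n-gram model over symbol sequences
#'
#' Counts all k-grams for k = 1..order within each line (no cross-line
#' n-grams). Two probability modes: `"none"` uses raw relative frequencies
#' with backoff to the longest context that was observed in training, and
#' `"kn"` uses interpolated Kneser-Ney smoothing (absolute discounting with
#' continuation counts at the lower orders and a uniform floor), so every
#' in-vocabulary symbol has positive probability in every context.
#'
#' @param corpus A list of character vectors (one symbol sequence per line),
#'   or a character vector of whitespace-separated lines.
#' @param order Model order (default 5: conditioning on 4 preceding symbols).
#' @param smoothing `"none"` or `"kn"`.
#' @param discount Absolute discount for `"kn"` (default 0.75).
#' @return An `ngram_model`.
#' @export
train_ngram <- function(corpus, order = 5, smoothing = c("none", "kn"),
                        discount = 0.75) {
  smoothing <- match.arg(smoothing)
  assert_count(order, "order", min = 1L)
  if (is.character(corpus)) corpus <- strsplit(trimws(corpus), "\\s+")
  corpus <- corpus[lengths(corpus) > 0L]
  if (!length(corpus)) stopf("training corpus is empty")

  keys <- vector("list", order)
  for (k in seq_len(order)) {
    kk <- lapply(corpus, function(syms) {
      n <- length(syms)
      if (n < k) return(character(0))
      if (k == 1L) return(syms)
      vapply(seq_len(n - k + 1L),
             function(i) ngram_key(syms[i:(i + k - 1L)]), character(1))
    })
    keys[[k]] <- unlist(kk, use.names = FALSE)
  }
  grams <- lapply(keys, function(x) {
    tb <- table(x)
    stats::setNames(as.numeric(tb), names(tb))
  })
  vocab <- sort(names(grams[[1]]))

  split_last <- function(g, k) {
    sp <- strsplit(names(g), NGRAM_SEP, fixed = TRUE)
    list(ctx = vapply(sp, function(s) ngram_key(s[-k]), character(1)),
         sym = vapply(sp, function(s) s[k], character(1)))
  }
  ctx_stats <- function(g, k) {
    if (k == 1L) {
      return(list(tot = c(. = sum(g)), types = c(. = length(g))))
    }
    parts <- split_last(g, k)
    tot <- rowsum(unname(g), parts$ctx)
    types <- table(parts$ctx)
    list(tot = stats::setNames(as.numeric(tot), rownames(tot)),
         types = stats::setNames(as.numeric(types), names(types)))
  }
  ctx <- lapply(seq_len(order), function(k) ctx_stats(grams[[k]], k))

  # continuation counts for Kneser-Ney lower orders: cc[[k]][g] = number of
  # distinct symbols v such that the (k+1)-gram (v, g) was observed
  cc <- cc_ctx <- vector("list", max(0L, order - 1L))
  for (k in seq_len(max(0L, order - 1L))) {
    sp <- strsplit(names(grams[[k + 1L]]), NGRAM_SEP, fixed = TRUE)
    suf <- vapply(sp, function(s) ngram_key(s[-1]), character(1))
    tb <- table(suf)
    cc[[k]] <- stats::setNames(as.numeric(tb), names(tb))
    cc_ctx[[k]] <- ctx_stats(cc[[k]], k)
  }

  structure(list(order = order, smoothing = smoothing, discount = discount,
                 vocab = vocab, grams = grams, ctx = ctx, cc = cc,
                 cc_ctx = cc_ctx, n_tokens = sum(grams[[1]])),
            class = "ngram_model")
}

#' @export
print.ngram_model <- function(x, ...) {
  cat(sprintf("<ngram_model> order %d, %d symbols, %d tokens, smoothing=%s\n",
              x$order, length(x$vocab), x$n_tokens, x$smoothing))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Probabilities

#' Next-symbol distribution given a context
#'
#' @param model An [train_ngram()] model.
#' @param context Character vector of preceding symbols (uses at most the
#'   last `order - 1`; may be empty).
#' @return Named probability vector over the model vocabulary (sums to 1).
#' @export
ngram_next_dist <- function(model, context) {
  m <- min(length(context), model$order - 1L)
  context <- if (m > 0) utils::tail(context, m) else character(0)
  if (model$smoothing == "kn") {
    kn_dist(model, m, context)
  } else {
    mle_dist(model, m, context)
  }
}

mle_dist <- function(model, m, context) {
  V <- model$vocab
  while (m > 0L) {
    ck <- ngram_key(context)
    tot <- model$ctx[[m + 1L]]$tot[ck]
    if (!is.na(tot) && tot > 0) {
      n <- model$grams[[m + 1L]][paste(ck, V, sep = NGRAM_SEP)]
      n[is.na(n)] <- 0
      return(stats::setNames(as.numeric(n) / as.numeric(tot), V))
    }
    context <- context[-1]
    m <- m - 1L
  }
  stats::setNames(as.numeric(model$grams[[1L]][V]) / model$n_tokens, V)
}

kn_dist <- function(model, m, context) {
  V <- model$vocab
  D <- model$discount
  if (m == 0L) {
    cc1 <- if (model$order > 1L) model$cc[[1L]] else model$grams[[1L]]
    n <- cc1[V]; n[is.na(n)] <- 0
    tot <- sum(cc1); types <- length(cc1)
    p <- pmax(n - D, 0) / tot + (D * types / tot) * (1 / length(V))
    return(stats::setNames(as.numeric(p), V))
  }
  ck <- ngram_key(context)
  top <- m == model$order - 1L
  G <- if (top) model$grams[[m + 1L]] else model$cc[[m + 1L]]
  st <- if (top) model$ctx[[m + 1L]] else model$cc_ctx[[m + 1L]]
  tot <- st$tot[ck]
  lower <- kn_dist(model, m - 1L, context[-1])
  if (is.na(tot) || tot == 0) return(lower)
  types <- st$types[ck]
  n <- G[paste(ck, V, sep = NGRAM_SEP)]
  n[is.na(n)] <- 0
  p <- pmax(as.numeric(n) - D, 0) / as.numeric(tot) +
    (D * as.numeric(types) / as.numeric(tot)) * lower
  stats::setNames(as.numeric(p), V)
}

#' Conditional probability and surprisal of a symbol
#'
#' @inheritParams ngram_next_dist
#' @param symbol The observed symbol.
#' @return `ngram_prob`: the probability; `ngram_surprisal`: `-log2(p)` bits.
#' @export
ngram_prob <- function(model, context, symbol) {
  dist <- ngram_next_dist(model, context)
  p <- dist[symbol]
  if (is.na(p)) stopf("symbol '%s' not in model vocabulary", symbol)
  if (p == 0) {
    stopf("zero probability for '%s' after context [%s] (unsmoothed model)",
          symbol, paste(context, collapse = " "))
  }
  as.numeric(p)
}

#' @rdname ngram_prob
#' @export
ngram_surprisal <- function(model, context, symbol) {
  -log2(ngram_prob(model, context, symbol))
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log2(p))
}

# ---------------------------------------------------------------------------
# Sublexical predictors

#' Sublexical 5-gram surprisal and entropy predictors
#'
#' At each phoneme event k, surprisal is `-log2 p(ph_k | 4 preceding
#' phonemes)` and entropy is the Shannon entropy of the distribution over the
#' next phoneme given the context ending at `ph_k`. Values are in bits and
#' placed as impulses at phoneme onsets.
#'
#' @param timeline A [phoneme_timeline()].
#' @param model A phoneme [train_ngram()] model.
#' @param fs Predictor grid rate in Hz (default 1000).
#' @return `list(surprisal =, entropy =)`, both [impulse_series()].
#' @export
sublexical_predictors <- function(timeline, model, fs = 1000) {
  ph <- timeline$events$phoneme
  oov <- setdiff(unique(ph), model$vocab)
  if (length(oov)) {
    stopf("phoneme(s) not in model vocabulary: %s",
          paste(oov, collapse = ", "))
  }
  n <- length(ph)
  h <- model$order - 1L
  sur <- ent <- numeric(n)
  for (k in seq_len(n)) {
    ctx_s <- if (k > 1L) ph[max(1L, k - h):(k - 1L)] else character(0)
    sur[k] <- -log2(ngram_prob(model, ctx_s, ph[k]))
    ctx_e <- ph[max(1L, k - h + 1L):k]
    ent[k] <- shannon_entropy(ngram_next_dist(model, ctx_e))
  }
  dur <- timeline$total_duration
  t <- timeline$events$onset
  list(surprisal = impulse_series(times = t, values = sur, fs = fs,
                                  duration = dur, name = "sublexical_surprisal"),
       entropy = impulse_series(times = t, values = ent, fs = fs,
                                duration = dur, name = "sublexical_entropy"))
}

# ---------------------------------------------------------------------------
# Cohort-model predictors

#' Default word priors from lexicon frequency counts
#'
#' @param lexicon A [toy_lexicon()].
#' @param words Optional words to ensure are present; missing words receive a
#'   count of 1 before normalization.
#' @return Named probability vector over lexicon entries.
#' @export
frequency_priors <- function(lexicon, words = NULL) {
  p <- stats::setNames(pmax(lexicon$count, 1), lexicon$word)
  p / sum(p)
}

#' Cohort-model phoneme surprisal and cohort entropy
#'
#' Implements incremental word recognition: at each word onset the cohort is
#' the full lexicon weighted by prior probabilities; each subsequent phoneme
#' removes entries that do not have that phoneme in that position, and the
#' remaining probabilities are renormalized. Phoneme surprisal at position k
#' is `-log2` of the posterior probability mass of words whose k-th phoneme
#' matches, given the first k-1 phonemes; cohort entropy is the Shannon
#' entropy over the pruned cohort.
#'
#' @param timeline A [phoneme_timeline()].
#' @param lexicon A [toy_lexicon()].
#' @param priors Named probability vector over lexicon entries (default:
#'   normalized frequency counts), or a list of such vectors, one per word
#'   instance in the timeline (as produced by [sentence_priors()]).
#' @param fs Predictor grid rate in Hz.
#' @param on_empty What to do when no lexicon entry is compatible:
#'   `"error"`, or `"uniform"` (warn once; the affected word's remaining
#'   phonemes get surprisal `log2(inventory size)` and entropy 0).
#' @return `list(surprisal =, entropy =)`, both [impulse_series()].
#' @export
cohort_predictors <- function(timeline, lexicon, priors = NULL, fs = 1000,
                              on_empty = c("error", "uniform")) {
  on_empty <- match.arg(on_empty)
  pron <- lexicon_pron(lexicon)
  pron_len <- lengths(pron)
  inv_bits <- log2(length(lexicon_inventory(lexicon)))
  ev <- timeline$events
  n_words <- max(ev$word_index)
  if (is.null(priors)) priors <- frequency_priors(lexicon)
  per_word <- is.list(priors) && !is.data.frame(priors)
  if (per_word && length(priors) != n_words) {
    stopf("need one prior vector per word instance (%d), got %d",
          n_words, length(priors))
  }
  # phoneme-by-position lookup table: pos_ph[[k]][entry]
  max_len <- max(pron_len)
  pos_ph <- lapply(seq_len(max_len), function(k)
    vapply(pron, function(p) if (length(p) >= k) p[k] else NA_character_,
           character(1)))

  n <- nrow(ev)
  sur <- ent <- numeric(n)
  warned <- FALSE
  for (w in seq_len(n_words)) {
    rows <- which(ev$word_index == w)
    p0 <- if (per_word) priors[[w]] else priors
    p0 <- p0[lexicon$word]
    p0[is.na(p0)] <- 0
    if (sum(p0) <= 0) stopf("priors assign zero mass to the lexicon")
    p <- p0 / sum(p0)
    active <- which(p > 0)
    dead <- FALSE
    for (j in seq_along(rows)) {
      k <- j # phoneme position within the word
      ph <- ev$phoneme[rows[j]]
      if (dead || k > max_len) {
        compat <- integer(0)
      } else {
        compat <- active[!is.na(pos_ph[[k]][active]) &
                           pos_ph[[k]][active] == ph]
      }
      psum <- sum(p[compat])
      if (!length(compat) || psum <= 0) {
        if (on_empty == "error") {
          stopf("cohort emptied at word %d ('%s'), phoneme %d ('%s')",
                w, ev$word_id[rows[1]], k, ph)
        }
        if (!warned) {
          warnf("cohort emptied; falling back to a uniform phoneme model")
          warned <- TRUE
        }
        dead <- TRUE
        sur[rows[j]] <- inv_bits
        ent[rows[j]] <- 0
        next
      }
      sur[rows[j]] <- -log2(psum)
      active <- compat
      p[active] <- p[active] / psum
      ent[rows[j]] <- shannon_entropy(p[active])
    }
  }
  dur <- timeline$total_duration
  list(surprisal = impulse_series(times = ev$onset, values = sur, fs = fs,
                                  duration = dur, name = "cohort_surprisal"),
       entropy = impulse_series(times = ev$onset, values = ent, fs = fs,
                                duration = dur, name = "cohort_entropy"))
}

#' Sentence-context priors for the cohort model
#'
#' For each word position, the prior probability of every lexicon entry is
#' set proportional to the lexical n-gram probability of its word given the
#' preceding (up to four) words, normalized over the lexicon. With a unigram
#' lexical model this reduces exactly to the frequency priors implied by the
#' model's unigram distribution.
#'
#' @param words Character vector: the word sequence of the stimulus.
#' @param lexical_model A word-level [train_ngram()] model.
#' @param lexicon A [toy_lexicon()].
#' @return List of named prior vectors, one per word position.
#' @export
sentence_priors <- function(words, lexical_model, lexicon) {
  lapply(seq_along(words), function(j) {
    ctx <- if (j > 1) words[max(1L, j - 4L):(j - 1L)] else character(0)
    dist <- ngram_next_dist(lexical_model, ctx)
    p <- dist[lexicon$word]
    p[is.na(p)] <- 0
    if (sum(p) <= 0) {
      stopf("lexical model assigns zero mass to every lexicon word")
    }
    stats::setNames(as.numeric(p / sum(p)), lexicon$word)
  })
}

#' Sentence-model cohort predictors
#'
#' Runs the cohort model of [cohort_predictors()] with per-word priors from
#' [sentence_priors()].
#'
#' @inheritParams cohort_predictors
#' @param lexical_model A word-level [train_ngram()] model.
#' @return `list(surprisal =, entropy =)`, both [impulse_series()].
#' @export
sentence_predictors <- function(timeline, lexicon, lexical_model, fs = 1000,
                                on_empty = c("error", "uniform")) {
  ev <- timeline$events
  words <- ev$word_id[ev$word_initial]
  pri <- sentence_priors(words, lexical_model, lexicon)
  out <- cohort_predictors(timeline, lexicon, priors = pri, fs = fs,
                           on_empty = match.arg(on_empty))
  out$surprisal$name <- "sentence_surprisal"
  out$entropy$name <- "sentence_entropy"
  out
}

# ---------------------------------------------------------------------------
# Segmentation predictors

#' Word-onset and phoneme-onset unit impulse predictors
#'
#' The two series partition the phoneme events: a unit impulse at each
#' word-initial phoneme goes to `word_onset`, and a unit impulse at every
#' other phoneme goes to `phoneme_onset`.
#'
#' @param timeline A [phoneme_timeline()].
#' @param fs Grid rate in Hz.
#' @return `list(word_onset =, phoneme_onset =)`, both [impulse_series()].
#' @export
segmentation_predictors <- function(timeline, fs = 1000) {
  ev <- timeline$events
  dur <- timeline$total_duration
  list(
    word_onset = impulse_series(times = ev$onset[ev$word_initial], values = 1,
                                fs = fs, duration = dur, name = "word_onset"),
    phoneme_onset = impulse_series(times = ev$onset[!ev$word_initial],
                                   values = 1, fs = fs, duration = dur,
                                   name = "phoneme_onset")
  )
}

#' All linguistic predictors for a stimulus
#'
#' Convenience wrapper bundling the segmentation, sublexical, word-form and
#' sentence predictors for one timeline.
#'
#' @inheritParams cohort_predictors
#' @param phoneme_model Phoneme-level [train_ngram()] model.
#' @param lexical_model Word-level [train_ngram()] model.
#' @return Named list of eight [impulse_series()].
#' @export
linguistic_predictors <- function(timeline, lexicon, phoneme_model,
                                  lexical_model, fs = 1000,
                                  on_empty = "error") {
  seg <- segmentation_predictors(timeline, fs)
  sub <- sublexical_predictors(timeline, phoneme_model, fs)
  wf <- cohort_predictors(timeline, lexicon, fs = fs, on_empty = on_empty)
  se <- sentence_predictors(timeline, lexicon, lexical_model, fs = fs,
                            on_empty = on_empty)
  list(word_onset = seg$word_onset, phoneme_onset = seg$phoneme_onset,
       sublexical_surprisal = sub$surprisal, sublexical_entropy = sub$entropy,
       wordform_surprisal = wf$surprisal, wordform_entropy = wf$entropy,
       sentence_surprisal = se$surprisal, sentence_entropy = se$entropy)
}
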