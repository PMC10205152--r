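# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: naive loops, direct counting, closed forms.

# Naive lagged design at lag-sample resolution (no basis), zero padded per
# trial. Used for the ridge normal-equations oracle.
oracle_lagged_design <- function(x, lags, bounds) {
  X <- matrix(0, length(x), length(lags))
  for (tr in seq_len(nrow(bounds))) {
    idx <- bounds[tr, 1]:bounds[tr, 2]
    for (j in seq_along(lags)) {
      for (t in seq_along(idx)) {
        s <- t - lags[j]
        if (s >= 1 && s <= length(idx)) X[idx[t], j] <- x[idx[s]]
      }
    }
  }
  X
}

# Ridge kernel with lambda -> 0 via the normal equations.
oracle_ridge_kernel <- function(x, y, lags, bounds, lambda = 1e-8) {
  X <- oracle_lagged_design(x, lags, bounds)
  as.numeric(solve(crossprod(X) + lambda * diag(length(lags)),
                   crossprod(X, y)))
}

# Brute-force n-gram count table: relative frequency of `sym` after `ctx`
# recounted directly from the corpus lines.
oracle_ngram_prob <- function(corpus, ctx, sym) {
  k <- length(ctx)
  num <- 0; den <- 0
  for (line in corpus) {
    n <- length(line)
    if (n < k + 1) next
    for (i in seq_len(n - k)) {
      if (k == 0 || all(line[i:(i + k - 1)] == ctx)) {
        den <- den + 1
        if (line[i + k] == sym) num <- num + 1
      }
    }
  }
  if (den == 0) NA_real_ else num / den
}

# Brute-force cohort posteriors: enumerate the lexicon directly.
oracle_cohort <- function(phones, pron, priors) {
  p <- priors / sum(priors)
  sur <- ent <- numeric(length(phones))
  for (k in seq_along(phones)) {
    match_k <- vapply(pron, function(pr)
      length(pr) >= k && pr[k] == phones[k], logical(1))
    psum <- sum(p[match_k])
    sur[k] <- -log2(psum)
    p[!match_k] <- 0
    p <- p / sum(p)
    q <- p[p > 0]
    ent[k] <- -sum(q * log2(q))
  }
  list(surprisal = sur, entropy = ent)
}

# Two-pass standard deviation (population form), one value per column.
oracle_population_sd <- function(K) {
  apply(K, 2, function(v) {
    m <- sum(v) / length(v)
    sqrt(sum((v - m)^2) / length(v))
  })
}

# Brute-force L1 boosting candidate scan (reference for the C++ fast path).
oracle_best_step <- function(Ztr, r, delta, frozen_groups, group) {
  best <- list(j = NA, sign = NA, d_err = Inf)
  for (j in seq_len(ncol(Ztr))) {
    if (group[j] %in% frozen_groups) next
    for (sgn in c(1, -1)) {
      d_err <- sum(abs(r - sgn * delta * Ztr[, j])) - sum(abs(r))
      if (d_err < best$d_err - 1e-12) best <- list(j = j, sign = sgn,
                                                   d_err = d_err)
    }
  }
  best
}

# Half-open binning rule, restated independently for tests.
event_sample_for_test <- function(t, fs) as.integer(floor(t * fs + 1e-9))

# Small deterministic fixture shared by several TRF tests.
make_recovery_sim <- function(duration = 100, fs = 100, n_channels = 2,
                              n_trials = 5, noise_sigma = 0, seed = 42) {
  basis <- lag_basis(fs = fs)
  pred <- random_impulse_predictor(duration, fs, rate = 4, seed = seed,
                                   name = "events")
  K <- random_smooth_kernels(1, basis$lags, n_channels, fs, seed = seed + 1)
  eeg <- synthesize_eeg(list(events = pred), list(events = K), n_channels,
                        fs, noise_sigma = noise_sigma, n_trials = n_trials,
                        seed = seed + 2)
  list(basis = basis, pred = pred, K = K, eeg = eeg)
}

zero_kernels <- function(n_dims, lags, n_channels) {
  structure(array(0, c(n_dims, length(lags), n_channels)),
            lags = as.integer(lags))
}
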