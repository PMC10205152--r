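# Multivariate temporal response function estimation: Hamming-window lag
# basis, L1 coordinate-descent boosting with validation-based freezing,
# nested five-fold cross-validation, and Fisher-z prediction accuracy.

# ---------------------------------------------------------------------------
# Lag basis

#' Hamming-window lag basis
#'
#' TRFs are parameterized as linear combinations of Hamming windows placed at
#' every sample of the lag axis: a one-hot coefficient vector expands to a
#' single `window`-second Hamming bump centered on that lag (truncated at the
#' ends of the axis). This smooths the estimated kernels at the scale of the
#' window while keeping the expansion linear.
#'
#' @param fs Sampling rate of the response in Hz (default 100).
#' @param lag_start,lag_end Lag window in seconds, window centers (defaults
#'   -0.1 and 0.5: stimulus leads response by up to 500 ms).
#' @param window Hamming window length in seconds (default 0.05).
#' @return A `lag_basis`: `lags` (samples), `fs`, `B` (L x L expansion
#'   matrix, columns are the bumps).
#' @export
lag_basis <- function(fs = 100, lag_start = -0.1, lag_end = 0.5,
                      window = 0.05) {
  if (lag_start >= lag_end) stopf("lag_start must be below lag_end")
  lags <- seq(as.integer(round(lag_start * fs)),
              as.integer(round(lag_end * fs)))
  L <- length(lags)
  wlen <- max(1L, as.integer(round(window * fs)))
  w <- if (wlen == 1L) 1 else
    0.54 - 0.46 * cos(2 * pi * seq(0, wlen - 1) / (wlen - 1))
  center <- (wlen - 1L) %/% 2L
  B <- matrix(0, L, L)
  for (j in seq_len(L)) {
    rows <- j + seq(0, wlen - 1L) - center
    ok <- rows >= 1L & rows <= L
    B[rows[ok], j] <- w[ok]
  }
  structure(list(lags = lags, fs = fs, window = window, B = B),
            class = "lag_basis")
}

#' Expand basis coefficients to a lag-sample kernel
#'
#' @param basis A [lag_basis()]. @param coef Coefficient vector or matrix
#'   (coefficients in rows).
#' @return The expanded kernel (`basis$B %*% coef`).
#' @export
expand_basis <- function(basis, coef) basis$B %*% coef

# ---------------------------------------------------------------------------
# Design matrix

coerce_predictors <- function(predictors) {
  if (!is.list(predictors) || is.null(names(predictors)) ||
      any(!nzchar(names(predictors)))) {
    stopf("`predictors` must be a named list")
  }
  out <- lapply(predictors, as_predictor_matrix)
  n <- unique(vapply(out, ncol, integer(1)))
  if (length(n) != 1L) stopf("all predictors must share the same grid length")
  out
}

# Basis-expanded lagged design, computed per trial with zero padding so that
# no stimulus information leaks across trial boundaries. Column order: for
# each predictor (in list order), each dimension, each basis index.
build_design <- function(X_list, bounds, basis) {
  L <- length(basis$lags)
  n_time <- ncol(X_list[[1]])
  n_col <- sum(vapply(X_list, nrow, integer(1))) * L
  Z <- matrix(0, n_time, n_col)
  col0 <- 0L
  for (X in X_list) {
    for (d in seq_len(nrow(X))) {
      for (tr in seq_len(nrow(bounds))) {
        idx <- bounds[tr, 1]:bounds[tr, 2]
        x <- X[d, idx]
        Tt <- length(idx)
        # S[t, l] = x[t - lag_l] within the trial (zero padded), so the
        # basis-expanded columns are S %*% B in one BLAS call
        S <- matrix(0, Tt, L)
        for (l in seq_len(L)) {
          lg <- basis$lags[l]
          if (lg >= 0) {
            if (lg < Tt) S[(lg + 1L):Tt, l] <- x[seq_len(Tt - lg)]
          } else {
            a <- -lg
            if (a < Tt) S[seq_len(Tt - a), l] <- x[(a + 1L):Tt]
          }
        }
        Z[idx, col0 + seq_len(L)] <- S %*% basis$B
      }
      col0 <- col0 + L
    }
  }
  Z
}

trial_samples <- function(bounds, trials) {
  unlist(lapply(trials, function(tr) bounds[tr, 1]:bounds[tr, 2]),
         use.names = FALSE)
}

# ---------------------------------------------------------------------------
# Cross-validation scheme

#' Five-fold cross-validation scheme over trials
#'
#' Trials are shuffled and split into five disjoint, exhaustive test folds
#' whose sizes differ by at most one. For each test fold, the remaining four
#' folds rotate through the validation role (each serving once), giving four
#' train/validation splits per test fold and twenty fits in total.
#'
#' @param n_trials Number of trials (>= 5).
#' @param seed Integer seed for the shuffle.
#' @param n_folds Number of folds (default 5).
#' @return A `cv_scheme`: `folds` (list of trial-index vectors), `n_trials`.
#' @export
make_cv_scheme <- function(n_trials, seed = NULL, n_folds = 5) {
  assert_count(n_trials, "n_trials", min = 1L)
  if (n_trials < n_folds) {
    stopf("need at least %d trials for %d folds, got %d",
          n_folds, n_folds, n_trials)
  }
  perm <- with_seed(seed, sample.int(n_trials))
  folds <- split(perm, rep(seq_len(n_folds), length.out = n_trials))
  folds <- lapply(unname(folds), sort)
  structure(list(folds = folds, n_trials = n_trials), class = "cv_scheme")
}

# ---------------------------------------------------------------------------
# Boosting fit

#' Fit a multivariate TRF by L1 coordinate-descent boosting
#'
#' Estimates basis coefficients for all predictors jointly. At each step the
#' single (predictor dimension, basis index, +/-step) update that most
#' reduces the training L1 error is applied; the validation L1 error is then
#' evaluated, and if it increased, the update is reverted and the whole named
#' predictor responsible is frozen in its prior state. Fitting continues
#' until every predictor is frozen (or no update reduces the training error,
#' or `max_steps` is reached). The accepted-step training error is therefore
#' non-increasing by construction.
#'
#' Before fitting, each predictor dimension is centered and scaled by its
#' mean absolute deviation over the scaling trials, and each channel is
#' centered; the step size is `step_frac` times the channel's training SD.
#' Reported kernels are rescaled back to raw predictor units.
#'
#' @param eeg Channel x time matrix.
#' @param predictors Named list of predictors (matrices `n_dims x n_time`,
#'   numeric vectors, or [impulse_series()]), on the EEG grid.
#' @param bounds Trial bounds matrix (`n_trials x 2`, 1-based inclusive),
#'   e.g. `eeg$trial_bounds` from [synthesize_eeg()].
#' @param basis A [lag_basis()].
#' @param train_trials,val_trials Disjoint trial index vectors.
#' @param step_frac Step size as a fraction of the channel SD (default
#'   0.005).
#' @param max_steps Cap on boosting steps per channel (default 10000).
#' @param scale_trials Trials used to compute centering/scaling (default:
#'   the training trials; [cross_validate()] passes all non-test trials so
#'   the four rotations of a fold share one scaling and their coefficients
#'   can be averaged).
#' @param freeze `"predictor"` (all dimensions of a named predictor freeze
#'   together; default) or `"dimension"`.
#' @return A `trf_model`: `kernels` (named list of `n_dims x n_lags x
#'   n_channels` arrays in raw units, with `lags` attribute), `coef` (same
#'   shape, scaled space), `basis`, `scaling`, and per-channel fit metadata
#'   (`n_steps`, `freeze_step`, `train_trace`).
#' @export
boost_fit <- function(eeg, predictors, bounds, basis, train_trials,
                      val_trials, step_frac = 0.005, max_steps = 10000,
                      scale_trials = NULL, freeze = c("predictor",
                                                      "dimension")) {
  freeze <- match.arg(freeze)
  preds <- coerce_predictors(predictors)
  n_ch <- nrow(eeg)
  if (ncol(eeg) != ncol(preds[[1]])) {
    stopf("EEG and predictors disagree on grid length (%d vs %d)",
          ncol(eeg), ncol(preds[[1]]))
  }
  if (length(intersect(train_trials, val_trials))) {
    stopf("train and validation trials must be disjoint")
  }
  scale_trials <- scale_trials %||% sort(c(train_trials, val_trials))
  idx_sc <- trial_samples(bounds, scale_trials)
  idx_tr <- trial_samples(bounds, train_trials)
  idx_va <- trial_samples(bounds, val_trials)

  # center/scale predictors on the scaling trials
  scaling <- list(mu = list(), s = list())
  for (nm in names(preds)) {
    X <- preds[[nm]]
    mu <- rowMeans(X[, idx_sc, drop = FALSE])
    s <- rowMeans(abs(X[, idx_sc, drop = FALSE] - mu))
    if (any(s == 0)) {
      stopf("predictor '%s' dimension %d has zero variance",
            nm, which(s == 0)[1])
    }
    preds[[nm]] <- (X - mu) / s
    scaling$mu[[nm]] <- mu
    scaling$s[[nm]] <- s
  }
  mu_y <- rowMeans(eeg[, idx_sc, drop = FALSE])
  sd_y <- apply(eeg[, idx_tr, drop = FALSE], 1, stats::sd)
  if (any(sd_y == 0)) {
    stopf("EEG channel %d has zero variance on the training set",
          which(sd_y == 0)[1])
  }

  Z <- build_design(preds, bounds, basis)
  Ztr <- Z[idx_tr, , drop = FALSE]
  Zva <- Z[idx_va, , drop = FALSE]

  L <- length(basis$lags)
  dims <- vapply(preds, nrow, integer(1))
  pred_of_col <- rep(seq_along(preds), dims * L)
  dim_of_col <- rep(unlist(lapply(dims, seq_len)), each = L)
  group <- if (freeze == "predictor") pred_of_col - 1L else
    as.integer(interaction(pred_of_col, dim_of_col, drop = TRUE)) - 1L

  n_groups <- max(group) + 1L
  coef_mat <- matrix(0, ncol(Z), n_ch)
  freeze_step <- matrix(NA_integer_, n_groups, n_ch)
  n_steps <- integer(n_ch)
  traces <- vector("list", n_ch)
  for (ch in seq_len(n_ch)) {
    fit <- boost_channel_cpp(Ztr, eeg[ch, idx_tr] - mu_y[ch],
                             Zva, eeg[ch, idx_va] - mu_y[ch],
                             group, step_frac * sd_y[ch], max_steps)
    coef_mat[, ch] <- fit$coef
    freeze_step[, ch] <- fit$freeze_step
    n_steps[ch] <- fit$n_steps
    traces[[ch]] <- fit$train_trace
  }

  kernels <- coef <- list()
  col0 <- 0L
  for (nm in names(preds)) {
    D <- dims[[nm]]
    co <- array(0, dim = c(D, L, n_ch))
    ke <- array(0, dim = c(D, L, n_ch))
    for (d in seq_len(D)) {
      cols <- col0 + (d - 1L) * L + seq_len(L)
      co[d, , ] <- coef_mat[cols, , drop = FALSE]
      ke[d, , ] <- (basis$B %*% coef_mat[cols, , drop = FALSE]) /
        scaling$s[[nm]][d]
    }
    attr(ke, "lags") <- basis$lags
    coef[[nm]] <- co
    kernels[[nm]] <- ke
    col0 <- col0 + D * L
  }
  structure(list(kernels = kernels, coef = coef, basis = basis,
                 scaling = c(scaling, list(mu_y = mu_y)),
                 dims = dims, freeze = freeze,
                 train_trials = train_trials, val_trials = val_trials,
                 meta = list(n_steps = n_steps, freeze_step = freeze_step,
                             train_trace = traces)),
            class = "trf_model")
}

#' @export
print.trf_model <- function(x, ...) {
  cat(sprintf("<trf_model> %s; %d lags @ %g Hz; %d channels\n",
              paste(names(x$kernels), collapse = ", "),
              length(x$basis$lags), x$basis$fs,
              dim(x$kernels[[1]])[3]))
  invisible(x)
}

#' Predict EEG from a fitted TRF model
#'
#' Applies the model's stored centering/scaling to the predictors, convolves
#' with the basis-expanded coefficients per trial, and adds back the channel
#' means, reproducing the fit-time prediction exactly.
#'
#' @param object A `trf_model`. @param predictors Named list as in
#'   [boost_fit()]. @param bounds Trial bounds matrix. @param ... Unused.
#' @return Channel x time matrix of predictions.
#' @export
predict.trf_model <- function(object, predictors, bounds, ...) {
  preds <- coerce_predictors(predictors)
  if (!identical(names(preds), names(object$kernels))) {
    stopf("predictor names must match the fitted model")
  }
  for (nm in names(preds)) {
    preds[[nm]] <- (preds[[nm]] - object$scaling$mu[[nm]]) /
      object$scaling$s[[nm]]
  }
  Z <- build_design(preds, bounds, object$basis)
  coef_mat <- flatten_coef(object)
  t(Z %*% coef_mat) + object$scaling$mu_y
}

flatten_coef <- function(model) {
  L <- length(model$basis$lags)
  n_ch <- dim(model$coef[[1]])[3]
  do.call(rbind, lapply(names(model$coef), function(nm) {
    co <- model$coef[[nm]]
    out <- matrix(0, model$dims[[nm]] * L, n_ch)
    for (d in seq_len(model$dims[[nm]])) {
      out[(d - 1L) * L + seq_len(L), ] <- co[d, , ]
    }
    out
  }))
}

# ---------------------------------------------------------------------------
# Nested cross-validation

#' Nested five-fold cross-validated mTRF estimation
#'
#' For each test fold, four models are fitted on the remaining trials (each
#' of the four folds serving as validation once) and their coefficients are
#' averaged; the averaged model predicts the held-out test trials, which are
#' therefore never seen during estimation. A single Pearson correlation per
#' channel is computed on the concatenation of the five test-fold
#' predictions against the measured EEG, and Fisher-z transformed. The
#' reported TRF is the average over all twenty fitted models.
#'
#' @inheritParams boost_fit
#' @param scheme A [make_cv_scheme()] matching the trial count.
#' @return A `trf_cv`: `accuracy` (data.frame `channel`, `r`, `z`), `trf`
#'   (named list of averaged kernel arrays, raw units), `predictions`
#'   (channel x time), `scheme`, `basis`, `meta`.
#' @export
cross_validate <- function(eeg, predictors, bounds, scheme, basis,
                           step_frac = 0.005, max_steps = 10000,
                           freeze = "predictor") {
  if (inherits(eeg, "synthetic_eeg")) {
    bounds <- eeg$trial_bounds
    eeg <- eeg$data
  }
  if (scheme$n_trials != nrow(bounds)) {
    stopf("scheme was built for %d trials but data has %d",
          scheme$n_trials, nrow(bounds))
  }
  n_ch <- nrow(eeg)
  pred_full <- matrix(NA_real_, n_ch, ncol(eeg))
  kernel_sum <- NULL
  n_models <- 0L
  meta <- list()
  for (f in seq_along(scheme$folds)) {
    test <- scheme$folds[[f]]
    rest_folds <- scheme$folds[-f]
    rest <- sort(unlist(rest_folds))
    coef_sum <- NULL
    last_fit <- NULL
    for (v in seq_along(rest_folds)) {
      val <- rest_folds[[v]]
      train <- sort(unlist(rest_folds[-v]))
      fit <- boost_fit(eeg, predictors, bounds, basis, train, val,
                       step_frac = step_frac, max_steps = max_steps,
                       scale_trials = rest, freeze = freeze)
      coef_sum <- if (is.null(coef_sum)) fit$coef else
        mapply(`+`, coef_sum, fit$coef, SIMPLIFY = FALSE)
      kernel_sum <- if (is.null(kernel_sum)) fit$kernels else
        mapply(function(a, b) {
          out <- a + b; attributes(out) <- attributes(a); out
        }, kernel_sum, fit$kernels, SIMPLIFY = FALSE)
      n_models <- n_models + 1L
      last_fit <- fit
      meta[[length(meta) + 1L]] <- list(fold = f, val_rotation = v,
                                        n_steps = fit$meta$n_steps)
    }
    # averaged model for this test fold: shared scaling, mean coefficients
    avg <- last_fit
    avg$coef <- lapply(coef_sum, function(x) x / length(rest_folds))
    test_idx <- trial_samples(bounds, test)
    # each fold's prediction is centered and standardized (per channel)
    # before concatenation: the five folds' models share training data, and
    # leaving fold-specific offsets and scales in the concatenation couples
    # a fold's prediction variance to other folds' noise, biasing the
    # concatenated correlation below zero under the null; within a fold the
    # standardization does not change the correlation
    pred <- predict(avg, predictors, bounds)[, test_idx, drop = FALSE]
    pred <- pred - rowMeans(pred)
    s_p <- sqrt(rowMeans(pred^2))
    pred_full[, test_idx] <- pred / ifelse(s_p > 0, s_p, 1)
  }
  if (anyNA(pred_full)) stopf("internal error: folds did not cover all trials")
  r <- vapply(seq_len(n_ch), function(ch) {
    if (stats::sd(pred_full[ch, ]) == 0) return(0) # all-zero model: no power
    stats::cor(pred_full[ch, ], eeg[ch, ])
  }, numeric(1))
  z <- fisher_z(r)
  trf <- lapply(kernel_sum, function(x) {
    out <- x / n_models; attributes(out) <- attributes(x); out
  })
  structure(list(accuracy = data.frame(channel = seq_len(n_ch), r = r, z = z),
                 trf = trf, predictions = pred_full, scheme = scheme,
                 basis = basis, meta = meta),
            class = "trf_cv")
}

#' @export
print.trf_cv <- function(x, ...) {
  cat(sprintf("<trf_cv> %d channels, mean z = %.4f [%s]\n",
              nrow(x$accuracy), mean(x$accuracy$z),
              paste(names(x$trf), collapse = ", ")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Accuracy measures

#' Fisher z-transform of a correlation
#'
#' `z = arctanh(r)`. Values with `|r| = 1` are capped at `+/- cap` with a
#' warning; `|r| > 1` is a domain error.
#'
#' @param r Correlations in `[-1, 1]`.
#' @param cap Cap for `|r| = 1` (default `atanh(1 - 1e-7)`, about 8.4).
#' @return Fisher-z values.
#' @export
fisher_z <- function(r, cap = atanh(1 - 1e-7)) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stopf("|r| > 1")
  r <- pmin(1, pmax(-1, r))
  hit <- abs(r) == 1
  if (any(hit, na.rm = TRUE)) {
    warnf("|r| = 1 capped at z = %.3f", cap)
  }
  z <- atanh(r)
  z[which(hit)] <- sign(r[which(hit)]) * cap
  z
}

#' Unique predictive power of a predictor set
#'
#' The per-channel drop in cross-validated prediction accuracy when the
#' predictors of interest are removed from the full model:
#' `delta_z = z_full - z_reduced`.
#'
#' @param full,reduced `trf_cv` results (or their `accuracy` data.frames)
#'   computed on the same data, channels and CV scheme.
#' @return data.frame with `channel` and `delta_z`.
#' @export
delta_z <- function(full, reduced) {
  acc <- function(x) if (inherits(x, "trf_cv")) x$accuracy else x
  a <- acc(full); b <- acc(reduced)
  if (!identical(a$channel, b$channel)) {
    stopf("full and reduced models disagree on channels")
  }
  data.frame(channel = a$channel, delta_z = a$z - b$z)
}

#' Combine visual onset and offset TRFs into an effective response function
#'
#' The offset TRF is shifted by the stimulus duration and summed with the
#' onset TRF on the overlap, yielding the response to the whole stimulus:
#' for 500 ms stimuli and TRFs on the -100..500 ms lag axis, the combined
#' axis spans -100 to 1000 ms relative to stimulus onset.
#'
#' @param onset_trf,offset_trf Kernels on the same lag axis: channel x lag
#'   matrices, or `1 x lag x channel` arrays as stored in `trf_cv$trf`.
#' @param stimulus_duration Stimulus duration in seconds (default 0.5).
#' @param lags Lag axis in samples (taken from a `lags` attribute if
#'   present). @param fs Sampling rate in Hz (default 100).
#' @return An `effective_rf`: `kernel` (channel x lag), `lags` (samples),
#'   `fs`, `lag_ms` (lag axis in ms).
#' @export
combine_visual_trf <- function(onset_trf, offset_trf, stimulus_duration = 0.5,
                               lags = NULL, fs = 100) {
  lags <- lags %||% attr(onset_trf, "lags")
  if (is.null(lags)) stopf("`lags` required (none found on the kernel)")
  lags_off <- attr(offset_trf, "lags") %||% lags
  if (!identical(as.integer(lags), as.integer(lags_off))) {
    stopf("onset and offset TRFs must share one lag axis")
  }
  on <- as_kernel_matrix(onset_trf)
  off <- as_kernel_matrix(offset_trf)
  if (!identical(dim(on), dim(off))) stopf("kernel shapes do not match")
  shift <- as.integer(round(stimulus_duration * fs))
  out_lags <- seq(min(lags), max(lags) + shift)
  K <- matrix(0, nrow(on), length(out_lags))
  pos_on <- match(lags, out_lags)
  pos_off <- match(lags + shift, out_lags)
  K[, pos_on] <- K[, pos_on] + on
  K[, pos_off] <- K[, pos_off] + off
  structure(list(kernel = K, lags = out_lags, fs = fs,
                 lag_ms = out_lags / fs * 1000),
            class = "effective_rf")
}

as_kernel_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[1] != 1L) stopf("expected a one-dimensional predictor kernel")
    return(t(x[1, , , drop = TRUE]))
  }
  if (is.numeric(x)) return(matrix(x, nrow = 1))
  stopf("cannot interpret kernel input")
}
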