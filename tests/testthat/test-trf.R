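# Lag basis, CV scheme, boosting, cross-validation, Fisher z, delta-z, and
# the combined visual response function.

test_that("one-hot coefficients expand to a single centered Hamming bump", {
  basis <- lag_basis(fs = 100, lag_start = -0.1, lag_end = 0.5,
                     window = 0.05)
  expect_equal(basis$lags, -10:50)
  L <- length(basis$lags)
  w <- 0.54 - 0.46 * cos(2 * pi * 0:4 / 4)
  j <- 25 # interior lag
  e <- numeric(L); e[j] <- 1
  k <- as.numeric(expand_basis(basis, e))
  expect_equal(k[(j - 2):(j + 2)], w)
  expect_true(all(k[-((j - 2):(j + 2))] == 0))
  # linearity of the expansion
  c1 <- rnorm(L); c2 <- rnorm(L)
  expect_equal(expand_basis(basis, c1 + 2 * c2),
               expand_basis(basis, c1) + 2 * expand_basis(basis, c2))
})

test_that("CV folds are disjoint, exhaustive and balanced", {
  s15 <- make_cv_scheme(15, seed = 1)
  expect_equal(lengths(s15$folds), rep(3L, 5))
  s5 <- make_cv_scheme(5, seed = 2)
  expect_equal(lengths(s5$folds), rep(1L, 5))
  s12 <- make_cv_scheme(12, seed = 3)
  expect_true(max(lengths(s12$folds)) - min(lengths(s12$folds)) <= 1)
  expect_identical(sort(unlist(s12$folds)), 1:12)
  expect_equal(sum(duplicated(unlist(s12$folds))), 0)
  expect_error(make_cv_scheme(4), "at least")
})

test_that("boosting candidate selection matches a brute-force scan", {
  set.seed(5)
  for (rep in 1:5) {
    Tt <- 40; J <- 6
    Ztr <- matrix(rnorm(Tt * J), Tt, J)
    y <- rnorm(Tt)
    delta <- 0.07
    group <- 0:(J - 1)
    fit <- speechtrf:::boost_channel_cpp(Ztr, y, Ztr, y, group, delta, 1L)
    oracle <- oracle_best_step(Ztr, y, delta, integer(0), group + 1)
    j_hat <- which(fit$coef != 0)
    expect_length(j_hat, 1)
    expect_equal(j_hat, oracle$j)
    expect_equal(sign(fit$coef[j_hat]), oracle$sign)
    expect_equal(fit$train_err - sum(abs(y)), oracle$d_err, tolerance = 1e-10)
  }
})

test_that("noiseless boosting recovers the true kernel and the ridge oracle", {
  sim <- make_recovery_sim(duration = 100, n_channels = 2, n_trials = 5)
  fit <- boost_fit(sim$eeg$data, list(events = sim$pred),
                   sim$eeg$trial_bounds, sim$basis,
                   train_trials = 1:4, val_trials = 5)
  x <- as_dense(sim$pred)
  for (ch in 1:2) {
    k_hat <- fit$kernels$events[1, , ch]
    expect_gt(cor(k_hat, sim$K[1, , ch]), 0.99)
    k_ridge <- oracle_ridge_kernel(x, sim$eeg$data[ch, ], sim$basis$lags,
                                   sim$eeg$trial_bounds)
    expect_gt(cor(k_hat, k_ridge), 0.99)
  }
  # accepted-step training error is monotonically non-increasing
  for (tr in fit$meta$train_trace) expect_true(all(diff(tr) <= 1e-10))
})

test_that("an unrelated predictor freezes early with a smaller kernel", {
  fs <- 100
  basis <- lag_basis(fs = fs)
  sig <- random_impulse_predictor(120, fs, rate = 4, seed = 61,
                                  name = "signal")
  nul <- random_impulse_predictor(120, fs, rate = 4, seed = 62, name = "null")
  K <- random_smooth_kernels(1, basis$lags, 1, fs, seed = 63)
  eeg <- synthesize_eeg(list(signal = sig), list(signal = K), 1, fs,
                        noise_sigma = 0.3, n_trials = 6, seed = 64)
  fit <- boost_fit(eeg$data, list(signal = sig, null = nul),
                   eeg$trial_bounds, basis, train_trials = 1:4,
                   val_trials = 5:6)
  norm2 <- function(a) sqrt(sum(a^2))
  expect_lt(norm2(fit$kernels$null), norm2(fit$kernels$signal))
  fs_ <- fit$meta$freeze_step
  expect_true(is.na(fs_[1, 1]) || is.na(fs_[2, 1]) || fs_[2, 1] <= fs_[1, 1])
})

test_that("boost_fit names the offender on zero-variance input", {
  sim <- make_recovery_sim(duration = 20, n_trials = 2)
  flat <- matrix(0, 1, ncol(sim$eeg$data))
  expect_error(boost_fit(sim$eeg$data,
                         list(events = sim$pred, flat = flat),
                         sim$eeg$trial_bounds, sim$basis, 1, 2),
               "flat")
  eeg0 <- sim$eeg$data
  eeg0[2, ] <- 5
  expect_error(boost_fit(eeg0, list(events = sim$pred),
                         sim$eeg$trial_bounds, sim$basis, 1, 2),
               "channel 2")
})

test_that("fold predictions from averaged coefficients equal averaged predictions", {
  sim <- make_recovery_sim(duration = 60, n_channels = 1, n_trials = 6,
                           noise_sigma = 0.5)
  preds <- list(events = sim$pred)
  rest_folds <- list(1:2, 3, 4, 5) # test fold would be trial 6
  rest <- 1:5
  fits <- lapply(seq_along(rest_folds), function(v) {
    boost_fit(sim$eeg$data, preds, sim$eeg$trial_bounds, sim$basis,
              train_trials = setdiff(rest, rest_folds[[v]]),
              val_trials = rest_folds[[v]], scale_trials = rest)
  })
  avg <- fits[[1]]
  avg$coef$events <- (fits[[1]]$coef$events + fits[[2]]$coef$events +
                        fits[[3]]$coef$events + fits[[4]]$coef$events) / 4
  p_avg <- predict(avg, preds, sim$eeg$trial_bounds)
  p_each <- lapply(fits, predict, predictors = preds,
                   bounds = sim$eeg$trial_bounds)
  expect_equal(p_avg, (p_each[[1]] + p_each[[2]] + p_each[[3]] +
                         p_each[[4]]) / 4, tolerance = 1e-10)
})

test_that("cross-validation finds signal and its delta-z is antisymmetric", {
  sim <- make_recovery_sim(duration = 100, n_channels = 1, n_trials = 5,
                           noise_sigma = 0.4)
  scheme <- make_cv_scheme(5, seed = 8)
  cv <- cross_validate(sim$eeg$data, list(events = sim$pred),
                       sim$eeg$trial_bounds, scheme, sim$basis)
  expect_gt(cv$accuracy$z[1], 0.5)
  dz0 <- delta_z(cv, cv)
  expect_true(all(dz0$delta_z == 0))
  nul <- random_impulse_predictor(100, 100, rate = 4, seed = 71,
                                  name = "null")
  cv_n <- cross_validate(sim$eeg$data, list(null = nul),
                         sim$eeg$trial_bounds, scheme, sim$basis)
  expect_equal(delta_z(cv, cv_n)$delta_z, -delta_z(cv_n, cv)$delta_z)
})

test_that("fisher_z matches a numerical tanh inverse and is odd", {
  expect_equal(fisher_z(0), 0)
  r <- c(-0.9, -0.5, 0.2, 0.5, 0.77)
  expect_equal(fisher_z(-r), -fisher_z(r))
  z_num <- vapply(r, function(ri)
    uniroot(function(z) tanh(z) - ri, c(-10, 10), tol = 1e-12)$root,
    numeric(1))
  expect_equal(fisher_z(r), z_num, tolerance = 1e-9)
  expect_error(fisher_z(1.2), "> 1")
  expect_warning(zc <- fisher_z(1), "capped")
  expect_true(is.finite(zc))
})

test_that("visual onset and offset TRFs combine to a -100..1000 ms axis", {
  basis <- lag_basis(fs = 100)
  C <- 3; L <- length(basis$lags)
  set.seed(9)
  on <- matrix(rnorm(C * L), C, L)
  off <- matrix(rnorm(C * L), C, L)
  eff <- combine_visual_trf(on, off, stimulus_duration = 0.5,
                            lags = basis$lags, fs = 100)
  expect_equal(range(eff$lag_ms), c(-100, 1000))
  # zero offset: onset kernel zero-padded out to 1000 ms
  eff0 <- combine_visual_trf(on, 0 * off, stimulus_duration = 0.5,
                             lags = basis$lags, fs = 100)
  expect_equal(eff0$kernel[, 1:L], on)
  expect_true(all(eff0$kernel[, (L + 1):ncol(eff0$kernel)] == 0))
  # overlap region (lags 400..500 ms) is the elementwise sum
  for (lag in 40:50) {
    i_out <- which(eff$lags == lag)
    i_on <- which(basis$lags == lag)
    i_off <- which(basis$lags == lag - 50)
    expect_equal(eff$kernel[, i_out], on[, i_on] + off[, i_off])
  }
  bad <- structure(off, lags = as.integer(basis$lags + 1))
  expect_error(combine_visual_trf(structure(on, lags = basis$lags), bad),
               "lag axis")
})
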