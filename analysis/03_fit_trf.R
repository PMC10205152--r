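#!/usr/bin/env Rscript
# Stage 3 — simulate subjects and estimate mTRFs by boosting.
#
# Six simulated subjects listen to the stage-2 stimulus. Each subject's
# 4-channel EEG is the convolution of subject-specific smooth kernels with
# the word-onset and word-form-surprisal predictors plus noise (10 dB SNR);
# a random impulse predictor, regenerated per subject so that chance
# alignments with the stimulus cancel across the group, serves as the null
# control. Condition A uses the full kernels; condition B halves them,
# mimicking weaker tracking under divided attention. For each subject we run
# nested five-fold cross-validated boosting for the full model and two
# reduced models, and record: prediction accuracy (z), unique contributions
# (delta-z) of the signal and null predictors, kernel recovery, and the GFP
# of the word-onset TRF in both conditions.
#
# Problem sizes (~100 s of stimulus, 4 channels, 6 subjects, a 0.01 boosting
# step) keep the full stage to roughly ten minutes on one core. Outputs
# under results/fit/.

suppressPackageStartupMessages(library(speechtrf))

pd <- "results/predictors"
if (!file.exists(file.path(pd, "n_samples.txt"))) {
  stop("missing stage-2 outputs; run analysis/02_predictors.R first",
       call. = FALSE)
}
verify_manifest(file.path(pd, "manifest.json"))
cfg <- pipeline_config(seed = 20260927L)
out <- "results/fit"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

n_samples <- as.integer(readLines(file.path(pd, "n_samples.txt")))
read_pred <- function(nm) {
  df <- read.table(file.path(pd, paste0(nm, ".tsv")), header = TRUE)
  impulse_series(samples = df$sample, values = df$value, fs = cfg$eeg_fs,
                 n_samples = n_samples, name = nm)
}
word_onset <- read_pred("word_onset")
surprisal <- read_pred("wordform_surprisal")

n_subjects <- 6L
n_trials <- 5L
n_samples <- min(n_samples, 10000L) # first ~100 s of the stimulus
len <- (n_samples %/% n_trials)
keep <- len * n_trials
crop <- function(x) impulse_series(samples = x$samples[x$samples < keep],
                                   values = x$values[x$samples < keep],
                                   fs = x$fs, n_samples = keep, name = x$name)
preds_sig <- lapply(list(word_onset = word_onset, surprisal = surprisal),
                    crop)
basis <- lag_basis(fs = cfg$eeg_fs, lag_start = cfg$lag_start,
                   lag_end = cfg$lag_end, window = cfg$basis_window)
message(sprintf("%d subjects, %d trials of %.0f s, %d channels",
                n_subjects, n_trials, len / cfg$eeg_fs, 4))

dz_signal <- dz_null <- matrix(NA_real_, n_subjects, 4)
z_full <- matrix(NA_real_, n_subjects, 4)
recovery <- numeric(n_subjects)
gfp_a <- gfp_b <- matrix(NA_real_, n_subjects, length(basis$lags))

for (s in seq_len(n_subjects)) {
  sseed <- cfg$seed + 100L * s
  K_wo <- random_smooth_kernels(1, basis$lags, 4, cfg$eeg_fs, seed = sseed)
  K_su <- random_smooth_kernels(1, basis$lags, 4, cfg$eeg_fs,
                                seed = sseed + 1L)
  K_null <- structure(array(0, c(1, length(basis$lags), 4)),
                      lags = as.integer(basis$lags))
  kernels_a <- list(word_onset = K_wo, surprisal = K_su, control = K_null)
  halve <- function(K) structure(K * 0.5, lags = attr(K, "lags"))
  kernels_b <- list(word_onset = halve(K_wo), surprisal = halve(K_su),
                    control = K_null)
  control <- random_impulse_predictor(keep / cfg$eeg_fs, fs = cfg$eeg_fs,
                                      rate = 3, seed = sseed + 9L,
                                      name = "control")
  preds <- c(preds_sig, list(control = control))

  scheme <- make_cv_scheme(n_trials, seed = sseed + 2L)
  run <- function(kern, which_preds) {
    eeg <- synthesize_eeg(preds, kern, n_channels = 4, fs = cfg$eeg_fs,
                          n_trials = n_trials, seed = sseed + 3L,
                          snr_db = 10)
    cross_validate(eeg$data, preds[which_preds], eeg$trial_bounds, scheme,
                   basis, step_frac = 0.01, max_steps = 4000)
  }
  cv_full <- run(kernels_a, c("word_onset", "surprisal", "control"))
  cv_wo_sig <- run(kernels_a, "control")
  cv_wo_nul <- run(kernels_a, c("word_onset", "surprisal"))
  cv_b <- run(kernels_b, c("word_onset", "surprisal", "control"))

  z_full[s, ] <- cv_full$accuracy$z
  dz_signal[s, ] <- delta_z(cv_full, cv_wo_sig)$delta_z
  dz_null[s, ] <- delta_z(cv_full, cv_wo_nul)$delta_z
  # a channel's kernel can be identically zero if the predictor froze at its
  # first step (its variance captured by the correlated surprisal predictor);
  # such channels carry no recovery information and are skipped
  recovery[s] <- mean(vapply(1:4, function(ch) {
    k <- cv_full$trf$word_onset[1, , ch]
    if (all(k == 0)) NA_real_ else cor(k, K_wo[1, , ch])
  }, numeric(1)), na.rm = TRUE)
  gfp_a[s, ] <- gfp(cv_full$trf$word_onset)
  gfp_b[s, ] <- gfp(cv_b$trf$word_onset)
  message(sprintf(
    "subject %d: mean z = %.3f, dz(signal) = %.3f, dz(null) = %+.4f, recovery r = %.3f",
    s, mean(z_full[s, ]), mean(dz_signal[s, ]), mean(dz_null[s, ]),
    recovery[s]))
}

save_tsv <- function(m, f, prefix = "ch") {
  df <- as.data.frame(m)
  names(df) <- sprintf("%s%02d", prefix, seq_len(ncol(m)))
  write.table(cbind(subject = seq_len(nrow(m)), df), file.path(out, f),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
save_tsv(z_full, "z_full.tsv")
save_tsv(dz_signal, "delta_z_signal.tsv")
save_tsv(dz_null, "delta_z_null.tsv")
save_tsv(gfp_a, "gfp_condA.tsv", prefix = "lag")
save_tsv(gfp_b, "gfp_condB.tsv", prefix = "lag")
write.table(data.frame(subject = seq_len(n_subjects), recovery_r = recovery),
            file.path(out, "recovery.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

write_manifest(file.path(out, "manifest.json"), stage = "fit",
               inputs = file.path(pd, c("word_onset.tsv",
                                        "wordform_surprisal.tsv",
                                        "n_samples.txt")),
               outputs = file.path(out, c("z_full.tsv", "delta_z_signal.tsv",
                                          "delta_z_null.tsv", "gfp_condA.tsv",
                                          "gfp_condB.tsv", "recovery.tsv")),
               config = cfg, seed = cfg$seed)
message("stage 3 complete: results/fit/")
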