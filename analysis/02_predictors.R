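#!/usr/bin/env Rscript
# Stage 2 — build the predictor variables from the simulated stimuli.
#
# Reads the TextGrid timeline, lexicon and corpus written by stage 1,
# trains the phoneme and word 5-gram models, and computes all eight
# linguistic predictors (word/phoneme onsets; sublexical, word-form and
# sentence surprisal and entropy) at 1000 Hz, resampled to the 100 Hz EEG
# grid. Also computes the 8-band gammatone and onset spectrograms from the
# synthetic audio.
#
# Outputs under results/predictors/ as sparse event TSVs (sample, value).

suppressPackageStartupMessages(library(speechtrf))

stim <- "results/stimuli"
if (!file.exists(file.path(stim, "story.TextGrid"))) {
  stop("missing stage-1 outputs; run analysis/01_simulate.R first",
       call. = FALSE)
}
verify_manifest(file.path(stim, "manifest.json"))
cfg <- pipeline_config(seed = 20260927L)
out <- "results/predictors"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tl <- read_textgrid(file.path(stim, "story.TextGrid"))
lex <- read_lexicon(file.path(stim, "lexicon.tsv"))
corpus <- strsplit(readLines(file.path(stim, "corpus.txt")), " ")

## language models: phoneme 5-gram without word boundaries, word 5-gram
pron <- attr(lex, "pron")
phoneme_lines <- lapply(corpus, function(u) unlist(pron[u], use.names = FALSE))
m_ph <- train_ngram(phoneme_lines, order = 5, smoothing = "kn")
m_wd <- train_ngram(corpus, order = 5, smoothing = "kn")
message(sprintf("phoneme model: %s tokens; word model: %s tokens",
                m_ph$n_tokens, m_wd$n_tokens))

preds <- linguistic_predictors(tl, lex, m_ph, m_wd,
                               fs = cfg$predictor_fs, on_empty = "uniform")
preds_eeg <- predictors_to_eeg_rate(preds, to = cfg$eeg_fs,
                                    from = cfg$predictor_fs)
for (nm in names(preds_eeg)) {
  p <- preds_eeg[[nm]]
  df <- data.frame(sample = p$samples, value = p$values)
  write.table(df, file.path(out, paste0(nm, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf("%-22s %5d events, mean value %.3f", nm,
                  length(p$samples), mean(p$values)))
}
writeLines(as.character(preds_eeg$word_onset$n_samples),
           file.path(out, "n_samples.txt"))

## acoustic predictors from the synthetic audio
wav <- read_wav(file.path(stim, "story.wav"))
ac <- acoustic_predictors(wav$wave, wav$fs)
ac100 <- lapply(ac, resample_predictor, to = cfg$eeg_fs)
for (nm in names(ac100)) {
  m <- t(ac100[[nm]]$values)
  colnames(m) <- sprintf("band%d", seq_len(ncol(m)))
  write.table(round(m, 6), file.path(out, paste0("acoustic_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
message(sprintf("acoustic: %d-band spectrogram and onsets, %d frames at %g Hz",
                nrow(ac100$spectrogram$values),
                ncol(ac100$spectrogram$values), cfg$eeg_fs))

write_manifest(file.path(out, "manifest.json"), stage = "predictors",
               inputs = file.path(stim, c("story.TextGrid", "lexicon.tsv",
                                          "corpus.txt", "story.wav")),
               outputs = file.path(out, c(paste0(names(preds_eeg), ".tsv"),
                                          "acoustic_spectrogram.tsv",
                                          "acoustic_onsets.tsv",
                                          "n_samples.txt")),
               config = cfg, seed = cfg$seed)
message("stage 2 complete: results/predictors/")
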