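#!/usr/bin/env Rscript
# Stage 1 — simulate the study materials.
#
# Generates everything a recording session would provide: n-back visual
# stimulus sequences for both load conditions, a toy phonological lexicon
# with a Zipf-distributed training corpus, a forced-alignment-style phoneme
# timeline for the "story" stimulus, and a short audio rendition (noise
# bursts at word onsets) used to exercise the acoustic predictors.
#
# Outputs under results/stimuli/, with a provenance manifest.

suppressPackageStartupMessages(library(speechtrf))

cfg <- pipeline_config(seed = 20260927L)
out <- "results/stimuli"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## visual stimulus sequences: 23 squares, 500 ms + 2500 ms ISI -> 69 s trials
for (load in c(0L, 3L)) {
  nb <- generate_nback_sequence(n_items = 23, n_targets = 6, load = load,
                                item_duration = 0.5, isi = 2.5,
                                seed = cfg$seed + load)
  f <- file.path(out, sprintf("nback_%dback.tsv", load))
  write.table(nb$items, f, sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%d-back: %d items, %d targets, %.0f s -> %s",
                  load, nrow(nb$items), sum(nb$items$target),
                  nb$total_duration, f))
}

## lexicon + corpus for the linguistic models
gen <- generate_lexicon_and_corpus(inventory_size = 10, n_words = 60,
                                   corpus_len = 800, zipf_exponent = 1,
                                   seed = cfg$seed + 10L)
write_lexicon(gen$lexicon, file.path(out, "lexicon.tsv"))
writeLines(vapply(gen$corpus, paste, character(1), collapse = " "),
           file.path(out, "corpus.txt"))
message(sprintf("lexicon: %d words over %d phonemes; corpus: %d utterances",
                nrow(gen$lexicon), length(attr(gen$lexicon, "inventory")),
                length(gen$corpus)))

## stimulus timeline: enough words for ~150 s of speech at 10 phonemes/s
pron <- attr(gen$lexicon, "pron")
cum <- cumsum(vapply(gen$corpus, function(u)
  sum(lengths(pron[u])), integer(1)))
n_utt <- which(cum >= 1510)[1]
stim <- gen$corpus[seq_len(n_utt)]
writeLines(vapply(stim, paste, character(1), collapse = " "),
           file.path(out, "stimulus_words.txt"))
tl <- timeline_from_corpus(stim, gen$lexicon, phoneme_rate = 10,
                           seed = cfg$seed + 20L)
write_textgrid(tl, file.path(out, "story.TextGrid"))
message(sprintf("timeline: %d phonemes / %d words over %.1f s",
                nrow(tl$events), sum(tl$events$word_initial),
                tl$total_duration))

## synthetic audio for the acoustic predictors: 10 s of band-limited noise
## bursts at word onsets (no speech synthesis is attempted)
fs_audio <- 16000
dur_audio <- 10
set.seed(cfg$seed + 30L)
wave <- numeric(dur_audio * fs_audio)
onsets <- tl$events$onset[tl$events$word_initial]
for (t0 in onsets[onsets < dur_audio - 0.2]) {
  i0 <- round(t0 * fs_audio)
  burst <- rnorm(round(0.15 * fs_audio)) *
    exp(-seq(0, 5, length.out = round(0.15 * fs_audio)))
  wave[i0 + seq_along(burst)] <- wave[i0 + seq_along(burst)] + 0.3 * burst
}
write_wav(wave, fs_audio, file.path(out, "story.wav"))

write_manifest(file.path(out, "manifest.json"), stage = "simulate",
               outputs = file.path(out, c("nback_0back.tsv",
                                          "nback_3back.tsv", "lexicon.tsv",
                                          "corpus.txt", "stimulus_words.txt",
                                          "story.TextGrid", "story.wav")),
               config = cfg, seed = cfg$seed)
message("stage 1 complete: results/stimuli/")
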