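---
title: "Methods: boosted temporal response functions for continuous speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: boosted temporal response functions for continuous speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechtrf)
```

## The encoding model

`speechtrf` quantifies how strongly multichannel EEG tracks properties of a
continuous speech stimulus. The forward model is a multivariate temporal
response function (mTRF): the response at channel $c$ and time $t$ is
modeled as

$$\hat y_c(t) = \sum_{i} \sum_{\tau} h_{i,c}(\tau)\, x_i(t - \tau),$$

where each $x_i$ is a predictor time series derived from the stimulus and
$h_{i,c}$ is a kernel over lags $\tau$ from $-100$ to $500$ ms. Predictive
power is measured as the Fisher-z transformed Pearson correlation between
predicted and measured EEG on held-out trials. The unique contribution of a
predictor set is $\Delta z = z_{\text{full}} - z_{\text{reduced}}$, the drop
in accuracy when the set is removed from the full model.

## Predictor variables

**Acoustic.** A 256-band gammatone spectrogram (4th-order filters,
ERB-spaced centers between 20 Hz and 5 kHz, envelopes at 1 kHz) is
compressed as $\log(1+x)$ and summed into 8 logarithmically spaced bands;
an acoustic-onset spectrogram applies, per band, the rectified
delayed-inhibition operator
$o(t) = \max\{0,\, x(t) - c\,\bar x(t - d)\}$ (moving average $\bar x$,
$d = 10$ ms, $c = 1$) before the same 8-band sum. The operator responds with
a transient to intensity increments, is exactly zero on constants, and
ignores decrements. The literature's auditory edge-detection models differ
in detail; this package pins down the contract (rectified transients, silence
on constants) rather than any one parameterization, and exposes $d$ and $c$.
Whether the log compression precedes or follows the band sum is ambiguous in
the field's descriptions; compression-first is the default, and summing
uncompressed values (which conserves total energy exactly, a property the
tests use) is available by computing the fine spectrogram with
`compress = FALSE`.

**Linguistic.** All linguistic predictors are impulse trains at phoneme
onsets, with values in bits:

* *Segmentation*: unit impulses at word-initial phonemes (`word_onset`) and
  at all other phonemes (`phoneme_onset`).
* *Sublexical*: surprisal $-\log_2 p(\mathrm{ph}_k \mid \mathrm{ph}_{k-4..k-1})$
  and next-phoneme entropy under a phoneme 5-gram trained on a corpus with
  word boundaries removed.
* *Word-form*: cohort-model phoneme surprisal and cohort entropy. At each
  word onset the cohort is the whole lexicon weighted by frequency priors
  (missing words count 1); each phoneme removes incompatible entries and
  renormalizes.
* *Sentence*: the same cohort procedure with priors proportional to a word
  5-gram probability given the four preceding words. With a unigram lexical
  model this reduces bit-for-bit to the word-form model (a nesting the tests
  assert).

N-gram smoothing is interpolated Kneser–Ney (absolute discount 0.75,
continuation counts at lower orders, uniform floor), so every in-vocabulary
symbol has positive probability in every context; an exact unsmoothed mode
backed off to the longest observed context exists for oracle testing.
Pronunciation variants are encoded as separate lexicon entries with distinct
ids; the toy generator never emits variants, and callers supplying real
dictionaries should split a word's count across its variants. If a cohort
empties (phoneme matches no entry), the configurable fallback scores the
word's remaining phonemes with a uniform phoneme model
($\log_2 |\text{inventory}|$ bits, entropy 0) and warns; the strict mode
errors.

## Estimation by boosting

Kernels are parameterized on a basis of 50 ms Hamming windows centered at
every sample of the $-100..500$ ms lag axis (truncated at the ends), which
smooths estimates at the window scale while keeping the expansion linear.
Estimation is coordinate-descent boosting of the $\ell_1$ prediction error:
at each step, the single (predictor dimension, basis index, $\pm$step)
update that most reduces the training error is applied; the validation error
is then evaluated, and if it increased, the update is reverted and the named
predictor responsible is frozen in its prior state (all its dimensions
together, e.g. the eight bands of a spectrogram predictor; per-dimension
freezing is available). Fitting stops when every predictor is frozen, when
no update reduces the training error, or at the step cap.

Numerical choices:

* Step size: 0.005 of the channel's training SD, after centering each
  channel and centering/scaling each predictor dimension by its mean
  absolute deviation. Kernels are rescaled to raw units for reporting.
* Ties in the candidate scan: lowest coefficient index wins, $+$ before
  $-$, so fits are exactly deterministic.
* The candidate scan in C++ uses the identity $|r - a| - |r| = -\mathrm{sign}(r)\,a$
  for $|r| \ge |a|$, with exact per-row corrections where it can fail; a
  test compares it against a brute-force scan.
* Convolutions are computed per trial with zero padding; no stimulus
  information crosses trial boundaries.
* Degenerate inputs (zero-variance channel or predictor dimension) abort
  with an error naming the offender.

## Nested cross-validation and prediction accuracy

Trials are shuffled into five test folds (sizes within one). For each test
fold the remaining four folds rotate through the validation role, giving
four fits; their basis coefficients are averaged and the averaged model
predicts the held-out fold, which no fit ever saw. Within a test fold, all
four fits share centering/scaling computed on the union of the four non-test
folds, so averaging their coefficients is well defined. The reported TRF is
the average over all twenty fits, in raw units.

A single accuracy per channel is computed on the concatenation of the five
test-fold predictions: Pearson $r$ against the measured EEG, then
$z = \mathrm{arctanh}(r)$ (capped near $|r| = 1$ with a warning). Each
fold's prediction is centered and standardized per channel before
concatenation. Within a fold this leaves the correlation unchanged; across
folds it matters: the five models share training data, and keeping
fold-specific offsets and scales in the pooled normalization couples each
fold's prediction variance to the other folds' noise, which measurably
biases the chance-level accuracy below zero (about $-0.0015$ at the scale of
the package's null simulations, with a standard error several times
smaller). With the standardization the chance level is statistically
indistinguishable from $z = 0$, the property the null-simulation acceptance
test asserts. A channel whose concatenated prediction is identically zero
(every model frozen at zero) is assigned $r = 0$: a zero model has no
predictive power.

## Inference

Per-channel $\Delta z$ values across subjects are tested with mass-univariate
cluster-mass permutation tests: one-sample $t$ against zero (one-sided by
default), cluster-forming threshold at uncorrected $p \le 0.05$,
adjacency-connected clusters scored by the sum of member $t$ values, and a
null distribution of the maximum cluster mass over whole-subject sign flips
— the complete set when $2^{n}\le 10{,}000$ (deterministic and
seed-independent), otherwise 10,000 random flips always including the
identity, so $p > 0$. Each cluster reports its mass, permutation $p$, and
$t_{\max}$, the largest member $|t|$. TRF waveforms are compared between
conditions via the global field power (across-channel standard deviation,
population form; RMS available) with paired two-sided cluster tests over
contiguous time samples.

Sensor adjacency is built by a distance threshold on montage coordinates
(`montage_adjacency`) or supplied as an explicit edge list
(`edge_adjacency`); no computational-geometry construction is attempted, and
tests use explicit small montages so no result depends on geometry code.

## Synthetic data and what it shows

The `synthdata` generators define the study conditions for every test:

* n-back visual sequences — 23 squares of 500 ms with 2500 ms ISI (69 s
  trials), 6 targets among the last 20 items, targets exactly satisfying the
  0-back or 3-back rule and non-targets exactly violating it.
* Toy lexicons and Zipf corpora (defaults: 10-symbol inventory, 60 words,
  exponent 1), and phoneme timelines at 10 phonemes/s with ±10% uniform
  onset jitter, standing in for forced alignment.
* Synthetic EEG: per-trial convolution of known smooth kernels with the
  predictors plus i.i.d. Gaussian noise (optionally 1/f-shaped); the signal
  and noise parts are exposed separately and sum bit-identically to the
  data. The noise spectrum and amplitude of real EEG are not modeled; SNR is
  a free simulation parameter, with 10 dB used for parameter-recovery
  checks and `snr_db` calibrating the noise to a requested ratio.

Passing tests therefore demonstrate parameter recovery and calibration under
Gaussian noise with exactly known generative kernels. They do not speak to
artifacts, non-stationarity, filtering effects, or alignment errors of real
recordings, nor to coarticulation-aware timing.

Problem sizes were chosen to keep every check comfortably within a desktop
run: null simulations use 50 datasets of 10 × 30 s trials at 100 Hz with 8
channels; parameter recovery uses 200 s at 10 dB SNR; cluster-test
calibration uses 500 null datasets of 10 subjects × 8 channels with the
complete 1024-flip enumeration; the analysis scripts simulate 6 subjects
with 4 channels and ~100 s of stimulus, with a coarser 0.01 boosting step.

## Known limitations

* The boosting estimator, like any nested-CV pipeline with shared training
  data, has finite-sample quirks; the fold standardization above removes
  the one that affects the chance level.
* The edge detector is a deliberately minimal delayed-inhibition operator,
  not a fitted model of auditory adaptation.
* Kneser–Ney here uses a single discount; toy-scale corpora make fancier
  estimators pointless.
* The TextGrid reader handles long-format interval tiers named
  `phones`/`words` (the common forced-aligner output), not point tiers or
  short format.
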