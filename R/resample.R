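# The single shared resampler: predictors computed at 1000 Hz are brought to
# the EEG rate (100 Hz) the same way everywhere in the pipeline.

#' Resample a predictor to a lower rate
#'
#' Dense series (vectors, matrices, spectrograms) are decimated with a
#' zero-phase FIR anti-alias filter; the decimation factor must be an
#' integer. Impulse series are re-binned by the half-open rule (an event in
#' original sample `s` lands in target sample `floor(s * to / from)`), which
#' conserves the sum of impulse values exactly.
#'
#' @param x Numeric vector, `n_dims x n_time` matrix, [spectrogram()], or
#'   [impulse_series()].
#' @param to Target rate in Hz.
#' @param from Source rate in Hz (taken from the object when available).
#' @return Same kind of object at rate `to`.
#' @export
resample_predictor <- function(x, to, from = NULL) {
  if (inherits(x, "impulse_series")) {
    n_new <- n_frames(x$n_samples / x$fs, to)
    samples <- as.integer(floor(x$samples * (to / x$fs) + 1e-9))
    return(impulse_series(samples = samples, values = x$values, fs = to,
                          n_samples = n_new, name = x$name))
  }
  if (inherits(x, "spectrogram")) {
    vals <- resample_predictor(x$values, to, from = x$fs)
    return(spectrogram(pmax(vals, 0), x$band_centers, to,
                       compressed = x$compressed))
  }
  if (is.null(from)) stopf("`from` rate required for a bare series")
  q <- from / to
  if (abs(q - round(q)) > 1e-9) {
    stopf("decimation factor %g is not an integer", q)
  }
  q <- as.integer(round(q))
  if (q == 1L) return(x)
  ord <- 64L
  fir <- as.numeric(signal::fir1(ord, 1 / q))
  fir <- fir / sum(fir) # unit DC gain: constants resample to themselves
  dec <- function(v) {
    # reflect-pad so the zero-phase filter has no edge transients
    pad <- min(length(v) - 1L, 3L * ord)
    vp <- c(rev(v[seq_len(pad) + 1L]), v,
            rev(v[length(v) - seq_len(pad)]))
    f <- signal::filtfilt(fir, 1, vp)[pad + seq_along(v)]
    f[seq(1, length(v), by = q)][seq_len(n_frames(length(v) / from, to))]
  }
  if (is.matrix(x)) t(apply(x, 1, dec)) else dec(x)
}

#' Bring a set of predictors onto the EEG grid
#'
#' Resamples each element with [resample_predictor()] and stacks
#' spectrograms into band x time matrices, ready for [boost_fit()].
#'
#' @param predictors Named list of predictors at `from` Hz.
#' @param to Target (EEG) rate. @param from Source rate.
#' @return Named list of matrices / impulse series at `to` Hz.
#' @export
predictors_to_eeg_rate <- function(predictors, to = 100, from = 1000) {
  lapply(predictors, function(p) {
    out <- resample_predictor(p, to, from = from)
    if (inherits(out, "spectrogram")) out$values else out
  })
}
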