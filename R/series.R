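# Sparse event predictors on a uniform sampling grid.

#' Create a sparse impulse predictor
#'
#' An impulse series represents a predictor that is zero everywhere except at
#' event samples: word onsets, phoneme onsets, surprisal and entropy values.
#' Events are stored as (0-based sample index, value) pairs on a uniform grid.
#' Events given as times are binned by the half-open rule: an event at time
#' `t` lands in sample `floor(t * fs)`. Events falling in the same sample sum
#' their values.
#'
#' @param times Event times in seconds (used if `samples` is `NULL`).
#' @param values Event values (bits for information predictors, 1 for onset
#'   markers). Recycled to the number of events.
#' @param fs Sampling rate of the grid in Hz.
#' @param duration Total duration of the grid in seconds (used if `n_samples`
#'   is `NULL`); the grid spans `floor(duration * fs)` samples.
#' @param samples 0-based sample indices, as an alternative to `times`.
#' @param n_samples Grid length in samples, as an alternative to `duration`.
#' @param name Predictor name.
#' @return An object of class `impulse_series` with fields `samples`
#'   (0-based, strictly increasing), `values`, `fs`, `n_samples`, `name`.
#' @export
#' @examples
#' x <- impulse_series(times = c(0.1, 0.25), values = 1, fs = 100,
#'                     duration = 1, name = "word_onset")
#' sum(as_dense(x)) # 2
impulse_series <- function(times = NULL, values = 1, fs, duration = NULL,
                           samples = NULL, n_samples = NULL, name = "impulse") {
  assert_scalar(fs, "fs", min = 1e-9)
  if (is.null(samples)) {
    if (is.null(times)) stopf("give either `times` or `samples`")
    samples <- event_sample(times, fs)
  }
  samples <- as.integer(samples)
  if (is.null(n_samples)) {
    if (is.null(duration)) stopf("give either `duration` or `n_samples`")
    n_samples <- n_frames(duration, fs)
  }
  n_samples <- assert_count(n_samples, "n_samples", min = 0L)
  values <- rep_len(as.numeric(values), length(samples))
  if (any(!is.finite(values))) stopf("impulse values must be finite")
  if (length(samples) && (min(samples) < 0L || max(samples) >= n_samples)) {
    stopf("event samples outside the grid [0, %d)", n_samples)
  }
  # merge same-sample events, keep sorted
  if (length(samples)) {
    agg <- rowsum(values, group = samples)
    samples <- as.integer(rownames(agg))
    values <- as.numeric(agg)
    o <- order(samples)
    samples <- samples[o]; values <- values[o]
  }
  structure(
    list(samples = samples, values = values, fs = fs,
         n_samples = n_samples, name = name),
    class = "impulse_series"
  )
}

#' Expand an impulse series to a dense vector
#'
#' @param x An `impulse_series`.
#' @return Numeric vector of length `x$n_samples`.
#' @export
as_dense <- function(x) {
  stopifnot(inherits(x, "impulse_series"))
  out <- numeric(x$n_samples)
  out[x$samples + 1L] <- x$values
  out
}

#' @export
print.impulse_series <- function(x, ...) {
  cat(sprintf("<impulse_series '%s'> %d events on %d samples @ %g Hz\n",
              x$name, length(x$samples), x$n_samples, x$fs))
  invisible(x)
}

#' @export
length.impulse_series <- function(x) x$n_samples
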