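# Shared internal helpers.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' Sets the seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so seeded generators do not perturb the global stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG stream untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialize a RNG state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Pipeline-wide rounding rule: a duration of d seconds at rate fs spans
# floor(d * fs) frames.
n_frames <- function(duration, fs) {
  as.integer(floor(duration * fs + 1e-9))
}

# Half-open binning rule shared by all event-to-grid conversions: an event at
# time t lands in 0-based sample floor(t * fs), i.e. bin [s/fs, (s+1)/fs).
event_sample <- function(time, fs) {
  as.integer(floor(time * fs + 1e-9))
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stopf("`%s` must be a single integer >= %d", name, min)
  }
  invisible(as.integer(x))
}

assert_scalar <- function(x, name, min = -Inf) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < min) {
    stopf("`%s` must be a single finite number >= %g", name, min)
  }
  invisible(as.numeric(x))
}
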