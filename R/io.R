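# File formats: Praat TextGrid timelines, TSV lexicons, WAV audio, and the
# native EEG container (flat float64 binary + JSON sidecar). All writes go
# through a temp file + rename so readers never see partial output.

atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stopf("failed to move temp file onto %s", path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# TextGrid

#' Write a phoneme timeline as a Praat TextGrid
#'
#' Emits a long-format TextGrid with a "phones" interval tier (one interval
#' per phoneme, from its onset to the next onset) and a "words" interval tier
#' (one interval per word instance).
#'
#' @param timeline A [phoneme_timeline()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(timeline, path) {
  ev <- timeline$events
  dur <- timeline$total_duration
  ph_xmin <- ev$onset
  ph_xmax <- c(ev$onset[-1], dur)
  w_first <- which(ev$word_initial)
  w_xmin <- ev$onset[w_first]
  w_xmax <- c(ev$onset[w_first[-1]], dur)
  w_text <- ev$word_id[w_first]

  tier <- function(name, xmin, xmax, text) {
    c(sprintf('        class = "IntervalTier"'),
      sprintf('        name = "%s"', name),
      sprintf("        xmin = 0"),
      sprintf("        xmax = %.10g", dur),
      sprintf("        intervals: size = %d", length(xmin)),
      unlist(lapply(seq_along(xmin), function(i) c(
        sprintf("        intervals [%d]:", i),
        sprintf("            xmin = %.10g", xmin[i]),
        sprintf("            xmax = %.10g", xmax[i]),
        sprintf('            text = "%s"', text[i])))))
  }
  lines <- c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    "",
    "xmin = 0",
    sprintf("xmax = %.10g", dur),
    "tiers? <exists>",
    "size = 2",
    "item []:",
    "    item [1]:",
    tier("phones", ph_xmin, ph_xmax, ev$phoneme),
    "    item [2]:",
    tier("words", w_xmin, w_xmax, w_text)
  )
  atomic_write(path, function(tmp) writeLines(lines, tmp))
}

#' Read a Praat TextGrid into a phoneme timeline
#'
#' Parses long-format TextGrids with interval tiers named `phones` and
#' `words` (case-insensitive, `phone`/`word` also accepted). Empty-text
#' intervals (silences) are skipped. Word-initial flags are assigned to the
#' first phoneme starting inside each word interval.
#'
#' @param path TextGrid file.
#' @return A [phoneme_timeline()].
#' @export
read_textgrid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_num <- function(l) as.numeric(sub(".*=\\s*", "", l))
  get_str <- function(l) {
    m <- regmatches(l, regexpr('"[^"]*"', l))
    if (!length(m)) "" else substr(m, 2, nchar(m) - 1)
  }
  xmax_doc <- get_num(grep("^\\s*xmax", lines, value = TRUE)[1])
  item_at <- grep("^\\s*item\\s*\\[[0-9]+\\]", lines)
  if (!length(item_at)) stopf("no tiers found in %s", path)
  tiers <- list()
  bounds <- c(item_at, length(lines) + 1L)
  for (k in seq_along(item_at)) {
    chunk <- lines[item_at[k]:(bounds[k + 1L] - 1L)]
    cls <- get_str(grep("class\\s*=", chunk, value = TRUE)[1])
    nm <- tolower(get_str(grep("name\\s*=", chunk, value = TRUE)[1]))
    if (!identical(cls, "IntervalTier")) next
    ia <- grep("^\\s*intervals\\s*\\[[0-9]+\\]", chunk)
    if (!length(ia)) next
    ib <- c(ia, length(chunk) + 1L)
    xmin <- xmax <- numeric(length(ia)); text <- character(length(ia))
    for (i in seq_along(ia)) {
      sub <- chunk[ia[i]:(ib[i + 1L] - 1L)]
      xmin[i] <- get_num(grep("xmin\\s*=", sub, value = TRUE)[1])
      xmax[i] <- get_num(grep("xmax\\s*=", sub, value = TRUE)[1])
      text[i] <- get_str(grep("text\\s*=", sub, value = TRUE)[1])
    }
    keep <- nzchar(trimws(text))
    tiers[[nm]] <- data.frame(xmin = xmin[keep], xmax = xmax[keep],
                              text = text[keep], stringsAsFactors = FALSE)
  }
  ph_nm <- intersect(c("phones", "phone"), names(tiers))[1]
  w_nm <- intersect(c("words", "word"), names(tiers))[1]
  if (is.na(ph_nm) || is.na(w_nm)) {
    stopf("TextGrid must contain 'phones' and 'words' interval tiers")
  }
  ph <- tiers[[ph_nm]]; wd <- tiers[[w_nm]]
  eps <- 1e-6
  wi <- findInterval(ph$xmin + eps, wd$xmin)
  if (any(wi < 1L) || any(ph$xmin + eps > wd$xmax[wi])) {
    stopf("phone outside any word interval")
  }
  word_initial <- !duplicated(wi)
  phoneme_timeline(ph$xmin, ph$text, word_initial, wd$text[wi],
                   total_duration = xmax_doc)
}

# ---------------------------------------------------------------------------
# Lexicon TSV

#' Write / read a lexicon as TSV (word, space-separated phonemes, count)
#'
#' @param lexicon A [toy_lexicon()]. @param path File path.
#' @return `path` (write) or a `toy_lexicon` (read).
#' @export
write_lexicon <- function(lexicon, path) {
  atomic_write(path, function(tmp) {
    utils::write.table(as.data.frame(lexicon)[c("word", "phonemes", "count")],
                       tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  toy_lexicon(df$word, df$phonemes, df$count)
}

# ---------------------------------------------------------------------------
# EEG container: float64 little-endian binary + JSON sidecar

#' Write / read channel-by-time data as binary with a JSON sidecar
#'
#' The binary file holds the matrix in column-major order (channel fastest)
#' as little-endian float64. The sidecar `<path>.json` records `fs`,
#' `channel_names`, `trial_bounds`, and the matrix shape.
#'
#' @param eeg A `synthetic_eeg`, or a plain channel x time matrix.
#' @param path Binary file path (sidecar written next to it).
#' @param fs,channel_names,trial_bounds Metadata when `eeg` is a bare matrix.
#' @return `path` (write); a list with `data`, `fs`, `channel_names`,
#'   `trial_bounds` (read).
#' @export
write_eeg_bin <- function(eeg, path, fs = NULL, channel_names = NULL,
                          trial_bounds = NULL) {
  if (inherits(eeg, "synthetic_eeg")) {
    data <- eeg$data; fs <- eeg$fs; channel_names <- eeg$channel_names
    trial_bounds <- eeg$trial_bounds
  } else {
    data <- eeg
    if (is.null(fs)) stopf("`fs` required for a bare matrix")
    channel_names <- channel_names %||% sprintf("ch%02d", seq_len(nrow(data)))
    trial_bounds <- trial_bounds %||% trial_bounds(ncol(data), 1L)
  }
  atomic_write(path, function(tmp) {
    con <- file(tmp, "wb"); on.exit(close(con))
    writeBin(as.vector(data), con, size = 8, endian = "little")
  })
  side <- list(fs = fs, n_channels = nrow(data), n_samples = ncol(data),
               channel_names = channel_names,
               trial_bounds = apply(trial_bounds, 1, as.list),
               dtype = "float64", order = "column-major", endian = "little")
  atomic_write(paste0(path, ".json"), function(tmp) {
    jsonlite::write_json(side, tmp, auto_unbox = TRUE, digits = NA)
  })
  invisible(path)
}

#' @rdname write_eeg_bin
#' @export
read_eeg_bin <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- side$n_channels * side$n_samples
  con <- file(path, "rb"); on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  data <- matrix(x, side$n_channels, side$n_samples)
  rownames(data) <- side$channel_names
  tb <- side$trial_bounds
  if (is.data.frame(tb)) tb <- as.matrix(tb)
  if (is.list(tb)) tb <- do.call(rbind, lapply(tb, unlist))
  colnames(tb) <- c("start", "end")
  list(data = data, fs = side$fs, channel_names = side$channel_names,
       trial_bounds = tb)
}

# ---------------------------------------------------------------------------
# WAV (PCM 16/24-bit)

#' Read a PCM WAV file
#'
#' Minimal RIFF parser for uncompressed 16- or 24-bit PCM. Samples are
#' rescaled to [-1, 1].
#'
#' @param path WAV file.
#' @return `list(wave = matrix channels x samples, fs = sample rate)`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (hdr != "RIFF") stopf("%s: not a RIFF file", path)
  readBin(con, "integer", 1, 4, endian = "little")
  if (readChar(con, 4, useBytes = TRUE) != "WAVE") stopf("not a WAVE file")
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (!nzchar(id)) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        n_channels = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        fs = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little"))
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stopf("missing fmt/data chunk")
  if (fmt$audio_format != 1L) stopf("only uncompressed PCM is supported")
  if (fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2, 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$bits == 24L) {
    b <- as.integer(data_raw)
    n <- length(b) %/% 3
    v <- b[seq(1, 3 * n, 3)] + 256 * b[seq(2, 3 * n, 3)] +
      65536 * b[seq(3, 3 * n, 3)]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else {
    stopf("unsupported bit depth: %d", fmt$bits)
  }
  wave <- matrix(x, nrow = fmt$n_channels)
  list(wave = wave, fs = fmt$fs)
}

#' Write a mono/stereo 16-bit PCM WAV file
#'
#' @param wave Numeric vector (mono) or channels x samples matrix in [-1, 1].
#' @param fs Sample rate in Hz.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, fs, path) {
  if (is.null(dim(wave))) wave <- matrix(wave, nrow = 1)
  pcm <- as.integer(pmax(-32768, pmin(32767, round(as.vector(wave) * 32767))))
  n_ch <- nrow(wave)
  data_sz <- length(pcm) * 2L
  atomic_write(path, function(tmp) {
    con <- file(tmp, "wb"); on.exit(close(con))
    writeChar("RIFF", con, eos = NULL)
    writeBin(as.integer(36L + data_sz), con, 4, endian = "little")
    writeChar("WAVEfmt ", con, eos = NULL)
    writeBin(16L, con, 4, endian = "little")
    writeBin(c(1L, n_ch), con, 2, endian = "little")
    writeBin(as.integer(fs), con, 4, endian = "little")
    writeBin(as.integer(fs * n_ch * 2L), con, 4, endian = "little")
    writeBin(c(as.integer(n_ch * 2L), 16L), con, 2, endian = "little")
    writeChar("data", con, eos = NULL)
    writeBin(data_sz, con, 4, endian = "little")
    writeBin(pcm, con, 2, endian = "little")
  })
}
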