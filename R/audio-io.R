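#' Construct a waveform
#'
#' A waveform is the package's unit of audio: a vector of amplitude samples
#' (nominal range \[-1, 1\]) plus its sampling rate in Hz.
#'
#' @param samples numeric vector of finite amplitude samples.
#' @param rate positive integer sampling rate (Hz).
#' @return An object of class `bleat_wave` with elements `samples` and `rate`.
#' @export
waveform <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (length(samples) && !all(is.finite(samples)))
    stop("waveform samples must all be finite")
  rate <- as.integer(rate)
  if (length(rate) != 1L || is.na(rate) || rate <= 0L)
    stop("sampling rate must be a positive integer")
  structure(list(samples = samples, rate = rate), class = "bleat_wave")
}

#' @export
print.bleat_wave <- function(x, ...) {
  cat(sprintf("<bleat_wave: %d samples @ %d Hz (%.3f s)>\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w a `bleat_wave`.
#' @return duration in seconds.
#' @export
wave_duration <- function(w) length(w$samples) / w$rate

#' Short-time analysis frame specification
#'
#' Defaults follow the pipeline's standardized windowing: a Hann window of
#' 2048 samples with a 512-sample hop.
#'
#' @param frame_length window length in samples.
#' @param hop_length hop in samples; must satisfy `0 < hop <= frame_length`.
#' @param window taper identifier; only `"hann"` is implemented.
#' @return An object of class `bleat_framespec`.
#' @export
frame_spec <- function(frame_length = 2048L, hop_length = 512L,
                       window = "hann") {
  frame_length <- as.integer(frame_length)
  hop_length <- as.integer(hop_length)
  if (hop_length <= 0L || hop_length > frame_length)
    stop("require 0 < hop_length <= frame_length")
  window <- match.arg(window, "hann")
  structure(list(frame_length = frame_length, hop_length = hop_length,
                 window = window), class = "bleat_framespec")
}

# ---- RIFF/WAVE reading and writing -----------------------------------------
# Minimal RIFF parser: PCM 16/24-bit and IEEE float 32-bit, any channel count
# (averaged to mono). No audio package is available in the target library, so
# the container format is handled here.

#' Load a WAV file as a mono waveform
#'
#' Multichannel audio is averaged to mono; integer PCM is rescaled to
#' \[-1, 1\]. Supports 16- and 24-bit PCM and 32-bit IEEE float.
#'
#' @param path path to a RIFF/WAVE file.
#' @return A [waveform()].
#' @export
load_wav <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  hdr <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1L, 4L, endian = "little")   # chunk size, unused
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (length(sz) == 0L) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      if (length(body) < 16L) stop("truncated fmt chunk in ", path)
      u16 <- function(off) sum(as.integer(body[off + 1:2]) * c(1L, 256L))
      u32 <- function(off) sum(as.numeric(body[off + 1:4]) * 256^(0:3))
      fmt <- list(code = u16(0L), channels = u16(2L), rate = u32(4L),
                  bits = u16(14L))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      seek(con, sz + sz %% 2L, origin = "current")
      next
    }
    if (sz %% 2L == 1L) seek(con, 1L, origin = "current")
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("undecodable WAV (missing fmt/data chunk): ", path)
  code <- fmt$code
  if (code == 65534) code <- if (fmt$bits == 32) 3 else 1   # extensible
  bytes <- fmt$bits %/% 8L
  n_total <- length(data_raw) %/% bytes

  if (code == 1 && fmt$bits == 16) {
    x <- readBin(data_raw, "integer", n_total, 2L, signed = TRUE,
                 endian = "little") / 32768
  } else if (code == 1 && fmt$bits == 24) {
    m <- matrix(as.integer(data_raw[seq_len(n_total * 3L)]), nrow = 3L)
    v <- m[1L, ] + 256L * m[2L, ] + 65536L * m[3L, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else if (code == 3 && fmt$bits == 32) {
    x <- readBin(data_raw, "double", n_total, 4L, endian = "little")
  } else {
    stop("unsupported WAV encoding (format ", code, ", ", fmt$bits, " bit)")
  }
  if (fmt$channels > 1L) {
    n_frames <- length(x) %/% fmt$channels
    x <- colMeans(matrix(x[seq_len(n_frames * fmt$channels)],
                         nrow = fmt$channels))
  }
  waveform(x, fmt$rate)
}

#' Write a waveform to a 16-bit PCM WAV file
#'
#' @param w a [waveform()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "bleat_wave"))
  pcm <- as.integer(pmax(-32768, pmin(32767, round(w$samples * 32768))))
  data_size <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  wr_u32 <- function(v) writeBin(as.integer(v), con, 4L, endian = "little")
  wr_u16 <- function(v) writeBin(as.integer(v), con, 2L, endian = "little")
  writeChar("RIFF", con, eos = NULL); wr_u32(36L + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); wr_u32(16L)
  wr_u16(1L); wr_u16(1L)              # PCM, mono
  wr_u32(w$rate); wr_u32(w$rate * 2L) # byte rate
  wr_u16(2L); wr_u16(16L)             # block align, bits
  writeChar("data", con, eos = NULL); wr_u32(data_size)
  writeBin(pcm, con, 2L, endian = "little")
  invisible(path)
}

#' Band-limited resampling
#'
#' FFT-domain resampling (zero-pad or truncate the spectrum), the same
#' band-limited scheme used by scientific DSP toolkits. Output length is
#' `round(n * target_rate / rate)`, preserving duration to within one sample
#' period. Linear interpolation is deliberately not used: it would smear
#' spectral peaks and break downstream descriptor contracts.
#'
#' @param w a [waveform()].
#' @param target_rate desired sampling rate (Hz).
#' @return A [waveform()] at `target_rate`.
#' @export
resample_wave <- function(w, target_rate) {
  stopifnot(inherits(w, "bleat_wave"))
  target_rate <- as.integer(target_rate)
  if (is.na(target_rate) || target_rate <= 0L)
    stop("target_rate must be positive")
  if (target_rate == w$rate) return(w)
  n <- length(w$samples)
  if (n == 0L) return(waveform(numeric(0), target_rate))
  m <- as.integer(round(n * target_rate / w$rate))
  X <- fft(w$samples)
  Y <- complex(m)
  # number of positive-frequency bins to carry over
  half <- min(n, m) %/% 2L
  Y[1L] <- X[1L]
  if (half >= 1L) {
    Y[2L:(half + 1L)] <- X[2L:(half + 1L)]
    if (half >= 2L) Y[(m - half + 2L):m] <- X[(n - half + 2L):n]
  }
  # split a shared Nyquist bin when both lengths are even
  if (min(n, m) %% 2L == 0L && half >= 1L) {
    nyq <- X[half + 1L]
    if (m < n) {
      Y[half + 1L] <- Re(nyq)
    } else if (m > n) {
      Y[half + 1L] <- nyq / 2
      Y[m - half + 1L] <- Conj(nyq) / 2
    }
  }
  y <- Re(fft(Y, inverse = TRUE)) / n
  waveform(y, target_rate)
}

#' Standardize a clip to a fixed duration
#'
#' Shorter clips are right-padded with zeros; longer clips keep their first
#' `target_s` seconds (the onset carries the attack features). Idempotent.
#'
#' @param w a [waveform()].
#' @param target_s target duration in seconds (default 2.0).
#' @return A [waveform()] of exactly `round(target_s * rate)` samples.
#' @export
standardize_duration <- function(w, target_s = 2.0) {
  stopifnot(inherits(w, "bleat_wave"))
  if (target_s <= 0) stop("target_s must be positive")
  n_target <- as.integer(round(target_s * w$rate))
  n <- length(w$samples)
  if (n == 0L)
    log_line("standardize_duration", c(warning = "empty_input_zero_padded"))
  x <- if (n >= n_target) w$samples[seq_len(n_target)] else
    c(w$samples, numeric(n_target - n))
  waveform(x, w$rate)
}

#' Read a class-labeled clip directory
#'
#' Walks `<root>/<class_name>/*.wav` and returns every clip with its label
#' taken from the directory name.
#'
#' @param root corpus root directory.
#' @return A list with `waves` (list of [waveform()]), `labels` (character)
#'   and `clip_ids` (file stems).
#' @export
read_corpus <- function(root) {
  if (!dir.exists(root)) stop("no such directory: ", root)
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  waves <- list(); labels <- character(); ids <- character()
  for (cl in classes) {
    files <- sort(list.files(file.path(root, cl), pattern = "\\.wav$",
                             full.names = TRUE, ignore.case = TRUE))
    for (f in files) {
      waves[[length(waves) + 1L]] <- load_wav(f)
      labels <- c(labels, cl)
      ids <- c(ids, tools::file_path_sans_ext(basename(f)))
    }
  }
  if (!length(waves)) stop("no WAV clips found under ", root)
  list(waves = waves, labels = labels, clip_ids = ids)
}
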