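# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths: direct DFT via an explicit basis matrix,
# per-frame loops for descriptors, per-clip counting for metrics.

make_sine <- function(freq, dur = 2, rate = 22050L, amp = 1) {
  t <- (seq_len(round(dur * rate)) - 1L) / rate
  waveform(amp * sin(2 * pi * freq * t), rate)
}

fft_peak_hz <- function(w) {
  s <- Mod(stats::fft(w$samples))
  half <- length(s) %/% 2L
  (which.max(s[seq_len(half)]) - 1L) * w$rate / length(s)
}

# direct-DFT magnitude spectrogram with the same framing convention
# (centered frames, reflection padding, periodic Hann), computed from the
# definition
naive_spectrogram <- function(w, frame_length = 2048L, hop = 512L) {
  x <- w$samples
  n <- length(x)
  half <- frame_length %/% 2L
  padded <- c(rev(x[2L:(half + 1L)]), x,
              rev(x[(n - frame_length):(n - 1L)]))
  n_frames <- 1L + n %/% hop
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(frame_length) - 1L) / frame_length)
  n_bins <- frame_length %/% 2L + 1L
  basis <- exp(-2i * pi * outer(seq_len(frame_length) - 1L,
                                seq_len(n_bins) - 1L) / frame_length)
  mag <- matrix(0, n_bins, n_frames)
  for (t in seq_len(n_frames)) {
    fr <- padded[(t - 1L) * hop + seq_len(frame_length)] * win
    mag[, t] <- Mod(as.vector(fr %*% basis))
  }
  mag
}

# per-frame descriptor loops straight from the formulas
naive_shape_stats <- function(mag, bin_freqs) {
  nf <- ncol(mag)
  cen <- ban <- rol <- flat <- ent <- numeric(nf)
  for (t in seq_len(nf)) {
    m <- mag[, t]
    if (sum(m) > 0) {
      cen[t] <- sum(bin_freqs * m) / sum(m)
      ban[t] <- sqrt(sum(m * (bin_freqs - cen[t])^2) / sum(m))
      cum <- cumsum(m)
      rol[t] <- bin_freqs[which(cum >= 0.85 * sum(m))[1L]]
    }
    p <- m^2
    if (sum(p) > 0) {
      flat[t] <- exp(mean(log(pmax(p, 1e-10)))) / mean(p)
      q <- p / sum(p)
      q <- q[q > 0]
      ent[t] <- -sum(q * log2(q))
    }
  }
  pop_sd_ref <- function(x) sqrt(mean((x - mean(x))^2))
  list(centroid_mean = mean(cen), centroid_std = pop_sd_ref(cen),
       bandwidth_mean = mean(ban), bandwidth_std = pop_sd_ref(ban),
       rolloff_mean = mean(rol), rolloff_std = pop_sd_ref(rol),
       flatness = mean(flat), entropy = mean(ent))
}

# per-clip brute-force metrics: no confusion-matrix algebra
naive_metrics <- function(y_true, y_pred) {
  labels <- sort(unique(y_true))
  acc <- mean(y_true == y_pred)
  prec <- rec <- f1 <- sup <- numeric(length(labels))
  for (i in seq_along(labels)) {
    cl <- labels[i]
    tp <- sum(y_true == cl & y_pred == cl)
    prec[i] <- if (sum(y_pred == cl) > 0) tp / sum(y_pred == cl) else 0
    rec[i] <- if (sum(y_true == cl) > 0) tp / sum(y_true == cl) else 0
    f1[i] <- if (prec[i] + rec[i] > 0)
      2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
    sup[i] <- sum(y_true == cl)
  }
  w <- sup / length(y_true)
  pe <- sum(vapply(labels, function(cl)
    mean(y_true == cl) * mean(y_pred == cl), 0))
  list(accuracy = acc, precision = sum(w * prec), recall = sum(w * rec),
       f1 = sum(w * f1),
       kappa = if (pe < 1) (acc - pe) / (1 - pe) else 0)
}

# build a bleat_spec by hand (for descriptor unit cases)
toy_spec <- function(mag, bin_freqs = NULL, rate = 22050L, hop = 512L) {
  if (is.null(bin_freqs)) bin_freqs <- seq_len(nrow(mag)) - 1L
  structure(list(magnitudes = mag, bin_freqs = bin_freqs,
                 frame_times = (seq_len(ncol(mag)) - 1L) * hop / rate,
                 rate = rate, spec = frame_spec()), class = "bleat_spec")
}

# stereo 16-bit PCM WAV writer (package only writes mono)
write_stereo_wav <- function(left, right, rate, path) {
  inter <- as.integer(round(pmax(-1, pmin(1, c(rbind(left, right)))) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  u32 <- function(v) writeBin(as.integer(v), con, 4L, endian = "little")
  u16 <- function(v) writeBin(as.integer(v), con, 2L, endian = "little")
  writeChar("RIFF", con, eos = NULL); u32(36L + length(inter) * 2L)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); u32(16L)
  u16(1L); u16(2L); u32(rate); u32(rate * 4L); u16(4L); u16(16L)
  writeChar("data", con, eos = NULL); u32(length(inter) * 2L)
  writeBin(inter, con, 2L, endian = "little")
  invisible(path)
}
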