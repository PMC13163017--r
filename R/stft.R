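#' Short-time Fourier transform magnitude spectrogram
#'
#' Hann-windowed, center-padded framing: the signal is reflection-padded by
#' `frame_length / 2` samples on both sides so frame `t` is centered on
#' sample `t * hop`, and the frame count is `1 + floor(n / hop)`.
#' Reflection (rather than zero) padding avoids placing an artificial
#' signal onset at the center of the edge windows, which would splatter
#' broadband energy across the spectrum.
#'
#' @param w a [waveform()].
#' @param spec a [frame_spec()].
#' @return An object of class `bleat_spec` with `magnitudes` (bins x frames,
#'   non-negative), `bin_freqs` (Hz), `frame_times` (s), `rate`, and `spec`.
#' @export
stft <- function(w, spec = frame_spec()) {
  stopifnot(inherits(w, "bleat_wave"), inherits(spec, "bleat_framespec"))
  n <- length(w$samples)
  if (n == 0L) stop("cannot compute the STFT of an empty waveform")
  fl <- spec$frame_length; hop <- spec$hop_length
  n_frames <- 1L + n %/% hop
  half <- fl %/% 2L
  padded <- pad_center_reflect(w$samples, half, fl)
  win <- hann_window(fl)
  starts <- (seq_len(n_frames) - 1L) * hop
  frames <- matrix(0, nrow = fl, ncol = n_frames)
  for (t in seq_len(n_frames))
    frames[, t] <- padded[starts[t] + seq_len(fl)]
  frames <- frames * win
  Z <- mvfft(frames)
  n_bins <- fl %/% 2L + 1L
  mag <- Mod(Z[seq_len(n_bins), , drop = FALSE])
  structure(list(
    magnitudes = mag,
    bin_freqs = (seq_len(n_bins) - 1L) * w$rate / fl,
    frame_times = starts / w$rate,
    rate = w$rate,
    spec = spec), class = "bleat_spec")
}

# periodic Hann taper (the DFT-symmetric convention used by audio toolkits)
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)

# reflect `left` samples on the left and `right` samples on the right,
# falling back to zeros when the signal is too short to reflect
pad_center_reflect <- function(x, left, right) {
  n <- length(x)
  lp <- if (n >= left + 1L) rev(x[2L:(left + 1L)]) else
    c(numeric(left - max(n - 1L, 0L)),
      if (n >= 2L) rev(x[2L:n]) else numeric(0))
  rp <- if (n >= right + 1L) rev(x[(n - right):(n - 1L)]) else
    c(if (n >= 2L) rev(x[1L:(n - 1L)]) else numeric(0),
      numeric(right - max(n - 1L, 0L)))
  c(lp, x, rp)
}

#' @export
print.bleat_spec <- function(x, ...) {
  cat(sprintf("<bleat_spec: %d bins x %d frames @ %d Hz>\n",
              nrow(x$magnitudes), ncol(x$magnitudes), x$rate))
  invisible(x)
}

# non-centered, fully populated frames of the raw signal (used by the
# time-domain descriptors so constant signals have zero frame variance)
full_frames <- function(x, fl, hop) {
  n <- length(x)
  if (n < fl) return(matrix(x, ncol = 1L, nrow = n))
  n_frames <- 1L + (n - fl) %/% hop
  out <- matrix(0, nrow = fl, ncol = n_frames)
  for (t in seq_len(n_frames)) out[, t] <- x[(t - 1L) * hop + seq_len(fl)]
  out
}

#' Temporal and energy descriptors
#'
#' Frame-wise RMS amplitude and zero-crossing rate (mean and standard
#' deviation across frames), plus the peak of the lag-0-normalized biased
#' autocorrelation searched over lags corresponding to 50-1000 Hz, a measure
#' of pitch strength / tonal stability. Frames are non-centered so a
#' constant signal has zero RMS dispersion.
#'
#' @param w a [waveform()] (normally already standardized to 2 s).
#' @param spec a [frame_spec()].
#' @return Named numeric vector: `rms_mean`, `rms_std`, `zcr_mean`,
#'   `zcr_std`, `autocorr_peak`.
#' @export
temporal_energy_features <- function(w, spec = frame_spec()) {
  stopifnot(inherits(w, "bleat_wave"))
  fr <- full_frames(w$samples, spec$frame_length, spec$hop_length)
  rms <- sqrt(colMeans(fr^2))
  # sign-change fraction over adjacent sample pairs within each frame
  pos <- fr >= 0
  nr <- nrow(fr)
  changes <- pos[-1L, , drop = FALSE] != pos[-nr, , drop = FALSE]
  zcr <- colMeans(changes)

  n <- length(w$samples)
  ac_peak <- 0
  if (n >= 4L && any(w$samples != 0)) {
    nfft <- 2L^ceiling(log2(2L * n))
    sp <- fft(c(w$samples, numeric(nfft - n)))
    ac <- Re(fft(sp * Conj(sp), inverse = TRUE))[seq_len(n)] / nfft
    ac <- ac / ac[1L]
    lag_lo <- max(2L, floor(w$rate / 1000))
    lag_hi <- min(n - 1L, ceiling(w$rate / 50))
    if (lag_hi >= lag_lo) ac_peak <- max(ac[lag_lo:lag_hi + 1L])
  }
  c(rms_mean = mean(rms), rms_std = pop_sd(rms),
    zcr_mean = mean(zcr), zcr_std = pop_sd(zcr),
    autocorr_peak = ac_peak)
}

# population (ddof 0) standard deviation, the convention used throughout
pop_sd <- function(x) {
  if (length(x) < 2L) return(0)
  sqrt(mean((x - mean(x))^2))
}

#' Time-evolution descriptors
#'
#' Spectral flux (half-wave-rectified magnitude increase, averaged over
#' bins; the first frame contributes 0) summarized as mean and standard
#' deviation, plus the temporal centroid: the energy-weighted center of
#' gravity of the per-frame RMS envelope, in seconds. A silent clip has its
#' centroid defined as the clip midpoint.
#'
#' @param S a `bleat_spec` from [stft()].
#' @return Named numeric vector: `flux_mean`, `flux_std`,
#'   `temporal_centroid`.
#' @export
time_evolution_features <- function(S) {
  stopifnot(inherits(S, "bleat_spec"))
  M <- S$magnitudes
  nf <- ncol(M)
  flux <- numeric(nf)
  if (nf > 1L) {
    d <- M[, -1L, drop = FALSE] - M[, -nf, drop = FALSE]
    d[d < 0] <- 0
    flux[-1L] <- colMeans(d)
  }
  env <- sqrt(colMeans(M^2))
  tc <- if (sum(env) > 0) sum(S$frame_times * env) / sum(env) else {
    log_line("time_evolution_features", c(warning = "silent_clip_midpoint"))
    max(S$frame_times) / 2
  }
  c(flux_mean = mean(flux), flux_std = pop_sd(flux), temporal_centroid = tc)
}

#' Spectral shape descriptors
#'
#' Per-frame spectral centroid, bandwidth (magnitude-weighted standard
#' deviation around the centroid), 85% roll-off, 7-band spectral contrast,
#' spectral flatness, and Shannon spectral entropy (base 2, on the
#' L1-normalized power spectrum). Centroid/bandwidth/roll-off are reported
#' as mean and standard deviation across frames; contrast as 7 band means
#' plus 7 band standard deviations; flatness and entropy as clip-level frame
#' means. Silent frames contribute 0 to centroid, bandwidth and roll-off
#' (documented 0/0 guard).
#'
#' Contrast uses 7 octave-spaced sub-bands starting at 200 Hz
#' (`[0,200], [200,400], ..., [6400, Nyquist]` Hz); within each band and
#' frame the peak (valley) is the mean of the top (bottom) 2% of sorted
#' power values (at least one bin), and contrast is their ratio in dB.
#'
#' @param S a `bleat_spec` from [stft()].
#' @return Named numeric vector of length 20:
#'   `centroid_mean/std`, `bandwidth_mean/std`, `rolloff_mean/std`,
#'   `contrast_mean_0..6`, `contrast_std_0..6`, `flatness`, `entropy`.
#' @export
spectral_shape_features <- function(S, rolloff_q = 0.85, n_bands = 7L,
                                    fmin_contrast = 200, quantile_frac = 0.02) {
  stopifnot(inherits(S, "bleat_spec"))
  M <- S$magnitudes
  f <- S$bin_freqs
  nf <- ncol(M)
  msum <- colSums(M)
  ok <- msum > 0

  centroid <- numeric(nf)
  bandwidth <- numeric(nf)
  rolloff <- numeric(nf)
  if (any(ok)) {
    Mo <- M[, ok, drop = FALSE]
    cs <- colSums(Mo * f) / msum[ok]
    centroid[ok] <- cs
    bandwidth[ok] <- sqrt(colSums(Mo * outer(f, cs, `-`)^2) / msum[ok])
    cum <- apply(Mo, 2L, cumsum)
    thr <- rolloff_q * msum[ok]
    rolloff[ok] <- f[apply(cum >= rep(thr, each = nrow(cum)), 2L,
                           which.max)]
  }

  P <- M^2
  # contrast bands: [0, fmin], then octave steps up to Nyquist
  edges <- c(0, fmin_contrast * 2^(0:(n_bands - 2L)), max(f) + 1)
  cm <- matrix(0, nrow = n_bands, ncol = nf)
  for (b in seq_len(n_bands)) {
    sel <- f >= edges[b] & f < edges[b + 1L]
    if (!any(sel)) next
    Pb <- P[sel, , drop = FALSE]
    k <- max(1L, floor(quantile_frac * nrow(Pb)))
    srt <- apply(Pb, 2L, sort)
    if (is.null(dim(srt))) srt <- matrix(srt, ncol = nf)
    valley <- colMeans(srt[seq_len(k), , drop = FALSE])
    peak <- colMeans(srt[nrow(srt) - seq_len(k) + 1L, , drop = FALSE])
    cm[b, ] <- 10 * (log10(peak + .amin) - log10(valley + .amin))
  }

  psum <- colSums(P)
  flat <- numeric(nf); ent <- numeric(nf)
  pos <- psum > 0
  if (any(pos)) {
    Pp <- P[, pos, drop = FALSE]
    gm <- exp(colMeans(log(pmax(Pp, .amin))))
    am <- colMeans(Pp)
    flat[pos] <- gm / am
    Q <- Pp / rep(psum[pos], each = nrow(Pp))
    Qs <- ifelse(Q > 0, Q * log2(Q), 0)
    ent[pos] <- -colSums(Qs)
  }

  out <- c(centroid_mean = mean(centroid), centroid_std = pop_sd(centroid),
           bandwidth_mean = mean(bandwidth), bandwidth_std = pop_sd(bandwidth),
           rolloff_mean = mean(rolloff), rolloff_std = pop_sd(rolloff),
           stats_rows(cm, "contrast"),
           flatness = mean(flat), entropy = mean(ent))
  out
}

# mean/std across columns for each row of a matrix, named prefix_mean_i etc.
stats_rows <- function(m, prefix) {
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, pop_sd)
  stats::setNames(c(mu, sdv),
                  c(paste0(prefix, "_mean_", seq_len(nrow(m)) - 1L),
                    paste0(prefix, "_std_", seq_len(nrow(m)) - 1L)))
}
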