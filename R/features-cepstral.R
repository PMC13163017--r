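#' Mel filter bank
#'
#' 128 triangular filters on the Slaney mel scale (linear below 1 kHz,
#' logarithmic above) with Slaney area normalization, spanning 0 Hz to
#' Nyquist. This is the dominant toolkit convention, chosen so the named
#' coefficients are comparable with published importance rankings.
#'
#' @param rate sampling rate (Hz).
#' @param n_fft FFT size (frame length).
#' @param n_mels number of mel bands.
#' @return `n_mels x (n_fft/2 + 1)` filter matrix.
#' @export
mel_filterbank <- function(rate, n_fft = 2048L, n_mels = 128L) {
  hz_to_mel <- function(hz) {
    f_sp <- 200 / 3
    mel <- hz / f_sp
    logstep <- log(6.4) / 27
    hi <- hz >= 1000
    mel[hi] <- 15 + log(hz[hi] / 1000) / logstep
    mel
  }
  mel_to_hz <- function(mel) {
    f_sp <- 200 / 3
    hz <- mel * f_sp
    logstep <- log(6.4) / 27
    hi <- mel >= 15
    hz[hi] <- 1000 * exp(logstep * (mel[hi] - 15))
    hz
  }
  n_bins <- n_fft %/% 2L + 1L
  fft_freqs <- (seq_len(n_bins) - 1L) * rate / n_fft
  mel_pts <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(rate / 2),
                           length.out = n_mels + 2L))
  fb <- matrix(0, nrow = n_mels, ncol = n_bins)
  for (m in seq_len(n_mels)) {
    lo <- mel_pts[m]; ctr <- mel_pts[m + 1L]; hi <- mel_pts[m + 2L]
    up <- (fft_freqs - lo) / (ctr - lo)
    down <- (hi - fft_freqs) / (hi - ctr)
    fb[m, ] <- pmax(0, pmin(up, down)) * 2 / (hi - lo)   # Slaney norm
  }
  fb
}

# orthonormal DCT-II matrix (n_out x n_in)
dct_matrix <- function(n_out, n_in) {
  k <- seq_len(n_out) - 1L
  n <- seq_len(n_in) - 1L
  M <- sqrt(2 / n_in) * cos(outer(k, n + 0.5) * pi / n_in)
  M[1L, ] <- M[1L, ] / sqrt(2)
  M
}

#' Mel-frequency cepstral coefficients
#'
#' Log mel power spectrogram (128 bands, dB scale) followed by an
#' orthonormal DCT-II along the band axis, truncated to `n_coeff`
#' coefficients per frame. Low orders encode the spectral envelope (vocal
#' tract filter / formants); high orders encode timbral micro-texture.
#'
#' @param S a `bleat_spec` from [stft()].
#' @param n_coeff number of coefficients to keep (the pipeline uses 20 or
#'   40).
#' @param n_mels number of mel bands.
#' @return An object of class `bleat_ceps`: `values` (frames x n_coeff),
#'   `n_coeff`, `order` (derivative order, 0 here).
#' @export
mfcc <- function(S, n_coeff = 40L, n_mels = 128L) {
  stopifnot(inherits(S, "bleat_spec"))
  n_coeff <- as.integer(n_coeff)
  if (n_coeff < 1L || n_coeff > n_mels)
    stop("n_coeff must be in [1, ", n_mels, "]")
  fb <- mel_filterbank(S$rate, S$spec$frame_length, n_mels)
  melP <- fb %*% (S$magnitudes^2)
  logmel <- 10 * log10(pmax(melP, .amin))
  # clamp 80 dB below the clip maximum (the standard top_db convention):
  # leakage-level bands otherwise wobble near the absolute floor, and the
  # clamp preserves the exact "gain shifts only coefficient 0" property
  logmel <- pmax(logmel, max(logmel) - 80)
  C <- dct_matrix(n_coeff, n_mels) %*% logmel    # n_coeff x frames
  structure(list(values = t(C), n_coeff = n_coeff, order = 0L),
            class = "bleat_ceps")
}

#' Temporal derivatives of a cepstral matrix
#'
#' Local linear-regression slope over a 9-frame window with edge-replicated
#' padding (the standard delta filter). `order = 2` applies the filter
#' twice.
#'
#' @param C a `bleat_ceps`.
#' @param order derivative order, 1 or 2.
#' @param width regression window length (odd, default 9).
#' @return A `bleat_ceps` of the same shape with `order` incremented.
#' @export
cepstral_delta <- function(C, order = 1L, width = 9L) {
  stopifnot(inherits(C, "bleat_ceps"))
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  if (width %% 2L != 1L || width < 3L) stop("width must be odd and >= 3")
  v <- C$values
  for (rep_i in seq_len(order)) v <- delta_once(v, width)
  structure(list(values = v, n_coeff = C$n_coeff,
                 order = C$order + as.integer(order)), class = "bleat_ceps")
}

delta_once <- function(v, width) {
  half <- (width - 1L) %/% 2L
  nf <- nrow(v)
  denom <- 2 * sum((seq_len(half))^2)
  # edge-replicate frames, then regression slope at each frame
  idx <- c(rep(1L, half), seq_len(nf), rep(nf, half))
  vp <- v[idx, , drop = FALSE]
  out <- matrix(0, nrow = nf, ncol = ncol(v))
  for (k in seq_len(half)) {
    out <- out + k * (vp[half + seq_len(nf) + k, , drop = FALSE] -
                        vp[half + seq_len(nf) - k, , drop = FALSE])
  }
  out / denom
}

#' Per-coefficient summary statistics across frames
#'
#' @param C a `bleat_ceps`.
#' @param which `"mean"` or `"mean_and_std"`.
#' @param prefix name prefix (`"mfcc"`, `"delta"`, `"delta2"`); coefficient
#'   indices are 0-based to match published feature tokens such as
#'   `mfcc_mean_1` or `mfcc_std_5`.
#' @return Named numeric vector of per-coefficient means (and population
#'   standard deviations when requested).
#' @export
cepstral_stats <- function(C, which = c("mean", "mean_and_std"),
                           prefix = "mfcc") {
  stopifnot(inherits(C, "bleat_ceps"))
  which <- match.arg(which)
  mu <- colMeans(C$values)
  names(mu) <- paste0(prefix, "_mean_", seq_along(mu) - 1L)
  if (which == "mean") return(mu)
  sdv <- apply(C$values, 2L, pop_sd)
  names(sdv) <- paste0(prefix, "_std_", seq_along(sdv) - 1L)
  c(mu, sdv)
}
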