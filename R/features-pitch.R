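#' Probabilistic YIN fundamental-frequency track
#'
#' Implements the probabilistic YIN scheme: per frame, the cumulative-mean-
#' normalized difference function (CMNDF) yields pitch candidates at its
#' local minima (parabolic-interpolated); a Beta(2, 18) prior over YIN
#' thresholds converts trough depths into candidate probabilities; and a
#' hidden Markov model over log-spaced pitch bins plus an explicit unvoiced
#' state is decoded with Viterbi to produce a smooth voiced/unvoiced pitch
#' track.
#'
#' @param w a [waveform()].
#' @param fmin,fmax pitch search range (Hz); defaults 65-2093 Hz cover
#'   adult and kid caprine calls.
#' @param spec a [frame_spec()]; the difference function uses half the
#'   frame length as its integration window.
#' @param bins_per_octave resolution of the HMM pitch grid.
#' @param switch_prob voiced/unvoiced transition probability.
#' @return An object of class `bleat_pitch`: `f0` (Hz, `NA` on unvoiced
#'   frames), `voiced` (logical), `frame_times` (s).
#' @export
pyin_track <- function(w, fmin = 65, fmax = 2093, spec = frame_spec(),
                       bins_per_octave = 12L, switch_prob = 0.01) {
  stopifnot(inherits(w, "bleat_wave"))
  if (!(fmin > 0 && fmin < fmax && fmax < w$rate / 2))
    stop("require 0 < fmin < fmax < Nyquist")
  fl <- spec$frame_length; hop <- spec$hop_length
  n <- length(w$samples)
  if (n < fl) {
    return(structure(list(f0 = numeric(0), voiced = logical(0),
                          frame_times = numeric(0)), class = "bleat_pitch"))
  }
  W <- fl %/% 2L
  tau_min <- max(2L, floor(w$rate / fmax))
  tau_max <- min(W, ceiling(w$rate / fmin))

  n_frames <- 1L + n %/% hop
  half <- fl %/% 2L
  padded <- pad_center_reflect(w$samples, half, fl)
  frames <- matrix(0, nrow = fl, ncol = n_frames)
  for (t in seq_len(n_frames))
    frames[, t] <- padded[(t - 1L) * hop + seq_len(fl)]

  # YIN difference function via FFT cross-correlation, all frames at once
  nfft <- 2L * fl
  A <- frames; A[(W + 1L):fl, ] <- 0                       # leading window
  FA <- mvfft(rbind(A, matrix(0, fl, n_frames)))
  FX <- mvfft(rbind(frames, matrix(0, fl, n_frames)))
  rho <- Re(mvfft(FX * Conj(FA), inverse = TRUE))[seq_len(tau_max + 1L), ,
                                                  drop = FALSE] / nfft
  cs <- apply(rbind(0, frames^2), 2L, cumsum)              # (fl+1) x frames
  e1 <- cs[W + 1L, ]
  taus <- 0:tau_max
  e2 <- cs[W + 1L + taus, , drop = FALSE] - cs[taus + 1L, , drop = FALSE]
  d <- sweep(e2 - 2 * rho, 2L, e1, `+`)
  d[d < 0] <- 0                                            # numerical guard

  # cumulative-mean normalization; silent frames degenerate to 1
  dc <- apply(d[-1L, , drop = FALSE], 2L, cumsum)
  cmndf <- rbind(1, d[-1L, , drop = FALSE] * taus[-1L] /
                   ifelse(dc > 0, dc, Inf))
  cmndf[1L, ] <- 1

  thr_prior_q <- function(v) stats::pbeta(pmax(pmin(v, 1), 0), 2, 18)
  n_bins <- as.integer(ceiling(bins_per_octave * log2(fmax / fmin))) + 1L
  bin_freqs <- fmin * 2^((seq_len(n_bins) - 1L) / bins_per_octave)

  # The unvoiced state is pitch-agnostic: its residual mass is spread as if
  # over the reference 10-cent pitch grid (the 2 x n_bins construction of
  # the original probabilistic YIN model), so the voiced/unvoiced prior
  # odds do not depend on the coarser decoding grid used here. A
  # moderately noisy tone then still favors its voiced bin, while noise is
  # rejected by the pitch-continuity transition model.
  n_unvoiced_ref <- ceiling(120 * log2(fmax / fmin))
  obs <- matrix(0, nrow = n_bins + 1L, ncol = n_frames)
  frame_cand <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    v <- cmndf[, t]
    rng <- tau_min:tau_max
    inner <- rng[rng > 1L & rng < tau_max]
    is_min <- v[inner + 1L] < v[inner] & v[inner + 1L] <= v[inner + 2L]
    troughs <- inner[is_min] + 1L          # lag tau at index tau+1
    if (!length(troughs)) { obs[n_bins + 1L, t] <- 1 / n_unvoiced_ref; next }
    # parabolic refinement on the raw difference function
    tv <- v[troughs]
    a <- v[troughs - 1L]; b <- v[troughs]; cc <- v[troughs + 1L]
    denom <- a - 2 * b + cc
    shift <- ifelse(abs(denom) > 1e-12, 0.5 * (a - cc) / denom, 0)
    shift <- pmax(-0.5, pmin(0.5, shift))
    lag_ref <- (troughs - 1L) + shift
    freq <- w$rate / lag_ref
    keep <- freq >= fmin & freq <= fmax
    if (!any(keep)) { obs[n_bins + 1L, t] <- 1; next }
    troughs <- troughs[keep]; tv <- tv[keep]; freq <- freq[keep]

    # threshold prior mass: trough j (in lag order) is selected by
    # thresholds in (depth_j, prefix_min_{j-1}]
    pm_prev <- c(Inf, cummin(tv)[-length(tv)])
    p <- pmax(0, thr_prior_q(pm_prev) - thr_prior_q(tv))
    mass0 <- thr_prior_q(min(tv))          # thresholds below every trough
    jmin <- which.min(tv)
    p[jmin] <- p[jmin] + 0.01 * mass0
    unvoiced <- 1 - sum(p)

    bins <- pmin(pmax(round(bins_per_octave * log2(freq / fmin)) + 1L, 1L),
                 n_bins)
    for (j in seq_along(p)) obs[bins[j], t] <- obs[bins[j], t] + p[j]
    obs[n_bins + 1L, t] <- max(unvoiced, 0) / n_unvoiced_ref
    frame_cand[[t]] <- list(bins = bins, freq = freq, p = p)
  }

  # transition model: triangular pitch-jump kernel, sticky voicing state
  max_jump <- bins_per_octave
  tri <- function(i) {
    wgt <- pmax(0, max_jump + 1 - abs(seq_len(n_bins) - i))
    wgt / sum(wgt)
  }
  A <- matrix(0, n_bins + 1L, n_bins + 1L)
  for (i in seq_len(n_bins)) {
    A[i, seq_len(n_bins)] <- (1 - switch_prob) * tri(i)
    A[i, n_bins + 1L] <- switch_prob
  }
  A[n_bins + 1L, seq_len(n_bins)] <- switch_prob / n_bins
  A[n_bins + 1L, n_bins + 1L] <- 1 - switch_prob

  path <- viterbi_decode(log(pmax(obs, 1e-12)), log(pmax(A, 1e-12)))

  f0 <- rep(NA_real_, n_frames)
  voiced <- path <= n_bins
  for (t in which(voiced)) {
    fc <- frame_cand[[t]]
    if (is.null(fc)) { f0[t] <- bin_freqs[path[t]]; next }
    in_bin <- which(fc$bins == path[t])
    f0[t] <- if (length(in_bin)) fc$freq[in_bin[which.max(fc$p[in_bin])]]
             else bin_freqs[path[t]]
  }
  structure(list(f0 = f0, voiced = voiced,
                 frame_times = (seq_len(n_frames) - 1L) * hop / w$rate),
            class = "bleat_pitch")
}

# max-product decoding; log_obs: states x frames, log_A: states x states
viterbi_decode <- function(log_obs, log_A) {
  S <- nrow(log_obs); nf <- ncol(log_obs)
  delta <- log(rep(1 / S, S)) + log_obs[, 1L]
  back <- matrix(0L, nrow = S, ncol = nf)
  for (t in seq_len(nf - 1L) + 1L) {
    m <- delta + log_A                      # delta[i] recycled down rows
    arg <- max.col(t(m), ties.method = "first")
    delta <- m[cbind(arg, seq_len(S))] + log_obs[, t]
    back[, t] <- arg
  }
  path <- integer(nf)
  path[nf] <- which.max(delta)
  if (nf > 1L) for (t in rev(seq_len(nf - 1L)))
    path[t] <- back[path[t + 1L], t + 1L]
  path
}

#' Fundamental-frequency summary statistics
#'
#' Mean, maximum, population standard deviation, and least-squares slope
#' (Hz/s, F0 against frame time) over voiced frames only. All four values
#' are 0 when fewer than two frames are voiced (sentinel rule keeping the
#' feature vector finite).
#'
#' @param t a `bleat_pitch` from [pyin_track()].
#' @return Named numeric vector: `f0_mean`, `f0_max`, `f0_std`, `f0_slope`.
#' @export
f0_stats <- function(t) {
  stopifnot(inherits(t, "bleat_pitch"))
  v <- which(t$voiced & is.finite(t$f0))
  if (length(v) < 2L)
    return(c(f0_mean = 0, f0_max = 0, f0_std = 0, f0_slope = 0))
  f <- t$f0[v]; tt <- t$frame_times[v]
  slope <- if (pop_sd(tt) > 0)
    sum((tt - mean(tt)) * (f - mean(f))) / sum((tt - mean(tt))^2) else 0
  c(f0_mean = mean(f), f0_max = max(f), f0_std = pop_sd(f),
    f0_slope = slope)
}

#' Acoustic Complexity Index
#'
#' For each frequency bin, the summed absolute frame-to-frame magnitude
#' change divided by the bin's total magnitude, accumulated over bins; a
#' single temporal block spans the whole clip, so the index measures
#' within-call amplitude-modulation chaos. Bins with zero total intensity
#' contribute 0. Invariant to global amplitude scaling.
#'
#' @param S a `bleat_spec` from [stft()].
#' @return Non-negative scalar ACI.
#' @export
aci <- function(S) {
  stopifnot(inherits(S, "bleat_spec"))
  M <- S$magnitudes
  if (ncol(M) < 2L) return(0)
  num <- rowSums(abs(M[, -1L, drop = FALSE] - M[, -ncol(M), drop = FALSE]))
  den <- rowSums(M)
  sum(ifelse(den > 0, num / den, 0))
}

#' Bioacoustic Index
#'
#' Area of the time-averaged dB power spectrum (reference = spectrum
#' maximum, floor -80 dB) above its band minimum, restricted to the 2-8 kHz
#' band typically dominated by caprine vocal activity; the frequency step is
#' expressed in kHz. A band that is uniformly at the floor (all clip energy
#' elsewhere) scores 0. Frames whose analysis window overlaps the
#' reflection padding of centered framing are excluded from the time
#' average (when enough frames remain): the padding crease splatters
#' broadband energy at roughly -66 dB, which would otherwise leak
#' artificial energy into the band.
#'
#' @param S a `bleat_spec` from [stft()].
#' @param band frequency band in Hz (default `c(2000, 8000)`).
#' @return Non-negative scalar index (dB * kHz).
#' @export
bioacoustic_index <- function(S, band = c(2000, 8000)) {
  stopifnot(inherits(S, "bleat_spec"))
  nyq <- S$rate / 2
  if (band[2L] > nyq) {
    log_line("bioacoustic_index",
             c(warning = "band_clipped_to_nyquist", nyquist = nyq))
    band[2L] <- nyq
  }
  M <- S$magnitudes
  k <- as.integer(ceiling((S$spec$frame_length / 2) / S$spec$hop_length))
  if (ncol(M) > 2L * k + 1L)
    M <- M[, (k + 1L):(ncol(M) - k), drop = FALSE]
  P <- rowMeans(M^2)
  ref <- max(P)
  if (ref <= 0) return(0)
  S_db <- pmax(10 * log10(pmax(P, .amin) / ref), .db_floor)
  sel <- S$bin_freqs >= band[1L] & S$bin_freqs <= band[2L]
  if (!any(sel)) return(0)
  df_khz <- (S$bin_freqs[2L] - S$bin_freqs[1L]) / 1000
  sum(S_db[sel] - min(S_db[sel])) * df_khz
}
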