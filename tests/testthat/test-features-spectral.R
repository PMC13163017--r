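test_that("STFT framing, zero input, and tone localization", {
  w <- make_sine(1000, dur = 2, rate = 22050L)
  S <- stft(w)
  expect_equal(ncol(S$magnitudes), 87L)            # 1 + floor(44100/512)
  expect_equal(nrow(S$magnitudes), 1025L)
  expect_true(all(S$magnitudes >= 0))
  expect_true(all(diff(S$frame_times) > 0))

  z <- stft(waveform(numeric(4410), 22050L))
  expect_true(all(z$magnitudes == 0))

  # per-frame argmax at the bin nearest 1 kHz for interior frames
  target_bin <- which.min(abs(S$bin_freqs - 1000))
  interior <- 3:(ncol(S$magnitudes) - 3L)
  argmax <- apply(S$magnitudes[, interior], 2L, which.max)
  expect_true(all(argmax == target_bin))

  expect_error(frame_spec(hop_length = 0L))
  # single frame when signal shorter than the window
  expect_equal(ncol(stft(waveform(numeric(100), 22050L))$magnitudes), 1L)
})

test_that("temporal and energy descriptors match closed forms", {
  const <- temporal_energy_features(waveform(rep(0.5, 44100), 22050L))
  expect_equal(unname(const["rms_mean"]), 0.5)
  expect_equal(unname(const["rms_std"]), 0)
  expect_equal(unname(const["zcr_mean"]), 0)

  alt <- temporal_energy_features(
    waveform(rep(c(1, -1), 22050), 22050L))
  expect_equal(unname(alt["zcr_mean"]), 1)

  w <- make_sine(440, dur = 2, rate = 22050L)
  tf <- temporal_energy_features(w)
  # brute-force sign-change count on the raw signal
  s <- w$samples >= 0
  brute_zcr <- mean(s[-1] != s[-length(s)])
  expect_equal(unname(tf["zcr_mean"]), brute_zcr, tolerance = 1e-3)
  expect_equal(unname(tf["zcr_mean"]), 2 * 440 / 22050, tolerance = 2e-3)
  expect_equal(unname(tf["rms_mean"]), 1 / sqrt(2), tolerance = 1e-3)
  # strong periodicity -> autocorrelation peak near 1
  expect_gt(unname(tf["autocorr_peak"]), 0.9)
})

test_that("time-evolution descriptors: flux and temporal centroid", {
  m <- matrix(rep(c(1, 2, 3), 4), nrow = 3)        # identical frames
  expect_equal(unname(time_evolution_features(toy_spec(m))["flux_mean"]), 0)
  expect_equal(unname(time_evolution_features(toy_spec(m))["flux_std"]), 0)

  # energy in a single frame -> centroid at that frame's time
  m2 <- matrix(0, 4, 10); m2[, 7] <- 5
  S2 <- toy_spec(m2)
  tev <- time_evolution_features(S2)
  expect_equal(unname(tev["temporal_centroid"]), S2$frame_times[7])

  # uniform envelope over 2 s -> centroid ~ 1 s
  w <- make_sine(500, dur = 2, rate = 22050L)
  tc <- unname(time_evolution_features(stft(w))["temporal_centroid"])
  expect_equal(tc, 1.0, tolerance = 0.05)

  sil <- suppressMessages(
    time_evolution_features(toy_spec(matrix(0, 4, 11))))
  expect_equal(unname(sil["temporal_centroid"]),
               max(toy_spec(matrix(0, 4, 11))$frame_times) / 2)
})

test_that("spectral shape on constructed spectra matches theory", {
  # all power in one bin at frequency f
  m <- matrix(0, 64, 5); m[11, ] <- 3
  freqs <- (0:63) * 100
  ss <- spectral_shape_features(toy_spec(m, freqs))
  expect_equal(unname(ss["centroid_mean"]), freqs[11])
  expect_equal(unname(ss["bandwidth_mean"]), 0)
  expect_lt(unname(ss["flatness"]), 1e-6)
  expect_lt(unname(ss["entropy"]), 1e-6)

  # two equal-power bins -> centroid midpoint, entropy 1 bit
  m2 <- matrix(0, 64, 5); m2[c(11, 21), ] <- 2
  ss2 <- spectral_shape_features(toy_spec(m2, freqs))
  expect_equal(unname(ss2["centroid_mean"]), (freqs[11] + freqs[21]) / 2)
  expect_equal(unname(ss2["entropy"]), 1)

  # flat spectrum -> flatness 1, entropy log2(bins)
  m3 <- matrix(1, 64, 5)
  ss3 <- spectral_shape_features(toy_spec(m3, freqs))
  expect_equal(unname(ss3["flatness"]), 1, tolerance = 1e-9)
  expect_equal(unname(ss3["entropy"]), log2(64), tolerance = 1e-9)
  expect_equal(sum(grepl("^contrast_", names(ss3))), 14L)
})

test_that("descriptors agree with a naive per-frame DFT reference", {
  set.seed(71)
  for (kind in c("noise", "tone_mix")) {
    x <- if (kind == "noise") rnorm(4410) * 0.3 else
      0.5 * sin(2 * pi * 700 * (0:4409) / 22050) +
      0.2 * sin(2 * pi * 2500 * (0:4409) / 22050) + 0.05 * rnorm(4410)
    w <- waveform(x, 22050L)
    S <- stft(w)
    ref_mag <- naive_spectrogram(w)
    expect_equal(S$magnitudes, ref_mag, tolerance = 1e-6)
    ref <- naive_shape_stats(ref_mag, S$bin_freqs)
    got <- spectral_shape_features(S)
    for (nm in names(ref))
      expect_equal(unname(got[nm]), ref[[nm]], tolerance = 1e-6,
                   label = paste(kind, nm))
  }
})

test_that("amplitude-scaling invariance and range bounds hold", {
  set.seed(5)
  x <- 0.3 * sin(2 * pi * 400 * (0:8819) / 22050) + 0.1 * rnorm(8820)
  w1 <- waveform(x, 22050L)
  w2 <- waveform(3.7 * x, 22050L)
  s1 <- spectral_shape_features(stft(w1))
  s2 <- spectral_shape_features(stft(w2))
  inv <- c("centroid_mean", "rolloff_mean", "flatness", "entropy",
           paste0("contrast_mean_", 0:6))
  expect_equal(s1[inv], s2[inv], tolerance = 1e-8)
  t1 <- temporal_energy_features(w1)
  t2 <- temporal_energy_features(w2)
  expect_equal(unname(t2["rms_mean"] / t1["rms_mean"]), 3.7,
               tolerance = 1e-9)
  expect_equal(t1["zcr_mean"], t2["zcr_mean"])

  expect_true(t1["zcr_mean"] >= 0 && t1["zcr_mean"] <= 1)
  expect_true(s1["flatness"] >= 0 && s1["flatness"] <= 1)
  expect_lte(unname(s1["entropy"]), log2(1025))
  expect_lte(unname(s1["rolloff_mean"]), 22050 / 2)
  expect_gte(unname(s1["bandwidth_mean"]), 0)
})
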