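test_that("WAV round trip preserves samples within PCM quantization", {
  set.seed(1)
  w <- waveform(runif(16000, -0.8, 0.8), 16000L)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(w, path)
  r <- load_wav(path)
  expect_equal(r$rate, 16000L)
  expect_equal(length(r$samples), 16000L)
  expect_lt(max(abs(r$samples - w$samples)), 1 / 32767)
})

test_that("loading handles format contracts and errors", {
  # 2-s 16-bit mono at 16 kHz -> 32000 samples
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(waveform(numeric(32000), 16000L), path)
  w <- load_wav(path)
  expect_equal(length(w$samples), 32000L)
  expect_true(all(w$samples == 0))

  # stereo with identical channels averages to either channel
  spath <- withr::local_tempfile(fileext = ".wav")
  x <- sin(2 * pi * 200 * (0:7999) / 16000) * 0.5
  write_stereo_wav(x, x, 16000L, spath)
  ws <- load_wav(spath)
  expect_lt(max(abs(ws$samples - x)), 2 / 32767)

  expect_error(load_wav(tempfile()), "no such file")
  bad <- withr::local_tempfile(fileext = ".wav")
  writeBin(as.raw(1:40), bad)
  expect_error(load_wav(bad))
})

test_that("resampling is band-limited and duration-preserving", {
  w <- make_sine(440, dur = 2, rate = 16000L)
  expect_identical(resample_wave(w, 16000L), w)
  r <- resample_wave(w, 22050L)
  expect_equal(length(r$samples), 44100L)
  # FFT-peak oracle on both signals
  expect_equal(fft_peak_hz(w), fft_peak_hz(r), tolerance = 1e-6)
  expect_error(resample_wave(w, 0), "positive")
  # duration within one sample period, generic rates
  for (tr in c(8000L, 30000L, 44100L)) {
    rr <- resample_wave(w, tr)
    expect_lt(abs(wave_duration(rr) - 2), 1 / min(tr, 16000L))
  }
})

test_that("duration standardization pads, truncates, and is idempotent", {
  rate <- 22050L
  short <- make_sine(300, dur = 0.7, rate = rate)
  out <- standardize_duration(short, 2.0)
  expect_equal(length(out$samples), 44100L)
  expect_equal(out$samples[seq_len(15435)], short$samples)
  expect_true(all(out$samples[(15436):44100] == 0))

  exact <- make_sine(300, dur = 2.0, rate = rate)
  expect_equal(standardize_duration(exact, 2.0)$samples, exact$samples)

  long <- make_sine(300, dur = 3.0, rate = rate)
  tr <- standardize_duration(long, 2.0)
  expect_equal(tr$samples, long$samples[seq_len(44100)])

  twice <- standardize_duration(standardize_duration(short, 2.0), 2.0)
  expect_identical(twice$samples, out$samples)

  empty <- suppressMessages(standardize_duration(waveform(numeric(0), rate)))
  expect_equal(length(empty$samples), 44100L)
  expect_true(all(empty$samples == 0))
})

test_that("corpus walker maps <root>/<class>/*.wav to labeled clips", {
  root <- withr::local_tempdir()
  for (cl in c("alpha", "beta")) {
    dir.create(file.path(root, cl))
    for (i in 1:2)
      write_wav(make_sine(100 * i, dur = 0.1, rate = 8000L),
                file.path(root, cl, sprintf("c%d.wav", i)))
  }
  corp <- read_corpus(root)
  expect_equal(length(corp$waves), 4L)
  expect_equal(corp$labels, c("alpha", "alpha", "beta", "beta"))
  expect_error(read_corpus(file.path(root, "nope")), "no such directory")
})
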