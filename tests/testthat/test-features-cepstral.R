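test_that("MFCC shape contracts and degenerate inputs", {
  S <- stft(make_sine(500, dur = 0.5))
  C <- mfcc(S, 40L)
  expect_equal(nrow(C$values), ncol(S$magnitudes))
  expect_equal(ncol(C$values), 40L)
  expect_error(mfcc(S, 200L), "n_coeff")

  # digital silence: every frame identical -> per-coefficient std 0
  Cz <- mfcc(stft(waveform(numeric(22050), 22050L)), 20L)
  expect_equal(unname(apply(Cz$values, 2L, stats::sd)), rep(0, 20L))

  # stationary tone: interior frames invariant (coefficients span tens of
  # dB-units; residual per-coefficient std comes from phase-dependent
  # leakage wobble near the dynamic-range clamp)
  Ct <- mfcc(stft(make_sine(800, dur = 2)), 40L)
  interior <- Ct$values[5:80, ]
  expect_lt(max(apply(interior, 2L, stats::sd)), 0.01)
})

test_that("log-scaling: doubling amplitude only shifts coefficient 0", {
  w <- make_sine(600, dur = 0.5, amp = 0.4)
  w2 <- waveform(w$samples * 2, w$rate)
  C1 <- mfcc(stft(w), 40L)
  C2 <- mfcc(stft(w2), 40L)
  d <- C2$values - C1$values
  expect_gt(abs(mean(d[, 1])), 1)                 # c0 moves by a constant
  expect_lt(max(abs(d[, 1] - mean(d[, 1]))), 1e-8)
  expect_lt(max(abs(d[, -1])), 1e-8)
})

test_that("40-coefficient run prefixes the 20-coefficient run", {
  S <- stft(make_sine(350, dur = 0.4))
  C20 <- mfcc(S, 20L)
  C40 <- mfcc(S, 40L)
  expect_equal(C40$values[, 1:20], C20$values, tolerance = 1e-6)
})

test_that("delta filter: constants, ramps, and shape preservation", {
  flat <- structure(list(values = matrix(5, 12, 3), n_coeff = 3L,
                         order = 0L), class = "bleat_ceps")
  expect_true(all(cepstral_delta(flat, 1L)$values == 0))

  ramp <- structure(list(values = matrix(rep(seq_len(30), 2), 30, 2),
                         n_coeff = 2L, order = 0L), class = "bleat_ceps")
  D1 <- cepstral_delta(ramp, 1L)
  expect_equal(dim(D1$values), dim(ramp$values))
  expect_equal(unname(D1$values[5:26, 1]), rep(1, 22))   # interior slope 1
  D2 <- cepstral_delta(ramp, 2L)
  expect_equal(unname(D2$values[9:22, 1]), rep(0, 14))   # 2nd deriv of line
  expect_error(cepstral_delta(ramp, 3L), "order")
})

test_that("cepstral statistics match a direct column-wise reference", {
  single <- structure(list(values = matrix(c(1, -2, 7), 1, 3),
                           n_coeff = 3L, order = 0L), class = "bleat_ceps")
  st <- cepstral_stats(single, "mean_and_std")
  expect_equal(unname(st[c("mfcc_mean_0", "mfcc_mean_1", "mfcc_mean_2")]),
               c(1, -2, 7))
  expect_equal(unname(st[c("mfcc_std_0", "mfcc_std_1", "mfcc_std_2")]),
               c(0, 0, 0))

  v <- matrix(rnorm(3), 1)
  sym <- structure(list(values = rbind(v, -v), n_coeff = 3L, order = 0L),
                   class = "bleat_ceps")
  expect_equal(unname(cepstral_stats(sym, "mean")), c(0, 0, 0))

  set.seed(9)
  m <- matrix(rnorm(15), 5, 3)
  Cm <- structure(list(values = m, n_coeff = 3L, order = 0L),
                  class = "bleat_ceps")
  st <- cepstral_stats(Cm, "mean_and_std", prefix = "delta")
  for (j in 1:3) {
    expect_equal(unname(st[paste0("delta_mean_", j - 1L)]), mean(m[, j]))
    expect_equal(unname(st[paste0("delta_std_", j - 1L)]),
                 sqrt(mean((m[, j] - mean(m[, j]))^2)))
  }
})
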