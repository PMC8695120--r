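fs <- 422

test_that("welch_psd handles null and scaled signals exactly", {
  x <- rep(0, 10 * fs)
  s <- welch_psd(x, fs)
  expect_true(all(s$power == 0))
  y <- tone(20, fs, 10)
  s1 <- welch_psd(y, fs)
  s2 <- welch_psd(2 * y, fs)
  expect_equal(s2$power, 4 * s1$power, tolerance = 1e-12)
  expect_error(welch_psd(y[1:100], fs), "full segment")
})

test_that("welch_psd of a unit sine: Parseval and peak location", {
  x <- tone(20, fs, 10)
  s <- welch_psd(x, fs)
  expect_equal(band_power(s, c(0, fs / 2)), 0.5, tolerance = 0.05)
  expect_equal(s$freq_hz[which.max(s$power)], 20, tolerance = s$freq_hz[2] + 1e-9)
  # agreement with the independent rectangular periodogram oracle
  expect_equal(band_power(s, c(15, 25)), naive_band_power(x, fs, c(15, 25)),
               tolerance = 0.05)
})

test_that("Parseval holds within 5% for stationary mixtures (property)", {
  set.seed(404)
  for (i in 1:5) {
    x <- tone(runif(1, 3, 40), fs, 8, amp = runif(1, 0.5, 3)) +
      tone(runif(1, 50, 150), fs, 8, amp = runif(1, 0.5, 2)) +
      rnorm(8 * fs, sd = runif(1, 0.1, 1))
    s <- welch_psd(x, fs)
    expect_equal(band_power(s, c(0, fs / 2)), var(x), tolerance = 0.05)
  }
})

test_that("band_power integrates bands correctly and validates them", {
  x <- tone(3, fs, 10) + tone(20, fs, 10)
  s <- welch_psd(x, fs)
  expect_equal(band_power(s, c(12, 30)), 0.5, tolerance = 0.05)
  expect_error(band_power(s, c(30, 12)), "increasing")
  expect_error(band_power(s, c(20.3, 20.7)), "no frequency bins")
  expect_error(band_power(s, c(100, 300)), "fs/2")
  # additivity over a partition of [0, fs/2)
  cuts <- c(0, 10, 30, 90, fs / 2)
  parts <- vapply(seq_len(length(cuts) - 1),
                  function(i) band_power(s, cuts[i:(i + 1)]), numeric(1))
  expect_equal(sum(parts), band_power(s, c(0, fs / 2)), tolerance = 1e-9)
})

test_that("normalization is an exact per-bin z-score with an exact inverse", {
  f <- 0:50
  tr <- lapply(1:20, function(i) as_psd(f, 2 + runif(51)))
  st <- norm_stats(tr)
  # spectrum equal to the training mean -> all-zero z-scores
  z0 <- normalize_spectrum(as_psd(f, st$mean), st)
  expect_true(all(abs(z0$power) < 1e-12))
  expect_true(z0$normalized)
  # definitional case: power 4, mean 2, sd 1 -> 2
  st1 <- structure(list(freq_hz = f, mean = rep(2, 51), sd = rep(1, 51)),
                   class = "norm_stats")
  expect_equal(normalize_spectrum(as_psd(f, rep(4, 51)), st1)$power,
               rep(2, 51))
  # algebraic round trip
  sp <- as_psd(f, 5 * runif(51) + 0.5)
  rt <- denormalize_spectrum(normalize_spectrum(sp, st), st)
  expect_equal(rt$power, sp$power, tolerance = 1e-12)
  # grid mismatch and degenerate bins are rejected
  expect_error(normalize_spectrum(as_psd(0:40, rep(1, 41)), st), "grid")
  st_bad <- structure(list(freq_hz = f, mean = rep(1, 51),
                           sd = c(0, rep(1, 50))), class = "norm_stats")
  expect_error(normalize_spectrum(sp, st_bad), "zero standard deviation.*0")
})

test_that("gyro magnitude spectrum is the per-bin Euclidean norm of axis PSDs", {
  set.seed(77)
  n <- 20 * 100
  g <- cbind(tone(5, 100, 20) + rnorm(n, sd = 0.3),
             rnorm(n, sd = 0.5),
             tone(2, 100, 20, amp = 0.7) + rnorm(n, sd = 0.2))
  wc <- window_config(segment_length_s = 2)
  ms <- gyro_magnitude_spectrum(g, 100, wc)
  px <- welch_psd(g[, 1], 100, wc)$power
  py <- welch_psd(g[, 2], 100, wc)$power
  pz <- welch_psd(g[, 3], 100, wc)$power
  expect_equal(ms$power, sqrt(px^2 + py^2 + pz^2), tolerance = 1e-12)
  # single-axis degeneracy and three-axis symmetry
  x <- tone(5, 100, 20)
  one <- gyro_magnitude_spectrum(cbind(x, 0 * x, 0 * x), 100, wc)
  expect_equal(one$power, welch_psd(x, 100, wc)$power, tolerance = 1e-12)
  three <- gyro_magnitude_spectrum(cbind(x, x, x), 100, wc)
  expect_equal(three$power, sqrt(3) * welch_psd(x, 100, wc)$power,
               tolerance = 1e-12)
  expect_error(gyro_magnitude_spectrum(cbind(x, x), 100, wc), "3 columns")
})

test_that("peak tremor frequency recovers tones and applies the band rules", {
  wc <- window_config(segment_length_s = 4)
  for (f0 in c(3, 5, 7.5)) {
    ms <- gyro_magnitude_spectrum(cbind(tone(f0, 100, 30), rep(0, 3000),
                                        rep(0, 3000)), 100, wc)
    pk <- peak_tremor_frequency(ms)
    expect_equal(pk$peak_hz, f0, tolerance = 0.25 + 1e-9)
    expect_true(all(pk$tremor_band >= 1.5 & pk$tremor_band <= 8))
  }
  # larger of two peaks wins (oracle: direct bin argmax in band)
  x <- tone(3, 100, 30, amp = 2) + tone(6, 100, 30, amp = 1)
  ms <- gyro_magnitude_spectrum(cbind(x, 0 * x, 0 * x), 100, wc)
  inband <- ms$freq_hz >= 1.5 & ms$freq_hz <= 8
  oracle_hz <- ms$freq_hz[inband][which.max(ms$power[inband])]
  pk <- peak_tremor_frequency(ms)
  expect_equal(pk$peak_hz, 3)
  expect_equal(pk$peak_hz, oracle_hz)
  # scaling invariance
  ms10 <- ms
  ms10$power <- ms$power * 10
  expect_equal(peak_tremor_frequency(ms10)$peak_hz, pk$peak_hz)
  # sub-1.5 Hz content only: ordinary movement, no tremor peak
  x <- tone(0.8, 100, 30, amp = 5)
  pk0 <- peak_tremor_frequency(
    gyro_magnitude_spectrum(cbind(x, 0 * x, 0 * x), 100, wc))
  expect_true(is.na(pk0$peak_hz))
  expect_null(pk0$tremor_band)
  # resolution precondition
  coarse <- gyro_magnitude_spectrum(cbind(x, 0 * x, 0 * x), 100,
                                    window_config(segment_length_s = 1))
  expect_error(peak_tremor_frequency(coarse), "resolution")
})

test_that("streaming band power: rate contract, steady state, step tracking", {
  z <- streaming_band_power(rep(0, 60 * fs), fs, c(12, 30))
  expect_length(z$values, 300)
  expect_true(all(z$values == 0))
  # steady state of an in-band tone equals the tone power A^2/2
  x <- tone(20, fs, 20, amp = 2)
  b <- streaming_band_power(x, fs, c(12, 30), smoothing_s = 0.5)
  expect_equal(mean(b$values[b$times_s > 5]), 2, tolerance = 0.1)
  # amplitude step tracked to 90% within 3 smoothing time constants
  x2 <- c(rep(0, 10 * fs), tone(20, fs, 10, amp = 2))
  b2 <- streaming_band_power(x2, fs, c(12, 30), smoothing_s = 0.5)
  t90 <- b2$times_s[b2$times_s > 10][
    which(b2$values[b2$times_s > 10] >= 0.9 * 2)[1]]
  expect_lte(t90 - 10, 3 * 0.5 + 0.2)
  # monotone in tone amplitude
  ss <- vapply(c(0.5, 1, 2, 4), function(a) {
    s <- streaming_band_power(tone(20, fs, 10, amp = a), fs, c(12, 30))
    mean(s$values[s$times_s > 5])
  }, numeric(1))
  expect_true(all(diff(ss) > 0))
  expect_error(streaming_band_power(x, fs, c(12, 300)), "fs/2")
  expect_error(streaming_band_power(x, fs, c(12, 30), smoothing_s = 0.05),
               "smoothing_s")
})
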