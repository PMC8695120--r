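test_that("indistinguishable classes give zero weights and scores of 0.5", {
  set.seed(1)
  f <- 0:50
  sp <- synth_spectra(8, f, mu = 5, sd_bin = 0.5)
  clf <- train_spectral_classifier(sp, sp, stim_tag = "off")
  expect_true(all(clf$weights == 0))
  for (s in sp[1:3]) {
    expect_equal(classify_spectrum(clf, s)$score, 0.5, tolerance = 1e-12)
  }
})

test_that("classify_spectrum computes logistic(w . z + b) (hand example)", {
  f <- c(10, 20, 30)
  st <- structure(list(freq_hz = f, mean = rep(0, 3), sd = rep(1, 3)),
                  class = "norm_stats")
  clf <- spectral_classifier(f, weights = c(1, -1, 0), stats = st, bias = 0,
                             threshold = 0.6, stim_tag = "off")
  call <- classify_spectrum(clf, as_psd(f, c(2, 1, 5)))
  expect_equal(call$score, plogis(1), tolerance = 1e-12)  # 0.7311
  expect_true(call$movement)  # 0.7311 > 0.6
  # threshold definition: score above theta means movement
  clf2 <- spectral_classifier(f, c(1, -1, 0), st, bias = 0, threshold = 0.8)
  expect_false(classify_spectrum(clf2, as_psd(f, c(2, 1, 5)))$movement)
  # grid mismatch is rejected
  expect_error(classify_spectrum(clf, as_psd(c(10, 20, 40), c(2, 1, 5))),
               "grid")
})

test_that("training preconditions are enforced", {
  f <- 0:50
  sp <- synth_spectra(6, f, 5, 0.5)
  expect_error(train_spectral_classifier(sp[1:4], sp, "off"), "at least 5")
  sp_bad <- synth_spectra(6, 0:40, 5, 0.5)
  expect_error(train_spectral_classifier(sp, sp_bad, "off"), "grid")
})

test_that("ERD confined to the beta band concentrates the top weights there", {
  cfg <- patient_config()
  sched <- make_prompt_schedule(150, 7, c(8, 14), seed = 31)
  rec <- simulate_session(cfg, sched, stim = 0, seed = 32)
  sp <- extract_training_spectra(rec)
  clf <- train_spectral_classifier(sp$rest, sp$movement, "off")
  top5 <- clf$freq_hz[order(abs(clf$weights), decreasing = TRUE)][1:5]
  expect_true(all(top5 >= 12 & top5 <= 30))
  # beta weights are negative: a power drop there raises the movement score
  beta_bins <- clf$freq_hz >= 12 & clf$freq_hz < 30
  expect_lt(mean(clf$weights[beta_bins]), 0)
})

test_that("held-out accuracy >= 90% at per-bin effect size d = 2", {
  set.seed(1234)
  f <- 0:50
  beta_bins <- which(f >= 12 & f < 30)
  train_rest <- synth_spectra(50, f, 10, 1)
  train_move <- synth_spectra(50, f, 10, 1, beta_bins, d = 2)
  clf <- train_spectral_classifier(train_rest, train_move, "off")
  test_rest <- synth_spectra(100, f, 10, 1)
  test_move <- synth_spectra(100, f, 10, 1, beta_bins, d = 2)
  pred <- function(ss) vapply(ss, function(s)
    classify_spectrum(clf, s)$movement, logical(1))
  acc <- (sum(!pred(test_rest)) + sum(pred(test_move))) / 200
  expect_gte(acc, 0.9)
})

test_that("label-shuffled training performs at chance over 20 repeats", {
  f <- 0:50
  beta_bins <- which(f >= 12 & f < 30)
  accs <- vapply(1:20, function(rep) {
    set.seed(5000 + rep)
    pool <- c(synth_spectra(20, f, 10, 1),
              synth_spectra(20, f, 10, 1, beta_bins, d = 2))
    idx <- sample(40)
    clf <- train_spectral_classifier(pool[idx[1:20]], pool[idx[21:40]], "off")
    test_rest <- synth_spectra(50, f, 10, 1)
    test_move <- synth_spectra(50, f, 10, 1, beta_bins, d = 2)
    pred <- function(ss) vapply(ss, function(s)
      classify_spectrum(clf, s)$movement, logical(1))
    (sum(!pred(test_rest)) + sum(pred(test_move))) / 100
  }, numeric(1))
  expect_gte(mean(accs), 0.40)
  expect_lte(mean(accs), 0.60)
})

test_that("a stim-off decoder degrades on stimulated spectra (dual-classifier rationale)", {
  cfg <- patient_config()
  sp <- stim_parameters()
  sched <- make_prompt_schedule(180, 8, c(8, 14), seed = 11)
  rec_off <- simulate_session(cfg, sched, 0, seed = 21, stim_params = sp)
  clf_off <- with(extract_training_spectra(rec_off),
                  train_spectral_classifier(rest, movement, "off"))
  eval_sched <- make_prompt_schedule(180, 8, c(8, 14), seed = 101)
  acc_on_state <- function(stim_v, seed) {
    ss <- extract_training_spectra(
      simulate_session(cfg, eval_sched, stim_v, seed = seed, stim_params = sp))
    pr <- vapply(ss$rest, function(s) classify_spectrum(clf_off, s)$movement,
                 logical(1))
    pm <- vapply(ss$movement, function(s) classify_spectrum(clf_off, s)$movement,
                 logical(1))
    (mean(!pr) + mean(pm)) / 2
  }
  acc_off <- acc_on_state(0, 201)
  acc_on <- acc_on_state(sp$v_max, 202)
  expect_gte(acc_off - acc_on, 0.05)
})

test_that("embedded training requires all four states with >= 30 s each", {
  segs <- list(off_rest = rnorm(422 * 31), on_rest = rnorm(422 * 31),
               off_move = rnorm(422 * 31))
  expect_error(train_embedded_classifier(segs, 422, 150), "on_move")
  segs$on_move <- rnorm(422 * 10)
  expect_error(train_embedded_classifier(segs, 422, 150), "shorter than 30")
})

test_that("embedded classifier decodes the stimulation state on >= 95% of ticks", {
  cfg <- patient_config()
  sp <- stim_parameters()
  segs <- collect_state_segments(cfg, sp, seed = 5)
  clf <- train_embedded_classifier(segs[c("off_rest", "on_rest",
                                          "off_move", "on_move")],
                                   fs = segs$fs, stim_freq = sp$frequency_hz)
  expect_false(clf$weak_stim_separation)
  acc_state <- function(x, truth_on) {
    s <- streaming_band_power(x, segs$fs, clf$stim_band)
    b <- streaming_band_power(x, segs$fs, clf$beta_band)
    keep <- s$times_s > 1.5
    calls <- classify_band_powers(clf, log(pmax(b$values[keep], 1e-12)),
                                  log(pmax(s$values[keep], 1e-12)))
    mean((calls$inferred_stim_state == "on") == truth_on)
  }
  accs <- c(acc_state(segs$off_rest, FALSE), acc_state(segs$on_rest, TRUE),
            acc_state(segs$off_move, FALSE), acc_state(segs$on_move, TRUE))
  expect_gte(mean(accs), 0.95)
})

test_that("the sensitivity bias never increases movement false negatives", {
  cfg <- patient_config()
  sp <- stim_parameters()
  segs <- collect_state_segments(cfg, sp, seed = 6)
  four <- segs[c("off_rest", "on_rest", "off_move", "on_move")]
  clf0 <- train_embedded_classifier(four, segs$fs, sp$frequency_hz, delta = 0)
  clf5 <- train_embedded_classifier(four, segs$fs, sp$frequency_hz, delta = 0.5)
  # held-out movement segment, stim off
  held <- collect_state_segments(cfg, sp, seed = 7)
  b <- streaming_band_power(held$off_move, segs$fs, clf0$beta_band)
  s <- streaming_band_power(held$off_move, segs$fs, clf0$stim_band)
  keep <- b$times_s > 1.5
  bl <- log(pmax(b$values[keep], 1e-12))
  sl <- log(pmax(s$values[keep], 1e-12))
  fn0 <- sum(!classify_band_powers(clf0, bl, sl)$movement)
  fn5 <- sum(!classify_band_powers(clf5, bl, sl)$movement)
  expect_lte(fn5, fn0)
  # tick-by-tick monotonicity: every delta = 0 movement call persists at 0.5
  expect_true(all(classify_band_powers(clf5, bl, sl)$movement |
                    !classify_band_powers(clf0, bl, sl)$movement))
})

test_that("classify_band_powers applies the cascaded thresholds", {
  clf <- embedded_classifier(beta_band = c(12, 28), stim_band = c(145, 155),
                             stim_state_threshold = 1.0,
                             beta_threshold_off = 2.0, beta_threshold_on = 3.0)
  a <- classify_band_powers(clf, beta_logpower = 1.5, stim_logpower = 0.5)
  expect_identical(a$inferred_stim_state, "off")
  expect_true(a$movement)   # 1.5 < 2.0
  b <- classify_band_powers(clf, beta_logpower = 3.2, stim_logpower = 1.4)
  expect_identical(b$inferred_stim_state, "on")
  expect_false(b$movement)  # 3.2 > 3.0
  expect_error(classify_band_powers(clf, NA, 1), "finite")
  # sweeping beta log power across the threshold flips the call exactly once
  sweep <- classify_band_powers(clf, seq(0, 4, by = 0.01), 0.5)$movement
  expect_identical(sum(diff(sweep) != 0), 1L)
})

test_that("peripheral detection finds EMG bursts with hold-time hysteresis", {
  fs <- 500
  set.seed(9)
  x <- rnorm(6 * fs, sd = 0.02)
  burst <- (2 * fs):(4 * fs)
  x[burst] <- x[burst] + rnorm(length(burst), sd = 0.5)
  rest_env <- mean(abs(x[1:fs]))
  det <- detect_movement_peripheral(x, fs, threshold = 5 * rest_env,
                                    window_s = 0.25, hold_s = 1)
  on_t <- det$times_s[det$movement]
  expect_gte(min(on_t), 2)           # no false detection before the burst
  expect_lte(min(on_t), 2 + 0.3)     # onset within the envelope window
  expect_lte(max(on_t), 4 + 1 + 0.3) # offset within the hold time
  # trivial thresholds
  z <- detect_movement_peripheral(rep(0, fs), fs, threshold = 0.1)
  expect_false(any(z$movement))
  all_on <- detect_movement_peripheral(abs(rnorm(fs)) + 0.1, fs, threshold = 0)
  w <- round(0.25 * fs)
  expect_true(all(all_on$movement[-(1:w)]))
  expect_error(detect_movement_peripheral(x, 4, threshold = 1, window_s = 0.25),
               "3 samples")
})
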