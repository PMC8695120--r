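#' Construct a spectrum from raw vectors
#'
#' Convenience constructor for a `psd` object on an explicit bin grid, used
#' when spectra come from outside [welch_psd()] (files, tests, toy examples).
#'
#' @param freq_hz strictly increasing bin-center frequencies starting at 0.
#' @param power per-bin power density (>= 0 unless `normalized`).
#' @param fs sampling rate the grid corresponds to; defaults to `2 * max(freq_hz)`.
#' @param normalized whether `power` holds z-scores.
#' @return A `psd`.
#' @export
as_psd <- function(freq_hz, power, fs = 2 * max(freq_hz), normalized = FALSE) {
  if (length(freq_hz) != length(power)) {
    stop("`freq_hz` and `power` must have equal length", call. = FALSE)
  }
  if (any(diff(freq_hz) <= 0)) {
    stop("`freq_hz` must be strictly increasing", call. = FALSE)
  }
  if (!normalized && any(power < 0)) {
    stop("un-normalized power must be >= 0", call. = FALSE)
  }
  new_psd(freq_hz, power, fs, window_config(), normalized = normalized)
}

#' Spectral movement classifier (one stimulation state)
#'
#' A linear decoder over z-scored Welch spectra: per-bin weights, the training
#' normalization statistics, a bias, and a logistic decision threshold. Two
#' such classifiers are trained per patient — one on stimulation-off data and
#' one on stimulation-on data — because stimulation reshapes the LFP spectrum.
#'
#' Weight orientation: bins whose power drops during movement (beta-band ERD)
#' receive negative weights, so an observed power drop in those bins raises
#' the logistic score; `score > threshold` calls movement.
#'
#' @param freq_hz bin grid (Hz).
#' @param weights per-bin weights.
#' @param stats a [norm_stats()] on the same grid.
#' @param bias scalar bias.
#' @param threshold decision threshold in (0, 1).
#' @param stim_tag `"off"` or `"on"`.
#' @return An object of class `spectral_classifier`.
#' @export
spectral_classifier <- function(freq_hz, weights, stats, bias,
                                threshold = 0.5, stim_tag = c("off", "on")) {
  stim_tag <- match.arg(stim_tag)
  stopifnot(inherits(stats, "norm_stats"))
  if (!grids_match(freq_hz, stats$freq_hz) || length(weights) != length(freq_hz)) {
    stop("weights, bin grid and norm_stats grids must agree", call. = FALSE)
  }
  assert_scalar_num(threshold, "threshold", lo = 1e-9, hi = 1 - 1e-9)
  assert_scalar_num(bias, "bias")
  structure(list(freq_hz = freq_hz, weights = weights, stats = stats,
                 bias = bias, threshold = threshold, stim_tag = stim_tag),
            class = "spectral_classifier")
}

#' Train a spectral movement classifier
#'
#' Per-bin weights measure how much the (z-scored) power in each bin changes
#' between rest and prompted movement: `w = mean(z_move) - mean(z_rest)`
#' (identity-covariance linear discriminant, closed form and seedless). Under
#' beta-band ERD the beta bins get negative weights and a power drop there
#' drives the logistic score up. The bias places the score-0.5 boundary at the
#' midpoint between the two class means, so with `threshold = 0.5` the decoder
#' is the unbiased linear discriminant; sensitivity tuning is done through the
#' threshold.
#'
#' @param rest_spectra,move_spectra lists of un-normalized `psd` objects on a
#'   common bin grid, at least 5 per class.
#' Weights outside `freq_range_hz` are forced to zero: bins at and above the
#' stimulation frequency are dominated by the stimulation artifact (and very
#' low bins by drift), so the decoder listens only to the physiological range.
#'
#' @param stim_tag which stimulation state the training data came from.
#' @param threshold decision threshold in (0, 1); values below 0.5 bias the
#'   decoder toward calling movement (stimulation sensitivity).
#' @param freq_range_hz half-open `[lo, hi)` range of bins allowed to carry
#'   weight (Hz).
#' @return A [spectral_classifier()].
#' @export
train_spectral_classifier <- function(rest_spectra, move_spectra,
                                      stim_tag = c("off", "on"),
                                      threshold = 0.5,
                                      freq_range_hz = c(4, 45)) {
  stim_tag <- match.arg(stim_tag)
  if (length(rest_spectra) < 5L || length(move_spectra) < 5L) {
    stop("need at least 5 training spectra per class", call. = FALSE)
  }
  pooled <- c(rest_spectra, move_spectra)
  check_common_grid(pooled)
  st <- norm_stats(pooled)
  zmat <- function(spectra) {
    do.call(rbind, lapply(spectra, function(s) normalize_spectrum(s, st)$power))
  }
  z_rest <- colMeans(zmat(rest_spectra))
  z_move <- colMeans(zmat(move_spectra))
  w <- z_move - z_rest
  w[st$freq_hz < freq_range_hz[1] | st$freq_hz >= freq_range_hz[2]] <- 0
  b <- -sum(w * (z_rest + z_move)) / 2
  spectral_classifier(st$freq_hz, w, st, b, threshold = threshold,
                      stim_tag = stim_tag)
}

#' Score a spectrum with a spectral classifier
#'
#' Normalizes the spectrum with the classifier's training statistics, takes
#' the dot product with the weights, and passes it through the logistic
#' function; `score > threshold` calls movement.
#'
#' @param classifier a [spectral_classifier()].
#' @param spectrum an un-normalized `psd` on the classifier's bin grid.
#' @param time_s optional timestamp carried into the call.
#' @return A movement call: list with `time_s`, `movement` (logical), `score`.
#' @export
classify_spectrum <- function(classifier, spectrum, time_s = NA_real_) {
  stopifnot(inherits(classifier, "spectral_classifier"), inherits(spectrum, "psd"))
  if (!grids_match(spectrum$freq_hz, classifier$freq_hz)) {
    stop("spectrum bin grid does not match the classifier grid", call. = FALSE)
  }
  z <- normalize_spectrum(spectrum, classifier$stats)$power
  score <- plogis(sum(classifier$weights * z) + classifier$bias)
  list(time_s = time_s, movement = score > classifier$threshold, score = score)
}

#' Two-band embedded classifier
#'
#' The decision structure an implanted pulse generator can evaluate from its
#' 5 Hz band-power estimates alone. Because the device cannot be told whether
#' stimulation is on, it infers the stimulation state from the log power in a
#' band around the stimulation frequency (the artifact band), then compares
#' log beta power against a per-state threshold: desynchronized (low) beta
#' means movement. Both beta thresholds are raised by the sensitivity bias
#' `delta`, so movement is called more readily — missed stimulation is worse
#' for the patient than unnecessary stimulation.
#'
#' @param beta_band,stim_band disjoint (lo, hi) bands in Hz.
#' @param stim_state_threshold log-power threshold on the stim band.
#' @param beta_threshold_off,beta_threshold_on log-power movement thresholds
#'   per inferred stimulation state (bias already applied).
#' @param delta sensitivity bias (log-power units, >= 0) recorded for
#'   provenance.
#' @param weak_stim_separation flag set at training when the stim-band class
#'   means are separated by less than one pooled standard deviation.
#' @return An object of class `embedded_classifier`.
#' @export
embedded_classifier <- function(beta_band, stim_band, stim_state_threshold,
                                beta_threshold_off, beta_threshold_on,
                                delta = 0.25, weak_stim_separation = FALSE) {
  if (max(beta_band[1], stim_band[1]) < min(beta_band[2], stim_band[2])) {
    stop("`stim_band` must be disjoint from `beta_band`", call. = FALSE)
  }
  for (nm in c("stim_state_threshold", "beta_threshold_off", "beta_threshold_on")) {
    assert_scalar_num(get(nm), nm)
  }
  assert_scalar_num(delta, "delta", lo = 0)
  structure(list(beta_band = beta_band, stim_band = stim_band,
                 stim_state_threshold = stim_state_threshold,
                 beta_threshold_off = beta_threshold_off,
                 beta_threshold_on = beta_threshold_on,
                 delta = delta,
                 weak_stim_separation = isTRUE(weak_stim_separation)),
            class = "embedded_classifier")
}

#' Train the embedded classifier from four labelled state segments
#'
#' Takes one LFP segment (>= 30 s) per patient/stimulator state — stim off at
#' rest, stim on at rest, stim off moving, stim on moving — extracts 5 Hz log
#' band-power features ([streaming_band_power()]) in the stimulation-artifact
#' band and the beta band, and places thresholds at class-mean midpoints:
#' the stim-state threshold between the off and on stim-band means, and one
#' beta threshold per stimulation state between its rest and movement means,
#' each raised by `delta` (stim-on bias).
#'
#' @param segments named list with elements `off_rest`, `on_rest`, `off_move`,
#'   `on_move`: numeric LFP vectors, each at least 30 s long.
#' @param fs LFP sampling rate (Hz).
#' @param stim_freq stimulation frequency (Hz).
#' @param beta_band beta band (Hz); the embedded default is `c(12, 28)`.
#' @param stim_halfwidth_hz half-width of the artifact band around `stim_freq`.
#' @param delta sensitivity bias in log-power units (>= 0).
#' @param smoothing_s band-power smoothing time constant (s).
#' @param min_segment_s minimum accepted segment length (s), default 30.
#' @return An [embedded_classifier()]; training feature means are attached as
#'   attribute `"training"`.
#' @export
train_embedded_classifier <- function(segments, fs, stim_freq,
                                      beta_band = c(12, 28),
                                      stim_halfwidth_hz = 5,
                                      delta = 0.25, smoothing_s = 0.5,
                                      min_segment_s = 30) {
  need <- c("off_rest", "on_rest", "off_move", "on_move")
  if (!is.list(segments) || !all(need %in% names(segments))) {
    miss <- setdiff(need, names(segments))
    stop("`segments` must contain all four states; missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (nm in need) {
    if (length(segments[[nm]]) < min_segment_s * fs) {
      stop(sprintf("segment `%s` is shorter than %g s", nm, min_segment_s),
           call. = FALSE)
    }
  }
  stim_band <- stim_freq + c(-1, 1) * stim_halfwidth_hz
  warmup_s <- 3 * smoothing_s
  feats <- lapply(segments[need], function(x) {
    b <- streaming_band_power(x, fs, beta_band, smoothing_s)
    s <- streaming_band_power(x, fs, stim_band, smoothing_s)
    keep <- b$times_s > warmup_s
    list(beta = log(pmax(b$values[keep], 1e-12)),
         stim = log(pmax(s$values[keep], 1e-12)))
  })
  m <- function(state, band) mean(feats[[state]][[band]])
  stim_off_mean <- mean(c(feats$off_rest$stim, feats$off_move$stim))
  stim_on_mean <- mean(c(feats$on_rest$stim, feats$on_move$stim))
  stim_thr <- (stim_off_mean + stim_on_mean) / 2
  pooled_sd <- sd(c(feats$off_rest$stim, feats$off_move$stim,
                    feats$on_rest$stim, feats$on_move$stim))
  weak <- abs(stim_on_mean - stim_off_mean) <= pooled_sd
  if (weak) {
    warning("stim-band class means are separated by less than one standard deviation; ",
            "stimulation-state inference may be unreliable", call. = FALSE)
  }
  clf <- embedded_classifier(
    beta_band = beta_band, stim_band = stim_band,
    stim_state_threshold = stim_thr,
    beta_threshold_off = (m("off_rest", "beta") + m("off_move", "beta")) / 2 + delta,
    beta_threshold_on = (m("on_rest", "beta") + m("on_move", "beta")) / 2 + delta,
    delta = delta, weak_stim_separation = weak)
  attr(clf, "training") <- list(
    stim_off_mean = stim_off_mean, stim_on_mean = stim_on_mean,
    beta_means = vapply(need, m, numeric(1), band = "beta"))
  clf
}

#' Classify one pair of band-power samples
#'
#' The embedded decision rule: the stimulation state is `on` iff the stim-band
#' log power exceeds `stim_state_threshold`; movement is called iff the beta
#' log power is *below* the beta threshold for the inferred state
#' (desynchronization = low beta = movement).
#'
#' @param embedded an [embedded_classifier()].
#' @param beta_logpower,stim_logpower finite log band powers (scalars or
#'   equal-length vectors).
#' @return A movement call: list with `movement` (logical),
#'   `inferred_stim_state` (`"off"`/`"on"`), and `margin`
#'   (threshold minus beta log power; positive means movement).
#' @export
classify_band_powers <- function(embedded, beta_logpower, stim_logpower) {
  stopifnot(inherits(embedded, "embedded_classifier"))
  if (!all(is.finite(beta_logpower)) || !all(is.finite(stim_logpower))) {
    stop("band powers must be finite", call. = FALSE)
  }
  on <- stim_logpower > embedded$stim_state_threshold
  thr <- ifelse(on, embedded$beta_threshold_on, embedded$beta_threshold_off)
  margin <- thr - beta_logpower
  list(movement = margin > 0,
       inferred_stim_state = ifelse(on, "on", "off"),
       margin = margin)
}

#' Detect movement from a peripheral (EMG or gyro) signal
#'
#' Rectified moving-average envelope compared against a threshold, with
#' hold-time hysteresis: once the envelope crosses the threshold, movement
#' stays called for `hold_s` seconds past the last crossing.
#'
#' @param signal numeric EMG (mV) or low-frequency gyro magnitude (deg/s).
#' @param fs sampling rate (Hz).
#' @param threshold envelope threshold (signal units).
#' @param window_s envelope moving-average window (s); must span >= 3 samples.
#' @param hold_s hysteresis hold time (s).
#' @return list of class `movement_stream`: `times_s`, `movement` (logical),
#'   `envelope`.
#' @export
detect_movement_peripheral <- function(signal, fs, threshold,
                                       window_s = 0.25, hold_s = 1) {
  assert_scalar_num(threshold, "threshold", lo = 0)
  w <- round(window_s * fs)
  if (w < 3) stop("envelope window must span at least 3 samples", call. = FALSE)
  env <- as.numeric(stats::filter(abs(signal), rep(1 / w, w), sides = 1))
  env[is.na(env)] <- 0  # warm-up
  raw <- env > threshold
  raw[seq_len(w - 1L)] <- FALSE
  hold_n <- round(hold_s * fs)
  last_true <- cummax(ifelse(raw, seq_along(raw), 0L))
  movement <- last_true > 0L & (seq_along(raw) - last_true) <= hold_n
  structure(list(times_s = (seq_along(signal) - 1) / fs,
                 movement = movement, envelope = env),
            class = "movement_stream")
}

#' Peripheral trigger specification for the closed loop
#'
#' @param threshold EMG envelope threshold (mV).
#' @param window_s envelope window (s).
#' @param hold_s hysteresis hold (s).
#' @return An object of class `peripheral_detector`.
#' @export
peripheral_detector <- function(threshold, window_s = 0.25, hold_s = 1) {
  assert_scalar_num(threshold, "threshold", lo = 0)
  structure(list(threshold = threshold, window_s = window_s, hold_s = hold_s),
            class = "peripheral_detector")
}

#' Oracle classifier (ground-truth movement labels)
#'
#' A stand-in decoder that reads the movement label straight from the prompt
#' schedule. Used to measure the controller's intrinsic timing (telemetry +
#' ramp) with detection taken out of the equation.
#'
#' @return An object of class `oracle_classifier`.
#' @export
oracle_classifier <- function() structure(list(), class = "oracle_classifier")

#' Extract labelled training spectra from a recording
#'
#' Slides a window over the session LFP, keeps windows lying entirely within
#' one schedule interval (skipping `settle_s` seconds after each prompt
#' transition so first-order onset transients do not blur the classes), and
#' returns Welch spectra grouped by label.
#'
#' @param recording a [simulate_session()] result (or [read_session()] output).
#' @param window_s analysis window length (s), default 2.
#' @param hop_s hop between windows (s), default 1.
#' @param window_cfg Welch configuration for each window.
#' @param settle_s transition time excluded at the start of each interval (s).
#' @return list with elements `rest`, `movement`, `imagined`: lists of `psd`.
#' @export
extract_training_spectra <- function(recording, window_s = 2, hop_s = 1,
                                     window_cfg = window_config(),
                                     settle_s = 1) {
  stopifnot(inherits(recording, "session_recording"))
  fs <- recording$config$lfp_fs
  x <- recording$lfp$lfp_uv
  iv <- recording$schedule$intervals
  out <- list(rest = list(), movement = list(), imagined = list())
  for (i in seq_len(nrow(iv))) {
    t0 <- iv$start_s[i] + settle_s
    while (t0 + window_s <= iv$end_s[i] + 1e-9) {
      i0 <- round(t0 * fs) + 1L
      i1 <- i0 + round(window_s * fs) - 1L
      if (i1 <= length(x)) {
        sp <- welch_psd(x[i0:i1], fs, window_cfg)
        lbl <- iv$label[i]
        out[[lbl]][[length(out[[lbl]]) + 1L]] <- sp
      }
      t0 <- t0 + hop_s
    }
  }
  out
}

#' Train the stim-off / stim-on classifier pair
#'
#' Trains the two parallel spectral decoders the distributed controller
#' switches between: one from a calibration session recorded with stimulation
#' off, one with stimulation held on.
#'
#' @param rec_off,rec_on calibration [simulate_session()] recordings with
#'   stimulation off and held at the therapeutic amplitude, respectively.
#' @param threshold decision threshold shared by both classifiers.
#' @param ... passed to [extract_training_spectra()].
#' @return list with elements `off` and `on` ([spectral_classifier()]s).
#' @export
train_classifier_pair <- function(rec_off, rec_on, threshold = 0.45, ...) {
  sp_off <- extract_training_spectra(rec_off, ...)
  sp_on <- extract_training_spectra(rec_on, ...)
  list(off = train_spectral_classifier(sp_off$rest, sp_off$movement,
                                       stim_tag = "off", threshold = threshold),
       on = train_spectral_classifier(sp_on$rest, sp_on$movement,
                                      stim_tag = "on", threshold = threshold))
}

#' Collect the four 30-second calibration state segments
#'
#' Simulates the embedded-training protocol: for each of the four
#' patient/stimulator states (stim off/on at rest, stim off/on moving) the
#' synthetic patient is recorded for `segment_s` seconds and the LFP segment
#' returned.
#'
#' @param cfg a [patient_config()].
#' @param stim_params a [stim_parameters()].
#' @param seed integer seed.
#' @param segment_s segment length per state (s), default 30.
#' @return list with `off_rest`, `on_rest`, `off_move`, `on_move` (numeric LFP
#'   vectors) and `fs`.
#' @export
collect_state_segments <- function(cfg, stim_params, seed, segment_s = 30) {
  pad <- 2  # settle time before the scored segment
  dur <- segment_s + 2 * pad
  sched_rest <- prompt_schedule(NULL, dur)
  sched_move <- prompt_schedule(
    data.frame(start_s = pad, end_s = pad + segment_s, label = "movement"),
    dur)
  grab <- function(schedule, v, sub) {
    rec <- simulate_session(cfg, schedule, stim = v,
                            seed = sub_seed(seed, sub), stim_params = stim_params)
    fs <- cfg$lfp_fs
    rec$lfp$lfp_uv[(round(pad * fs) + 1L):round((pad + segment_s) * fs)]
  }
  list(off_rest = grab(sched_rest, 0, "cal-off-rest"),
       on_rest = grab(sched_rest, stim_params$v_max, "cal-on-rest"),
       off_move = grab(sched_move, 0, "cal-off-move"),
       on_move = grab(sched_move, stim_params$v_max, "cal-on-move"),
       fs = cfg$lfp_fs)
}
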