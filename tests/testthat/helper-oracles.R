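# Shared fixtures and independent oracles, built in code at test time.

# Independent spectral oracle: plain rectangular-window periodogram over the
# whole signal (no Welch averaging, no taper). Used only to cross-check the
# package's Welch path.
naive_psd <- function(x, fs) {
  n <- length(x)
  nf <- n %/% 2L + 1L
  p <- Mod(fft(x)[seq_len(nf)])^2 / (n * fs)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (n %% 2L == 0L) dbl[nf] <- 1
  list(freq_hz = (seq_len(nf) - 1) * fs / n, power = p * dbl, df = fs / n)
}

naive_band_power <- function(x, fs, band) {
  o <- naive_psd(x, fs)
  sel <- o$freq_hz >= band[1] & o$freq_hz < band[2]
  sum(o$power[sel]) * o$df
}

tone <- function(freq, fs, dur, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (0:(round(dur * fs) - 1)) / fs + phase)
}

# Spectra drawn around a template with i.i.d. Gaussian per-bin noise; the
# movement class is shifted down by `d` standard deviations in the beta bins.
synth_spectra <- function(n, freq_hz, mu, sd_bin, shift_bins = integer(0), d = 0) {
  lapply(seq_len(n), function(i) {
    p <- rnorm(length(freq_hz), mu, sd_bin)
    p[shift_bins] <- p[shift_bins] - d * sd_bin
    as_psd(freq_hz, pmax(p, 0.01))
  })
}

gyro_mat <- function(rec) as.matrix(rec$imu[, c("gyro_x", "gyro_y", "gyro_z")])

# Small, quiet patient for analytic checks.
quiet_cfg <- function(...) {
  patient_config(pink_noise_scale = 0, gyro_noise = 0, accel_noise = 0,
                 compass_noise = 0, emg_noise_mv = 0, stim_floor_gain = 0,
                 beta_carrier = "tone", ...)
}
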