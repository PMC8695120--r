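#' Welch spectral-averaging configuration
#'
#' @param segment_length_s segment length in seconds (default 1.0, giving
#'   ~1 Hz resolution at the supported sampling rates).
#' @param overlap_fraction fractional overlap between consecutive segments,
#'   in `[0, 1)` (default 0.5).
#' @param window_shape taper; only `"hann"` is provided.
#' @return An object of class `window_config`.
#' @export
window_config <- function(segment_length_s = 1.0, overlap_fraction = 0.5,
                          window_shape = "hann") {
  assert_scalar_num(segment_length_s, "segment_length_s", lo = 1e-6)
  assert_scalar_num(overlap_fraction, "overlap_fraction", lo = 0)
  if (overlap_fraction >= 1) stop("`overlap_fraction` must be < 1", call. = FALSE)
  window_shape <- match.arg(window_shape, "hann")
  structure(list(segment_length_s = segment_length_s,
                 overlap_fraction = overlap_fraction,
                 window_shape = window_shape),
            class = "window_config")
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

new_psd <- function(freq_hz, power, fs, window_cfg, normalized = FALSE) {
  structure(list(freq_hz = freq_hz, power = power, fs = fs,
                 window_cfg = window_cfg, normalized = normalized),
            class = "psd")
}

#' Welch power spectral density
#'
#' One-sided PSD by Welch's method: the signal is split into Hann-tapered
#' segments with the configured overlap, per-segment periodograms are averaged,
#' and the result is scaled as a density so that the integral over all bins
#' (bin width times density sum) approximates the signal variance (Parseval).
#'
#' @param samples numeric signal vector.
#' @param fs sampling rate (Hz).
#' @param window_cfg a [window_config()].
#' @return An object of class `psd`: `freq_hz` (0 to fs/2), `power` (density,
#'   input-units^2 per Hz), `fs`, `window_cfg`, `normalized` flag.
#' @examples
#' fs <- 422; t <- seq(0, 10, by = 1 / fs)
#' s <- welch_psd(sin(2 * pi * 20 * t), fs)
#' s$freq_hz[which.max(s$power)]  # ~20 Hz
#' @export
welch_psd <- function(samples, fs, window_cfg = window_config()) {
  assert_scalar_num(fs, "fs", lo = 1e-9)
  stopifnot(inherits(window_cfg, "window_config"))
  nperseg <- round(window_cfg$segment_length_s * fs)
  if (nperseg < 8) {
    stop("segment_length_s * fs must be at least 8 samples", call. = FALSE)
  }
  n <- length(samples)
  if (n < nperseg) {
    stop(sprintf("need at least one full segment (%d samples), got %d",
                 nperseg, n), call. = FALSE)
  }
  step <- max(1L, round(nperseg * (1 - window_cfg$overlap_fraction)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- hann_window(nperseg)
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s0 in starts) {
    seg <- samples[s0:(s0 + nperseg - 1L)] * w
    X <- fft(seg)[seq_len(nfreq)]
    acc <- acc + Mod(X)^2
  }
  p <- acc * scale / length(starts)
  # one-sided: double everything except DC (and Nyquist when nperseg is even)
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nperseg %% 2L == 0L) dbl[nfreq] <- 1
  new_psd(freq_hz = (seq_len(nfreq) - 1) * fs / nperseg, power = p * dbl,
          fs = fs, window_cfg = window_cfg)
}

#' Per-bin normalization statistics from training spectra
#'
#' Per-frequency-bin mean and standard deviation of a set of training spectra,
#' used to z-score spectra before classification.
#'
#' @param spectra list of un-normalized [welch_psd()] objects on a common grid.
#' @return An object of class `norm_stats` with `freq_hz`, `mean`, `sd`.
#' @export
norm_stats <- function(spectra) {
  check_common_grid(spectra)
  m <- do.call(rbind, lapply(spectra, `[[`, "power"))
  structure(list(freq_hz = spectra[[1]]$freq_hz,
                 mean = colMeans(m),
                 sd = apply(m, 2, sd)),
            class = "norm_stats")
}

check_common_grid <- function(spectra) {
  if (!length(spectra)) stop("no spectra supplied", call. = FALSE)
  f0 <- spectra[[1]]$freq_hz
  for (s in spectra) {
    if (!inherits(s, "psd")) stop("expected `psd` objects", call. = FALSE)
    if (length(s$freq_hz) != length(f0) || any(abs(s$freq_hz - f0) > 1e-9)) {
      stop("spectra are not on a common frequency-bin grid", call. = FALSE)
    }
  }
  invisible(f0)
}

grids_match <- function(a_freq, b_freq) {
  length(a_freq) == length(b_freq) && all(abs(a_freq - b_freq) < 1e-9)
}

#' Z-score a spectrum against training statistics
#'
#' @param spectrum an un-normalized `psd`.
#' @param stats a [norm_stats()] on the same bin grid.
#' @return A `psd` with per-bin z-scores and `normalized = TRUE`.
#' @export
normalize_spectrum <- function(spectrum, stats) {
  stopifnot(inherits(spectrum, "psd"), inherits(stats, "norm_stats"))
  if (!grids_match(spectrum$freq_hz, stats$freq_hz)) {
    stop("spectrum and norm_stats bin grids do not match", call. = FALSE)
  }
  zero <- which(stats$sd <= 0)
  if (length(zero)) {
    stop(sprintf(
      "degenerate training data: zero standard deviation in bin(s) at %s Hz",
      paste(format(stats$freq_hz[zero[seq_len(min(3, length(zero)))]]),
            collapse = ", ")), call. = FALSE)
  }
  out <- spectrum
  out$power <- (spectrum$power - stats$mean) / stats$sd
  out$normalized <- TRUE
  out
}

#' Invert [normalize_spectrum()]
#'
#' @param spectrum a normalized `psd`.
#' @param stats the [norm_stats()] used to normalize it.
#' @return The un-normalized `psd`.
#' @export
denormalize_spectrum <- function(spectrum, stats) {
  stopifnot(inherits(spectrum, "psd"), inherits(stats, "norm_stats"),
            isTRUE(spectrum$normalized))
  if (!grids_match(spectrum$freq_hz, stats$freq_hz)) {
    stop("spectrum and norm_stats bin grids do not match", call. = FALSE)
  }
  out <- spectrum
  out$power <- spectrum$power * stats$sd + stats$mean
  out$normalized <- FALSE
  out
}

#' Integrated band power of a spectrum
#'
#' Integral of the power spectral density over the half-open band
#' `[lo, hi)` Hz; bins belong to the band by bin-center frequency, and the
#' integral is bin width times the density sum.
#'
#' @param spectrum an un-normalized `psd`.
#' @param band_hz length-2 numeric `(lo, hi)`, within `[0, fs/2]`.
#' @return band power in input-units^2.
#' @export
band_power <- function(spectrum, band_hz) {
  stopifnot(inherits(spectrum, "psd"))
  if (isTRUE(spectrum$normalized)) {
    stop("band_power requires an un-normalized spectrum", call. = FALSE)
  }
  if (length(band_hz) != 2L || !all(is.finite(band_hz)) ||
      band_hz[2] <= band_hz[1]) {
    stop("`band_hz` must be an increasing (lo, hi) pair in Hz", call. = FALSE)
  }
  if (band_hz[1] < 0 || band_hz[2] > spectrum$fs / 2 + 1e-9) {
    stop("`band_hz` must lie within [0, fs/2]", call. = FALSE)
  }
  df <- spectrum$freq_hz[2] - spectrum$freq_hz[1]
  sel <- spectrum$freq_hz >= band_hz[1] - 1e-12 & spectrum$freq_hz < band_hz[2] - 1e-12
  if (!any(sel)) {
    stop(sprintf("band [%g, %g) Hz contains no frequency bins",
                 band_hz[1], band_hz[2]), call. = FALSE)
  }
  sum(spectrum$power[sel]) * df
}

#' Gyroscope magnitude spectrum
#'
#' Welch PSD of each gyroscope axis independently, combined per frequency bin
#' by the Euclidean norm `sqrt(Px^2 + Py^2 + Pz^2)` to give an
#' orientation-insensitive magnitude spectrum of angular velocity.
#'
#' @param gyro_3axis numeric matrix or data.frame with three equal-length
#'   columns (deg/s).
#' @param fs sampling rate (Hz).
#' @param window_cfg a [window_config()]; the default 2 s segments give the
#'   0.5 Hz resolution needed in the tremor band.
#' @return A `psd` of the combined magnitude.
#' @export
gyro_magnitude_spectrum <- function(gyro_3axis, fs,
                                    window_cfg = window_config(segment_length_s = 2)) {
  g <- as.matrix(gyro_3axis)
  if (ncol(g) != 3L) stop("`gyro_3axis` must have exactly 3 columns", call. = FALSE)
  if (anyNA(g)) stop("gyroscope axes contain missing values", call. = FALSE)
  ps <- lapply(1:3, function(j) welch_psd(g[, j], fs, window_cfg))
  out <- ps[[1]]
  out$power <- sqrt(ps[[1]]$power^2 + ps[[2]]$power^2 + ps[[3]]$power^2)
  out
}

#' Find the patient's peak tremor frequency
#'
#' The largest local maximum of a gyroscope magnitude spectrum within the
#' 1.5-8.0 Hz tremor band. Spectral content below 1.5 Hz is ordinary
#' movement, not tremor, and is excluded. The patient's tremor band is the
#' peak +/- `band_halfwidth_hz`, clipped to [1.5, 8.0] Hz.
#'
#' A candidate peak must be a strict local maximum and must stand clear of the
#' in-band noise floor: at least `floor_mult` times the median in-band power
#' and at least `rel_min` times the spectrum-wide maximum (both criteria are
#' invariant to overall scaling). If no candidate qualifies the result carries
#' `peak_hz = NA` ("no tremor peak").
#'
#' @param magnitude_spectrum a `psd`, typically from
#'   [gyro_magnitude_spectrum()], with resolution <= 0.5 Hz over the band.
#' @param band_halfwidth_hz half-width of the reported tremor band (Hz).
#' @param search_band_hz band searched for the peak, default `c(1.5, 8)`.
#' @param floor_mult,rel_min noise-floor criteria (see above).
#' @return list with `peak_hz` (NA if no peak) and `tremor_band` (length-2 or NULL).
#' @export
peak_tremor_frequency <- function(magnitude_spectrum, band_halfwidth_hz = 1,
                                  search_band_hz = c(1.5, 8),
                                  floor_mult = 5, rel_min = 2e-3) {
  stopifnot(inherits(magnitude_spectrum, "psd"))
  f <- magnitude_spectrum$freq_hz
  p <- magnitude_spectrum$power
  df <- f[2] - f[1]
  if (df > 0.5 + 1e-9) {
    stop(sprintf(
      "spectrum resolution is %.3g Hz; <= 0.5 Hz is required over the tremor band (use longer Welch segments)",
      df), call. = FALSE)
  }
  inband <- which(f >= search_band_hz[1] & f <= search_band_hz[2])
  if (length(inband) < 3) stop("spectrum does not cover the tremor band", call. = FALSE)
  # strict local maxima (ties broken toward lower frequency by >= on the right)
  idx <- inband[inband > 1 & inband < length(p)]
  is_peak <- p[idx] > p[idx - 1] & p[idx] >= p[idx + 1]
  cand <- idx[is_peak]
  floor_lvl <- max(floor_mult * median(p[inband]), rel_min * max(p))
  cand <- cand[p[cand] >= floor_lvl]
  if (!length(cand)) {
    return(list(peak_hz = NA_real_, tremor_band = NULL))
  }
  best <- cand[which.max(p[cand])]  # which.max takes the first (lowest f) on ties
  peak <- f[best]
  band <- clamp(c(peak - band_halfwidth_hz, peak + band_halfwidth_hz),
                search_band_hz[1], search_band_hz[2])
  list(peak_hz = peak, tremor_band = band)
}

#' Emulated device band-power stream at 5 Hz
#'
#' Emulates the implanted pulse generator's streamed analog band-power
#' estimates: the signal is band-passed (4th-order Butterworth), squared,
#' smoothed by a first-order exponential filter, and decimated to 5 Hz. For a
#' stationary in-band tone of amplitude A the steady-state output is the tone
#' power A^2/2.
#'
#' @param samples numeric signal.
#' @param fs sampling rate (Hz).
#' @param band_hz length-2 band (Hz), within (0, fs/2).
#' @param smoothing_s smoothing time constant (s), >= 0.2.
#' @return An object of class `band_power_stream`: `times_s` (5 Hz grid),
#'   `values` (band power, input-units^2), `band_hz`.
#' @export
streaming_band_power <- function(samples, fs, band_hz, smoothing_s = 0.5) {
  assert_scalar_num(fs, "fs", lo = 1e-9)
  assert_scalar_num(smoothing_s, "smoothing_s", lo = 0.2)
  if (length(band_hz) != 2L || band_hz[1] <= 0 || band_hz[2] <= band_hz[1] ||
      band_hz[2] >= fs / 2) {
    stop("`band_hz` must satisfy 0 < lo < hi < fs/2", call. = FALSE)
  }
  bf <- signal::butter(4, band_hz / (fs / 2), type = "pass")
  y <- signal::filter(bf, samples)          # causal, like the analog chain
  sq <- as.numeric(y)^2
  sm <- first_order_relax(sq, alpha = 1 / (smoothing_s * fs), init = 0)
  out_rate <- 5
  n_out <- floor(length(samples) / fs * out_rate)
  times <- seq_len(n_out) / out_rate
  idx <- pmin(length(sm), round(times * fs))
  structure(list(times_s = times, values = pmax(0, sm[idx]), band_hz = band_hz),
            class = "band_power_stream")
}

#' Export a spectrum as CSV
#'
#' Writes `freq_hz,power` rows.
#' @param spectrum a `psd`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "psd"))
  write.csv(data.frame(freq_hz = spectrum$freq_hz, power = spectrum$power),
            path, row.names = FALSE)
  invisible(path)
}

#' @export
print.psd <- function(x, ...) {
  cat(sprintf("<psd> %d bins, 0-%.1f Hz (df = %.3g Hz)%s\n",
              length(x$freq_hz), max(x$freq_hz), x$freq_hz[2] - x$freq_hz[1],
              if (isTRUE(x$normalized)) ", z-scored" else ""))
  invisible(x)
}
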