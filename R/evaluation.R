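#' Windowed tremor severity from gyroscope data
#'
#' For each sliding window, the gyroscope magnitude spectrum is integrated
#' over the patient's tremor band and over the whole spectrum, and tremor
#' severity is computed as
#' `severity = (tremor band power)^severity_exponent / total power`
#' (default exponent 2). Squaring the band power emphasises genuine tremor
#' over broadband movement, and dividing by total power discounts windows
#' dominated by ordinary (sub-1.5 Hz) movement; for a pure tremor tone of
#' power P the severity reduces to P. Windows with total power below `eps`
#' report severity 0.
#'
#' @param gyro_3axis 3-column matrix/data.frame of gyroscope axes (deg/s).
#' @param fs sampling rate (Hz).
#' @param tremor_band patient tremor band (Hz), within `[1.5, 8]`.
#' @param window_s sliding window length (s), >= 2 and spanning at least two
#'   tremor periods.
#' @param hop_s hop between windows (s).
#' @param window_cfg Welch configuration inside each window.
#' @param severity_exponent exponent on the band power (default 2; 1 gives the
#'   plain band-power fraction).
#' @param eps total-power floor below which severity is reported as 0.
#' @return data.frame of class `tremor_metrics`: `window_start_s`,
#'   `window_end_s`, `tremor_band_power`, `total_power`, `severity`.
#' @export
tremor_severity <- function(gyro_3axis, fs, tremor_band,
                            window_s = 4, hop_s = 2,
                            window_cfg = window_config(segment_length_s = 2),
                            severity_exponent = 2, eps = 1e-10) {
  g <- as.matrix(gyro_3axis)
  if (ncol(g) != 3L) stop("`gyro_3axis` must have 3 columns", call. = FALSE)
  if (length(tremor_band) != 2L || tremor_band[1] < 1.5 - 1e-9 ||
      tremor_band[2] > 8 + 1e-9 || tremor_band[1] >= tremor_band[2]) {
    stop("`tremor_band` must be an increasing pair within [1.5, 8] Hz", call. = FALSE)
  }
  assert_scalar_num(window_s, "window_s", lo = 2)
  if (window_s < 2 / tremor_band[1]) {
    stop("window must span at least two tremor periods", call. = FALSE)
  }
  n <- nrow(g)
  win_n <- round(window_s * fs)
  hop_n <- max(1L, round(hop_s * fs))
  if (n < win_n) stop("signal shorter than one analysis window", call. = FALSE)
  starts <- seq(1L, n - win_n + 1L, by = hop_n)
  rows <- lapply(starts, function(s0) {
    spec <- gyro_magnitude_spectrum(g[s0:(s0 + win_n - 1L), , drop = FALSE],
                                    fs, window_cfg)
    total <- band_power(spec, c(0, fs / 2))
    bp <- band_power(spec, tremor_band)
    sev <- if (total < eps) 0 else bp^severity_exponent / total
    data.frame(window_start_s = (s0 - 1) / fs,
               window_end_s = (s0 - 1 + win_n) / fs,
               tremor_band_power = bp, total_power = total, severity = sev)
  })
  out <- do.call(rbind, rows)
  attr(out, "tremor_band") <- tremor_band
  attr(out, "severity_exponent") <- severity_exponent
  class(out) <- c("tremor_metrics", "data.frame")
  out
}

#' Mean severity over windows inside schedule intervals with a given label
#'
#' @param metrics a [tremor_severity()] result.
#' @param schedule a [prompt_schedule()].
#' @param label interval label to restrict to (default `"movement"`).
#' @return mean severity over windows fully inside matching intervals
#'   (NA if none).
#' @export
severity_by_label <- function(metrics, schedule, label = "movement") {
  stopifnot(inherits(metrics, "tremor_metrics"), inherits(schedule, "prompt_schedule"))
  iv <- schedule$intervals[schedule$intervals$label == label, , drop = FALSE]
  inside <- rep(FALSE, nrow(metrics))
  for (i in seq_len(nrow(iv))) {
    inside <- inside | (metrics$window_start_s >= iv$start_s[i] - 1e-9 &
                        metrics$window_end_s <= iv$end_s[i] + 1e-9)
  }
  if (!any(inside)) return(NA_real_)
  mean(metrics$severity[inside])
}

overlap_len <- function(a0, a1, b0, b1) pmax(0, pmin(a1, b1) - pmax(a0, b0))

#' Total electrical energy delivered (TEED)
#'
#' Integrates the instantaneous stimulation power `V^2 * f * p / z` (watts)
#' over the experiment interval: for each constant-amplitude segment of the
#' stimulation log the energy contribution is `V^2 * f * p / z * duration`
#' (joules). The TEED ratio divides by the energy continuous stimulation
#' (cDBS) at `v_max` would have delivered over the same interval, and
#' per-second values are reported separately over the schedule's movement and
#' rest time.
#'
#' @param slog a [stim_log()] covering the interval.
#' @param stim_params a [stim_parameters()] (V, Hz, s, ohm units).
#' @param schedule optional [prompt_schedule()] for the movement/rest split.
#' @param interval length-2 experiment interval (s); defaults to the schedule
#'   span, or the log span if no schedule is given.
#' @return list of class `teed_result`: `teed_joules`, `teed_ratio_vs_cdbs`,
#'   `teed_per_s_movement`, `teed_per_s_rest` (the last two NA without a
#'   schedule).
#' @examples
#' sp <- stim_parameters(150, 90e-6, 1200, v_max = 3)
#' sl <- stim_log(c(0, 30), c(3, 0))
#' compute_teed(sl, sp, interval = c(0, 60))$teed_joules  # 3.0375e-3 J
#' @export
compute_teed <- function(slog, stim_params, schedule = NULL, interval = NULL) {
  stopifnot(inherits(stim_params, "stim_parameters"))
  if (!is.data.frame(slog) || !all(c("time_s", "amplitude_v") %in% names(slog))) {
    stop("`slog` must be a stim_log (time_s, amplitude_v)", call. = FALSE)
  }
  if (stim_params$impedance_ohm <= 0) stop("impedance must be > 0", call. = FALSE)
  if (is.null(interval)) {
    interval <- if (!is.null(schedule)) c(0, schedule$total_duration_s)
                else range(slog$time_s)
  }
  if (interval[2] <= interval[1]) stop("empty experiment interval", call. = FALSE)
  if (nrow(slog) == 0L || slog$time_s[1] > interval[1] + 1e-9) {
    stop("stimulation log does not cover the experiment interval", call. = FALSE)
  }
  # piecewise-constant segments clipped to the interval
  t0 <- pmax(slog$time_s, interval[1])
  t1 <- pmin(c(slog$time_s[-1L], interval[2]), interval[2])
  v <- slog$amplitude_v
  keep <- t1 > t0
  t0 <- t0[keep]; t1 <- t1[keep]; v <- v[keep]
  p_w <- v^2 * stim_params$frequency_hz * stim_params$pulse_width_s /
    stim_params$impedance_ohm
  teed <- sum(p_w * (t1 - t0))
  cdbs <- stim_params$v_max^2 * stim_params$frequency_hz *
    stim_params$pulse_width_s / stim_params$impedance_ohm *
    (interval[2] - interval[1])
  per_move <- NA_real_
  per_rest <- NA_real_
  if (!is.null(schedule)) {
    iv <- schedule$intervals
    mv <- iv[iv$label == "movement", , drop = FALSE]
    e_move <- 0
    t_move <- 0
    for (j in seq_len(nrow(mv))) {
      ol <- overlap_len(t0, t1, mv$start_s[j], mv$end_s[j])
      e_move <- e_move + sum(p_w * ol)
      t_move <- t_move + overlap_len(interval[1], interval[2],
                                     mv$start_s[j], mv$end_s[j])
    }
    t_total <- interval[2] - interval[1]
    t_rest <- t_total - t_move
    per_move <- if (t_move > 0) e_move / t_move else NA_real_
    per_rest <- if (t_rest > 0) (teed - e_move) / t_rest else NA_real_
  }
  structure(list(teed_joules = teed,
                 teed_ratio_vs_cdbs = teed / cdbs,
                 teed_per_s_movement = per_move,
                 teed_per_s_rest = per_rest),
            class = "teed_result")
}

#' Detection and latency metrics for a session
#'
#' Scores an applied-amplitude trajectory against the ground-truth prompt
#' schedule. "Effective stimulation" means amplitude at or above
#' `effective_fraction * v_max` (default 1: full therapeutic level, matching
#' delay-to-maximum-level reporting; lower values give the
#' clinically-effective-level variant). Tick-level sensitivity is the
#' percentage of movement-labelled ticks with effective stimulation; the
#' false-positive rate is the same percentage over rest ticks. Each movement
#' prompt contributes one onset-to-effective-stimulation latency; prompts
#' during which stimulation never reaches the effective level are flagged.
#'
#' @param trace a closed-loop trace (data.frame with `time_s` and `applied_v`)
#'   or a [stim_log()] (resampled on a 0.1 s grid).
#' @param schedule a [prompt_schedule()].
#' @param stim_params a [stim_parameters()] (supplies `v_max`).
#' @param effective_fraction fraction of `v_max` counted as effective, in (0, 1].
#' @return list of class `detection_report`: `sensitivity_pct`,
#'   `false_positive_pct`, `pct_time_stim_movement`, `pct_time_stim_rest`,
#'   `event_latencies_s` (one per movement prompt, NA when never effective),
#'   `n_events_missed`.
#' @export
detection_metrics <- function(trace, schedule, stim_params,
                              effective_fraction = 1) {
  if (is.null(schedule) || !inherits(schedule, "prompt_schedule") ||
      nrow(schedule$intervals) == 0L) {
    stop("a non-empty prompt schedule is required", call. = FALSE)
  }
  assert_scalar_num(effective_fraction, "effective_fraction", lo = 1e-9, hi = 1)
  if (!is.data.frame(trace)) stop("`trace` must be a data.frame", call. = FALSE)
  if (!"applied_v" %in% names(trace)) {
    if ("amplitude_v" %in% names(trace)) {
      tt <- seq(0, schedule$total_duration_s - 1e-9, by = 0.1)
      trace <- data.frame(time_s = tt, applied_v = eval_stim(trace, tt))
    } else {
      stop("`trace` needs an `applied_v` (or stim_log `amplitude_v`) column",
           call. = FALSE)
    }
  }
  level <- effective_fraction * stim_params$v_max
  eff <- trace$applied_v >= level - 1e-9
  lab <- schedule_labels(schedule, trace$time_s)
  move <- lab == "movement"
  sens <- if (any(move)) 100 * mean(eff[move]) else NA_real_
  fpr <- if (any(!move)) 100 * mean(eff[!move]) else NA_real_

  mv <- schedule$intervals[schedule$intervals$label == "movement", , drop = FALSE]
  lat <- rep(NA_real_, nrow(mv))
  for (j in seq_len(nrow(mv))) {
    sel <- which(trace$time_s >= mv$start_s[j] - 1e-9 &
                 trace$time_s < mv$end_s[j] & eff)
    if (length(sel)) lat[j] <- max(0, trace$time_s[sel[1]] - mv$start_s[j])
  }
  structure(list(sensitivity_pct = sens,
                 false_positive_pct = fpr,
                 pct_time_stim_movement = sens,
                 pct_time_stim_rest = fpr,
                 event_latencies_s = lat,
                 n_events_missed = sum(is.na(lat)),
                 effective_fraction = effective_fraction),
            class = "detection_report")
}

#' @export
print.teed_result <- function(x, ...) {
  cat(sprintf("<teed_result> %.4g J, ratio vs cDBS %.3f\n",
              x$teed_joules, x$teed_ratio_vs_cdbs))
  invisible(x)
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf(
    "<detection_report> sensitivity %.1f%%, FPR %.1f%%, median latency %.2f s (%d event(s) missed)\n",
    x$sensitivity_pct, x$false_positive_pct,
    median(x$event_latencies_s, na.rm = TRUE), x$n_events_missed))
  invisible(x)
}
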