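#' Synthetic tremor-patient configuration
#'
#' Parameters of the generative "plant": a patient whose sensorimotor cortex
#' shows a beta-band oscillation that desynchronizes during overt and imagined
#' movement (event-related desynchronization, ERD), whose hand carries an
#' action tremor in the 1.5-8 Hz band that appears during movement and is
#' attenuated by stimulation with a lag, and whose LFP is contaminated by a
#' stimulation artifact near the stimulation frequency.
#'
#' Units are fixed across the package: LFP in microvolts, gyroscope in deg/s,
#' EMG in millivolts, stimulation amplitude in volts.
#'
#' @param lfp_fs LFP sampling rate (Hz); one of 200, 422 or 800 (the rates the
#'   sensing hardware supports). Default 422, the single-channel streaming rate.
#' @param imu_fs IMU sampling rate (Hz), default 100.
#' @param emg_fs EMG sampling rate (Hz), default 500.
#' @param beta_band beta band (Hz), default `c(12, 30)`.
#' @param beta_baseline_amp resting beta oscillation amplitude (uV); the
#'   oscillation's band power is `beta_baseline_amp^2 / 2`, the power of a
#'   tone of that amplitude.
#' @param beta_carrier `"narrowband"` (default): the beta rhythm is
#'   band-limited noise spanning `beta_band`, so desynchronization is spread
#'   over the whole band as in cortical recordings; `"tone"`: a deterministic
#'   sinusoid at the band centre, useful for analytic checks.
#' @param erd_fraction fractional drop of beta amplitude during movement or
#'   imagined movement, in `[0, 1]`.
#' @param stim_beta_suppression fractional reduction of baseline beta
#'   amplitude at the therapeutic stimulation amplitude (high-frequency DBS
#'   visibly reshapes the cortical spectrum, including the beta band — the
#'   reason a separate stim-on classifier is needed). Scales linearly with
#'   `V / therapeutic_voltage`, capped at 1.
#' @param pink_noise_scale standard deviation of the 1/f LFP background (uV).
#' @param stim_artifact_gain amplitude of the LFP artifact tone at the
#'   stimulation frequency, per volt of stimulation (uV/V).
#' @param stim_floor_gain broadband (white) LFP floor lift per volt of
#'   stimulation (uV/V); stimulation visibly reshapes the whole spectrum.
#' @param tremor_freq patient's tremor frequency (Hz), within `[1.5, 8]`.
#' @param tremor_baseline_amp gyroscope tremor amplitude during unstimulated
#'   movement (deg/s).
#' @param tremor_time_constant_s first-order time constant of tremor growth at
#'   movement onset and decay under stimulation or at rest (s).
#' @param transition_time_s first-order time constant of the movement /
#'   ERD envelope at prompt onsets and offsets (s).
#' @param therapeutic_voltage stimulation amplitude at which therapy is
#'   normally delivered (V).
#' @param efficacy_v50,efficacy_slope stimulation efficacy is a logistic in
#'   amplitude: `efficacy(V) = plogis(efficacy_slope * (V - efficacy_v50))`,
#'   half-maximal at `efficacy_v50` volts with slope in 1/V.
#' @param movement_lowfreq_amp amplitude of the sub-1.5 Hz gyroscope component
#'   present during overt movement (deg/s); this is ordinary movement, not tremor.
#' @param movement_lowfreq_hz frequency of that component (Hz), < 1.5.
#' @param emg_burst_gain EMG burst amplitude during overt movement (mV).
#' @param emg_noise_mv resting EMG noise level (mV).
#' @param gyro_noise,accel_noise,compass_noise sensor noise standard
#'   deviations (deg/s, m/s^2, a.u.).
#' @return An object of class `patient_config`.
#' @export
patient_config <- function(lfp_fs = 422, imu_fs = 100, emg_fs = 500,
                           beta_band = c(12, 30),
                           beta_baseline_amp = 5,
                           beta_carrier = c("narrowband", "tone"),
                           erd_fraction = 0.7,
                           stim_beta_suppression = 0.23,
                           pink_noise_scale = 2,
                           stim_artifact_gain = 4,
                           stim_floor_gain = 0.4,
                           tremor_freq = 5,
                           tremor_baseline_amp = 10,
                           tremor_time_constant_s = 0.8,
                           transition_time_s = 0.5,
                           therapeutic_voltage = 2,
                           efficacy_v50 = 1.2,
                           efficacy_slope = 3,
                           movement_lowfreq_amp = 15,
                           movement_lowfreq_hz = 0.6,
                           emg_burst_gain = 0.5,
                           emg_noise_mv = 0.02,
                           gyro_noise = 0.2,
                           accel_noise = 0.05,
                           compass_noise = 0.01) {
  beta_carrier <- match.arg(beta_carrier)
  cfg <- mget(setdiff(names(formals(patient_config)), "beta_carrier"))
  cfg$beta_carrier <- beta_carrier
  assert_scalar_num(stim_beta_suppression, "stim_beta_suppression", 0, 1)
  if (!lfp_fs %in% c(200, 422, 800)) {
    stop("`lfp_fs` must be one of 200, 422, 800 Hz", call. = FALSE)
  }
  assert_scalar_num(erd_fraction, "erd_fraction", 0, 1)
  assert_scalar_num(tremor_freq, "tremor_freq", 1.5, 8)
  assert_scalar_num(movement_lowfreq_hz, "movement_lowfreq_hz", 0, 1.5)
  for (nm in c("beta_baseline_amp", "pink_noise_scale", "stim_artifact_gain",
               "stim_floor_gain", "tremor_baseline_amp", "movement_lowfreq_amp",
               "emg_burst_gain", "emg_noise_mv", "gyro_noise", "accel_noise",
               "compass_noise", "therapeutic_voltage")) {
    assert_scalar_num(get(nm), nm, lo = 0)
  }
  assert_scalar_num(tremor_time_constant_s, "tremor_time_constant_s", lo = 1e-3)
  assert_scalar_num(transition_time_s, "transition_time_s", lo = 1e-3)
  if (length(beta_band) != 2L || beta_band[1] >= beta_band[2]) {
    stop("`beta_band` must be an increasing (lo, hi) pair in Hz", call. = FALSE)
  }
  structure(cfg, class = "patient_config")
}

#' Stimulation efficacy at a given amplitude
#'
#' Logistic dose-response mapping stimulation amplitude to the fraction of
#' tremor suppressed, saturating in `[0, 1]`.
#'
#' @param cfg a [patient_config()].
#' @param v stimulation amplitude(s), volts.
#' @return efficacy in `[0, 1]`, same length as `v`.
#' @export
efficacy <- function(cfg, v) {
  stopifnot(inherits(cfg, "patient_config"))
  plogis(cfg$efficacy_slope * (v - cfg$efficacy_v50))
}

#' Stimulation settings
#'
#' The electrical stimulation parameters held fixed while amplitude is
#' adapted: pulse frequency, pulse width and electrode impedance, plus the
#' amplitude limits the controller may command.
#'
#' @param frequency_hz pulse frequency (Hz), default 150.
#' @param pulse_width_s pulse width (s), default 90e-6 (90 us).
#' @param impedance_ohm electrode impedance (ohm), default 1200.
#' @param v_max maximum (clinically permitted) amplitude (V).
#' @param v_min minimum amplitude (V), default 0; a nonzero floor supports
#'   high/low "graded" switching.
#' @return An object of class `stim_parameters`.
#' @export
stim_parameters <- function(frequency_hz = 150, pulse_width_s = 90e-6,
                            impedance_ohm = 1200, v_max = 2, v_min = 0) {
  assert_scalar_num(frequency_hz, "frequency_hz", lo = 1e-9)
  assert_scalar_num(pulse_width_s, "pulse_width_s", lo = 1e-12)
  assert_scalar_num(impedance_ohm, "impedance_ohm", lo = 1e-9)
  assert_scalar_num(v_max, "v_max", lo = 1e-9)
  assert_scalar_num(v_min, "v_min", lo = 0)
  if (v_min >= v_max) stop("`v_min` must be < `v_max`", call. = FALSE)
  structure(list(frequency_hz = frequency_hz, pulse_width_s = pulse_width_s,
                 impedance_ohm = impedance_ohm, v_max = v_max, v_min = v_min),
            class = "stim_parameters")
}

#' Stimulation amplitude log (step function)
#'
#' A piecewise-constant record of applied stimulation amplitude: at
#' `time_s[i]` the amplitude becomes `amplitude_v[i]` and holds until the next
#' entry. Amplitude before the first entry is 0.
#'
#' @param time_s strictly increasing times (s).
#' @param amplitude_v amplitudes (V), >= 0.
#' @return data.frame of class `stim_log`.
#' @export
stim_log <- function(time_s, amplitude_v) {
  if (length(time_s) != length(amplitude_v)) {
    stop("`time_s` and `amplitude_v` must have equal length", call. = FALSE)
  }
  if (length(time_s) && any(diff(time_s) <= 0)) {
    stop("`time_s` must be strictly increasing", call. = FALSE)
  }
  if (any(amplitude_v < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  structure(data.frame(time_s = time_s, amplitude_v = amplitude_v),
            class = c("stim_log", "data.frame"))
}

# Evaluate a stimulation input (NULL, scalar, stim_log, or function of time)
# at the given sample times.
eval_stim <- function(stim, times_s) {
  if (is.null(stim)) return(rep(0, length(times_s)))
  if (is.function(stim)) return(pmax(0, as.numeric(stim(times_s))))
  if (is.numeric(stim) && length(stim) == 1L) return(rep(stim, length(times_s)))
  if (is.data.frame(stim)) {
    idx <- findInterval(times_s + 1e-12, stim$time_s)
    v <- c(0, stim$amplitude_v)[idx + 1L]
    return(v)
  }
  stop("`stim` must be NULL, a single voltage, a stim_log, or a function of time",
       call. = FALSE)
}

# Canonical step-function form of an arbitrary stimulation input.
as_stim_log <- function(stim, duration_s, dt = 0.1) {
  if (is.data.frame(stim)) return(stim_log(stim$time_s, stim$amplitude_v))
  tt <- seq(0, duration_s - dt / 2, by = dt)
  v <- eval_stim(stim, tt)
  keep <- c(TRUE, diff(v) != 0)
  stim_log(tt[keep], v[keep])
}

# Unit-RMS beta-rhythm carrier over the session time grid: noise confined
# exactly to the beta band (spectral masking, no filter roll-off leakage),
# or a deterministic tone at the band centre.
make_beta_carrier <- function(t, fs, cfg, phase) {
  if (cfg$beta_carrier == "tone") {
    return(sqrt(2) * sin(2 * pi * mean(cfg$beta_band) * t + phase))
  }
  n <- length(t)
  X <- fft(rnorm(n))
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  X[f < cfg$beta_band[1] | f >= cfg$beta_band[2]] <- 0
  x <- Re(fft(X, inverse = TRUE)) / n
  x / sd(x)
}

# 1/f-amplitude-shaped Gaussian noise, unit variance, length n.
pink_noise <- function(n, fs) {
  w <- rnorm(n)
  X <- fft(w)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  shape <- c(0, 1 / sqrt(f[-1]))
  x <- Re(fft(X * shape, inverse = TRUE)) / n
  x / sd(x)
}

#' Simulate a synchronized multi-sensor recording session
#'
#' Runs the synthetic patient through a prompt schedule under a given
#' stimulation input and returns the full sensor suite: cortical LFP (uV),
#' 9-axis IMU at 100 Hz (gyroscope deg/s, accelerometer m/s^2, compass a.u.),
#' EMG (mV), and the stimulation log, all spanning the same session.
#'
#' The LFP is 1/f background noise plus a beta-band oscillation whose
#' amplitude drops by `erd_fraction` (first-order transition) during movement
#' and imagined movement, plus a stimulation artifact: a tone at the
#' stimulation frequency and a broadband floor lift, both proportional to the
#' applied amplitude. The gyroscope carries a sub-1.5 Hz movement component
#' and a tremor tone whose envelope relaxes (time constant
#' `tremor_time_constant_s`) toward `tremor_baseline_amp * (1 - efficacy(V))`
#' during overt movement and toward 0 at rest. EMG burst activity accompanies
#' overt movement. Imagined movement produces ERD only. The recording is a
#' deterministic function of (config, schedule, stim, seed).
#'
#' @param cfg a [patient_config()].
#' @param schedule a [prompt_schedule()].
#' @param stim stimulation input: `NULL` (off), a single voltage, a
#'   [stim_log()], or a function `f(times_s) -> volts` (closed-loop callback).
#' @param seed integer seed.
#' @param stim_params a [stim_parameters()]; sets the artifact tone frequency.
#' @return An object of class `session_recording` with elements `lfp`, `imu`,
#'   `emg` (data.frames with `time_s` plus channels), `stim_log`, `schedule`,
#'   `seed`, `config`, `stim_params`.
#' @export
simulate_session <- function(cfg, schedule, stim = NULL, seed = 1,
                             stim_params = stim_parameters()) {
  stopifnot(inherits(cfg, "patient_config"), inherits(schedule, "prompt_schedule"))
  if (stim_params$frequency_hz >= cfg$lfp_fs / 2) {
    stop(sprintf(
      "stimulation frequency %g Hz is at or above the LFP Nyquist frequency %g Hz: the artifact tone would alias",
      stim_params$frequency_hz, cfg$lfp_fs / 2), call. = FALSE)
  }
  dur <- schedule$total_duration_s

  grids <- lapply(c(lfp = cfg$lfp_fs, imu = cfg$imu_fs, emg = cfg$emg_fs),
                  function(fs) {
                    n <- round(dur * fs)
                    (seq_len(n) - 1) / fs
                  })

  noise <- with_seed(sub_seed(seed, "plant"), {
    phase <- runif(4, 0, 2 * pi)
    list(
      pink = pink_noise(length(grids$lfp), cfg$lfp_fs) * cfg$pink_noise_scale,
      floor = rnorm(length(grids$lfp)),
      phase = phase,
      beta = make_beta_carrier(grids$lfp, cfg$lfp_fs, cfg, phase[1]),
      gyro = matrix(rnorm(3 * length(grids$imu), sd = cfg$gyro_noise), ncol = 3),
      accel = matrix(rnorm(3 * length(grids$imu), sd = cfg$accel_noise), ncol = 3),
      compass = matrix(rnorm(3 * length(grids$imu), sd = cfg$compass_noise), ncol = 3),
      emg_base = rnorm(length(grids$emg), sd = cfg$emg_noise_mv),
      emg_burst = rnorm(length(grids$emg))
    )
  })

  streams <- plant_streams(cfg, schedule, stim, stim_params, grids, noise)

  structure(list(
    lfp = data.frame(time_s = grids$lfp, lfp_uv = streams$lfp),
    imu = data.frame(time_s = grids$imu,
                     gyro_x = streams$gyro[, 1], gyro_y = streams$gyro[, 2],
                     gyro_z = streams$gyro[, 3],
                     accel_x = noise$accel[, 1], accel_y = noise$accel[, 2],
                     accel_z = noise$accel[, 3],
                     mag_x = noise$compass[, 1], mag_y = noise$compass[, 2],
                     mag_z = noise$compass[, 3]),
    emg = data.frame(time_s = grids$emg, emg_mv = streams$emg),
    stim_log = as_stim_log(stim, dur),
    schedule = schedule,
    seed = seed,
    config = cfg,
    stim_params = stim_params
  ), class = "session_recording")
}

# Deterministic part of the plant given pre-drawn noise. Shared by
# simulate_session (whole session at once) and the closed loop (chunked).
plant_streams <- function(cfg, schedule, stim, stim_params, grids, noise,
                          state = NULL) {
  lab_lfp <- schedule_labels(schedule, grids$lfp)
  lab_imu <- schedule_labels(schedule, grids$imu)
  lab_emg <- schedule_labels(schedule, grids$emg)
  v_lfp <- eval_stim(stim, grids$lfp)
  v_imu <- eval_stim(stim, grids$imu)

  if (is.null(state)) {
    state <- list(erd = 0, move_imu = 0, tremor = 0, move_emg = 0)
  }

  # LFP: pink background + ERD- and stim-modulated beta rhythm + artifact.
  erd_target <- as.numeric(lab_lfp %in% c("movement", "imagined"))
  erd_env <- first_order_relax(erd_target, 1 / (cfg$transition_time_s * cfg$lfp_fs),
                               init = state$erd)
  beta_amp <- cfg$beta_baseline_amp * (1 - cfg$erd_fraction * erd_env) *
    (1 - cfg$stim_beta_suppression * clamp(v_lfp / cfg$therapeutic_voltage, 0, 1))
  lfp <- noise$pink +
    beta_amp / sqrt(2) * noise$beta +
    cfg$stim_artifact_gain * v_lfp *
      sin(2 * pi * stim_params$frequency_hz * grids$lfp + noise$phase[2]) +
    cfg$stim_floor_gain * v_lfp * noise$floor

  # Gyroscope: tremor (axis x) + low-frequency overt-movement component.
  move_target <- as.numeric(lab_imu == "movement")
  move_env <- first_order_relax(move_target, 1 / (cfg$transition_time_s * cfg$imu_fs),
                                init = state$move_imu)
  trem_target <- cfg$tremor_baseline_amp * (1 - efficacy(cfg, v_imu)) * move_target
  trem_env <- first_order_relax(trem_target, 1 / (cfg$tremor_time_constant_s * cfg$imu_fs),
                                init = state$tremor)
  lowfreq <- cfg$movement_lowfreq_amp * move_env *
    sin(2 * pi * cfg$movement_lowfreq_hz * grids$imu + noise$phase[3])
  gyro <- noise$gyro
  gyro[, 1] <- gyro[, 1] +
    trem_env * sin(2 * pi * cfg$tremor_freq * grids$imu + noise$phase[4]) +
    lowfreq
  gyro[, 2] <- gyro[, 2] + 0.6 * lowfreq
  gyro[, 3] <- gyro[, 3] + 0.3 * lowfreq

  # EMG: noise floor + amplitude-modulated broadband bursts during movement.
  emg_target <- as.numeric(lab_emg == "movement")
  emg_env <- first_order_relax(emg_target, 1 / (cfg$transition_time_s * cfg$emg_fs),
                               init = state$move_emg)
  emg <- noise$emg_base + cfg$emg_burst_gain * emg_env * noise$emg_burst

  list(lfp = lfp, gyro = gyro, emg = emg,
       state = list(erd = tail(erd_env, 1), move_imu = tail(move_env, 1),
                    tremor = tail(trem_env, 1), move_emg = tail(emg_env, 1)))
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf(
    "<session_recording> %.1f s | LFP %g Hz, IMU %g Hz, EMG %g Hz | seed %s\n",
    x$schedule$total_duration_s, x$config$lfp_fs, x$config$imu_fs,
    x$config$emg_fs, format(x$seed)))
  invisible(x)
}
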