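#' Closed-loop controller configuration
#'
#' Timing and hysteresis settings of the stimulation state machine. Mode
#' defaults reflect the link each mode runs over: the distributed mode is
#' quantized to the 400 ms telemetry packet cadence with one packet of
#' transport delay (worst-case biomarker-to-command latency 0.8 s); the
#' embedded mode runs on-device at the 5 Hz band-power rate with no transport
#' delay; the peripheral mode is distributed (wearable-sensor) control.
#'
#' @param mode `"distributed"`, `"embedded"` or `"peripheral"`.
#' @param tick_s control tick (s); defaults 0.4 (distributed/peripheral) or
#'   0.2 (embedded).
#' @param ramp_rate maximum amplitude slew (V/s); the fastest ramp the patient
#'   tolerates without paresthesia.
#' @param off_consecutive number K of consecutive rest calls required before
#'   ramping down (rest-side hysteresis); movement triggers on a single call.
#' @param transport_delay_s telemetry transport delay (s); defaults 0.4
#'   (distributed/peripheral) or 0 (embedded).
#' @param buffer_s trailing analysis buffer (s); defaults 2 (distributed),
#'   1 (embedded and peripheral).
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(mode = c("distributed", "embedded", "peripheral"),
                              tick_s = NULL, ramp_rate = 2,
                              off_consecutive = 3, transport_delay_s = NULL,
                              buffer_s = NULL) {
  mode <- match.arg(mode)
  if (is.null(tick_s)) tick_s <- if (mode == "embedded") 0.2 else 0.4
  if (is.null(transport_delay_s)) {
    transport_delay_s <- if (mode == "embedded") 0 else 0.4
  }
  if (is.null(buffer_s)) buffer_s <- if (mode == "distributed") 2 else 1
  assert_scalar_num(tick_s, "tick_s", lo = 1e-6)
  assert_scalar_num(ramp_rate, "ramp_rate", lo = 1e-9)
  assert_scalar_num(off_consecutive, "off_consecutive", lo = 1)
  assert_scalar_num(transport_delay_s, "transport_delay_s", lo = 0)
  assert_scalar_num(buffer_s, "buffer_s", lo = tick_s)
  structure(list(mode = mode, tick_s = tick_s, ramp_rate = ramp_rate,
                 off_consecutive = as.integer(off_consecutive),
                 transport_delay_s = transport_delay_s, buffer_s = buffer_s),
            class = "controller_config")
}

#' Initial state of the stimulation state machine
#'
#' @param stim_params a [stim_parameters()]; the machine starts OFF at `v_min`.
#' @return list with `phase` (`"OFF"`), `rest_count` (0), `current_v` (`v_min`).
#' @export
controller_state <- function(stim_params) {
  list(phase = "OFF", rest_count = 0L, current_v = stim_params$v_min)
}

#' Slew-rate-limited amplitude step
#'
#' Moves the amplitude toward the target by at most `ramp_rate * dt`, clamping
#' at the target. Step-wise ramping keeps amplitude changes below the
#' paresthesia-inducing slew for the patient.
#'
#' @param current_v,target_v amplitudes (V).
#' @param ramp_rate maximum slew (V/s), >= 0.
#' @param dt time step (s), > 0.
#' @return the next amplitude (V).
#' @examples
#' apply_ramp(0, 2, ramp_rate = 0.5, dt = 0.4)  # 0.2 V
#' @export
apply_ramp <- function(current_v, target_v, ramp_rate, dt) {
  if (!is.finite(ramp_rate) || ramp_rate < 0) {
    stop("`ramp_rate` must be >= 0", call. = FALSE)
  }
  assert_scalar_num(dt, "dt", lo = 1e-12)
  # snap to the target when within one step (plus float tolerance), so a
  # full traverse takes exactly ceiling(dV / (rate * dt)) ticks
  if (abs(target_v - current_v) <= ramp_rate * dt + 1e-9) return(target_v)
  current_v + clamp(target_v - current_v, -ramp_rate * dt, ramp_rate * dt)
}

#' Telemetry transport delay with tick alignment
#'
#' Models the half-duplex telemetry link: each command is delayed by the
#' transport time and then takes effect at the next command-tick boundary, so
#' the effective latency lies in `[transport_delay_s, transport_delay_s +
#' tick_s]`. With `tick_s = NULL` (or 0) and zero delay this is the identity.
#'
#' @param command_times_s command timestamps (s).
#' @param transport_delay_s transport delay (s), >= 0.
#' @param tick_s command grid (s), or `NULL`/0 for no alignment.
#' @return applied timestamps (s), same length.
#' @export
telemetry_delay <- function(command_times_s, transport_delay_s, tick_s = NULL) {
  assert_scalar_num(transport_delay_s, "transport_delay_s", lo = 0)
  t <- command_times_s + transport_delay_s
  if (is.null(tick_s) || tick_s == 0) return(t)
  tick_s * ceiling(t / tick_s - 1e-9)
}

#' One step of the stimulation state machine
#'
#' Four phases: `OFF -> (movement call) -> RAMP_UP -> (amplitude reaches
#' v_max) -> ON -> (K consecutive rest calls) -> RAMP_DOWN -> (amplitude
#' reaches v_min) -> OFF`. A movement call during `RAMP_DOWN` re-enters
#' `RAMP_UP`. Ramping continues through contrary calls until complete. The
#' active spectral decoder follows the phase: the stim-off classifier in
#' `OFF`/`RAMP_DOWN`, the stim-on classifier in `RAMP_UP`/`ON`.
#'
#' @param state controller state ([controller_state()]), with the current
#'   commanded amplitude in `current_v`.
#' @param movement logical movement call for this tick.
#' @param config a [controller_config()] (supplies K).
#' @param stim_params a [stim_parameters()] (supplies v_min / v_max).
#' @return list with `state` (updated phase and rest counter) and `target_v`.
#' @export
controller_step <- function(state, movement, config, stim_params) {
  phase <- state$phase
  if (!phase %in% c("OFF", "RAMP_UP", "ON", "RAMP_DOWN")) {
    stop("unknown controller phase: ", phase, call. = FALSE)
  }
  movement <- isTRUE(movement)
  v <- state$current_v
  K <- config$off_consecutive
  rest_count <- state$rest_count
  tol <- 1e-9

  if (phase == "OFF") {
    if (movement) {
      phase <- "RAMP_UP"
      rest_count <- 0L
    }
  } else if (phase == "RAMP_UP") {
    if (v >= stim_params$v_max - tol) {
      phase <- "ON"
      rest_count <- 0L
    }
  } else if (phase == "ON") {
    rest_count <- if (movement) 0L else rest_count + 1L
    if (rest_count >= K) {
      phase <- "RAMP_DOWN"
      rest_count <- 0L
    }
  } else { # RAMP_DOWN
    if (movement) {
      phase <- "RAMP_UP"
      rest_count <- 0L
    } else if (v <= stim_params$v_min + tol) {
      phase <- "OFF"
    }
  }
  target_v <- if (phase %in% c("RAMP_UP", "ON")) stim_params$v_max else stim_params$v_min
  list(state = list(phase = phase, rest_count = rest_count, current_v = v),
       target_v = target_v)
}

classifier_tag_for_phase <- function(phase) {
  if (phase %in% c("OFF", "RAMP_DOWN")) "off" else "on"
}

# Expected Welch bin grid for a given sampling rate and window config.
welch_grid <- function(fs, window_cfg) {
  nperseg <- round(window_cfg$segment_length_s * fs)
  (seq_len(nperseg %/% 2L + 1L) - 1) * fs / nperseg
}

#' Run the full closed loop: plant, decoder, controller
#'
#' Per control tick: the synthetic patient emits one tick of LFP/IMU/EMG under
#' the currently applied amplitude; features are computed on the trailing
#' buffer; the active decoder makes a movement call; the state machine and the
#' ramp limiter produce the next commanded amplitude, which reaches the plant
#' after the telemetry transport delay. The whole run is a deterministic
#' function of its arguments and the seed.
#'
#' @param cfg a [patient_config()].
#' @param schedule a [prompt_schedule()].
#' @param controller_cfg a [controller_config()]; its mode must match the
#'   classifier type.
#' @param classifiers for distributed mode a list with `off` and `on`
#'   [spectral_classifier()]s; for embedded mode an [embedded_classifier()];
#'   for peripheral mode a [peripheral_detector()]; any mode also accepts an
#'   [oracle_classifier()] (ground-truth labels, for timing analysis).
#' @param stim_params a [stim_parameters()].
#' @param seed integer seed.
#' @return list with `recording` (a `session_recording` whose `stim_log` is
#'   the applied amplitude) and `trace` (data.frame, one row per tick:
#'   `time_s` = tick start, `score`, `movement`, `classifier`, `state`,
#'   `commanded_v`, `applied_v`).
#' @export
run_closed_loop <- function(cfg, schedule, controller_cfg, classifiers,
                            stim_params = stim_parameters(), seed = 1) {
  stopifnot(inherits(cfg, "patient_config"),
            inherits(schedule, "prompt_schedule"),
            inherits(controller_cfg, "controller_config"))
  if (stim_params$frequency_hz >= cfg$lfp_fs / 2) {
    stop("stimulation frequency is above the LFP Nyquist frequency: aliasing",
         call. = FALSE)
  }
  mode <- controller_cfg$mode
  oracle <- inherits(classifiers, "oracle_classifier")
  wcfg <- window_config(segment_length_s = 1)

  # validate classifier / sampling-rate compatibility before the loop starts
  if (!oracle) {
    if (mode == "distributed") {
      if (!is.list(classifiers) || !inherits(classifiers$off, "spectral_classifier") ||
          !inherits(classifiers$on, "spectral_classifier")) {
        stop("distributed mode needs a list(off=, on=) of spectral classifiers",
             call. = FALSE)
      }
      grid <- welch_grid(cfg$lfp_fs, wcfg)
      if (!grids_match(classifiers$off$freq_hz, grid) ||
          !grids_match(classifiers$on$freq_hz, grid)) {
        stop("classifier bin grid is incompatible with the configured LFP sampling rate",
             call. = FALSE)
      }
    } else if (mode == "embedded") {
      if (!inherits(classifiers, "embedded_classifier")) {
        stop("embedded mode needs an embedded_classifier", call. = FALSE)
      }
      if (classifiers$stim_band[2] >= cfg$lfp_fs / 2) {
        stop("embedded stim band exceeds the LFP Nyquist frequency", call. = FALSE)
      }
    } else {
      if (!inherits(classifiers, "peripheral_detector")) {
        stop("peripheral mode needs a peripheral_detector", call. = FALSE)
      }
    }
  }

  dur <- schedule$total_duration_s
  tick <- controller_cfg$tick_s
  n_ticks <- floor(dur / tick + 1e-9)
  delay_ticks <- as.integer(round(controller_cfg$transport_delay_s / tick))

  n_lfp <- round(dur * cfg$lfp_fs)
  n_imu <- round(dur * cfg$imu_fs)
  n_emg <- round(dur * cfg$emg_fs)

  noise <- with_seed(sub_seed(seed, "plant"), {
    phase <- runif(4, 0, 2 * pi)
    list(
      pink = pink_noise(n_lfp, cfg$lfp_fs) * cfg$pink_noise_scale,
      floor = rnorm(n_lfp),
      phase = phase,
      beta = make_beta_carrier((seq_len(n_lfp) - 1) / cfg$lfp_fs, cfg$lfp_fs,
                               cfg, phase[1]),
      gyro = matrix(rnorm(3 * n_imu, sd = cfg$gyro_noise), ncol = 3),
      accel = matrix(rnorm(3 * n_imu, sd = cfg$accel_noise), ncol = 3),
      compass = matrix(rnorm(3 * n_imu, sd = cfg$compass_noise), ncol = 3),
      emg_base = rnorm(n_emg, sd = cfg$emg_noise_mv),
      emg_burst = rnorm(n_emg)
    )
  })

  lfp <- numeric(n_lfp)
  gyro <- matrix(0, n_imu, 3)
  emg <- numeric(n_emg)
  plant_state <- NULL

  st <- controller_state(stim_params)
  commanded <- rep(stim_params$v_min, n_ticks)
  trace <- data.frame(time_s = (seq_len(n_ticks) - 1) * tick,
                      score = NA_real_, movement = FALSE,
                      classifier = NA_character_, state = NA_character_,
                      commanded_v = NA_real_, applied_v = NA_real_)

  buf_n_lfp <- round(controller_cfg$buffer_s * cfg$lfp_fs)
  seg_n <- round(wcfg$segment_length_s * cfg$lfp_fs)
  last_cross_t <- -Inf

  end_idx <- function(i, fs) round(i * tick * fs)

  for (i in seq_len(n_ticks)) {
    # command issued at the end of tick j reaches the device at the tick
    # boundary (j + delay_ticks) * tick, i.e. it governs tick j+delay_ticks+1
    v_app <- if (i > delay_ticks + 1L) commanded[i - delay_ticks - 1L] else stim_params$v_min

    # plant: generate this tick's samples under the applied amplitude
    r_lfp <- (end_idx(i - 1, cfg$lfp_fs) + 1L):end_idx(i, cfg$lfp_fs)
    r_imu <- (end_idx(i - 1, cfg$imu_fs) + 1L):end_idx(i, cfg$imu_fs)
    r_emg <- (end_idx(i - 1, cfg$emg_fs) + 1L):end_idx(i, cfg$emg_fs)
    grids <- list(lfp = (r_lfp - 1) / cfg$lfp_fs,
                  imu = (r_imu - 1) / cfg$imu_fs,
                  emg = (r_emg - 1) / cfg$emg_fs)
    chunk_noise <- list(pink = noise$pink[r_lfp], floor = noise$floor[r_lfp],
                        phase = noise$phase, beta = noise$beta[r_lfp],
                        gyro = noise$gyro[r_imu, , drop = FALSE],
                        emg_base = noise$emg_base[r_emg],
                        emg_burst = noise$emg_burst[r_emg])
    ch <- plant_streams(cfg, schedule, v_app, stim_params, grids, chunk_noise,
                        state = plant_state)
    plant_state <- ch$state
    lfp[r_lfp] <- ch$lfp
    gyro[r_imu, ] <- ch$gyro
    emg[r_emg] <- ch$emg

    # decode movement from the trailing buffer
    t_now <- i * tick
    tag <- classifier_tag_for_phase(st$phase)
    movement <- FALSE
    score <- NA_real_
    if (oracle) {
      movement <- schedule_labels(schedule, t_now - tick / 2) == "movement"
      score <- as.numeric(movement)
    } else if (mode == "distributed") {
      hi <- r_lfp[length(r_lfp)]
      if (hi >= buf_n_lfp) {
        spec <- welch_psd(lfp[(hi - buf_n_lfp + 1L):hi], cfg$lfp_fs, wcfg)
        call <- classify_spectrum(classifiers[[tag]], spec, time_s = t_now)
        movement <- call$movement
        score <- call$score
      }
    } else if (mode == "embedded") {
      hi <- r_lfp[length(r_lfp)]
      if (hi >= seg_n) {
        spec <- welch_psd(lfp[(hi - seg_n + 1L):hi], cfg$lfp_fs, wcfg)
        beta_lp <- log(max(band_power(spec, classifiers$beta_band), 1e-12))
        stim_lp <- log(max(band_power(spec, classifiers$stim_band), 1e-12))
        call <- classify_band_powers(classifiers, beta_lp, stim_lp)
        movement <- call$movement
        score <- call$margin
        tag <- call$inferred_stim_state
      }
    } else { # peripheral
      hi <- r_emg[length(r_emg)]
      w_n <- round(classifiers$window_s * cfg$emg_fs)
      if (hi >= w_n) {
        env <- mean(abs(emg[(hi - w_n + 1L):hi]))
        score <- env
        if (env > classifiers$threshold) last_cross_t <- t_now
        movement <- (t_now - last_cross_t) <= classifiers$hold_s
      }
    }

    step <- controller_step(st, movement, controller_cfg, stim_params)
    new_v <- apply_ramp(st$current_v, step$target_v, controller_cfg$ramp_rate, tick)
    st <- step$state
    st$current_v <- new_v
    commanded[i] <- new_v

    trace$score[i] <- score
    trace$movement[i] <- movement
    trace$classifier[i] <- tag
    trace$state[i] <- st$phase
    trace$commanded_v[i] <- new_v
    trace$applied_v[i] <- v_app
  }

  applied <- trace$applied_v
  keep <- c(TRUE, diff(applied) != 0)
  slog <- stim_log(trace$time_s[keep], applied[keep])

  recording <- structure(list(
    lfp = data.frame(time_s = (seq_len(n_lfp) - 1) / cfg$lfp_fs, lfp_uv = lfp),
    imu = data.frame(time_s = (seq_len(n_imu) - 1) / cfg$imu_fs,
                     gyro_x = gyro[, 1], gyro_y = gyro[, 2], gyro_z = gyro[, 3],
                     accel_x = noise$accel[, 1], accel_y = noise$accel[, 2],
                     accel_z = noise$accel[, 3],
                     mag_x = noise$compass[, 1], mag_y = noise$compass[, 2],
                     mag_z = noise$compass[, 3]),
    emg = data.frame(time_s = (seq_len(n_emg) - 1) / cfg$emg_fs, emg_mv = emg),
    stim_log = slog,
    schedule = schedule,
    seed = seed,
    config = cfg,
    stim_params = stim_params
  ), class = "session_recording")

  list(recording = recording, trace = trace)
}
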