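SESSION_FORMAT_VERSION <- "1"
CLASSIFIER_FORMAT_VERSION <- "1"

# Cheap deterministic content hash for manifests/logs (hex string).
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  b <- utf8ToInt(as.character(s))
  h <- 5381
  for (v in b) h <- (h * 33 + v) %% 2^31
  sprintf("%08x", as.integer(h))
}

log_stage <- function(stage, seed, hash, verbose = TRUE) {
  if (isTRUE(verbose)) {
    message(sprintf("[adbsim] %s | seed=%s config=%s", stage, format(seed), hash))
  }
}

#' Write a session recording to a directory
#'
#' Sessions are plain-text directories: `lfp.csv`, `imu.csv`, `emg.csv`
#' (columns `time_s,<channels...>`), `stim.csv` (`time_s,amplitude_v`, a step
#' function), `schedule.json`, and `meta.json` (format version, stream
#' inventory with sampling rates and units, seed, configuration and its hash).
#'
#' @param recording a `session_recording`.
#' @param path directory to create/overwrite.
#' @param verbose log a stage line with the seed and config hash.
#' @return the manifest (contents of `meta.json`), invisibly.
#' @export
write_session <- function(recording, path, verbose = FALSE) {
  stopifnot(inherits(recording, "session_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write.csv(recording$lfp, file.path(path, "lfp.csv"), row.names = FALSE)
  write.csv(recording$imu, file.path(path, "imu.csv"), row.names = FALSE)
  write.csv(recording$emg, file.path(path, "emg.csv"), row.names = FALSE)
  write.csv(as.data.frame(recording$stim_log), file.path(path, "stim.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(intervals = recording$schedule$intervals,
         total_duration_s = recording$schedule$total_duration_s),
    file.path(path, "schedule.json"), auto_unbox = TRUE, digits = NA)
  cfg <- unclass(recording$config)
  manifest <- list(
    format_version = SESSION_FORMAT_VERSION,
    streams = list(
      lfp = list(file = "lfp.csv", fs = recording$config$lfp_fs, units = "uV",
                 channels = setdiff(names(recording$lfp), "time_s")),
      imu = list(file = "imu.csv", fs = recording$config$imu_fs,
                 units = "deg/s|m/s^2|a.u.",
                 channels = setdiff(names(recording$imu), "time_s")),
      emg = list(file = "emg.csv", fs = recording$config$emg_fs, units = "mV",
                 channels = setdiff(names(recording$emg), "time_s")),
      stim = list(file = "stim.csv", fs = NA, units = "V",
                  channels = "amplitude_v")
    ),
    seed = recording$seed,
    config = cfg,
    stim_params = unclass(recording$stim_params),
    config_hash = config_hash(cfg),
    schedule_file = "schedule.json"
  )
  jsonlite::write_json(manifest, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_stage("write_session", recording$seed, manifest$config_hash, verbose)
  invisible(manifest)
}

read_stream_csv <- function(path, file, fs, expected_channels) {
  f <- file.path(path, file)
  if (!file.exists(f)) {
    stop(sprintf("missing stream file `%s` referenced by the manifest", file),
         call. = FALSE)
  }
  d <- read.csv(f)
  if (!"time_s" %in% names(d)) {
    stop(sprintf("stream `%s` lacks a time_s column", file), call. = FALSE)
  }
  if (!all(expected_channels %in% names(d))) {
    stop(sprintf("stream `%s` is missing channel(s): %s", file,
                 paste(setdiff(expected_channels, names(d)), collapse = ", ")),
         call. = FALSE)
  }
  dt <- diff(d$time_s)
  bad <- which(dt <= 0)
  if (length(bad)) {
    stop(sprintf("non-monotone time in `%s` at row %d", file, bad[1] + 1L),
         call. = FALSE)
  }
  if (!is.na(fs) && nrow(d) > 1L) {
    fs_obs <- 1 / median(dt)
    if (abs(fs_obs - fs) > 0.01 * fs) {
      stop(sprintf("stream `%s`: sampling rate %.3g Hz does not match manifest fs = %g Hz",
                   file, fs_obs, fs), call. = FALSE)
    }
  }
  d
}

#' Read a session recording from a directory
#'
#' Inverse of [write_session()]; validates the manifest (format version,
#' referenced files, monotone timestamps, sampling rates) and rebuilds the
#' `session_recording`.
#'
#' @param path session directory.
#' @return a `session_recording`.
#' @export
read_session <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("no meta.json manifest at ", path, call. = FALSE)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(as.character(meta$format_version), SESSION_FORMAT_VERSION)) {
    stop("unsupported session format_version: ", meta$format_version, call. = FALSE)
  }
  sj <- jsonlite::read_json(file.path(path, meta$schedule_file),
                            simplifyVector = TRUE)
  iv <- as.data.frame(sj$intervals)
  schedule <- prompt_schedule(iv[iv$label != "rest", , drop = FALSE],
                              sj$total_duration_s)
  cfg <- do.call(patient_config, as.list(meta$config))
  sp <- do.call(stim_parameters, as.list(meta$stim_params))
  lfp <- read_stream_csv(path, meta$streams$lfp$file, meta$streams$lfp$fs,
                         meta$streams$lfp$channels)
  imu <- read_stream_csv(path, meta$streams$imu$file, meta$streams$imu$fs,
                         meta$streams$imu$channels)
  emg <- read_stream_csv(path, meta$streams$emg$file, meta$streams$emg$fs,
                         meta$streams$emg$channels)
  stim <- read_stream_csv(path, meta$streams$stim$file, NA,
                          meta$streams$stim$channels)
  structure(list(lfp = lfp, imu = imu, emg = emg,
                 stim_log = stim_log(stim$time_s, stim$amplitude_v),
                 schedule = schedule, seed = meta$seed, config = cfg,
                 stim_params = sp),
            class = "session_recording")
}

#' Save a classifier as versioned JSON
#'
#' @param model a [spectral_classifier()] or [embedded_classifier()].
#' @param path output `.json` file.
#' @param metadata optional named list stored alongside (e.g. training seed).
#' @return `path`, invisibly.
#' @export
save_classifier <- function(model, path, metadata = NULL) {
  if (inherits(model, "spectral_classifier")) {
    payload <- list(
      format_version = CLASSIFIER_FORMAT_VERSION,
      type = "spectral_classifier",
      stim_tag = model$stim_tag,
      freq_hz = model$freq_hz,
      weights = model$weights,
      norm_mean = model$stats$mean,
      norm_sd = model$stats$sd,
      bias = model$bias,
      threshold = model$threshold,
      metadata = metadata)
  } else if (inherits(model, "embedded_classifier")) {
    payload <- list(
      format_version = CLASSIFIER_FORMAT_VERSION,
      type = "embedded_classifier",
      beta_band = model$beta_band,
      stim_band = model$stim_band,
      stim_state_threshold = model$stim_state_threshold,
      beta_threshold_off = model$beta_threshold_off,
      beta_threshold_on = model$beta_threshold_on,
      delta = model$delta,
      weak_stim_separation = model$weak_stim_separation,
      metadata = metadata)
  } else {
    stop("`model` must be a spectral_classifier or embedded_classifier",
         call. = FALSE)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a classifier saved by [save_classifier()]
#'
#' Rejects unknown format versions and validates fields through the type
#' constructors.
#'
#' @param path `.json` file.
#' @return the classifier object.
#' @export
load_classifier <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format_version) ||
      !identical(as.character(p$format_version), CLASSIFIER_FORMAT_VERSION)) {
    stop("unsupported classifier format_version: ",
         if (is.null(p$format_version)) "<missing>" else p$format_version,
         call. = FALSE)
  }
  if (identical(p$type, "spectral_classifier")) {
    need <- c("freq_hz", "weights", "norm_mean", "norm_sd", "bias",
              "threshold", "stim_tag")
    miss <- need[vapply(need, function(k) is.null(p[[k]]), logical(1))]
    if (length(miss)) {
      stop("classifier JSON is missing field(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    st <- structure(list(freq_hz = p$freq_hz, mean = p$norm_mean, sd = p$norm_sd),
                    class = "norm_stats")
    spectral_classifier(p$freq_hz, p$weights, st, p$bias, p$threshold, p$stim_tag)
  } else if (identical(p$type, "embedded_classifier")) {
    embedded_classifier(p$beta_band, p$stim_band, p$stim_state_threshold,
                        p$beta_threshold_off, p$beta_threshold_on,
                        delta = p$delta,
                        weak_stim_separation = isTRUE(p$weak_stim_separation))
  } else {
    stop("unknown classifier type: ", p$type, call. = FALSE)
  }
}

#' Write a closed-loop trace as CSV
#'
#' @param trace trace data.frame from [run_closed_loop()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
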