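sp <- stim_parameters()  # v_max 2 V, v_min 0

test_that("apply_ramp is slew-limited, clamped arithmetic", {
  expect_equal(apply_ramp(1.2, 1.2, 0.5, 0.4), 1.2)        # fixed point
  expect_equal(apply_ramp(0, 2, 0.5, 0.4), 0.2)            # limited step
  expect_equal(apply_ramp(1.95, 2, 0.5, 0.4), 2)           # clamps at target
  expect_equal(apply_ramp(2, 0, 0.5, 0.4), 1.8)            # downward
  # full traverse 0 -> 2 V at 0.5 V/s with 0.4 s ticks: exactly 10 ticks
  v <- 0
  n <- 0L
  while (v < 2) {
    v <- apply_ramp(v, 2, 0.5, 0.4)
    n <- n + 1L
  }
  expect_identical(n, 10L)  # ceiling(2 / 0.2)
  expect_error(apply_ramp(0, 2, -1, 0.4), "ramp_rate")
})

test_that("telemetry delay aligns to the next tick and bounds latency", {
  expect_equal(telemetry_delay(c(0.3, 1.0), 0), c(0.3, 1.0))  # identity
  expect_equal(telemetry_delay(1.0, 0.4, 0.4), 1.6)
  expect_equal(telemetry_delay(1.2, 0.4, 0.4), 1.6)  # lands exactly on grid
  set.seed(99)
  t_cmd <- runif(1000, 0, 100)
  t_app <- telemetry_delay(t_cmd, 0.4, 0.4)
  lat <- t_app - t_cmd
  expect_lte(max(lat), 0.8 + 1e-9)
  expect_gte(min(lat), 0.4 - 1e-9)
})

test_that("state machine follows the hand-computed trace (K = 3)", {
  cc <- controller_config("distributed", ramp_rate = 100)  # ramps in one tick
  calls <- c(rep(FALSE, 3), rep(TRUE, 5), rep(FALSE, 2), TRUE, rep(FALSE, 4))
  expected <- c("OFF", "OFF", "OFF",
                "RAMP_UP", "ON", "ON", "ON", "ON",
                "ON", "ON",          # rest x2 < K
                "ON",                # movement resets the counter
                "ON", "ON", "RAMP_DOWN", "OFF")
  st <- controller_state(sp)
  got <- character(0)
  for (m in calls) {
    step <- controller_step(st, m, cc, sp)
    st <- step$state
    st$current_v <- apply_ramp(st$current_v, step$target_v, cc$ramp_rate, cc$tick_s)
    got <- c(got, st$phase)
  }
  expect_identical(got, expected)
  # exactly one ramp-down episode, after the final 3 consecutive rest calls
  expect_identical(sum(got == "RAMP_DOWN"), 1L)
  expect_identical(which(got == "RAMP_DOWN"), 14L)
  expect_error(controller_step(list(phase = "LIMBO", rest_count = 0, current_v = 0),
                               TRUE, cc, sp), "unknown")
})

test_that("movement during RAMP_DOWN re-enters RAMP_UP", {
  cc <- controller_config("distributed", ramp_rate = 1)
  st <- list(phase = "RAMP_DOWN", rest_count = 0L, current_v = 1.0)
  step <- controller_step(st, TRUE, cc, sp)
  expect_identical(step$state$phase, "RAMP_UP")
  expect_equal(step$target_v, sp$v_max)
})

test_that("larger K yields fewer ramp-down episodes on noisy call streams", {
  count_rampdowns <- function(calls, K) {
    cc <- controller_config("distributed", ramp_rate = 100, off_consecutive = K)
    st <- controller_state(sp)
    n <- 0
    for (m in calls) {
      prev <- st$phase
      step <- controller_step(st, m, cc, sp)
      st <- step$state
      st$current_v <- apply_ramp(st$current_v, step$target_v, cc$ramp_rate, cc$tick_s)
      if (prev != "RAMP_DOWN" && st$phase == "RAMP_DOWN") n <- n + 1
    }
    n
  }
  set.seed(21)
  for (i in 1:5) {
    calls <- runif(300) < 0.6
    expect_lte(count_rampdowns(calls, 3), count_rampdowns(calls, 1))
  }
})

test_that("rest-only noise-free session never triggers stimulation", {
  cfg <- quiet_cfg()
  sched <- prompt_schedule(NULL, 30)
  loop <- run_closed_loop(cfg, sched, controller_config("distributed"),
                          oracle_classifier(), sp, seed = 1)
  expect_true(all(loop$trace$applied_v == sp$v_min))
  expect_true(all(loop$trace$state == "OFF"))
  te <- compute_teed(loop$recording$stim_log, sp, sched)
  expect_equal(te$teed_joules, 0)
})

test_that("oracle-classifier time to full amplitude matches the closed form", {
  cfg <- patient_config()
  cc <- controller_config("distributed")
  sched <- prompt_schedule(
    data.frame(start_s = c(10, 30, 50), end_s = c(22, 42, 62),
               label = "movement"), 70)
  loop <- run_closed_loop(cfg, sched, cc, oracle_classifier(), sp, seed = 2)
  det <- detection_metrics(loop$trace, sched, sp)
  ramp_time <- (sp$v_max - sp$v_min) / cc$ramp_rate
  for (lat in det$event_latencies_s) {
    # telemetry latency in [transport, transport + tick], onset-to-detection
    # adds up to one more tick of quantization
    expect_gte(lat - ramp_time, cc$transport_delay_s - 1e-9)
    expect_lte(lat - ramp_time, cc$transport_delay_s + 2 * cc$tick_s + 1e-9)
  }
})

test_that("every trace respects the amplitude ceiling and the ramp-rate bound", {
  cfg <- patient_config()
  sched <- make_prompt_schedule(80, 3, c(8, 12), seed = 3)
  for (mode in c("distributed", "embedded")) {
    cc <- controller_config(mode)
    loop <- run_closed_loop(cfg, sched, cc, oracle_classifier(), sp, seed = 4)
    expect_lte(max(loop$trace$applied_v), sp$v_max + 1e-12)
    expect_gte(min(loop$trace$applied_v), sp$v_min - 1e-12)
    expect_lte(max(abs(diff(loop$trace$applied_v))),
               cc$ramp_rate * cc$tick_s + 1e-9)
    expect_lte(max(abs(diff(loop$trace$commanded_v))),
               cc$ramp_rate * cc$tick_s + 1e-9)
  }
})

test_that("the closed loop is reproducible bit-for-bit", {
  cfg <- patient_config()
  sched <- make_prompt_schedule(60, 2, c(8, 12), seed = 5)
  a <- run_closed_loop(cfg, sched, controller_config("distributed"),
                       oracle_classifier(), sp, seed = 6)
  b <- run_closed_loop(cfg, sched, controller_config("distributed"),
                       oracle_classifier(), sp, seed = 6)
  expect_identical(a, b)
})

test_that("classifier/plant incompatibilities are caught before the loop", {
  cfg <- patient_config()
  sched <- prompt_schedule(NULL, 10)
  f <- 0:50  # not the Welch grid of any supported LFP rate buffer
  st <- structure(list(freq_hz = f, mean = rep(1, 51), sd = rep(1, 51)),
                  class = "norm_stats")
  clf <- spectral_classifier(f, rep(0, 51), st, 0, 0.5, "off")
  expect_error(
    run_closed_loop(cfg, sched, controller_config("distributed"),
                    list(off = clf, on = clf), sp, seed = 1),
    "incompatible")
  expect_error(
    run_closed_loop(cfg, sched, controller_config("embedded"),
                    peripheral_detector(0.1), sp, seed = 1),
    "embedded_classifier")
  bad_emb <- embedded_classifier(c(12, 28), c(300, 320), 0, 0, 0)
  expect_error(
    run_closed_loop(cfg, sched, controller_config("embedded"), bad_emb, sp,
                    seed = 1),
    "Nyquist")
})

test_that("the peripheral EMG trigger drives the loop", {
  cfg <- patient_config()
  sched <- prompt_schedule(
    data.frame(start_s = 10, end_s = 25, label = "movement"), 40)
  det <- peripheral_detector(threshold = 5 * cfg$emg_noise_mv * sqrt(2 / pi))
  loop <- run_closed_loop(cfg, sched, controller_config("peripheral"), det, sp,
                          seed = 8)
  rep <- detection_metrics(loop$trace, sched, sp, effective_fraction = 0.5)
  expect_gte(rep$sensitivity_pct, 60)
  expect_lte(rep$false_positive_pct, 40)
})
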