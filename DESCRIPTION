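Package: adbsim
Title: Closed-Loop Adaptive Deep Brain Stimulation Simulation for Essential Tremor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale test bench for adaptive deep brain stimulation (aDBS)
    in essential tremor. Provides a seeded synthetic patient that emits cortical
    local field potentials with movement-related beta-band desynchronization and
    stimulation artifact, wearable gyroscope tremor, and EMG; Welch spectral
    band-power features including an emulation of device-streamed 5 Hz band
    power; trainable movement classifiers (dual stim-on/stim-off spectral
    decoders, a two-band embedded classifier, peripheral EMG/IMU triggers); a
    ramp-rate-limited stimulation state machine with telemetry-delay modeling;
    and therapy evaluation metrics (tremor severity, total electrical energy
    delivered, detection sensitivity and latency). Sessions, classifiers and
    traces round-trip through plain CSV/JSON files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
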