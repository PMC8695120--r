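---
title: "Closed-loop adaptive DBS for essential tremor: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop adaptive DBS for essential tremor: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adbsim)
```

# The control problem

Essential tremor produces a 2–8 Hz action tremor: it appears when the patient
moves or holds a posture and is largely absent at rest. Thalamic (VIM) deep
brain stimulation suppresses it, but conventional systems stimulate
continuously. Because the symptom is movement-locked, an adaptive controller
only needs to solve a comparatively simple problem: detect movement from a
biomarker, ramp stimulation up quickly, and ramp it back down at rest.

The biomarker used throughout this package is beta-band (12–30 Hz)
event-related desynchronization (ERD) in sensorimotor-cortex field
potentials: beta power drops when the patient moves — or imagines moving —
and recovers at rest. ERD is a proxy for movement rather than a direct
tremor readout, which bounds how close to optimal any such controller can
get; the package treats that as a property of the problem, not a defect of
the implementation.

`adbsim` implements the three controller generations such a program goes
through — peripheral (EMG/IMU-triggered), distributed (PC-in-the-loop
spectral decoding), and fully embedded (two band-power thresholds the
implant can evaluate on-board) — together with a synthetic patient rich
enough to exercise all of them, and the evaluation metrics used to compare
them against continuous stimulation (cDBS).

# The synthetic patient

`simulate_session()` generates, under a prompt schedule and a stimulation
input, the full sensor suite at fixed units: LFP in µV, gyroscope in deg/s,
EMG in mV, stimulation amplitude in V.

**LFP.** Three components sum:

* 1/f background: white Gaussian noise shaped to a 1/f amplitude spectrum in
  the frequency domain, scaled to `pink_noise_scale` (default 2 µV RMS).
  Spectral shaping was chosen over autoregressive fitting because it is
  exact, seeded, and trivially reproducible.
* Beta rhythm: band-limited noise confined exactly to `beta_band` (spectral
  masking of white noise; a deterministic tone at the band centre is
  available via `beta_carrier = "tone"` for analytic tests). Its amplitude
  is `beta_baseline_amp` (default 5 µV, so band power 12.5 µV²) multiplied
  by `1 − erd_fraction · m(t)` where `m(t)` is the movement/imagined prompt
  indicator passed through a first-order lag (`transition_time_s`, default
  0.5 s), and by `1 − stim_beta_suppression · V/V_ther` — high-frequency
  stimulation visibly reshapes the cortical spectrum, including a partial
  suppression of the beta rhythm itself. This stimulation-dependence of the
  spectrum is what makes a single movement decoder fail across stimulation
  states and motivates the dual stim-off/stim-on classifier design.
* Stimulation artifact: a tone at the stimulation frequency with amplitude
  `stim_artifact_gain · V` (default 4 µV/V) plus a broadband floor lift
  `stim_floor_gain · V` of white noise. The artifact's true shape on any
  given device is idiosyncratic; a tone plus floor is the minimal model that
  makes the stimulation state decodable from the spectrum and contaminates
  broadband statistics, which is all the downstream methods rely on.
  Requesting a stimulation frequency at or above the LFP Nyquist frequency
  is an error (the artifact would alias).

**Gyroscope.** Axis one carries the tremor tone at `tremor_freq` (default
5 Hz). Its envelope relaxes with time constant `tremor_time_constant_s`
(default 0.8 s) toward `tremor_baseline_amp · (1 − efficacy(V))` during
overt movement and toward zero at rest; tremor therefore bursts at movement
onset before stimulation catches up, and decays with a lag once stimulation
becomes effective. `efficacy(V)` is a logistic dose–response
(`plogis(efficacy_slope (V − efficacy_v50))`), half-maximal at 1.2 V with
slope 3 V⁻¹ by default, giving ~92% suppression at the 2 V therapeutic
amplitude. A sub-1.5 Hz component (`movement_lowfreq_amp`, spread over all
three axes) represents ordinary movement — the reason the tremor metrics
exclude everything below 1.5 Hz. Imagined-movement prompts produce ERD but
neither gyroscope nor EMG activity.

**EMG.** Amplitude-modulated broadband noise: a resting noise floor plus
`emg_burst_gain` of burst activity during overt movement.

First-order (exponential) transitions are used for every envelope because
the source phenomenology — tremor bursts at onset, lagged suppression —
fixes the shape only qualitatively; a single time constant per mechanism is
the smallest parameterisation that reproduces it.

The generator emulates the features the decoders and metrics actually
consume: band powers, their movement- and stimulation-dependence, artifact
contamination, and tremor energetics. It does not emulate electrode
placement effects, non-stationary drift of biomarkers across sessions,
accelerometer/compass physics (noise placeholders only), or any biophysics
of the tremor network. Tests passing against this plant therefore show that
the algorithms are correct and well-calibrated, not that they would achieve
the same numbers in a clinic.

# Spectral estimation

`welch_psd()` uses Hann-tapered segments of 1.0 s with 50% overlap by
default: with the supported sampling rates (200/422/800 Hz) this yields
~1 Hz bins, enough to resolve the beta band, and the segment length divides
the 2 s analysis buffer used by the distributed decoder. The one-sided
density is normalized so that bin width × density sums to the signal
variance (Parseval); the test suite holds this to 5% on stationary
mixtures against an independent rectangular-window periodogram oracle.

Bands are half-open `[lo, hi)` with membership by bin centre, making band
partitions exactly additive. `gyro_magnitude_spectrum()` combines per-axis
PSDs by the per-bin Euclidean norm, giving an orientation-insensitive
magnitude. `peak_tremor_frequency()` takes the largest strict local maximum
in 1.5–8.0 Hz; a candidate must exceed five times the median in-band power
and 0.2% of the spectrum-wide maximum — both scale-invariant, so the
result is invariant to overall gain — otherwise the result is "no tremor
peak" (for example when only sub-1.5 Hz ordinary-movement power is present).
Ties break toward the lower frequency. The patient's tremor band is the
peak ±1 Hz, clipped to [1.5, 8.0].

`streaming_band_power()` emulates the implant's analog 5 Hz band-power
telemetry digitally: causal 4th-order Butterworth band-pass, squaring,
first-order exponential smoothing (default 0.5 s), decimation to 5 Hz. The
device's true analog transfer function and scaling are not public; only
relative comparisons are meaningful, which is all the embedded classifier
uses. For a stationary in-band tone of amplitude A the steady state is
A²/2, anchoring the scale to the Welch band power so thresholds trained on
one estimator transfer to the other.

# Movement decoders

**Distributed spectral classifier.** Welch spectra of trailing 2 s buffers
are z-scored per bin by the training mean and standard deviation; the
weight vector is the difference of z-scored class means (an
identity-covariance linear discriminant — closed-form, seedless, and
directly testable), the bias puts the decision boundary at the class-mean
midpoint, and the logistic of the weighted sum is compared against a
threshold θ. Weights outside 4–45 Hz are zeroed: bins near the stimulation
frequency are artifact-dominated (their z-scores under off-state statistics
explode once stimulation turns on), and the lowest bins carry drift.
Because stimulation suppresses and reshapes the beta band, two classifiers
are trained — one on stim-off, one on stim-on calibration data — and the
controller switches between them with the machine state. The default
θ = 0.45 in `train_classifier_pair()` biases toward calling movement:
missed stimulation harms the patient more than unnecessary stimulation.

**Embedded classifier.** The implant cannot be told its own stimulation
state, so the decoder infers it from the log power in a band around the
stimulation frequency and then compares log beta power (default band
12–28 Hz, the embedded convention) against a per-state threshold;
desynchronized (low) beta means movement. Thresholds are class-mean
midpoints from four 30 s calibration segments (stim off/on × rest/move),
with each beta threshold raised by the sensitivity bias δ (default 0.25
log-units — the bias is a clinical choice, not a measured constant, so it
is config-exposed). The two cascaded scalar thresholds are the minimal
structure consistent with a four-state-trained band-power classifier; a
single linear function of both bands would be the natural alternative and
is intentionally not implemented, since nothing in the feature model
distinguishes them here.

**Peripheral trigger.** Rectified moving-average envelope (default 0.25 s)
with threshold and hold-time hysteresis, applicable to EMG or low-frequency
gyro magnitude.

# The stimulation controller

A four-phase machine: `OFF → RAMP_UP → ON → RAMP_DOWN`. A single movement
call triggers ramp-up; K consecutive rest calls (default K = 3) are
required before ramp-down — asymmetric hysteresis again favouring
sensitivity. Ramping continues through contrary calls until the amplitude
limit is reached; a movement call during ramp-down re-enters ramp-up
(interrupt semantics are not dictated by the source phenomenology, so the
re-trigger rule — the sensitivity-preserving choice — was adopted). The
active spectral decoder follows the phase: off-classifier in
`OFF`/`RAMP_DOWN`, on-classifier in `RAMP_UP`/`ON`.

Amplitude moves by at most `ramp_rate · tick` per tick (`apply_ramp()`,
which snaps to the target within float tolerance so a full traverse takes
exactly `⌈ΔV/(rate·tick)⌉` ticks). The amplitude floor `v_min` defaults to
0 but is configurable to support high/low "graded" switching between a
sub-perceptual and the clinically effective level.

Timing: distributed commands are quantized to the 400 ms telemetry packet
cadence and delayed by one packet of transport, so the biomarker-to-command
latency is bounded by 0.8 s; the embedded mode ticks at the 5 Hz band-power
rate with no transport delay. In the closed loop the embedded features are
computed from a trailing 1 s Welch window at each 0.2 s tick — the same
band-power quantity the streaming estimator produces, so thresholds
transfer — rather than re-running the stateful streaming chain inside the
loop.

With the default patient (V_max 2 V, ramp 2 V/s) the expected
onset-to-full-amplitude delay decomposes as detection (≈0.6–1 s of ERD
entering the 2 s buffer) + telemetry (0.4–0.8 s) + ramp (1.0 s) ≈ 2.2–2.6 s
in distributed mode, and roughly a second less in embedded mode — the
quantitative form of the argument that moving decoding on-board is worth a
simpler classifier.

# Evaluation metrics

**Tremor severity** per sliding window (default 4 s, 2 s hop) is
`(tremor-band power)² / total power` from the gyroscope magnitude spectrum.
Squaring the numerator emphasises concentrated tremor-band energy over
broadband movement; dividing by total power discounts windows dominated by
ordinary movement. The printed form of this metric is ambiguous about the
exponent, so `severity_exponent` is a config switch (default 2, used by all
internal tests; 1 gives the plain band-power fraction). Windows with total
power below a floor report zero. Absolute severity values depend on window
length and units; only within-configuration comparisons (aDBS vs stim-off
vs cDBS under identical analysis settings) are meaningful, and that is how
the package reports them.

**TEED.** Instantaneous stimulation power `V²·f·p/z` (watts) integrated
over constant-amplitude segments of the stimulation log gives joules; the
reported ratio divides by the energy of continuous stimulation at `v_max`
over the same interval, which is the unit-invariant quantity of interest.
Per-second energies during movement and rest are reported separately:
low movement TEED with suppressed tremor means efficient stimulation, rest
TEED measures over-stimulation.

**Detection metrics.** Tick-level sensitivity (movement ticks with
effective stimulation) and false-positive rate (rest ticks), with
"effective" defaulting to 100% of `v_max` (delay-to-maximum-level
reporting; `effective_fraction` exposes the clinically-effective-level
variant), plus one onset-to-effective latency per movement prompt.

# Numerical and design choices

* All randomness flows from one session seed through named sub-streams
  (plant, schedule, calibration), so every pipeline is bit-for-bit
  reproducible and modules can be re-seeded independently.
* Welch bin grids are compared exactly (1e-9) and mismatches are errors, not
  warnings — a grid mismatch between training and inference silently
  corrupts every downstream decision.
* Zero-variance training bins make z-scoring undefined and raise an error
  naming the bin; degenerate (noise-free) training data is a user error.
* Schedule feasibility is checked against the worst-case draw
  (`n · max-duration` plus minimum rests), so infeasibility does not depend
  on the seed.
* Default study conditions for closed-loop evaluation: 300 s sessions with
  10 movement prompts of 12–24 s. Prompt lengths of this order keep the
  ~2.5 s actuation delay a minority of each movement epoch, which is the
  regime adaptive stimulation is designed for; the calibration sessions use
  180 s with eight 8–14 s prompts, and embedded calibration uses the
  four-state 30 s-per-state block protocol. Test and acceptance runs use
  these sizes (a few minutes of compute on one core).

# Known limitations

* The plant's tremor responds to stimulation instantaneously through a
  static dose–response with a single lag; real patients show wash-in/out
  dynamics over many seconds to minutes and day-to-day biomarker drift.
* Severity numbers are not comparable to any clinical scale; FTM-style
  ratings are out of scope.
* The embedded decision structure is a cascade of two scalar thresholds;
  devices with richer state tables could express policies this package does
  not model.
* Bollinger-band "graded" amplitude control and frequency/pulse-width
  adaptation are out of scope; the amplitude floor hook (`v_min`) exists,
  but no graded policy is implemented or evaluated.
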