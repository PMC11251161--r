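---
title: "dbsense: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dbsense: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbsense)
```

dbsense works with the sensing data produced by deep-brain-stimulation
neurostimulators that record local field potentials (LFPs) from their own
electrodes. Such devices produce two families of data: **in-clinic**
recordings — Survey and Setup traces used for calibration, and Streaming
traces at a fixed time-domain rate (250 Hz here) paired with a low-rate
band-power and stimulation-amplitude stream — and **chronic** recordings —
a per-hemisphere band-power *Timeline* at 10-minute cadence spanning up to
60 days, and patient-marked *Events*, optionally carrying an on-device FFT
snapshot. This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic tests do and do not establish.

## The data model and the tolerant parser

`parse_session()` maps a session JSON file (dialect in the package's
`SCHEMA.md`) onto typed collections. The vendor's real schema is
undocumented and version-drifting, so the parser is deliberately tolerant:
unknown top-level keys are warnings, absent sections become empty
collections, and only sampling information plus values are required per
record. Hemisphere labels are normalized to `left`/`right`. All timestamps
are held in UTC; the session's local offset is kept separately because the
circadian analyses are wall-clock phenomena (a rhythm that peaks at 15:00
local time should bin at hour 15 regardless of the recording time zone).
Sample indices in the dialect are 0-based with half-open intervals;
R-facing functions use 1-based indices, and the ground-truth loader
converts (`peak_samples_r`).

## The synthetic-data generator as a stated world

Because no clinical recordings ship with the package, every analysis is
validated against `generate_session()`, whose defaults are a plausible
chronic Parkinsonian beta-sensing scenario rather than knobs to be tuned:

* **Timeline**: `power(t) = mean + amplitude * sin(2*pi*(hour - acrophase)/24)
  + N(0, sd)` with mean 8 a.u., amplitude 2, acrophase 15:00, noise SD 0.3,
  at 10-minute cadence. Values are clipped at 0 (band power is
  non-negative); with the default parameters clipping is a > 5-sigma event,
  so it never distorts recovery tests.
* **Events**: thrice-daily "Medication" intakes (jitter SD 5 min) that add
  a -2 a.u. offset from 10 min after intake, decaying exponentially with a
  60-minute time constant; "I feel stuck" episodes precede intakes with
  larger jitter and no power effect. Medication events carry FFT snapshots
  (1/f background plus a 15 Hz bump of log-normal amplitude).
* **Streaming**: a 20 Hz, 5 µV oscillation on 1/f noise (SD 2 µV). The
  titration scenario steps stimulation every 30 s and multiplies the
  oscillation amplitude by 0.5 per step — the textbook beta-suppression
  pattern, which downstream must recover as ~4x per-level power ratios.
* **ECG artifact**: a Mexican-hat (biphasic, QRS-like) pulse, 100 ms wide,
  50 µV peak, at 75 bpm with 2% R-R jitter, added to the left channel only.
  It is analytically compact, so residuals after cleaning are measurable
  against the stored artifact-free trace.
* **Wearable**: 50 Hz three-axis accelerometer CSV, gravity on one axis,
  0.02 a.u. noise floor, and white movement noise (SD 1.0) injected exactly
  inside configured `[start, end)` epochs.

Two deliberate serialization choices make the round-trip tests exact:
every float array is quantized to 1e-6 before writing (a 15-significant-
digit JSON emitter then reproduces each double bit-exactly), and a single
seeded RNG drives all draws, so a config maps to byte-identical files.

What a green test establishes is therefore *algorithmic correctness
against a known model*, not clinical realism: real chronic data has
non-sinusoidal rhythms, missing telemetry far messier than the uniform
dropout option, ECG morphologies that vary beat to beat, and movement
artifacts that are not white. The analyses make none of those assumptions
beyond what is stated here, but their *accuracy targets* (e.g. 15% on the
event-triggered drop) were only demonstrated in this stated world.

## Filtering

The paper-style "highlight a band of interest" filter is an even-order
Butterworth (default order 4 per band) applied forward-backward, so the
phase response is identically zero — a hard requirement for event-locked
analyses. Multi-band highlight specs are merged to their interval union
and applied as a parallel bank (outputs summed); at an internal crossover
such as 12/13 Hz the summed gain stays within the 5% passband ripple
budget. Band-stop filters cascade instead.

**Edge handling.** Zero-phase filtering of a finite recording is done, as
in the standard scipy/MATLAB implementations, by odd-reflection padding.
The padding length is derived from the slowest filter pole (enough samples
for a 1e-9 transient decay), which matters for low corners: a 0.5 Hz
high-pass settles over seconds, and the naive "3x filter order" padding
leaves large start-up transients. Even with correct padding, the
*reflection junction* itself injects a small broadband transient whose
in-band part survives both passes; this is inherent to pad-based filtfilt
(scipy's default shows the identical effect). The filter object therefore
reports `settle_samples`/`settle_s`, and steady-state claims (e.g.
stop-band rejection) should be evaluated outside that region. Linearity
and the zero-lag property hold everywhere.

## ECG detection and cleaning

Detection runs on a 0.5-30 Hz band-passed copy: amplitude-threshold peak
picking (4 robust SDs, scaled MAD) on the dominant polarity with a 0.3 s
refractory spacing. The periodicity score is the fraction of successive
inter-peak intervals within ±20% of their median; a trace is
cleaning-eligible iff the score is at least 0.8 and the implied rate lies
in 40-120 bpm. White noise fails the score gate by construction; a clean
oscillation fails the threshold/rate gates. Cleaning averages peak-centered
windows (half-width 0.3x the median inter-peak interval, capped at 200 ms)
into a zero-mean template, then subtracts it at each peak with a per-peak
least-squares amplitude. Samples farther than one half-width from every
detected peak are untouched, and an ineligible trace is returned
bit-identical. All constants are stand-ins exposed in
`dbsense_defaults()$ecg`, not published values.

## Spectral estimators

`welch_psd()` is a Hann-windowed averaged periodogram (2 s windows, 50%
overlap by default) with density scaling, so integrating over `[0, fs/2]`
recovers the variance (the Parseval check used in tests).
`band_power_series()` integrates a per-window Hann periodogram over the
band, with timestamps at window centers. `morlet_scalogram()` uses a
constant-Q complex Morlet (7 cycles by default) on an exactly log-spaced
grid (60 frequencies over 1-100 Hz), normalized so a unit sine reads a
magnitude of ~1; the cone of influence, `cycles/(2f)` seconds per
frequency, is reported and edge values are retained but flagged. The paper
family of tools names no wavelet or PSD parameters, so all of these are
configurable defaults, not claims.

## Chronic analytics

* **Circadian profile**: samples folded by local wall clock into 30-minute
  bins (the bin width must divide 24 h so bins tile `[0, 24)` exactly);
  per-bin mean and IQR (robust to single outlier days). The profile is
  invariant to permuting days by construction.
* **Event histograms**: half-open hour-of-day bins; an event at exactly
  midnight belongs to `[0, 1)`.
* **Relative offsets**: each target event is paired with the *nearest*
  reference within the window, exact ties broken toward the preceding
  (negative) reference; `nearest = FALSE` switches to preceding-only. The
  implementation is checked against an all-pairs brute-force oracle.
* **Event-triggered average**: the Timeline is read onto a uniform lag
  grid (one step per cadence) by nearest-sample lookup, never interpolating
  across gaps longer than one cadence — chronic data has telemetry gaps and
  bridging them would manufacture data. Events whose window leaves the
  Timeline range are excluded with reason `edge`; an all-excluded call is
  an error, never a silent empty result. Uncertainty is a seeded
  1000-resample bootstrap percentile CI across events; the RNG state is
  restored afterwards.
* **Snapshot summaries**: pointwise median and quartiles across event FFT
  snapshots; snapshots must share one frequency grid (devices disagree
  rarely, and silent resampling would hide that), so mixed grids are an
  error with resampling left as an explicit upstream step.

The ETA accuracy test deserves a note: its oracle is the closed-form
expectation of the generator model (circadian term plus exponentially
decaying event offsets, averaged over the same lag grid and baseline
window as the estimator). Against a jitter-free 14-day schedule the
estimator lands within 15% of that expectation; with realistic intake
jitter the nearest-sample lookup smears the onset lag and the gap widens —
a genuine property of 10-minute-cadence data, not an estimator bug.

## Cross-signal analysis

Wearable CSVs are aligned to the streaming recording purely by absolute
timestamps (no resampling; a manual `offset_override` exists because
device clocks drift). Motion power is the per-window variance of the
acceleration magnitude taken *after* a per-axis 0.5 Hz high-pass: removing
the constants per axis first makes the measure exactly invariant to sensor
orientation and to the gravity vector, which the more literal
"high-pass of the magnitude" is not. Stimulation-locked summaries
partition the span by constant stimulation level, drop a 2 s window after
each transition (covering the low-frequency step transient), and summarize
`band_power_series()` per level. Cross-correlation maps the finer series
onto the coarser grid by nearest neighbor — interpolating upward would
invent high-frequency content — and reports the peak-|r| lag, positive
when band power lags motion.

## Command-line interface

`inst/cli/dbsense` is a thin Rscript over the exported functions:
`info`, `calibration`, `chronic`, `spectrum`, `scalogram`, `filter`,
`clean-ecg`, `screen`, `xsig`, `export`, `synth`. Outputs are CSV/JSON
first, plots opt-in. Exit codes: 0 success, 1 user/validation error, 2
internal error. All numeric thresholds live in one schema
(`dbsense_defaults()`), dump/load via YAML or JSON (`--config`), and input
files are never modified.

## FieldTrip export

`export_fieldtrip()` writes one MAT (level 5) container per sensing mode
with exactly the raw-data keys `label`, `fsample`, `trial`, `time`
(per-trial axes starting at 0 s). The writer/reader pair is implemented in
the package (no MAT library is available in the target environment) for
the value types a raw container needs — double matrices, cell arrays, char
arrays — and was cross-validated against `scipy.io.loadmat`; round trips
are bit-exact. Timeline exports use one single-row trial per hemisphere;
event exports place the snapshot frequency grid on the `time` axis, with
`fsample` the reciprocal frequency step — a documented convention, since
FieldTrip has no native chronic-trend container.

## Known limitations

* No vendor files were available: the parser is validated only against the
  documented dialect plus its tolerance properties, not against real
  Percept exports.
* ECG cleaning assumes a repeating artifact shape; it will under-correct
  morphologies that drift within a recording, and the constants are not
  the (unpublished) values of the clinical toolchains it emulates.
* Edge regions of zero-phase filtering carry junction transients (see
  above); analyses on short recordings should trim `settle_s`.
* Classification of artifact *sources* and cross-patient statistics are
  out of scope.
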