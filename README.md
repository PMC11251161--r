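# dbsense

Parsing and analysis of sensing data from deep-brain-stimulation (DBS)
neurostimulators with local field potential (LFP) sensing, in the style of
Percept-PC session exports — for researchers and engineers who need the
computations behind a sensing-review GUI as a scriptable R library and
command line.

Implanted sensing devices produce two data families. **In-clinic**: Survey
and Setup calibration traces and Streaming time-domain recordings (250 Hz)
paired with a low-rate band-power + stimulation-amplitude stream.
**Chronic**: a per-hemisphere band-power *Timeline* (10-minute cadence, up
to 60 days) and patient-marked *Events* with optional on-device FFT
snapshots. dbsense parses session JSON files into a typed model, organizes
multi-file batches per patient, and provides the four analysis streams:

* **Calibration** — impedance tables, survey/setup Welch spectra.
* **Chronic** — circadian profile of the Timeline (wall-clock folding,
  per-bin mean ± IQR), daily event histograms, offsets of symptom events
  relative to medication intakes (nearest-reference pairing), bootstrap
  event-triggered averages of band power, and median/quartile summaries of
  event FFT snapshots. The circadian model is the first harmonic
  `P(h) = m + A sin(2π(h − φ)/24)`; an ETA around intakes recovers
  post-event power drops with exponential wear-in.
* **Streaming** — zero-phase Butterworth band filters ("highlight
  13–35 Hz"), ECG-artifact cleaning by template subtraction with per-peak
  least-squares scaling, stimulation-transition and broadband artifact
  screening, Welch PSDs, and Morlet scalograms (constant-Q, 7 cycles,
  log-spaced 1–100 Hz axis).
* **Cross-signal** — wearable accelerometer CSV ingestion, timestamp
  alignment, motion power, per-stimulation-level band power (titration),
  and band-power-vs-motion cross-correlation.

A seeded synthetic-session generator (`synth_config()` /
`generate_session()`) emulates the whole format with a ground-truth sidecar
— injected ECG peak positions, the artifact-free trace, circadian
parameters, event schedules, stimulation change times — so every analysis
is testable without clinical data. `export_fieldtrip()` writes
FieldTrip-compatible MAT containers (`label`, `fsample`, `trial`, `time`)
for interoperability; the session dialect is documented in
[`inst/SCHEMA.md`](inst/SCHEMA.md).

## Worked example

```r
library(dbsense)

cfg <- synth_config(seed = 42, n_days = 14)        # 14-day chronic scenario
res <- generate_session(cfg, "session.json")
s <- parse_session("session.json")
print(s)
#> <dbs_session> session.json
#>   patient PT01 | Percept-like synthetic neurostimulator | session 2024-03-04 09:00:00 (UTC+00:00)
#>   available sensing modes: survey, setup, streaming, timeline, events
#>   6 impedance(s), 1 survey(s), 1 setup(s), 1 streaming(s), 84 event(s)
#>   timeline left: 2016 points
#>   timeline right: 2016 points

prof <- circadian_profile(s$timeline$left, 30, s$utc_offset_min)
#> peak bin 21.5 h (mean 9.94 a.u.), trough bin 8.5 h (mean 4.70 a.u.)

eta <- event_triggered_average(s$timeline$left, s$events, "Medication",
                               window_min = 120)
print(eta)
#> <dbs_eta> 'Medication': 42 event(s) used, 0 excluded; lags -120..120 min (baseline-subtracted)
mean(eta$mean_power[eta$lags_min > 0 & eta$lags_min <= 60])
#> [1] -0.87

cleaned <- clean_ecg(s$streamings[[1]]$td, "L_1-3")
print(cleaned$report)
#> <dbs_cleaning_report> 149 peak(s), rate 74.6 bpm, periodicity 1.00, eligible: TRUE, cleaned: TRUE
```

Reading the numbers: the Timeline folds to a diurnal profile spanning
4.7–9.9 a.u.; the trough sits in the morning and the apparent peak shifts
into the evening because thrice-daily medication intakes carve transient
notches into the underlying rhythm (injected acrophase 15:00). The
event-triggered average shows band power dropping by ~0.9 a.u. (baseline-
subtracted, decay-weighted over the first hour) after intakes — the
wear-in effect the generator injects. The streaming trace's cardiac
artifact is detected at 74.6 bpm with perfect inter-beat periodicity and
removed by template subtraction.

The same workflows are scriptable from a shell via the thin CLI wrapper:

```sh
Rscript inst/cli/dbsense synth --seed 42 --out fixtures/
Rscript inst/cli/dbsense info fixtures/session.json
Rscript inst/cli/dbsense chronic fixtures/session.json --event Medication --window 120 --out out/
Rscript inst/cli/dbsense xsig fixtures/session.json --wearable fixtures/wearable.csv --band 13:35 --out out/
Rscript inst/cli/dbsense export fixtures/session.json --mode streaming --out out/ft
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main workflows from scratch on
seeded synthetic fixtures — generation, parsing, chronic analytics
(circadian profile, histograms, ETA, snapshot summaries), ECG cleaning,
filtering, spectra/scalograms, artifact screening, wearable alignment,
stimulation-locked band power, cross-correlation, and FieldTrip export —
and writes its results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
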