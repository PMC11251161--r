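# dbsense session JSON dialect (`dbsense-session/1`)

The vendor schema of Percept-style session exports is undocumented and
drifts across firmware versions, so dbsense defines its own documented
dialect for synthetic fixtures and testing. The parser (`parse_session()`)
is a tolerant reader: every section is optional (absent sections become
empty collections), unknown top-level keys are warnings, and only the
minimal fields listed as **required** below are enforced.

All timestamps are ISO-8601 with an explicit UTC offset
(`YYYY-MM-DDTHH:MM:SS[.fff]+HH:MM`); instants are stored in UTC, while
`session.utc_offset_minutes` preserves the local wall clock for circadian
analyses. All floating-point arrays are quantized to 1e-6 (device-style
quantization), which makes JSON round-trips bit-exact. Sample indices are
0-based; intervals are half-open `[start, end)`.

## Top-level object

| key | content |
|---|---|
| `schema` | dialect tag, `"dbsense-session/1"` |
| `device` | `{model, implant_date, lead_locations: {left, right}}` |
| `patient` | `{id}` |
| `session` | `{time, utc_offset_minutes}` |
| `impedances` | array of `{hemisphere, electrode_pair, impedance_ohm}` |
| `surveys`, `setups` | arrays of time-domain recordings (below) |
| `streamings` | array of `{time_domain, power_stream}` |
| `timeline` | `{left: trend, right: trend}` (either may be absent) |
| `events` | array of event records |

## Time-domain recording

```json
{"mode": "survey", "channels": ["L_0-1", "..."], "fs_hz": 250,
 "start_time": "2024-03-04T09:05:00+00:00",
 "samples_uv": [[...channel 1...], [...channel 2...]]}
```
Required: `channels`, `fs_hz` (> 0), `samples_uv` (channels x samples, µV).
Channel labels are `<hemisphere>_<contact pair>` and must be unique.

## Power stream (paired with each streaming recording)

Per hemisphere: `{timestamps: [...], band_power: [...],
stim_amplitude_ma: [...], band_edges_hz: [lo, hi]}`.
Timestamps non-decreasing; `stim_amplitude_ma` >= 0.

## Timeline trend (chronic band power)

Per hemisphere: `{timestamps, band_power, stim_amplitude_ma,
band_edges_hz}`, nominally one sample per 10 minutes for up to 60 days;
the parser accepts any cadence and tolerates gaps. Timestamps strictly
increasing, `band_power` >= 0.

## Event record

```json
{"name": "Medication", "time": "2024-03-04T08:02:11+00:00",
 "snapshot": {"left": {"freqs_hz": [...], "power": [...]},
              "right": {...}}}
```
`snapshot` is optional; when present, `freqs_hz` is strictly increasing and
the two arrays have equal length.

## Hemisphere labels

Accepted synonyms (any case): `left/l/lt/left_hemisphere`,
`right/r/rt/right_hemisphere`; normalized to `left`/`right`.

## Ground-truth sidecar (`<stem>.truth.json`)

Written by `generate_session()` next to each synthetic session: injected
ECG peak sample indices (0-based) and channel, the quantized artifact trace
and the artifact-free signal, circadian model parameters, scheduled event
times, stimulation change times (s), the noise-free deterministic Timeline,
movement epochs and the wearable start offset.

## Wearable CSV

Header `timestamp,ax,ay,az`; ISO-8601 timestamps, three acceleration axes
(a.u. or m/s²). Extra columns are ignored by `load_wearable()`.
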