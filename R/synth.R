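# Synthetic Percept-like session generator.
#
# Emulates the sensing-mode taxonomy of an LFP-sensing DBS neurostimulator:
# in-clinic Survey/Setup/Streaming time-domain recordings (250 Hz), a
# low-rate band-power + stimulation-amplitude stream paired with each
# Streaming recording, a chronic Timeline (per-hemisphere band power at
# 10-minute cadence, up to the 60-day device buffer), timestamped patient
# Events with optional FFT snapshots, and an impedance table. Every
# stochastic draw goes through one seeded RNG so a config maps to
# byte-identical files; a ground-truth sidecar records what was injected.

TIMELINE_CADENCE_S <- 600   # 10-minute chronic cadence
EVENT_DECAY_MIN <- 60       # exponential decay constant of post-event offsets

# one-level spec merge: named sub-lists are merged recursively, everything
# else (including unnamed lists such as movement_epochs or oscillations) is
# replaced wholesale. utils::modifyList silently skips unnamed elements,
# which would make those overrides no-ops.
merge_spec <- function(def, user) {
  for (nm in names(user)) {
    both_named_lists <- is.list(def[[nm]]) && is.list(user[[nm]]) &&
      length(user[[nm]]) > 0 && !is.null(names(user[[nm]])) &&
      all(nzchar(names(user[[nm]])))
    def[[nm]] <- if (both_named_lists) merge_spec(def[[nm]], user[[nm]])
                 else user[[nm]]
  }
  def
}

#' Build and validate a synthetic-session configuration
#'
#' Returns the full configuration for [generate_session()] /
#' [generate_wearable_csv()], with defaults chosen to resemble a chronic
#' Parkinsonian beta-band sensing scenario: a diurnal band-power rhythm
#' peaking mid-afternoon, thrice-daily medication intakes that transiently
#' suppress power, a 20 Hz oscillation riding on 1/f noise in the streaming
#' trace, and a QRS-like cardiac artifact on the left channel.
#'
#' @param seed integer RNG seed for all stochastic draws.
#' @param n_days Timeline span in days (1-60; the device buffer caps at 60).
#' @param fs_td time-domain sampling rate, Hz.
#' @param fs_power band-power stream rate, Hz.
#' @param utc_offset_min session local-time offset, minutes east of UTC.
#' @param start_time session timestamp (ISO-8601 text or POSIXct); the
#'   Timeline starts at the preceding local midnight.
#' @param patient_id opaque patient identifier.
#' @param circadian list: `mean`, `amplitude`, `acrophase_hour`, `noise_sd`
#'   of the diurnal band-power model
#'   `mean + amplitude * sin(2*pi*(hour - acrophase)/24) + noise`.
#' @param events list of event specs, each a list with `name`,
#'   `daily_times` (hours), `jitter_min` (SD of normal jitter, minutes),
#'   `post_effect` (additive band-power offset, a.u.), `effect_delay_min`
#'   (onset delay), and `snapshot` (attach an FFT snapshot?). The offset
#'   decays exponentially with a 60-minute time constant.
#' @param streaming list: `duration_s`, `oscillations` (list of
#'   `freq_hz`/`amplitude_uV`), `noise` (`kind` "white" or "one_over_f",
#'   `sd_uV`).
#' @param ecg list: `enabled`, `rate_bpm`, `template_amp_uV`,
#'   `template_width_ms` of the biphasic Mexican-hat-like cardiac artifact
#'   injected on the left streaming channel.
#' @param stim_ramp list: `enabled`, `start_mA`, `step_mA`, `step_every_s`,
#'   `osc_scale_per_step` (each step multiplies the oscillation amplitude,
#'   emulating stimulation-induced beta suppression during titration).
#' @param wearable list: `fs_hz`, `movement_epochs` (list of
#'   `[start_s, end_s)` pairs), `start_offset_s` relative to the streaming
#'   recording start, `duration_s` (defaults to the streaming duration),
#'   `noise_sd`, `movement_sd` (accelerometer noise floor and movement
#'   amplitude, a.u.).
#' @param survey,setup lists with `duration_s` for the calibration modes.
#' @param timeline_dropout list: `enabled`, `fraction` of 10-minute bins
#'   randomly dropped (simple telemetry-gap emulation).
#' @param band_edges_hz sensing band of the power streams (Hz).
#' @return validated config list of class `dbs_synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_days = 3L,
                         fs_td = 250,
                         fs_power = 2,
                         utc_offset_min = 0L,
                         start_time = "2024-03-04T09:00:00+00:00",
                         patient_id = "PT01",
                         circadian = list(),
                         events = NULL,
                         streaming = list(),
                         ecg = list(),
                         stim_ramp = list(),
                         wearable = list(),
                         survey = list(),
                         setup = list(),
                         timeline_dropout = list(),
                         band_edges_hz = c(13, 35)) {
  circadian <- merge_spec(
    list(mean = 8, amplitude = 2, acrophase_hour = 15, noise_sd = 0.3),
    circadian)
  if (is.null(events)) {
    events <- list(
      list(name = "Medication", daily_times = c(8, 12, 18), jitter_min = 5,
           post_effect = -2, effect_delay_min = 10, snapshot = TRUE),
      list(name = "I feel stuck", daily_times = c(7.5, 11.5, 17.5),
           jitter_min = 20, post_effect = 0, effect_delay_min = 0,
           snapshot = FALSE))
  }
  events <- lapply(events, function(e) {
    merge_spec(list(name = "Event", daily_times = numeric(0),
                           jitter_min = 0, post_effect = 0,
                           effect_delay_min = 0, snapshot = FALSE), e)
  })
  streaming <- merge_spec(
    list(duration_s = 120, n_recordings = 1L,
         oscillations = list(list(freq_hz = 20, amplitude_uV = 5)),
         noise = list(kind = "one_over_f", sd_uV = 2)),
    streaming)
  ecg <- merge_spec(
    list(enabled = TRUE, rate_bpm = 75, template_amp_uV = 50,
         template_width_ms = 100), ecg)
  stim_ramp <- merge_spec(
    list(enabled = FALSE, start_mA = 0, step_mA = 0.5, step_every_s = 30,
         osc_scale_per_step = 0.5), stim_ramp)
  wearable <- merge_spec(
    list(fs_hz = 50, movement_epochs = list(c(30, 60)), start_offset_s = 0,
         duration_s = NULL, noise_sd = 0.02, movement_sd = 1.0), wearable)
  survey <- merge_spec(list(duration_s = 20), survey)
  setup <- merge_spec(list(duration_s = 10), setup)
  timeline_dropout <- merge_spec(
    list(enabled = FALSE, fraction = 0), timeline_dropout)

  cfg <- list(seed = as.integer(seed), n_days = as.integer(n_days),
              fs_td = fs_td, fs_power = fs_power,
              utc_offset_min = as.integer(utc_offset_min),
              start_time = start_time, patient_id = patient_id,
              circadian = circadian, events = events, streaming = streaming,
              ecg = ecg, stim_ramp = stim_ramp, wearable = wearable,
              survey = survey, setup = setup,
              timeline_dropout = timeline_dropout,
              band_edges_hz = band_edges_hz)
  class(cfg) <- "dbs_synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  bad <- function(field, why) {
    dbs_stop(sprintf("invalid synthetic config: field '%s' %s", field, why),
             "dbsense_config_error", field = field)
  }
  if (is.na(cfg$n_days) || cfg$n_days < 1 || cfg$n_days > 60)
    bad("n_days", "must be in [1, 60] (device Timeline buffer spans up to 60 days)")
  if (!is.finite(cfg$fs_td) || cfg$fs_td <= 0) bad("fs_td", "must be > 0")
  if (!is.finite(cfg$fs_power) || cfg$fs_power <= 0) bad("fs_power", "must be > 0")
  if (cfg$circadian$mean < 0) bad("circadian.mean", "must be >= 0")
  if (cfg$circadian$amplitude < 0) bad("circadian.amplitude", "must be >= 0")
  if (cfg$circadian$noise_sd < 0) bad("circadian.noise_sd", "must be >= 0")
  for (osc in cfg$streaming$oscillations) {
    if (osc$amplitude_uV < 0) bad("streaming.oscillations.amplitude_uV", "must be >= 0")
    if (osc$freq_hz <= 0 || osc$freq_hz >= cfg$fs_td / 2)
      bad("streaming.oscillations.freq_hz", "must be in (0, fs_td/2)")
  }
  if (cfg$streaming$noise$sd_uV < 0) bad("streaming.noise.sd_uV", "must be >= 0")
  if (!cfg$streaming$noise$kind %in% c("white", "one_over_f"))
    bad("streaming.noise.kind", "must be 'white' or 'one_over_f'")
  if (cfg$streaming$duration_s <= 0) bad("streaming.duration_s", "must be > 0")
  if (cfg$streaming$n_recordings < 1) bad("streaming.n_recordings", "must be >= 1")
  if (isTRUE(cfg$ecg$enabled)) {
    if (cfg$ecg$rate_bpm <= 0) bad("ecg.rate_bpm", "must be > 0")
    if (cfg$ecg$template_amp_uV < 0) bad("ecg.template_amp_uV", "must be >= 0")
    if (cfg$ecg$template_width_ms <= 0) bad("ecg.template_width_ms", "must be > 0")
  }
  if (cfg$wearable$fs_hz <= 0) bad("wearable.fs_hz", "must be > 0")
  for (ep in cfg$wearable$movement_epochs) {
    if (length(ep) != 2 || ep[1] < 0 || ep[2] <= ep[1])
      bad("wearable.movement_epochs", "entries must be [start_s, end_s) with start < end")
  }
  if (cfg$timeline_dropout$fraction < 0 || cfg$timeline_dropout$fraction >= 1)
    bad("timeline_dropout.fraction", "must be in [0, 1)")
  if (length(cfg$band_edges_hz) != 2 || cfg$band_edges_hz[1] <= 0 ||
      cfg$band_edges_hz[2] <= cfg$band_edges_hz[1])
    bad("band_edges_hz", "must be increasing positive [low, high]")
  invisible(cfg)
}

# -- signal building blocks ---------------------------------------------------

# Gaussian 1/f ("pink"-like) noise via spectral shaping; sd set exactly.
noise_series <- function(n, sd, kind = "one_over_f") {
  if (sd == 0 || n == 0) return(numeric(n))
  if (kind == "white") return(stats::rnorm(n, 0, sd))
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))            # avoid DC blow-up
  f <- pmin(f, n - f + 1)              # symmetric fold
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  x * (sd / stats::sd(x))
}

# Biphasic QRS-like pulse: Mexican hat, unit peak, total support = width.
ecg_template <- function(width_ms, fs) {
  half <- max(1L, round(width_ms / 2000 * fs))
  t <- seq(-half, half) / fs
  sigma <- (width_ms / 1000) / 8
  psi <- (1 - (t / sigma)^2) * exp(-t^2 / (2 * sigma^2))
  psi / max(psi)
}

# Deterministic circadian + event-effect band power at given UTC instants.
timeline_deterministic <- function(t_utc, cfg, event_times_utc) {
  hrs <- wallclock_hours(t_utc, cfg$utc_offset_min)
  p <- cfg$circadian$mean +
    cfg$circadian$amplitude * sin(2 * pi * (hrs - cfg$circadian$acrophase_hour) / 24)
  for (i in seq_along(cfg$events)) {
    ev <- cfg$events[[i]]
    if (ev$post_effect == 0) next
    for (te in event_times_utc[[ev$name]]) {
      dt_min <- (as.numeric(t_utc) - as.numeric(te)) / 60 - ev$effect_delay_min
      on <- dt_min >= 0
      p[on] <- p[on] + ev$post_effect * exp(-dt_min[on] / EVENT_DECAY_MIN)
    }
  }
  p
}

# Multi-channel time-domain block: oscillations (optionally amplitude-scaled
# per stim level) + noise. Returns channels x time matrix.
td_block <- function(cfg, duration_s, labels, osc_scale = NULL) {
  n <- round(duration_s * cfg$fs_td)
  t <- seq_len(n) / cfg$fs_td
  scale_t <- if (is.null(osc_scale)) rep(1, n) else osc_scale
  out <- matrix(0, nrow = length(labels), ncol = n,
                dimnames = list(labels, NULL))
  for (ch in seq_along(labels)) {
    sig <- numeric(n)
    for (osc in cfg$streaming$oscillations) {
      phase <- stats::runif(1, 0, 2 * pi)
      sig <- sig + osc$amplitude_uV * scale_t *
        sin(2 * pi * osc$freq_hz * t + phase)
    }
    sig <- sig + noise_series(n, cfg$streaming$noise$sd_uV,
                              cfg$streaming$noise$kind)
    out[ch, ] <- sig
  }
  out
}

# -- main generator -----------------------------------------------------------

#' Generate a synthetic session file with ground-truth sidecar
#'
#' Writes a Percept-like session JSON (dialect documented in the package's
#' `SCHEMA.md`) containing metadata, an impedance table, one Survey and one
#' Setup recording, one Streaming recording with its paired band-power /
#' stimulation-amplitude stream, a per-hemisphere Timeline at 10-minute
#' cadence spanning `n_days`, and scheduled Events. A `*.truth.json` sidecar
#' records everything injected (ECG peak positions and the artifact-free
#' trace, circadian parameters, event times, stimulation change times, the
#' noise-free Timeline) so analyses can be validated without clinical data.
#'
#' All float arrays are quantized to 1e-6 before serialization so that a
#' parse of the written file reproduces every sample bit-exactly, and the
#' same config (including seed) always yields byte-identical files.
#'
#' @param config a [synth_config()] object.
#' @param out_path destination of the session JSON; the sidecar is written
#'   next to it as `<stem>.truth.json`.
#' @return invisibly, a list with `session_path`, `truth_path`, and the
#'   ground-truth list `truth` (with R-side 1-based peak indices in
#'   `truth$ecg$peak_samples_r`).
#' @export
generate_session <- function(config, out_path) {
  if (!inherits(config, "dbs_synth_config")) config <- do.call(synth_config, config)
  validate_synth_config(config)
  cfg <- config
  set.seed(cfg$seed)

  session_t0 <- if (inherits(cfg$start_time, "POSIXct")) cfg$start_time
                else parse_iso8601(cfg$start_time)
  off <- cfg$utc_offset_min
  iso <- function(t) format_iso8601(t, off)

  # Timeline grid: n_days from the local midnight preceding the session time.
  local_midnight <- as.POSIXct(
    floor((as.numeric(session_t0) + off * 60) / 86400) * 86400 - off * 60,
    origin = "1970-01-01", tz = "UTC")
  tl_start <- local_midnight - as.difftime(cfg$n_days, units = "days")
  n_tl <- cfg$n_days * 86400 %/% TIMELINE_CADENCE_S   # 144 points/day
  tl_times <- tl_start + (seq_len(n_tl) - 1) * TIMELINE_CADENCE_S

  # -- events (scheduled over the Timeline span) -----------------------------
  event_times_utc <- list()
  event_records <- list()
  snapshot_freqs <- seq(1, 96, by = 1)
  for (ev in cfg$events) {
    times <- c()
    for (day in seq_len(cfg$n_days) - 1L) {
      for (h in ev$daily_times) {
        jit <- if (ev$jitter_min > 0) stats::rnorm(1, 0, ev$jitter_min) else 0
        te <- tl_start + day * 86400 + h * 3600 + jit * 60
        if (te >= tl_start && te < tl_start + cfg$n_days * 86400)
          times <- c(times, as.numeric(te))
      }
    }
    times <- sort(times)
    event_times_utc[[ev$name]] <- as.POSIXct(times, origin = "1970-01-01",
                                             tz = "UTC")
    for (te in times) {
      rec <- list(name = ev$name,
                  time = iso(as.POSIXct(te, origin = "1970-01-01", tz = "UTC")))
      if (isTRUE(ev$snapshot)) {
        snap <- list()
        for (hemi in c("left", "right")) {
          base <- 10 / snapshot_freqs
          bump_amp <- stats::rlnorm(1, log(2), 0.3)
          bump <- bump_amp * exp(-(snapshot_freqs - 15)^2 / (2 * 2^2))
          snap[[hemi]] <- list(freqs_hz = snapshot_freqs,
                               power = quantize6(base + bump))
        }
        rec$snapshot <- snap
      }
      event_records[[length(event_records) + 1L]] <- rec
    }
  }

  # -- timeline (both hemispheres; shared deterministic part, own noise) -----
  det <- timeline_deterministic(tl_times, cfg, event_times_utc)
  timeline <- list()
  for (hemi in c("left", "right")) {
    p <- pmax(0, det + stats::rnorm(n_tl, 0, cfg$circadian$noise_sd))
    keep <- rep(TRUE, n_tl)
    if (isTRUE(cfg$timeline_dropout$enabled) && cfg$timeline_dropout$fraction > 0)
      keep <- stats::runif(n_tl) >= cfg$timeline_dropout$fraction
    timeline[[hemi]] <- list(
      hemisphere = hemi,
      timestamps = vapply(which(keep), function(i) iso(tl_times[i]), ""),
      band_power = quantize6(p[keep]),
      stim_amplitude_ma = quantize6(rep(1.5, sum(keep))),
      band_edges_hz = cfg$band_edges_hz)
  }

  # -- impedance table --------------------------------------------------------
  pairs <- c("0-1", "1-2", "2-3")
  impedances <- list()
  for (hemi in c("left", "right")) for (pr in pairs) {
    impedances[[length(impedances) + 1L]] <- list(
      hemisphere = hemi, electrode_pair = pr,
      impedance_ohm = round(stats::runif(1, 600, 1500)))
  }

  # -- survey / setup ---------------------------------------------------------
  survey_labels <- as.vector(outer(c("L", "R"), pairs, paste, sep = "_"))
  survey_t0 <- session_t0 + 300
  survey_mat <- td_block(cfg, cfg$survey$duration_s, survey_labels)
  setup_labels <- c("L_1-3", "R_1-3")
  setup_t0 <- session_t0 + 400
  setup_mat <- td_block(cfg, cfg$setup$duration_s, setup_labels)

  # -- streaming + paired power stream + artifacts ---------------------------
  str_t0 <- session_t0 + 600
  dur <- cfg$streaming$duration_s
  n_td <- round(dur * cfg$fs_td)
  td_t <- seq_len(n_td) / cfg$fs_td

  stim_change_times <- numeric(0)
  stim_level_at <- function(ts) rep(cfg$stim_ramp$start_mA, length(ts))
  osc_scale <- rep(1, n_td)
  if (isTRUE(cfg$stim_ramp$enabled)) {
    step_s <- cfg$stim_ramp$step_every_s
    n_steps <- floor((dur - 1e-9) / step_s)
    stim_change_times <- step_s * seq_len(n_steps)
    stim_change_times <- stim_change_times[stim_change_times < dur]
    stim_level_at <- function(ts) {
      k <- floor(ts / step_s)
      cfg$stim_ramp$start_mA + k * cfg$stim_ramp$step_mA
    }
    osc_scale <- cfg$stim_ramp$osc_scale_per_step ^ floor(td_t / step_s)
  }

  str_labels <- c("L_1-3", "R_1-3")
  ecg_channel <- NULL; peak_samples0 <- integer(0)
  artifact <- numeric(n_td)
  artifact_free1 <- numeric(0)
  streamings <- list()
  for (rec_i in seq_len(cfg$streaming$n_recordings)) {
    rec_t0 <- str_t0 + (rec_i - 1) * (dur + 60)   # 1-min gaps between recs
    clean_mat <- td_block(cfg, dur, str_labels, osc_scale = osc_scale)
    clean_q <- quantize6(clean_mat)
    str_mat <- clean_q
    # cardiac artifact goes on the left channel of the first recording only
    if (rec_i == 1L && isTRUE(cfg$ecg$enabled) && cfg$ecg$template_amp_uV > 0) {
      ecg_channel <- str_labels[1]
      tmpl <- cfg$ecg$template_amp_uV *
        ecg_template(cfg$ecg$template_width_ms, cfg$fs_td)
      half <- (length(tmpl) - 1L) %/% 2L
      rr <- 60 / cfg$ecg$rate_bpm
      margin <- max(0.3, (half + 1) / cfg$fs_td)
      tk <- margin
      peaks <- c()
      while (tk <= dur - margin) {
        peaks <- c(peaks, tk)
        tk <- tk + rr * (1 + stats::rnorm(1, 0, 0.02))
      }
      peak_samples0 <- as.integer(round(peaks * cfg$fs_td))   # 0-based indices
      for (p0 in peak_samples0) {
        idx <- (p0 - half):(p0 + half) + 1L                   # 1-based window
        ok <- idx >= 1 & idx <= n_td
        artifact[idx[ok]] <- artifact[idx[ok]] + tmpl[ok]
      }
      artifact <- quantize6(artifact)
      str_mat[ecg_channel, ] <- quantize6(clean_q[ecg_channel, ] + artifact)
    }
    if (rec_i == 1L)
      artifact_free1 <- if (!is.null(ecg_channel)) clean_q[ecg_channel, ]
                        else numeric(0)

    # power stream: generator-model band power (oscillation power within the
    # sensing band, amplitude-scaled by the ramp) + multiplicative noise
    n_pow <- floor(dur * cfg$fs_power)
    pow_ts <- (seq_len(n_pow) - 1) / cfg$fs_power
    power_stream <- list()
    for (hemi in c("left", "right")) {
      base <- numeric(n_pow)
      for (osc in cfg$streaming$oscillations) {
        if (osc$freq_hz >= cfg$band_edges_hz[1] && osc$freq_hz <= cfg$band_edges_hz[2]) {
          amp <- osc$amplitude_uV *
            (if (isTRUE(cfg$stim_ramp$enabled))
               cfg$stim_ramp$osc_scale_per_step ^ floor(pow_ts / cfg$stim_ramp$step_every_s)
             else rep(1, n_pow))
          base <- base + amp^2 / 2
        }
      }
      bp <- base * exp(stats::rnorm(n_pow, 0, 0.05))
      power_stream[[hemi]] <- list(
        timestamps = vapply(pow_ts, function(s) iso(rec_t0 + s), ""),
        band_power = quantize6(bp),
        stim_amplitude_ma = quantize6(stim_level_at(pow_ts)),
        band_edges_hz = cfg$band_edges_hz)
    }
    streamings[[rec_i]] <- list(
      time_domain = list(mode = "streaming", channels = str_labels,
                         fs_hz = cfg$fs_td, start_time = iso(rec_t0),
                         samples_uv = str_mat),
      power_stream = power_stream)
  }

  session <- list(
    schema = "dbsense-session/1",
    device = list(model = "Percept-like synthetic neurostimulator",
                  implant_date = "2023-11-15",
                  lead_locations = list(left = "STN", right = "STN")),
    patient = list(id = cfg$patient_id),
    session = list(time = iso(session_t0),
                   utc_offset_minutes = off),
    impedances = impedances,
    surveys = list(list(mode = "survey", channels = survey_labels,
                        fs_hz = cfg$fs_td, start_time = iso(survey_t0),
                        samples_uv = quantize6(survey_mat))),
    setups = list(list(mode = "setup", channels = setup_labels,
                       fs_hz = cfg$fs_td, start_time = iso(setup_t0),
                       samples_uv = quantize6(setup_mat))),
    streamings = streamings,
    timeline = timeline,
    events = event_records)

  jsonlite::write_json(session, out_path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)

  truth <- list(
    seed = cfg$seed,
    ecg = list(channel = ecg_channel,
               peak_samples = peak_samples0,          # 0-based, schema units
               template_amp_uV = cfg$ecg$template_amp_uV,
               template_width_ms = cfg$ecg$template_width_ms,
               rate_bpm = cfg$ecg$rate_bpm,
               artifact = artifact,
               artifact_free_signal = artifact_free1),
    circadian_params = cfg$circadian,
    utc_offset_min = off,
    event_times = lapply(event_times_utc, function(tt)
      vapply(seq_along(tt), function(i) iso(tt[i]), "")),
    stim_change_times = stim_change_times,
    timeline_start = iso(tl_start),
    timeline_deterministic = quantize6(det),
    streaming_start = iso(str_t0),
    movement_epochs = cfg$wearable$movement_epochs,
    wearable_start_offset_s = cfg$wearable$start_offset_s)

  truth_path <- paste0(sub("\\.json$", "", out_path), ".truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)

  truth$ecg$peak_samples_r <- truth$ecg$peak_samples + 1L
  dbs_log(sprintf("wrote synthetic session %s (%d timeline pts/hemisphere, %d events)",
                  out_path, n_tl, length(event_records)), level = "debug")
  invisible(list(session_path = out_path, truth_path = truth_path,
                 truth = truth))
}

#' Generate a synthetic wearable accelerometer CSV
#'
#' Writes a CSV with header `timestamp,ax,ay,az`: ISO-8601 timestamps at the
#' configured accelerometer rate, a constant gravity vector on `az` plus a
#' small noise floor, and elevated-variance samples exactly inside the
#' configured movement epochs (half-open `[start_s, end_s)` relative to the
#' trace start). The trace starts `wearable$start_offset_s` after
#' `session_start`.
#'
#' @param config a [synth_config()] object.
#' @param session_start trace time origin (POSIXct or ISO-8601 text),
#'   typically the streaming recording start.
#' @param out_path destination CSV path.
#' @return invisibly, `out_path`.
#' @export
generate_wearable_csv <- function(config, session_start, out_path) {
  if (!inherits(config, "dbs_synth_config")) config <- do.call(synth_config, config)
  validate_synth_config(config)
  cfg <- config$wearable
  if (cfg$fs_hz <= 0)
    dbs_stop("invalid synthetic config: field 'wearable.fs_hz' must be > 0",
             "dbsense_config_error", field = "wearable.fs_hz")
  set.seed(config$seed + 1013L)
  t0 <- if (inherits(session_start, "POSIXct")) session_start
        else parse_iso8601(session_start)
  t0 <- t0 + cfg$start_offset_s
  dur <- cfg$duration_s %||% config$streaming$duration_s
  n <- floor(dur * cfg$fs_hz)
  if (n == 0) {
    writeLines("timestamp,ax,ay,az", out_path)
    return(invisible(out_path))
  }
  rel <- (seq_len(n) - 1) / cfg$fs_hz
  ax <- stats::rnorm(n, 0, cfg$noise_sd)
  ay <- stats::rnorm(n, 0, cfg$noise_sd)
  az <- 9.81 + stats::rnorm(n, 0, cfg$noise_sd)
  for (ep in cfg$movement_epochs) {
    sel <- rel >= ep[1] & rel < ep[2]
    m <- sum(sel)
    if (m > 0) {
      ax[sel] <- ax[sel] + stats::rnorm(m, 0, cfg$movement_sd)
      ay[sel] <- ay[sel] + stats::rnorm(m, 0, cfg$movement_sd)
      az[sel] <- az[sel] + stats::rnorm(m, 0, cfg$movement_sd)
    }
  }
  # millisecond-exact stamps (strftime %OS truncates, producing fake jitter)
  tot_ms <- round((as.numeric(t0) + rel) * 1000)
  secs <- as.POSIXct(tot_ms %/% 1000, origin = "1970-01-01", tz = "UTC")
  stamp <- sprintf("%s.%03d+00:00", format(secs, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                   tot_ms %% 1000)
  df <- data.frame(timestamp = stamp,
                   ax = sprintf("%.6f", ax),
                   ay = sprintf("%.6f", ay),
                   az = sprintf("%.6f", az))
  utils::write.csv(df, out_path, row.names = FALSE, quote = FALSE)
  invisible(out_path)
}
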