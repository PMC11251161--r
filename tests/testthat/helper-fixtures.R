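# Shared fixtures and independent oracles. Sessions are generated once per
# test run (cached in the session tempdir) and reused across files.

rms <- function(x) sqrt(mean(x^2))

.fx_cache <- new.env(parent = emptyenv())

# generate (memoized) a synthetic session; returns list(session, truth, path)
fx_session <- function(key, ...) {
  if (!is.null(.fx_cache[[key]])) return(.fx_cache[[key]])
  path <- file.path(tempdir(), paste0("fx_", key, ".json"))
  cfg <- synth_config(...)
  res <- generate_session(cfg, path)
  out <- list(cfg = cfg, session = parse_session(path), truth = res$truth,
              path = path, truth_path = res$truth_path)
  .fx_cache[[key]] <- out
  out
}

# default-ish session reused by several files (short streaming to stay fast)
fx_default <- function() {
  fx_session("default", seed = 101, n_days = 3,
             streaming = list(duration_s = 60))
}

# titration session: 20 Hz oscillation halving in amplitude at each stim step
fx_titration <- function() {
  fx_session("titration", seed = 202,
             streaming = list(duration_s = 120,
                              oscillations = list(list(freq_hz = 20,
                                                       amplitude_uV = 10)),
                              noise = list(kind = "one_over_f", sd_uV = 0.5)),
             stim_ramp = list(enabled = TRUE, step_every_s = 30),
             ecg = list(enabled = FALSE),
             wearable = list(fs_hz = 50, movement_epochs = list(c(30, 60)),
                             start_offset_s = 12))
}

# build a bare event record list
make_event <- function(name, time, snapshot = NULL) {
  out <- list(name = name, time = parse_iso8601(time))
  if (!is.null(snapshot)) out$snapshot <- snapshot
  out
}

# build a timeline object directly (strictly increasing POSIXct timestamps)
make_timeline <- function(timestamps, band_power, hemisphere = "left",
                          stim = rep(0, length(band_power))) {
  dbsense:::new_timeline(hemisphere, timestamps, band_power, stim, c(13, 35))
}

# brute-force all-pairs nearest-reference oracle for relative offsets
brute_offsets <- function(ref_times, tgt_times, window_min) {
  offs <- numeric(0); excluded <- 0L
  for (tt in as.numeric(tgt_times)) {
    best <- NA_real_
    for (rr in as.numeric(ref_times)) {
      d <- (tt - rr) / 60
      if (abs(d) > window_min) next
      if (is.na(best) || abs(d) < abs(best) || (abs(d) == abs(best) && d < best))
        best <- d
    }
    if (is.na(best)) excluded <- excluded + 1L else offs <- c(offs, best)
  }
  list(offsets_min = offs, n_excluded = excluded)
}

# first-harmonic fit of a circadian profile (independent of the package's
# profile code): returns amplitude and acrophase hour of
# mean + A sin(2 pi (h - phi) / 24)
harmonic_fit <- function(hours, values) {
  s <- sin(2 * pi * hours / 24); c_ <- cos(2 * pi * hours / 24)
  fit <- stats::lm(values ~ s + c_)
  a <- stats::coef(fit)[["s"]]; b <- stats::coef(fit)[["c_"]]
  list(amplitude = sqrt(a^2 + b^2),
       acrophase_hour = (atan2(-b, a) * 24 / (2 * pi)) %% 24)
}

# closed-form deterministic band power of the generator's timeline model at
# arbitrary UTC instants (circadian + exponentially decaying event offsets)
model_power_at <- function(t_utc, circ, utc_offset_min, event_specs,
                           event_times) {
  hrs <- ((as.numeric(t_utc) + utc_offset_min * 60) %% 86400) / 3600
  p <- circ$mean + circ$amplitude * sin(2 * pi * (hrs - circ$acrophase_hour) / 24)
  for (ev in event_specs) {
    if (ev$post_effect == 0) next
    for (te in as.numeric(event_times[[ev$name]])) {
      dt_min <- (as.numeric(t_utc) - te) / 60 - ev$effect_delay_min
      on <- dt_min >= 0
      p[on] <- p[on] + ev$post_effect * exp(-dt_min[on] / 60)
    }
  }
  p
}
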