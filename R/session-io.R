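# Session-file parsing and the typed multi-patient data model.
#
# Tolerant-reader policy: unknown top-level keys are logged as warnings and
# skipped, absent sections become empty collections, and only minimal fields
# are required per record (sampling info + values). Vendor exports drift
# across firmware versions, so the parser must never be brittle.

KNOWN_TOPLEVEL <- c("schema", "device", "patient", "session", "impedances",
                    "surveys", "setups", "streamings", "timeline", "events")

new_td_recording <- function(mode, channels, fs, start_time, samples) {
  samples <- matrix(as.numeric(samples), nrow = length(channels),
                    dimnames = list(channels, NULL))
  if (!is.finite(fs) || fs <= 0)
    dbs_stop("time-domain recording: field 'fs_hz' must be > 0",
             "dbsense_schema_error")
  if (anyDuplicated(channels))
    dbs_stop("time-domain recording: field 'channels' has duplicate labels",
             "dbsense_schema_error")
  structure(list(mode = mode, channels = channels, fs = fs,
                 start_time = start_time, samples = samples),
            class = "dbs_td")
}

#' Construct a time-domain recording
#'
#' Builds a `dbs_td` object from raw samples — useful for analyzing signals
#' that did not come from a session file.
#'
#' @param samples numeric vector (one channel) or channels x time matrix.
#' @param fs sampling rate, Hz.
#' @param channels channel labels (unique); defaults to `ch1`, `ch2`, ...
#' @param mode sensing-mode tag (default `"streaming"`).
#' @param start_time recording start (POSIXct or ISO-8601 text).
#' @return a `dbs_td`.
#' @export
td_recording <- function(samples, fs, channels = NULL, mode = "streaming",
                         start_time = "1970-01-01T00:00:00+00:00") {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(samples)))
  if (is.character(start_time)) start_time <- parse_iso8601(start_time)
  new_td_recording(mode, channels, fs, start_time, samples)
}

#' @export
print.dbs_td <- function(x, ...) {
  cat(sprintf("<dbs_td %s> %d channel(s) x %d samples @ %g Hz (%.1f s), start %s\n",
              x$mode, nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs, format(x$start_time, usetz = TRUE)))
  invisible(x)
}

new_timeline <- function(hemisphere, timestamps, band_power, stim_amplitude,
                         band_edges) {
  if (is.unsorted(timestamps, strictly = TRUE))
    dbs_stop(sprintf("timeline (%s): timestamps must be strictly increasing",
                     hemisphere), "dbsense_schema_error")
  if (any(band_power < 0))
    dbs_stop(sprintf("timeline (%s): field 'band_power' must be >= 0",
                     hemisphere), "dbsense_schema_error")
  structure(list(hemisphere = hemisphere, timestamps = timestamps,
                 band_power = as.numeric(band_power),
                 stim_amplitude = as.numeric(stim_amplitude),
                 band_edges = as.numeric(band_edges)),
            class = "dbs_timeline")
}

#' @export
print.dbs_timeline <- function(x, ...) {
  cat(sprintf("<dbs_timeline %s> %d points, %s .. %s, band %g-%g Hz\n",
              x$hemisphere, length(x$timestamps),
              format(min(x$timestamps)), format(max(x$timestamps)),
              x$band_edges[1], x$band_edges[2]))
  invisible(x)
}

parse_power_stream <- function(ps) {
  out <- list()
  for (key in names(ps)) {
    hemi <- normalize_hemisphere(key)
    p <- ps[[key]]
    ts <- parse_iso8601(unlist(p$timestamps))
    if (is.unsorted(ts))
      dbs_stop(sprintf("power stream (%s): timestamps must be non-decreasing", hemi),
               "dbsense_schema_error")
    stim <- as.numeric(unlist(p$stim_amplitude_ma %||% numeric(0)))
    if (length(stim) && any(stim < 0))
      dbs_stop(sprintf("power stream (%s): field 'stim_amplitude_ma' must be >= 0", hemi),
               "dbsense_schema_error")
    out[[hemi]] <- list(timestamps = ts,
                        band_power = as.numeric(unlist(p$band_power)),
                        stim_amplitude = stim,
                        band_edges = as.numeric(unlist(p$band_edges_hz %||% c(NA, NA))))
  }
  out
}

#' Parse a session JSON file into the typed data model
#'
#' Maps every recognized section of a Percept-like session file (dialect in
#' the package's `SCHEMA.md`) onto typed collections: device/patient
#' metadata, impedance table, Survey/Setup/Streaming time-domain recordings,
#' the per-hemisphere Timeline, and Events. Unrecognized top-level keys are
#' reported as warnings, never errors; absent sections yield empty
#' collections, so a metadata-only file parses cleanly.
#'
#' @param path session JSON file.
#' @return an object of class `dbs_session`: a list with `device`,
#'   `patient_id`, `session_time` (POSIXct UTC), `utc_offset_min`,
#'   `impedances` (data.frame hemisphere/electrode_pair/impedance_ohm),
#'   `surveys`, `setups` (lists of `dbs_td`), `streamings` (lists of
#'   `dbs_streaming`: `$td` plus `$power_stream`), `timeline` (named list of
#'   `dbs_timeline` per hemisphere), `events` (list of event records with
#'   `name`, `time`, optional `snapshot`), and `path`. Printing the object
#'   summarizes the available sensing modes.
#' @export
parse_session <- function(path) {
  if (!file.exists(path))
    dbs_stop(paste0("session file not found: ", path), "dbsense_io_error")
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = TRUE),
    error = function(e) {
      off <- regmatches(conditionMessage(e),
                        regexpr("[0-9]+", conditionMessage(e)))
      dbs_stop(sprintf("invalid JSON in '%s' (near byte offset %s): %s", path,
                       if (length(off)) off[1] else "?", conditionMessage(e)),
               "dbsense_parse_error")
    })
  if (!is.list(raw))
    dbs_stop(sprintf("invalid session file '%s': top level is not an object", path),
             "dbsense_parse_error")

  unknown <- setdiff(names(raw), KNOWN_TOPLEVEL)
  if (length(unknown))
    dbs_warn(sprintf("session '%s': ignoring unrecognized top-level key(s): %s",
                     path, paste(unknown, collapse = ", ")),
             "dbsense_unknown_key_warning")

  dev <- raw$device %||% list()
  device <- list(model = dev$model %||% "unknown device",
                 implant_date = dev$implant_date %||% NA_character_,
                 lead_locations = dev$lead_locations %||% list())
  if (!nzchar(device$model))
    dbs_stop("section 'device': field 'model' must be non-empty",
             "dbsense_schema_error")
  patient_id <- (raw$patient %||% list())$id %||% "unknown"
  sess <- raw$session %||% list()
  session_time <- if (!is.null(sess$time)) parse_iso8601(sess$time)
                  else as.POSIXct(NA)
  utc_offset_min <- as.integer(sess$utc_offset_minutes %||% 0L)

  imp <- raw$impedances %||% list()
  impedances <- if (length(imp)) {
    df <- data.frame(
      hemisphere = normalize_hemisphere(vapply(imp, function(r) r$hemisphere, "")),
      electrode_pair = vapply(imp, function(r) as.character(r$electrode_pair), ""),
      impedance_ohm = vapply(imp, function(r) as.numeric(r$impedance_ohm), 0),
      stringsAsFactors = FALSE)
    if (any(df$impedance_ohm < 0))
      dbs_stop("section 'impedances': field 'impedance_ohm' must be >= 0",
               "dbsense_schema_error")
    df
  } else {
    data.frame(hemisphere = character(0), electrode_pair = character(0),
               impedance_ohm = numeric(0))
  }

  parse_td <- function(rec, mode) {
    for (f in c("channels", "fs_hz", "samples_uv")) {
      if (is.null(rec[[f]]))
        dbs_stop(sprintf("section '%s': record missing required field '%s'",
                         mode, f), "dbsense_schema_error")
    }
    new_td_recording(mode = rec$mode %||% mode,
                     channels = unlist(rec$channels),
                     fs = rec$fs_hz,
                     start_time = parse_iso8601(rec$start_time %||% NA_character_),
                     samples = rec$samples_uv)
  }

  surveys <- lapply(raw$surveys %||% list(), parse_td, mode = "survey")
  setups <- lapply(raw$setups %||% list(), parse_td, mode = "setup")
  streamings <- lapply(raw$streamings %||% list(), function(sr) {
    td <- parse_td(sr$time_domain %||% sr, mode = "streaming")
    ps <- if (!is.null(sr$power_stream)) parse_power_stream(sr$power_stream)
          else list()
    structure(list(td = td, power_stream = ps), class = "dbs_streaming")
  })

  timeline <- list()
  for (key in names(raw$timeline %||% list())) {
    hemi <- normalize_hemisphere(key)
    tl <- raw$timeline[[key]]
    timeline[[hemi]] <- new_timeline(
      hemisphere = hemi,
      timestamps = parse_iso8601(unlist(tl$timestamps)),
      band_power = unlist(tl$band_power),
      stim_amplitude = unlist(tl$stim_amplitude_ma %||% numeric(0)),
      band_edges = unlist(tl$band_edges_hz %||% c(NA, NA)))
  }

  events <- lapply(raw$events %||% list(), function(ev) {
    if (is.null(ev$name) || is.null(ev$time))
      dbs_stop("section 'events': record missing required field 'name' or 'time'",
               "dbsense_schema_error")
    out <- list(name = ev$name, time = parse_iso8601(ev$time))
    if (!is.null(ev$snapshot)) {
      snap <- list()
      for (key in names(ev$snapshot)) {
        hemi <- normalize_hemisphere(key)
        s <- ev$snapshot[[key]]
        freqs <- as.numeric(unlist(s$freqs_hz))
        pow <- as.numeric(unlist(s$power))
        if (length(freqs) != length(pow) || is.unsorted(freqs, strictly = TRUE))
          dbs_stop("section 'events': snapshot freqs/power must be equal length with strictly increasing freqs",
                   "dbsense_schema_error")
        snap[[hemi]] <- list(freqs = freqs, power = pow)
      }
      out$snapshot <- snap
    }
    out
  })

  out <- structure(list(device = device, patient_id = patient_id,
                        session_time = session_time,
                        utc_offset_min = utc_offset_min,
                        impedances = impedances, surveys = surveys,
                        setups = setups, streamings = streamings,
                        timeline = timeline, events = events, path = path),
                   class = "dbs_session")
  dbs_log(sprintf("parsed '%s': %s", path,
                  paste(names(available_modes(out))[unlist(available_modes(out))],
                        collapse = ", ")), level = "debug")
  out
}

#' Which sensing modes does a session contain?
#'
#' @param session a `dbs_session`.
#' @return named logical vector over the five sensing modes
#'   (survey, setup, streaming, timeline, events).
#' @export
available_modes <- function(session) {
  c(survey = length(session$surveys) > 0,
    setup = length(session$setups) > 0,
    streaming = length(session$streamings) > 0,
    timeline = length(session$timeline) > 0 &&
      any(vapply(session$timeline, function(t) length(t$timestamps) > 0, TRUE)),
    events = length(session$events) > 0)
}

#' @export
print.dbs_session <- function(x, ...) {
  cat("<dbs_session>", x$path %||% "", "\n")
  cat(sprintf("  patient %s | %s | session %s (UTC%+03d:%02d)\n",
              x$patient_id, x$device$model,
              format(x$session_time, "%Y-%m-%d %H:%M:%S"),
              x$utc_offset_min %/% 60L, abs(x$utc_offset_min) %% 60L))
  am <- available_modes(x)
  cat("  available sensing modes:",
      if (any(am)) paste(names(am)[am], collapse = ", ") else "(none)", "\n")
  cat(sprintf("  %d impedance(s), %d survey(s), %d setup(s), %d streaming(s), %d event(s)\n",
              nrow(x$impedances), length(x$surveys), length(x$setups),
              length(x$streamings), length(x$events)))
  for (hemi in names(x$timeline))
    cat(sprintf("  timeline %s: %d points\n", hemi,
                length(x$timeline[[hemi]]$timestamps)))
  invisible(x)
}

#' Load multiple session files into a patient-grouped batch
#'
#' Groups parsed sessions by patient identifier and orders each group
#' chronologically by session time. A duplicate file (same patient and
#' session time) is dropped with a warning.
#'
#' @param paths character vector of session JSON paths (length >= 1).
#' @return `dbs_batch`: a named list (patient id -> list of `dbs_session`).
#' @export
load_batch <- function(paths) {
  if (length(paths) < 1)
    dbs_stop("load_batch needs at least one path", "dbsense_io_error")
  sessions <- lapply(paths, parse_session)
  batch <- list()
  for (s in sessions) {
    grp <- batch[[s$patient_id]] %||% list()
    dup <- any(vapply(grp, function(g)
      identical(as.numeric(g$session_time), as.numeric(s$session_time)), TRUE))
    if (dup) {
      dbs_warn(sprintf("duplicate session for patient %s at %s (%s) dropped",
                       s$patient_id, format(s$session_time), s$path),
               "dbsense_duplicate_warning")
      next
    }
    grp[[length(grp) + 1L]] <- s
    batch[[s$patient_id]] <- grp
  }
  for (pid in names(batch)) {
    ord <- order(vapply(batch[[pid]], function(s) as.numeric(s$session_time), 0))
    batch[[pid]] <- batch[[pid]][ord]
  }
  structure(batch, class = "dbs_batch")
}

#' @export
print.dbs_batch <- function(x, ...) {
  cat(sprintf("<dbs_batch> %d patient(s)\n", length(x)))
  for (pid in names(x))
    cat(sprintf("  %s: %d session file(s)\n", pid, length(x[[pid]])))
  invisible(x)
}

#' Merge the Timelines of all of one patient's session files
#'
#' Concatenates per-hemisphere Timeline series across a patient's files,
#' sorts by timestamp, and removes duplicated timestamps (the first
#' occurrence wins, with a warning), enabling aggregated chronic analysis
#' over a span longer than one device read-out.
#'
#' @param batch a `dbs_batch` from [load_batch()].
#' @param patient_id patient to merge.
#' @return named list (hemisphere -> `dbs_timeline`).
#' @export
merge_timelines <- function(batch, patient_id) {
  if (!patient_id %in% names(batch))
    dbs_stop(sprintf("patient '%s' not present in batch (has: %s)", patient_id,
                     paste(names(batch), collapse = ", ")),
             "dbsense_lookup_error")
  out <- list()
  for (hemi in c("left", "right")) {
    ts <- as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC")
    bp <- numeric(0); st <- numeric(0); be <- c(NA_real_, NA_real_)
    for (s in batch[[patient_id]]) {
      tl <- s$timeline[[hemi]]
      if (is.null(tl)) next
      ts <- c(ts, tl$timestamps)
      bp <- c(bp, tl$band_power)
      st <- c(st, if (length(tl$stim_amplitude)) tl$stim_amplitude
                  else rep(NA_real_, length(tl$timestamps)))
      if (!anyNA(tl$band_edges)) be <- tl$band_edges
    }
    if (!length(ts)) next
    ord <- order(ts)
    ts <- ts[ord]; bp <- bp[ord]; st <- st[ord]
    dup <- duplicated(as.numeric(ts))
    if (any(dup))
      dbs_warn(sprintf("merge_timelines(%s, %s): dropped %d duplicated timestamp(s), keeping first",
                       patient_id, hemi, sum(dup)), "dbsense_duplicate_warning")
    out[[hemi]] <- new_timeline(hemi, ts[!dup], bp[!dup], st[!dup], be)
  }
  out
}
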