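# Artifact screening for streaming recordings: stimulation-amplitude
# transitions (abrupt low-frequency transients in the raw LFP when the
# stimulator steps during titration) and broadband epochs (movement/cable
# artifacts spanning the whole spectrum, optionally cross-annotated with
# wearable motion power).

new_artifact_flags <- function(stim_transitions, broadband_epochs, notes = "") {
  structure(list(stim_transitions = stim_transitions,
                 broadband_epochs = broadband_epochs, notes = notes),
            class = "dbs_artifact_flags")
}

#' @export
print.dbs_artifact_flags <- function(x, ...) {
  cat(sprintf("<dbs_artifact_flags> %d stim transition(s), %d broadband epoch(s)\n",
              nrow(x$stim_transitions), nrow(x$broadband_epochs)))
  if (nzchar(x$notes)) cat(" ", x$notes, "\n")
  invisible(x)
}

empty_transitions <- function() {
  data.frame(time_s = numeric(0), start_s = numeric(0), end_s = numeric(0))
}
empty_epochs <- function() {
  data.frame(start_s = numeric(0), end_s = numeric(0),
             motion_power = numeric(0), motion_overlap = logical(0))
}

#' Flag stimulation-amplitude transitions in a streaming recording
#'
#' Every change of the stimulation amplitude in the paired power stream is
#' flagged, with a mark window `[t, t+window_s)` on the time-domain trace
#' (times in seconds relative to the recording start) covering the abrupt
#' low-frequency transient the step induces. Overlapping windows are merged.
#'
#' @param sr a `dbs_streaming` (time-domain + power stream) record.
#' @param window_s mark-window length, default 2 s.
#' @return `dbs_artifact_flags` with the `stim_transitions` table filled
#'   (`time_s`, `start_s`, `end_s`); empty with a warning when no
#'   stimulation trace is present.
#' @export
flag_stim_transitions <- function(sr,
                                  window_s = dbsense_defaults()$stim$transition_window_s) {
  stopifnot(inherits(sr, "dbs_streaming"))
  ps <- Filter(function(p) length(p$stim_amplitude) > 0, sr$power_stream)
  if (!length(ps)) {
    dbs_warn("flag_stim_transitions: no stimulation-amplitude trace in recording",
             "dbsense_missing_warning")
    return(new_artifact_flags(empty_transitions(), empty_epochs(),
                              "no stim trace"))
  }
  dur <- ncol(sr$td$samples) / sr$td$fs
  t0 <- as.numeric(sr$td$start_time)
  times <- c()
  for (p in ps) {
    chg <- which(diff(p$stim_amplitude) != 0)
    if (length(chg))
      times <- c(times, as.numeric(p$timestamps[chg + 1]) - t0)
  }
  times <- sort(unique(times))
  times <- times[times >= 0 & times <= dur]
  wins <- merge_intervals(lapply(times, function(t) c(t, min(t + window_s, dur))))
  trans <- data.frame(time_s = times,
                      start_s = vapply(times, function(t) t, 0),
                      end_s = vapply(times, function(t) min(t + window_s, dur), 0))
  # merged, non-overlapping windows are what downstream exclusion uses
  attr(trans, "merged_windows") <- wins
  new_artifact_flags(trans, empty_epochs(),
                     sprintf("%d stimulation transition(s)", length(times)))
}

#' Screen a recording for broadband artifact epochs
#'
#' Computes per-window (default 1 s) power of the 1-100 Hz band-passed
#' trace on every channel and flags windows whose power on any channel
#' exceeds the channel median + 5 scaled MADs; contiguous flagged windows
#' are merged into half-open epochs `[start_s, end_s)`. If a wearable trace
#' is supplied, each epoch is annotated with the concurrent motion power and
#' whether it overlaps elevated motion (> 2x the median motion power).
#'
#' @param rec a `dbs_td` recording.
#' @param wearable optional `dbs_wearable` from [load_wearable()].
#' @param config screen parameter list (`dbsense_defaults()$screen`).
#' @return `dbs_artifact_flags` with the `broadband_epochs` table filled.
#' @export
screen_broadband <- function(rec, wearable = NULL,
                             config = dbsense_defaults()$screen) {
  stopifnot(inherits(rec, "dbs_td"))
  fs <- rec$fs
  win <- round(config$window_s * fs)
  n <- ncol(rec$samples)
  n_win <- n %/% win
  if (n_win < 3)
    return(new_artifact_flags(empty_transitions(), empty_epochs(),
                              "recording too short to screen"))
  band <- c(max(config$band[1], 0.5), min(config$band[2], fs / 2 * 0.98))
  cf <- butter_coeffs(4, band, fs, type = "pass")
  flagged <- rep(FALSE, n_win)
  for (ch in seq_len(nrow(rec$samples))) {
    xf <- filtfilt_ba(cf$b, cf$a, rec$samples[ch, ])
    pw <- vapply(seq_len(n_win), function(k)
      mean(xf[((k - 1) * win + 1):(k * win)]^2), 0)
    thr <- stats::median(pw) + config$mad_mult * mad_sigma(pw)
    flagged <- flagged | (pw > thr)
  }
  if (!any(flagged)) {
    return(new_artifact_flags(empty_transitions(), empty_epochs(),
                              "no broadband epochs"))
  }
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  epochs <- data.frame(
    start_s = (starts[r$values] - 1) * config$window_s,
    end_s = ends[r$values] * config$window_s)
  epochs$motion_power <- NA_real_
  epochs$motion_overlap <- NA
  if (!is.null(wearable)) {
    mp <- motion_power(wearable, window_s = config$window_s)
    # map epochs (relative to rec start) onto the wearable clock
    shift <- as.numeric(rec$start_time) - as.numeric(wearable$start_time)
    med_mp <- stats::median(mp$power)
    for (i in seq_len(nrow(epochs))) {
      sel <- mp$time_s >= (epochs$start_s[i] + shift) &
             mp$time_s < (epochs$end_s[i] + shift)
      if (any(sel)) {
        epochs$motion_power[i] <- mean(mp$power[sel])
        epochs$motion_overlap[i] <- epochs$motion_power[i] > 2 * med_mp
      }
    }
  }
  dbs_log(sprintf("screen_broadband: %d epoch(s) flagged", nrow(epochs)),
          level = "debug")
  new_artifact_flags(empty_transitions(), epochs,
                     sprintf("%d broadband epoch(s)", nrow(epochs)))
}
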