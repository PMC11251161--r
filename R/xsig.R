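# Streaming cross-signal analysis: wearable accelerometer ingestion,
# motion power, timestamp alignment against the LFP stream,
# stimulation-locked band-power segmentation, and band-power-vs-motion
# cross-correlation.

#' Load a wearable accelerometer CSV
#'
#' Expects a header `timestamp,ax,ay,az` (extra columns are ignored) with
#' ISO-8601 timestamps. Rows out of order are sorted with a warning; the
#' sampling rate is inferred from the median timestamp delta, and a warning
#' is raised if deltas drift by more than 1% from it.
#'
#' @param path CSV file.
#' @return object of class `dbs_wearable`: `timestamps` (POSIXct UTC),
#'   `start_time`, `fs` (Hz), `axes` (3 x samples matrix, rows ax/ay/az).
#' @export
load_wearable <- function(path) {
  if (!file.exists(path))
    dbs_stop(paste0("wearable file not found: ", path), "dbsense_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "ax", "ay", "az")
  missing <- setdiff(need, names(df))
  if (length(missing))
    dbs_stop(sprintf("wearable CSV '%s' lacks column(s) %s; expected header 'timestamp,ax,ay,az'",
                     path, paste(missing, collapse = ", ")),
             "dbsense_format_error")
  if (nrow(df) == 0) {
    dbs_warn(sprintf("wearable CSV '%s' has a header but no samples", path),
             "dbsense_empty_warning")
    return(structure(list(timestamps = as.POSIXct(character(0), tz = "UTC"),
                          start_time = as.POSIXct(NA), fs = NA_real_,
                          axes = matrix(numeric(0), nrow = 3,
                                        dimnames = list(c("ax", "ay", "az"), NULL))),
                     class = "dbs_wearable"))
  }
  ts <- parse_iso8601(df$timestamp)
  if (is.unsorted(ts)) {
    dbs_warn(sprintf("wearable CSV '%s': rows out of chronological order, sorted",
                     path), "dbsense_sort_warning")
    ord <- order(ts)
    ts <- ts[ord]; df <- df[ord, ]
  }
  fs <- NA_real_
  if (nrow(df) > 1) {
    dt <- diff(as.numeric(ts))
    med <- stats::median(dt)
    fs <- 1 / med
    if (any(abs(dt - med) > 0.01 * med))
      dbs_warn(sprintf("wearable CSV '%s': irregular sampling (> 1%% drift from %.3g Hz)",
                       path, fs), "dbsense_drift_warning")
  }
  structure(list(timestamps = ts, start_time = ts[1], fs = fs,
                 axes = rbind(ax = df$ax, ay = df$ay, az = df$az)),
            class = "dbs_wearable")
}

#' @export
print.dbs_wearable <- function(x, ...) {
  cat(sprintf("<dbs_wearable> %d samples @ %.3g Hz, start %s\n",
              ncol(x$axes), x$fs, format(x$start_time, usetz = TRUE)))
  invisible(x)
}

#' Motion power of a wearable trace
#'
#' Per-window variance of the acceleration magnitude after a 0.5 Hz
#' high-pass on each axis. High-passing the axes before taking the magnitude
#' removes gravity without vector bookkeeping, and makes the result exactly
#' invariant to sensor orientation (axis permutation) and to any constant
#' offset vector.
#'
#' @param w a `dbs_wearable`.
#' @param window_s window length (non-overlapping), default 1 s.
#' @param highpass_hz gravity-removal corner, default 0.5 Hz.
#' @return data.frame with `time_s` (window centers, seconds from trace
#'   start) and `power` (a.u.); attribute `start_time`.
#' @export
motion_power <- function(w, window_s = dbsense_defaults()$wearable$window_s,
                         highpass_hz = dbsense_defaults()$wearable$highpass_hz) {
  stopifnot(inherits(w, "dbs_wearable"))
  n <- ncol(w$axes)
  if (!n || n / w$fs < window_s)
    dbs_stop(sprintf("motion_power: trace shorter than one window (%g s)",
                     window_s), "dbsense_duration_error")
  if (all(w$axes == 0)) {
    hp <- w$axes                                 # exactly zero in -> zero out
  } else {
    cf <- butter_coeffs(2, highpass_hz, w$fs, type = "high")
    hp <- t(apply(w$axes, 1, function(x) filtfilt_ba(cf$b, cf$a, x)))
  }
  mag <- sqrt(colSums(hp^2))
  win <- round(window_s * w$fs)
  n_win <- n %/% win
  power <- vapply(seq_len(n_win), function(k)
    stats::var(mag[((k - 1) * win + 1):(k * win)]), 0)
  out <- data.frame(time_s = (seq_len(n_win) - 0.5) * window_s, power = power)
  attr(out, "start_time") <- w$start_time
  out
}

#' Align a wearable trace with a streaming recording by timestamps
#'
#' Maps both series onto a common relative time axis (origin = the LFP
#' recording start) from their absolute start timestamps. No resampling is
#' performed, only axis computation; a manual override is available when
#' device clocks are known to disagree.
#'
#' @param sr a `dbs_streaming`.
#' @param w a `dbs_wearable`.
#' @param offset_override optional manual offset (s) to use instead of the
#'   timestamp difference.
#' @return object of class `dbs_aligned`: `lfp_times`, `wearable_times`
#'   (seconds on the shared axis), `offset_applied` (s), `method`.
#' @export
align_wearable <- function(sr, w, offset_override = NULL) {
  stopifnot(inherits(sr, "dbs_streaming"), inherits(w, "dbs_wearable"))
  n_lfp <- ncol(sr$td$samples)
  dur_lfp <- n_lfp / sr$td$fs
  offset <- if (!is.null(offset_override)) offset_override
            else as.numeric(w$start_time) - as.numeric(sr$td$start_time)
  dur_w <- ncol(w$axes) / w$fs
  if (offset >= dur_lfp || offset + dur_w <= 0)
    dbs_stop(sprintf("align_wearable: no temporal overlap (LFP [0, %.1f] s, wearable [%.1f, %.1f] s on the LFP axis)",
                     dur_lfp, offset, offset + dur_w), "dbsense_alignment_error")
  structure(list(lfp_times = (seq_len(n_lfp) - 1) / sr$td$fs,
                 wearable_times = offset + (seq_len(ncol(w$axes)) - 1) / w$fs,
                 offset_applied = offset,
                 method = if (is.null(offset_override)) "timestamps" else "manual"),
            class = "dbs_aligned")
}

#' Band power per constant-stimulation level
#'
#' Partitions the streaming span by stimulation amplitude (from the paired
#' power stream), drops the transition windows flagged by
#' [flag_stim_transitions()], computes the sliding band power of the
#' time-domain trace, and summarizes it (mean, IQR, n windows) per level.
#' Used to quantify stimulation-induced band suppression during titration.
#'
#' @param sr a `dbs_streaming` with a stimulation trace.
#' @param band `c(low, high)` Hz.
#' @param channel time-domain channel to analyze.
#' @param window_s,step_s band-power windowing (defaults 1 s / 0.5 s).
#' @param transition_window_s exclusion window after each stim change.
#' @return object of class `dbs_stim_segments`: `summary` data.frame
#'   (`amplitude_mA`, `mean_power`, `iqr_power`, `n_windows`), `intervals`
#'   (per level, list of half-open `[start_s, end_s)`), `band`.
#' @export
stim_locked_band_power <- function(sr, band, channel = 1L, window_s = 1,
                                   step_s = 0.5,
                                   transition_window_s = dbsense_defaults()$stim$transition_window_s) {
  stopifnot(inherits(sr, "dbs_streaming"))
  ps <- Filter(function(p) length(p$stim_amplitude) > 0, sr$power_stream)
  if (!length(ps))
    dbs_stop("stim_locked_band_power: no stimulation-amplitude trace",
             "dbsense_data_error")
  p <- ps[[1]]
  t0 <- as.numeric(sr$td$start_time)
  dur <- ncol(sr$td$samples) / sr$td$fs
  rel <- as.numeric(p$timestamps) - t0
  r <- rle(p$stim_amplitude)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  seg_start <- rel[starts_idx]
  seg_end <- c(rel[starts_idx[-1]], dur)
  # steady part of each segment: skip the post-transition window
  steady_start <- ifelse(seq_along(seg_start) == 1, seg_start,
                         seg_start + transition_window_s)
  keep <- steady_start < seg_end
  if (!any(keep))
    dbs_stop("stim_locked_band_power: no steady segments between transitions",
             "dbsense_data_error")
  segs <- data.frame(amplitude_mA = r$values[keep],
                     start_s = steady_start[keep], end_s = seg_end[keep])

  bp <- band_power_series(sr$td, band, window_s = window_s, step_s = step_s,
                          channel = channel)
  seg_of <- rep(NA_integer_, nrow(bp))
  half <- window_s / 2
  for (i in seq_len(nrow(segs))) {
    sel <- (bp$time_s - half) >= segs$start_s[i] &
           (bp$time_s + half) <= segs$end_s[i]
    seg_of[sel] <- i
  }
  if (all(is.na(seg_of)))
    dbs_stop("stim_locked_band_power: no steady segments long enough for a band-power window",
             "dbsense_data_error")
  levels <- sort(unique(segs$amplitude_mA))
  summary <- do.call(rbind, lapply(levels, function(a) {
    rows <- which(segs$amplitude_mA == a)
    v <- bp$power[!is.na(seg_of) & seg_of %in% rows]
    data.frame(amplitude_mA = a,
               mean_power = if (length(v)) mean(v) else NA_real_,
               iqr_power = if (length(v))
                 unname(diff(stats::quantile(v, c(0.25, 0.75)))) else NA_real_,
               n_windows = length(v))
  }))
  intervals <- lapply(levels, function(a) {
    rows <- which(segs$amplitude_mA == a)
    lapply(rows, function(i) c(segs$start_s[i], segs$end_s[i]))
  })
  names(intervals) <- as.character(levels)
  structure(list(summary = summary, intervals = intervals, band = band,
                 segments = segs),
            class = "dbs_stim_segments")
}

#' @export
print.dbs_stim_segments <- function(x, ...) {
  cat(sprintf("<dbs_stim_segments> band %g-%g Hz, %d level(s)\n",
              x$band[1], x$band[2], nrow(x$summary)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Cross-correlation between band power and motion power
#'
#' Maps the finer-sampled series onto the coarser grid by nearest-neighbor
#' (no interpolation — the coarser grid bounds the information available),
#' then computes the normalized cross-correlation over lags up to
#' `max_lag_s`. Positive lag means band power is delayed relative to motion.
#' If both series carry a `start_time` attribute the absolute clocks are
#' used to align their time axes first.
#'
#' @param band_power data.frame `time_s`/`power` (e.g. from
#'   [band_power_series()]).
#' @param motion data.frame `time_s`/`power` (e.g. from [motion_power()]).
#' @param max_lag_s maximum lag to scan, seconds.
#' @return object of class `dbs_xcorr`: `lag_s` and `correlation` at the
#'   peak (largest |r|), plus the full `lags_s`/`r` profile and `n_overlap`.
#' @export
xcorr_power_motion <- function(band_power, motion, max_lag_s) {
  bt <- band_power$time_s; mt <- motion$time_s
  b0 <- attr(band_power, "start_time"); m0 <- attr(motion, "start_time")
  if (!is.null(b0) && !is.null(m0) && !is.na(b0) && !is.na(m0)) {
    shift <- as.numeric(m0) - as.numeric(b0)
    mt <- mt + shift                    # both now on the band-power clock
  }
  step_b <- stats::median(diff(bt)); step_m <- stats::median(diff(mt))
  if (step_b >= step_m) {               # band power is the coarser grid
    grid_t <- bt; x <- band_power$power
    y <- motion$power[vapply(grid_t, function(t) which.min(abs(mt - t)), 0L)]
    valid <- grid_t >= min(mt) - step_m / 2 & grid_t <= max(mt) + step_m / 2
    step <- step_b
  } else {
    grid_t <- mt; y <- motion$power
    x <- band_power$power[vapply(grid_t, function(t) which.min(abs(bt - t)), 0L)]
    valid <- grid_t >= min(bt) - step_b / 2 & grid_t <= max(bt) + step_b / 2
    step <- step_m
  }
  x <- x[valid]; y <- y[valid]
  n <- length(x)
  if (n < 10)
    dbs_stop(sprintf("xcorr_power_motion: only %d overlapping samples (need >= 10)", n),
             "dbsense_data_error")
  K <- floor(max_lag_s / step)
  lags <- (-K:K) * step
  r <- vapply(-K:K, function(k) {
    if (k >= 0) {
      xi <- x[(k + 1):n]; yi <- y[1:(n - k)]
    } else {
      xi <- x[1:(n + k)]; yi <- y[(1 - k):n]
    }
    if (length(xi) < 3 || stats::sd(xi) == 0 || stats::sd(yi) == 0)
      return(NA_real_)
    stats::cor(xi, yi)
  }, 0)
  peak <- which.max(abs(r))
  structure(list(lag_s = lags[peak], correlation = r[peak],
                 lags_s = lags, r = r, n_overlap = n),
            class = "dbs_xcorr")
}

#' @export
print.dbs_xcorr <- function(x, ...) {
  cat(sprintf("<dbs_xcorr> peak r = %.3f at lag %+.2f s (n = %d)\n",
              x$correlation, x$lag_s, x$n_overlap))
  invisible(x)
}
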