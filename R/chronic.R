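# Chronic (out-of-clinic) analytics on Timeline and Events.
#
# The Timeline is a per-hemisphere band-power trend at 10-minute cadence
# spanning weeks; Events are patient-marked episodes, optionally carrying an
# on-device FFT snapshot. The analyses here mirror the standard chronic
# questions: what is the diurnal band-power profile, when during the day do
# episodes occur, how are symptom events timed relative to medication
# intakes, and how does band power evolve around an event.
#
# Circadian folding uses the session's local wall clock (pass the session's
# utc_offset_min); telemetry gaps are never interpolated across.

events_of <- function(events, name) {
  Filter(function(e) identical(e$name, name), events)
}

#' Circadian band-power profile of a Timeline
#'
#' Folds Timeline samples by wall-clock time of day into bins of
#' `bin_minutes` and summarizes each bin with the mean and the inter-quartile
#' range across all days (IQR is robust to single outlier days).
#'
#' @param tl a `dbs_timeline`.
#' @param bin_minutes bin width; must divide 24 h (default 30).
#' @param utc_offset_min session local-time offset, minutes east of UTC.
#' @return data.frame of class `dbs_circadian` with `bin_start_hours`
#'   (tiling `[0, 24)`), `mean_power`, `dispersion` (IQR), `n` per bin.
#' @export
circadian_profile <- function(tl, bin_minutes = dbsense_defaults()$chronic$circadian_bin_min,
                              utc_offset_min = 0L) {
  stopifnot(inherits(tl, "dbs_timeline"))
  if (!length(tl$timestamps))
    dbs_stop("circadian_profile: empty timeline", "dbsense_data_error")
  if (1440 %% bin_minutes != 0)
    dbs_stop("circadian_profile: bin_minutes must divide 24 h",
             "dbsense_validation_error")
  span_s <- diff(range(as.numeric(tl$timestamps)))
  cadence <- if (length(tl$timestamps) > 1)
    stats::median(diff(as.numeric(tl$timestamps))) else 0
  if (span_s + cadence < 86400 - 1)     # under one full day of coverage
    dbs_warn(sprintf("circadian_profile: only %.1f h of data (< 1 day); per-bin statistics rest on single observations",
                     span_s / 3600), "dbsense_data_warning")
  hrs <- wallclock_hours(tl$timestamps, utc_offset_min)
  nb <- as.integer(1440 / bin_minutes)
  bin <- pmin(floor(hrs * 60 / bin_minutes), nb - 1L) + 1L
  starts <- (seq_len(nb) - 1L) * bin_minutes / 60
  mean_power <- dispersion <- rep(NA_real_, nb)
  n <- integer(nb)
  for (b in seq_len(nb)) {
    v <- tl$band_power[bin == b]
    n[b] <- length(v)
    if (n[b] > 0) {
      mean_power[b] <- mean(v)
      dispersion[b] <- unname(diff(stats::quantile(v, c(0.25, 0.75))))
    }
  }
  structure(data.frame(bin_start_hours = starts, mean_power = mean_power,
                       dispersion = dispersion, n = n),
            class = c("dbs_circadian", "data.frame"),
            bin_minutes = bin_minutes, hemisphere = tl$hemisphere)
}

#' @export
plot.dbs_circadian <- function(x, ...) {
  ctr <- x$bin_start_hours + attr(x, "bin_minutes") / 120
  graphics::plot(ctr, x$mean_power, type = "l", lwd = 2,
                 xlab = "wall-clock hour", ylab = "band power (a.u.)",
                 main = sprintf("circadian profile (%s)",
                                attr(x, "hemisphere") %||% ""), ...)
  graphics::arrows(ctr, x$mean_power - x$dispersion / 2,
                   ctr, x$mean_power + x$dispersion / 2,
                   angle = 90, code = 3, length = 0.02, col = "grey50")
  invisible(x)
}

#' Daily distribution of an event type
#'
#' Counts events of one name by wall-clock hour-of-day bins (half-open:
#' an event at exactly midnight lands in `[0, bin)`).
#'
#' @param events list of event records (`$name`, `$time` POSIXct).
#' @param name event name to count.
#' @param bin_hours bin width in hours; must divide 24 (default 1).
#' @param utc_offset_min session local-time offset, minutes east of UTC.
#' @return list of class `dbs_event_hist`: `event_name`,
#'   `bin_edges_hours` (0..24), `counts`.
#' @export
event_daily_histogram <- function(events, name, bin_hours = 1,
                                  utc_offset_min = 0L) {
  if (24 %% bin_hours != 0)
    dbs_stop("event_daily_histogram: bin_hours must divide 24",
             "dbsense_validation_error")
  evs <- events_of(events, name)
  nb <- as.integer(24 / bin_hours)
  counts <- integer(nb)
  if (length(evs)) {
    hrs <- wallclock_hours(do.call(c, lapply(evs, `[[`, "time")),
                           utc_offset_min)
    idx <- pmin(floor(hrs / bin_hours), nb - 1L) + 1L
    tab <- tabulate(idx, nbins = nb)
    counts <- as.integer(tab)
  }
  structure(list(event_name = name,
                 bin_edges_hours = seq(0, 24, by = bin_hours),
                 counts = counts),
            class = "dbs_event_hist")
}

#' @export
print.dbs_event_hist <- function(x, ...) {
  cat(sprintf("<dbs_event_hist> '%s': %d event(s) over %d bins\n",
              x$event_name, sum(x$counts), length(x$counts)))
  invisible(x)
}

#' Offsets of target events relative to the nearest reference event
#'
#' For each target event, the signed offset in minutes to the nearest
#' reference event within `+/- window_min` (negative = target precedes the
#' reference). Exact ties between a preceding and a following reference are
#' broken toward the preceding one (negative offset); set
#' `nearest = FALSE` to pair with the most recent preceding reference only.
#' Targets with no reference in the window are excluded and counted.
#'
#' @param events list of event records.
#' @param reference_name,target_name event names.
#' @param window_min search half-window, minutes.
#' @param nearest pair to nearest reference (default) or preceding only.
#' @return list with `offsets_min` (one per paired target), `n_targets`,
#'   `n_excluded`.
#' @export
relative_event_offsets <- function(events, reference_name, target_name,
                                   window_min, nearest = TRUE) {
  refs <- as.numeric(do.call(c, c(list(as.POSIXct(character(0), tz = "UTC")),
                                  lapply(events_of(events, reference_name),
                                         `[[`, "time"))))
  tgts <- as.numeric(do.call(c, c(list(as.POSIXct(character(0), tz = "UTC")),
                                  lapply(events_of(events, target_name),
                                         `[[`, "time"))))
  offsets <- numeric(0)
  excluded <- 0L
  for (tt in tgts) {
    d <- (tt - refs) / 60                       # minutes, target - reference
    if (!nearest) d <- d[d >= 0]
    d <- d[abs(d) <= window_min]
    if (!length(d)) { excluded <- excluded + 1L; next }
    best <- d[order(abs(d), d)][1]              # ties -> negative (preceding)
    offsets <- c(offsets, best)
  }
  list(offsets_min = offsets, n_targets = length(tgts), n_excluded = excluded)
}

#' Event-triggered average of Timeline band power
#'
#' Resamples the Timeline onto a uniform lag grid around each event of the
#' given name (one step per Timeline cadence; nearest sample, never
#' interpolating across gaps longer than `gap_cadences` cadences), averages
#' across events, and attaches a seeded bootstrap 95% percentile CI. Events
#' whose window exceeds the Timeline range are excluded with reason
#' `"edge"`; lag positions falling in telemetry gaps are NA for that event.
#'
#' @param tl a `dbs_timeline`.
#' @param events list of event records.
#' @param name event name to trigger on.
#' @param window_min half-window, minutes (>= 2 Timeline cadences).
#' @param baseline subtract each event's pre-event (negative-lag) mean?
#' @param n_boot bootstrap resamples (default 1000).
#' @param boot_seed seed for the bootstrap (RNG state is restored).
#' @param gap_cadences largest bridgeable gap, in cadences (default 1).
#' @return object of class `dbs_eta`: `lags_min`, `mean_power`, `ci_low`,
#'   `ci_high`, `n_events_used`, `excluded` (named counts by reason),
#'   `per_event` matrix (events x lags).
#' @export
event_triggered_average <- function(tl, events, name, window_min,
                                    baseline = TRUE,
                                    n_boot = dbsense_defaults()$chronic$n_boot,
                                    boot_seed = dbsense_defaults()$chronic$boot_seed,
                                    gap_cadences = dbsense_defaults()$chronic$gap_cadences) {
  stopifnot(inherits(tl, "dbs_timeline"))
  ts <- as.numeric(tl$timestamps)
  if (length(ts) < 3)
    dbs_stop("event_triggered_average: timeline too short", "dbsense_data_error")
  cadence <- stats::median(diff(ts))
  if (window_min * 60 < 2 * cadence)
    dbs_stop(sprintf("event_triggered_average: window (%g min) must span >= 2 cadences (%g min each)",
                     window_min, cadence / 60), "dbsense_validation_error")
  lags_s <- seq(-window_min * 60, window_min * 60, by = cadence)
  evs <- events_of(events, name)
  if (!length(evs))
    dbs_stop(sprintf("event_triggered_average: no '%s' events", name),
             "dbsense_data_error")
  used <- list(); reasons <- character(0)
  for (e in evs) {
    te <- as.numeric(e$time)
    if (te - window_min * 60 < ts[1] || te + window_min * 60 > ts[length(ts)]) {
      reasons <- c(reasons, "edge"); next
    }
    want <- te + lags_s
    idx <- findInterval(want, ts)
    lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(ts))
    pick <- ifelse(abs(want - ts[lo]) <= abs(ts[hi] - want), lo, hi)
    dist <- abs(ts[pick] - want)
    row <- tl$band_power[pick]
    row[dist > gap_cadences * cadence] <- NA_real_   # never bridge gaps
    if (all(is.na(row))) { reasons <- c(reasons, "gap"); next }
    used[[length(used) + 1L]] <- row
  }
  if (!length(used)) {
    tab <- table(reasons)
    dbs_stop(sprintf("event_triggered_average: no usable '%s' events (%s)", name,
                     paste(sprintf("%s: %d", names(tab), as.integer(tab)),
                           collapse = ", ")), "dbsense_data_error")
  }
  m <- do.call(rbind, used)
  if (baseline) {
    pre <- lags_s < 0
    m <- m - rowMeans(m[, pre, drop = FALSE], na.rm = TRUE)
  }
  mean_power <- colMeans(m, na.rm = TRUE)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(boot_seed)
  nr <- nrow(m)
  boots <- matrix(NA_real_, n_boot, ncol(m))
  for (b in seq_len(n_boot)) {
    sel <- sample.int(nr, nr, replace = TRUE)
    boots[b, ] <- colMeans(m[sel, , drop = FALSE], na.rm = TRUE)
  }
  ci <- apply(boots, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  excluded <- if (length(reasons)) table(reasons) else table(character(0))
  dbs_log(sprintf("event_triggered_average('%s'): %d used, %d excluded",
                  name, nr, length(reasons)), level = "debug")
  structure(list(lags_min = lags_s / 60, mean_power = mean_power,
                 ci_low = ci[1, ], ci_high = ci[2, ],
                 n_events_used = nr,
                 excluded = excluded,
                 per_event = m, baseline = baseline, event_name = name),
            class = "dbs_eta")
}

#' @export
print.dbs_eta <- function(x, ...) {
  cat(sprintf("<dbs_eta> '%s': %d event(s) used, %d excluded; lags %g..%g min%s\n",
              x$event_name, x$n_events_used, sum(x$excluded),
              min(x$lags_min), max(x$lags_min),
              if (x$baseline) " (baseline-subtracted)" else ""))
  invisible(x)
}

#' @export
plot.dbs_eta <- function(x, ...) {
  graphics::plot(x$lags_min, x$mean_power, type = "l", lwd = 2,
                 ylim = range(c(x$ci_low, x$ci_high), na.rm = TRUE),
                 xlab = "lag (min)", ylab = "band power (a.u.)",
                 main = sprintf("event-triggered average: %s", x$event_name),
                 ...)
  graphics::lines(x$lags_min, x$ci_low, lty = 2, col = "grey50")
  graphics::lines(x$lags_min, x$ci_high, lty = 2, col = "grey50")
  graphics::abline(v = 0, col = "red3", lty = 3)
  invisible(x)
}

#' Median and quartile FFT-snapshot profile of an event type
#'
#' Pointwise median and quartiles across the FFT snapshots attached to
#' events of one name, on their common frequency grid. Snapshot-less events
#' are ignored (counted in `n_without`); snapshots on differing grids are an
#' error — resample upstream if devices disagree.
#'
#' @param events list of event records.
#' @param name event name.
#' @param hemisphere `"left"` or `"right"` snapshot to summarize.
#' @return object of class `dbs_event_spectra`: `event_name`, `freqs`,
#'   `median_power`, `q25`, `q75`, `n_snapshots`, `n_without`.
#' @export
event_spectra_summary <- function(events, name, hemisphere = "left") {
  evs <- events_of(events, name)
  snaps <- list(); n_without <- 0L
  for (e in evs) {
    s <- e$snapshot[[hemisphere]]
    if (is.null(s)) { n_without <- n_without + 1L; next }
    snaps[[length(snaps) + 1L]] <- s
  }
  if (!length(snaps))
    dbs_stop(sprintf("event_spectra_summary: no snapshot-bearing '%s' events (%d without snapshots)",
                     name, n_without), "dbsense_data_error")
  freqs <- snaps[[1]]$freqs
  for (s in snaps) {
    if (!isTRUE(all.equal(s$freqs, freqs)))
      dbs_stop("event_spectra_summary: snapshots are on different frequency grids; resample to a common grid first",
               "dbsense_data_error")
  }
  m <- do.call(rbind, lapply(snaps, `[[`, "power"))
  structure(list(event_name = name, freqs = freqs,
                 median_power = apply(m, 2, stats::median),
                 q25 = apply(m, 2, stats::quantile, 0.25),
                 q75 = apply(m, 2, stats::quantile, 0.75),
                 n_snapshots = length(snaps), n_without = n_without,
                 hemisphere = hemisphere),
            class = "dbs_event_spectra")
}

#' @export
print.dbs_event_spectra <- function(x, ...) {
  cat(sprintf("<dbs_event_spectra> '%s' (%s): %d snapshot(s) (%d events without), %d freq bins %g-%g Hz\n",
              x$event_name, x$hemisphere, x$n_snapshots, x$n_without,
              length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}
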