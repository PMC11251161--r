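# Cardiac-artifact detection and template-subtraction cleaning.
#
# LFPs sensed from DBS leads are frequently contaminated by the ECG (the
# extension cable runs near the heart). The cleaner follows the classical
# template-subtraction recipe: detect QRS-like peaks on a band-passed copy,
# verify that the inter-peak intervals are periodic at a plausible heart
# rate, average peak-centered windows into a template, and subtract the
# template at each peak with a per-peak least-squares amplitude. If the
# periodicity/rate gate fails, the signal is returned untouched.

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

pick_peaks <- function(x, threshold, min_dist) {
  cand <- local_maxima(x)
  cand <- cand[x[cand] >= threshold]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= min_dist)) kept <- c(kept, i)
  }
  sort(kept)
}

new_cleaning_report <- function(cleaned, n_peaks, mean_rate_bpm, template,
                                peak_indices, periodicity_score, eligible) {
  structure(list(cleaned = cleaned, n_peaks = n_peaks,
                 mean_rate_bpm = mean_rate_bpm, template = template,
                 peak_indices = peak_indices,
                 periodicity_score = periodicity_score, eligible = eligible),
            class = "dbs_cleaning_report")
}

#' @export
print.dbs_cleaning_report <- function(x, ...) {
  cat(sprintf("<dbs_cleaning_report> %d peak(s), rate %.1f bpm, periodicity %.2f, eligible: %s, cleaned: %s\n",
              x$n_peaks, x$mean_rate_bpm %||% NA_real_, x$periodicity_score,
              x$eligible, x$cleaned))
  invisible(x)
}

#' Detect cardiac-artifact peaks in an LFP trace
#'
#' Band-passes a copy of the signal (default 0.5-30 Hz, where the QRS
#' complex lives), picks amplitude-threshold peaks on the dominant polarity
#' with a refractory spacing, and scores periodicity as the fraction of
#' successive inter-peak intervals within +/-20% of their median.
#' The trace is *cleaning-eligible* iff the periodicity score is >= 0.8 and
#' the implied rate lies in 40-120 bpm — white noise or genuine oscillations
#' fail this gate by construction.
#'
#' All thresholds are configurable via `config` (see [dbsense_defaults()],
#' section `ecg`); they are pragmatic stand-ins, not clinical constants.
#'
#' @param signal numeric trace, microvolts.
#' @param fs sampling rate, Hz.
#' @param config ECG parameter list (`dbsense_defaults()$ecg`).
#' @return `dbs_cleaning_report` with detection fields (`cleaned` is FALSE;
#'   `peak_indices` are 1-based sample indices).
#' @export
detect_ecg <- function(signal, fs, config = dbsense_defaults()$ecg) {
  if (length(signal) / fs < 10)
    dbs_stop(sprintf("ECG detection needs >= 10 s of signal (got %.1f s)",
                     length(signal) / fs), "dbsense_duration_error")
  cf <- butter_coeffs(2, config$band, fs, type = "pass")
  xf <- filtfilt_ba(cf$b, cf$a, signal)
  sigma <- mad_sigma(xf)
  if (sigma == 0) {
    return(new_cleaning_report(FALSE, 0L, NA_real_, NULL, integer(0), 0, FALSE))
  }
  thr <- config$threshold_sigmas * sigma
  min_dist <- round(config$min_spacing_s * fs)
  # detect on the dominant polarity so a flipped lead still works
  pk_pos <- pick_peaks(xf, thr, min_dist)
  pk_neg <- pick_peaks(-xf, thr, min_dist)
  peaks <- if (length(pk_pos) >= length(pk_neg)) pk_pos else pk_neg
  if (length(peaks) < 3) {
    return(new_cleaning_report(FALSE, length(peaks), NA_real_, NULL, peaks,
                               0, FALSE))
  }
  ipi <- diff(peaks)
  med <- stats::median(ipi)
  score <- mean(abs(ipi - med) <= config$interval_tol * med)
  rate <- 60 * fs / med
  eligible <- score >= config$score_min &&
    rate >= config$rate_bpm[1] && rate <= config$rate_bpm[2]
  dbs_log(sprintf("detect_ecg: %d peaks, %.1f bpm, periodicity %.2f -> eligible %s",
                  length(peaks), rate, score, eligible), level = "debug")
  new_cleaning_report(FALSE, length(peaks), rate, NULL, peaks, score, eligible)
}

#' Remove the cardiac artifact from one channel by template subtraction
#'
#' Runs [detect_ecg()] on the chosen channel; if the trace is
#' cleaning-eligible, builds the artifact template as the mean of
#' peak-centered windows (half-width 0.3x the median inter-peak interval,
#' capped at 200 ms) and subtracts it at every detected peak with a per-peak
#' least-squares amplitude. Samples farther than one template half-width
#' from any peak are never altered. An ineligible trace is returned
#' unchanged with `cleaned = FALSE`.
#'
#' @param rec a `dbs_td` recording or a bare numeric vector (then give `fs`).
#' @param channel channel label or index (ignored for vector input).
#' @param fs sampling rate for vector input.
#' @param config ECG parameter list (see [dbsense_defaults()]).
#' @return list with `rec` (same type as the input, cleaned channel
#'   replaced) and `report` (a `dbs_cleaning_report` with the template).
#' @export
clean_ecg <- function(rec, channel = 1L, fs = NULL,
                      config = dbsense_defaults()$ecg) {
  vec_input <- is.numeric(rec)
  if (vec_input) {
    x <- rec
    stopifnot(!is.null(fs))
  } else {
    stopifnot(inherits(rec, "dbs_td"))
    fs <- rec$fs
    x <- rec$samples[channel, ]
  }
  report <- detect_ecg(x, fs, config)
  if (!report$eligible) {
    dbs_log("clean_ecg: trace not cleaning-eligible, returned unchanged",
            level = "debug")
    return(list(rec = rec, report = report))
  }
  peaks <- report$peak_indices
  med_ipi <- stats::median(diff(peaks))
  half <- min(round(config$template_halfwidth_factor * med_ipi),
              round(config$template_halfwidth_max_s * fs))
  half <- max(half, 2L)
  n <- length(x)
  full <- peaks[(peaks - half) >= 1 & (peaks + half) <= n]
  if (length(full) < 3) {
    report$eligible <- FALSE
    return(list(rec = rec, report = report))
  }
  wins <- vapply(full, function(p) x[(p - half):(p + half)],
                 numeric(2 * half + 1))
  template <- rowMeans(wins)
  template <- template - mean(template)     # artifact is zero-mean transient
  y <- x
  for (p in peaks) {
    idx <- (p - half):(p + half)
    ok <- idx >= 1 & idx <= n
    alpha <- sum(y[idx[ok]] * template[ok]) / sum(template[ok]^2)
    y[idx[ok]] <- y[idx[ok]] - alpha * template[ok]
  }
  report$cleaned <- TRUE
  report$template <- template
  dbs_log(sprintf("clean_ecg: subtracted template (half-width %d samples) at %d peak(s)",
                  half, length(peaks)), level = "debug")
  if (vec_input) return(list(rec = y, report = report))
  rec$samples[channel, ] <- y
  list(rec = rec, report = report)
}
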