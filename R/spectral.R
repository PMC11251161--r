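# Spectral estimators: Welch PSD, sliding band power, Morlet scalogram.
#
# The scalogram uses a constant-Q complex Morlet (default 7 cycles) on a
# log-spaced frequency grid, matching the usual presentation of DBS LFP
# time-frequency maps (log y-axis, 1-100 Hz). Magnitudes are normalized so
# a unit-amplitude sine at an interior frequency reads ~1.

coerce_signal <- function(rec, fs, channel = 1L) {
  if (is.numeric(rec)) {
    stopifnot(!is.null(fs))
    list(x = as.numeric(rec), fs = fs, label = "signal",
         start_time = NULL)
  } else {
    stopifnot(inherits(rec, "dbs_td"))
    list(x = rec$samples[channel, ], fs = rec$fs,
         label = rownames(rec$samples)[channel] %||% as.character(channel),
         start_time = rec$start_time)
  }
}

hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

# one-sided Hann-windowed periodogram, density scaling (a.u.^2 / Hz)
periodogram_hann <- function(x, fs) {
  n <- length(x)
  w <- hann(n)
  x <- (x - mean(x)) * w
  X <- stats::fft(x)
  nf <- floor(n / 2) + 1
  p <- (Mod(X[1:nf])^2) / (fs * sum(w^2))
  mult <- rep(2, nf); mult[1] <- 1
  if (n %% 2 == 0) mult[nf] <- 1
  list(freqs = (0:(nf - 1)) * fs / n, power = p * mult)
}

#' Welch power spectral density
#'
#' Averaged Hann-windowed periodogram over overlapping segments, density
#' scaling (signal units squared per Hz): integrating the estimate over
#' `[0, fs/2]` recovers the signal variance (Parseval).
#'
#' @param rec a `dbs_td` recording (all channels estimated) or a numeric
#'   vector (then give `fs`).
#' @param window_s segment length in seconds (default 2).
#' @param overlap fractional overlap between segments (default 0.5).
#' @param fs sampling rate for vector input.
#' @return object of class `dbs_psd`: `freqs` (Hz), `power`
#'   (channels x freqs matrix), `window_s`, `overlap`, `channels`, `fs`.
#' @export
welch_psd <- function(rec, window_s = dbsense_defaults()$welch$window_s,
                      overlap = dbsense_defaults()$welch$overlap, fs = NULL) {
  mats <- if (is.numeric(rec)) {
    stopifnot(!is.null(fs))
    matrix(as.numeric(rec), nrow = 1, dimnames = list("signal", NULL))
  } else {
    stopifnot(inherits(rec, "dbs_td"))
    fs <- rec$fs
    rec$samples
  }
  n <- ncol(mats)
  nper <- round(window_s * fs)
  if (n < 2 * nper)
    dbs_stop(sprintf("welch_psd needs >= 2x the window (%.1f s) of signal, got %.1f s",
                     window_s, n / fs), "dbsense_duration_error")
  if (overlap < 0 || overlap >= 1)
    dbs_stop("welch_psd: overlap must be in [0, 1)", "dbsense_validation_error")
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, n - nper + 1L, by = step)
  nf <- floor(nper / 2) + 1
  power <- matrix(0, nrow = nrow(mats), ncol = nf,
                  dimnames = list(rownames(mats), NULL))
  freqs <- (0:(nf - 1)) * fs / nper
  for (ch in seq_len(nrow(mats))) {
    acc <- numeric(nf)
    for (s in starts) {
      pg <- periodogram_hann(mats[ch, s:(s + nper - 1L)], fs)
      acc <- acc + pg$power
    }
    power[ch, ] <- acc / length(starts)
  }
  structure(list(freqs = freqs, power = power, window_s = window_s,
                 overlap = overlap, channels = rownames(mats), fs = fs),
            class = "dbs_psd")
}

#' @export
print.dbs_psd <- function(x, ...) {
  cat(sprintf("<dbs_psd> %d channel(s), %d bins 0-%g Hz (window %g s, overlap %g)\n",
              nrow(x$power), length(x$freqs), max(x$freqs), x$window_s,
              x$overlap))
  invisible(x)
}

#' @export
plot.dbs_psd <- function(x, log = "y", ...) {
  graphics::matplot(x$freqs, t(pmax(x$power, .Machine$double.xmin)),
                    type = "l", lty = 1, log = log, xlab = "frequency (Hz)",
                    ylab = expression(PSD ~ (a.u.^2/Hz)), ...)
  graphics::legend("topright", legend = x$channels, lty = 1,
                   col = seq_along(x$channels), bty = "n", cex = 0.8)
  invisible(x)
}

#' Integrate a PSD estimate over a band
#'
#' @param psd a `dbs_psd`.
#' @param band `c(low, high)` Hz, inclusive.
#' @return named numeric vector, one integrated power per channel.
#' @export
band_power <- function(psd, band) {
  stopifnot(inherits(psd, "dbs_psd"))
  df <- psd$freqs[2] - psd$freqs[1]
  sel <- psd$freqs >= band[1] & psd$freqs <= band[2]
  out <- rowSums(psd$power[, sel, drop = FALSE]) * df
  stats::setNames(out, psd$channels)
}

#' Sliding band-power time series
#'
#' Integrated Hann-periodogram power within a band, over sliding windows;
#' timestamps are window centers in seconds from the recording start.
#'
#' @param rec `dbs_td` or numeric vector (with `fs`).
#' @param band `c(low, high)` Hz; must lie below Nyquist.
#' @param window_s window length (default 1 s).
#' @param step_s hop between windows (default `window_s / 2`).
#' @param channel channel (label or index) for multichannel input.
#' @param fs sampling rate for vector input.
#' @return data.frame with `time_s` (window centers) and `power` (a.u.);
#'   attribute `start_time` carries the absolute origin when known.
#' @export
band_power_series <- function(rec, band, window_s = 1, step_s = window_s / 2,
                              channel = 1L, fs = NULL) {
  sig <- coerce_signal(rec, fs, channel)
  if (length(band) != 2 || band[1] < 0 || band[2] <= band[1] ||
      band[2] > sig$fs / 2)
    dbs_stop(sprintf("band_power_series: band must be 0 <= low < high <= Nyquist (%g Hz)",
                     sig$fs / 2), "dbsense_validation_error")
  win <- round(window_s * sig$fs)
  step <- max(1L, round(step_s * sig$fs))
  n <- length(sig$x)
  if (n < win)
    dbs_stop("band_power_series: recording shorter than one window",
             "dbsense_duration_error")
  starts <- seq(1L, n - win + 1L, by = step)
  power <- numeric(length(starts))
  for (i in seq_along(starts)) {
    pg <- periodogram_hann(sig$x[starts[i]:(starts[i] + win - 1L)], sig$fs)
    df <- pg$freqs[2] - pg$freqs[1]
    sel <- pg$freqs >= band[1] & pg$freqs <= band[2]
    power[i] <- sum(pg$power[sel]) * df
  }
  out <- data.frame(time_s = (starts - 1 + win / 2) / sig$fs, power = power)
  attr(out, "start_time") <- sig$start_time
  attr(out, "band") <- band
  out
}

#' Morlet-wavelet scalogram on a log-spaced frequency grid
#'
#' Continuous wavelet transform magnitude with a constant-Q complex Morlet
#' (`cycles` cycles per wavelet, default 7). Frequencies are exactly
#' log-spaced between `fmin` and `fmax`. The cone of influence —
#' `cycles / (2 f)` seconds at each frequency — is reported in `coi_s`;
#' values inside it are retained but should be treated as edge-contaminated.
#'
#' @param rec `dbs_td` or numeric vector (with `fs`).
#' @param fmin,fmax frequency range, Hz (`fmin >= 1`, `fmax < fs/2`).
#' @param n_freqs number of log-spaced frequencies (default 60).
#' @param cycles wavelet cycles (default 7).
#' @param channel channel for multichannel input.
#' @param fs sampling rate for vector input.
#' @return object of class `dbs_scalogram`: `freqs`, `times`, `magnitude`
#'   (freqs x times), `cycles`, `coi_s`, `fs`, `channel`.
#' @export
morlet_scalogram <- function(rec, fmin = dbsense_defaults()$scalogram$fmin,
                             fmax = dbsense_defaults()$scalogram$fmax,
                             n_freqs = dbsense_defaults()$scalogram$n_freqs,
                             cycles = dbsense_defaults()$scalogram$cycles,
                             channel = 1L, fs = NULL) {
  sig <- coerce_signal(rec, fs, channel)
  if (fmin < 1 || fmax <= fmin || fmax >= sig$fs / 2)
    dbs_stop(sprintf("morlet_scalogram: need 1 <= fmin < fmax < Nyquist (%g Hz)",
                     sig$fs / 2), "dbsense_validation_error")
  freqs <- exp(seq(log(fmin), log(fmax), length.out = n_freqs))
  n <- length(sig$x)
  nfft <- stats::nextn(2L * n, 2)
  X <- stats::fft(c(sig$x, rep(0, nfft - n)))
  mag <- matrix(0, nrow = n_freqs, ncol = n)
  for (i in seq_len(n_freqs)) {
    f <- freqs[i]
    sigma_t <- cycles / (2 * pi * f)
    half <- min(ceiling(4 * sigma_t * sig$fs), floor((n - 1) / 2))
    tt <- (-half:half) / sig$fs
    g <- exp(-tt^2 / (2 * sigma_t^2))
    kern <- g * exp(2i * pi * f * tt) / sum(g)
    klen <- length(kern)
    K <- stats::fft(c(kern, rep(0, nfft - klen)))
    conv <- stats::fft(X * K, inverse = TRUE) / nfft
    mag[i, ] <- 2 * Mod(conv[(half + 1):(half + n)])
  }
  structure(list(freqs = freqs, times = (seq_len(n) - 1) / sig$fs,
                 magnitude = mag, cycles = cycles,
                 coi_s = cycles / (2 * freqs), fs = sig$fs,
                 channel = sig$label),
            class = "dbs_scalogram")
}

#' @export
print.dbs_scalogram <- function(x, ...) {
  cat(sprintf("<dbs_scalogram> channel %s: %d log-spaced freqs %g-%g Hz x %d times (%.1f s), %g cycles\n",
              x$channel, length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), max(x$times), x$cycles))
  invisible(x)
}

#' @export
plot.dbs_scalogram <- function(x, ...) {
  graphics::image(x$times, log10(x$freqs), t(x$magnitude),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "time (s)", ylab = "log10 frequency (Hz)",
                  main = sprintf("scalogram: %s", x$channel), ...)
  invisible(x)
}
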