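# Butterworth design + zero-phase (forward-backward) filtering.
#
# Implemented from the analog prototype via zpk band transforms and the
# bilinear transform (the environment ships no DSP package). Filters are
# always applied forward-backward, so the effective magnitude response is
# |H|^2 and the phase response is identically zero — a requirement for the
# time-locked analyses downstream.

butter_zpk <- function(n) {
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  list(z = complex(0), p = p, k = 1)
}

lp2bp_zpk <- function(zpk, wo, bw) {
  deg <- length(zpk$p) - length(zpk$z)
  zl <- zpk$z * bw / 2; pl <- zpk$p * bw / 2
  list(z = c(zl + sqrt(zl^2 - wo^2), zl - sqrt(zl^2 - wo^2), rep(0+0i, deg)),
       p = c(pl + sqrt(pl^2 - wo^2), pl - sqrt(pl^2 - wo^2)),
       k = zpk$k * bw^deg)
}

lp2bs_zpk <- function(zpk, wo, bw) {
  deg <- length(zpk$p) - length(zpk$z)
  zh <- (bw / 2) / zpk$z; ph <- (bw / 2) / zpk$p
  zh <- zh[is.finite(zh)]
  list(z = c(zh + sqrt(zh^2 - wo^2), zh - sqrt(zh^2 - wo^2),
             rep(1i * wo, deg), rep(-1i * wo, deg)),
       p = c(ph + sqrt(ph^2 - wo^2), ph - sqrt(ph^2 - wo^2)),
       k = zpk$k * Re(prod(-zpk$z) / prod(-zpk$p)))
}

lp2hp_zpk <- function(zpk, wo) {
  deg <- length(zpk$p) - length(zpk$z)
  num <- if (length(zpk$z)) prod(-zpk$z) else 1+0i
  list(z = c(wo / zpk$z, rep(0+0i, deg))[is.finite(c(wo / zpk$z, rep(0+0i, deg)))],
       p = wo / zpk$p,
       k = zpk$k * Re(num / prod(-zpk$p)))
}

lp2lp_zpk <- function(zpk, wo) {
  deg <- length(zpk$p) - length(zpk$z)
  list(z = zpk$z * wo, p = zpk$p * wo, k = zpk$k * wo^deg)
}

bilinear_zpk <- function(zpk, fs) {
  fs2 <- 2 * fs
  deg <- length(zpk$p) - length(zpk$z)
  zd <- (fs2 + zpk$z) / (fs2 - zpk$z)
  pd <- (fs2 + zpk$p) / (fs2 - zpk$p)
  kd <- zpk$k * Re(prod(fs2 - zpk$z) / prod(fs2 - zpk$p))
  list(z = c(zd, rep(-1+0i, deg)), p = pd, k = kd)
}

poly_from_roots <- function(r) {
  cf <- 1+0i
  for (root in r) cf <- c(cf, 0+0i) - c(0+0i, cf) * root
  Re(cf)
}

# digital Butterworth coefficients; edges in Hz
butter_coeffs <- function(n, edges, fs,
                          type = c("pass", "stop", "low", "high")) {
  type <- match.arg(type)
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  proto <- butter_zpk(n)
  analog <- switch(type,
    pass = {
      w <- warp(edges); lp2bp_zpk(proto, sqrt(w[1] * w[2]), w[2] - w[1])
    },
    stop = {
      w <- warp(edges); lp2bs_zpk(proto, sqrt(w[1] * w[2]), w[2] - w[1])
    },
    low = lp2lp_zpk(proto, warp(edges[1])),
    high = lp2hp_zpk(proto, warp(edges[1])))
  d <- bilinear_zpk(analog, fs)
  list(b = d$k * poly_from_roots(d$z), a = poly_from_roots(d$p))
}

# single-pass complex frequency response at frequencies f (Hz)
freqz_ba <- function(b, a, f, fs) {
  zi <- exp(-1i * 2 * pi * f / fs)
  num <- Reduce(function(acc, cf) acc * zi + cf, b, accumulate = FALSE,
                init = 0+0i)
  den <- Reduce(function(acc, cf) acc * zi + cf, a, accumulate = FALSE,
                init = 0+0i)
  num / den
}

iir_filter <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b)
  z <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution", sides = 1)
  z <- as.numeric(z)[nb:(nb - 1 + length(x))]
  if (length(a) > 1) {
    z <- as.numeric(stats::filter(z, -a[-1], method = "recursive"))
  }
  z
}

# zero-phase forward-backward filtering with odd-reflection padding.
# The pad must outlast the filter's own settling time (set by its slowest
# pole), not just 3x the order — a 0.5 Hz corner settles over seconds.
filtfilt_ba <- function(b, a, x) {
  nfact <- 3L * (max(length(a), length(b)) - 1L)
  poles <- polyroot(rev(a))
  pmax_mod <- max(Mod(poles))
  if (is.finite(pmax_mod) && pmax_mod < 1) {
    nfact <- max(nfact, ceiling(log(1e-9) / log(pmax_mod)))
  } else {
    nfact <- nfact * 10L
  }
  n <- length(x)
  if (n <= 3L * (max(length(a), length(b)) - 1L))
    dbs_stop(sprintf(
      "signal too short to filter: %d samples but the zero-phase filter needs > %d; use a shorter filter order or a longer recording",
      n, 3L * (max(length(a), length(b)) - 1L)), "dbsense_padding_error")
  nfact <- min(nfact, n - 1L)
  ext <- c(2 * x[1] - x[(nfact + 1):2], x, 2 * x[n] - x[(n - 1):(n - nfact)])
  y <- iir_filter(b, a, ext)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(nfact + 1):(nfact + n)]
}

merge_intervals <- function(ints) {
  if (!length(ints)) return(list())
  ints <- ints[order(vapply(ints, `[`, 0, 1))]
  out <- list(ints[[1]])
  for (iv in ints[-1]) {
    last <- out[[length(out)]]
    if (iv[1] <= last[2]) out[[length(out)]] <- c(last[1], max(last[2], iv[2]))
    else out[[length(out) + 1L]] <- iv
  }
  out
}

#' Specify a band filter
#'
#' Describes a customized filter to highlight one or more bands of interest
#' (e.g. beta, 13-35 Hz), or to remove them.
#'
#' @param passbands list of `c(low_hz, high_hz)` bands (a single `c(lo, hi)`
#'   is accepted); overlapping bands are merged to their union.
#' @param order Butterworth order per band (even; default 4).
#' @param kind `"highlight"` (pass the union of the bands, the default; the
#'   synonym `"bandpass"` is accepted) or `"bandstop"` (remove the bands).
#' @return object of class `dbs_filter_spec`.
#' @export
band_filter_spec <- function(passbands, order = 4L,
                             kind = c("highlight", "bandpass", "bandstop")) {
  kind <- match.arg(kind)
  if (is.numeric(passbands)) passbands <- list(passbands)
  if (!length(passbands))
    dbs_stop("band_filter_spec: 'passbands' must contain at least one band",
             "dbsense_validation_error")
  for (b in passbands) {
    if (length(b) != 2 || !all(is.finite(b)) || b[1] <= 0 || b[2] <= b[1])
      dbs_stop("band_filter_spec: each band must be c(low, high) with 0 < low < high",
               "dbsense_validation_error")
  }
  if (order < 1 || order %% 2 != 0)
    dbs_stop("band_filter_spec: 'order' must be a positive even integer",
             "dbsense_validation_error")
  structure(list(passbands = merge_intervals(passbands),
                 order = as.integer(order), kind = kind),
            class = "dbs_filter_spec")
}

#' Design a zero-phase band filter for a sampling rate
#'
#' Builds even-order Butterworth coefficients per band. `highlight` (and
#' `bandpass`) filters are applied as a parallel bank — the output is the sum
#' of the band-passed components, so the response is (approximately) unity
#' over the union of the passbands and strongly attenuated elsewhere;
#' `bandstop` filters are cascaded. All application is forward-backward, so
#' the returned `response(f)` is the effective zero-phase magnitude
#' (|H(f)|^2 per pass).
#'
#' Like any finite-recording zero-phase filter (pad-based forward-backward
#' application, as in scipy/MATLAB `filtfilt`), edge transients remain within
#' a settling region at each end of the output; its length is reported as
#' `settle_samples` / `settle_s` so analyses can trim or annotate it. The
#' steady-state behavior matches `response(f)` (the example oracle).
#'
#' @param spec a [band_filter_spec()] (or a bare `c(low, high)` / list of
#'   bands, taken as a highlight spec with defaults).
#' @param fs sampling rate, Hz.
#' @return object of class `dbs_filter`: coefficients per band, the spec,
#'   `fs`, `response` (a vectorized function of frequency in Hz giving the
#'   effective zero-phase gain), and `settle_samples`/`settle_s`.
#' @export
design_filter <- function(spec, fs) {
  if (!inherits(spec, "dbs_filter_spec")) spec <- band_filter_spec(spec)
  for (b in spec$passbands) {
    if (b[2] >= fs / 2)
      dbs_stop(sprintf("band edge %g Hz is at or above Nyquist (%g Hz)",
                       b[2], fs / 2), "dbsense_validation_error")
  }
  type <- if (spec$kind == "bandstop") "stop" else "pass"
  coefs <- lapply(spec$passbands, function(b)
    butter_coeffs(spec$order, b, fs, type = type))
  # edge-settling length from the slowest pole (forward-backward filtering
  # leaves in-band transients within this many samples of each edge)
  settle <- max(vapply(coefs, function(cf) {
    pm <- max(Mod(polyroot(rev(cf$a))))
    if (is.finite(pm) && pm < 1) ceiling(log(1e-9) / log(pm))
    else 30L * (length(cf$a) - 1L)
  }, 0))
  stop_kind <- spec$kind == "bandstop"
  response <- function(f) {
    mags <- vapply(coefs, function(cf)
      abs(freqz_ba(cf$b, cf$a, f, fs))^2, numeric(length(f)))
    mags <- matrix(mags, nrow = length(f))
    if (stop_kind) apply(mags, 1, prod) else rowSums(mags)
  }
  structure(list(spec = spec, fs = fs, coefs = coefs, response = response,
                 settle_samples = as.integer(settle), settle_s = settle / fs),
            class = "dbs_filter")
}

#' @export
print.dbs_filter <- function(x, ...) {
  bands <- paste(vapply(x$spec$passbands, function(b)
    sprintf("%g-%g Hz", b[1], b[2]), ""), collapse = ", ")
  cat(sprintf("<dbs_filter %s order %d @ %g Hz> bands: %s\n",
              x$spec$kind, x$spec$order, x$fs, bands))
  invisible(x)
}

# zero-phase application to one numeric series
apply_filter_signal <- function(x, filt) {
  if (filt$spec$kind == "bandstop") {
    for (cf in filt$coefs) x <- filtfilt_ba(cf$b, cf$a, x)
    x
  } else {
    Reduce(`+`, lapply(filt$coefs, function(cf) filtfilt_ba(cf$b, cf$a, x)))
  }
}

#' Apply a zero-phase band filter to a time-domain recording
#'
#' @param rec a `dbs_td` recording (or a bare numeric vector, in which case
#'   `fs` must be given).
#' @param spec a [band_filter_spec()], a designed [design_filter()] object,
#'   or a bare band `c(low, high)`.
#' @param fs sampling rate, required only for bare numeric input.
#' @return an object of the same shape: filtered `dbs_td` with identical
#'   labels, rate and start time, or a numeric vector.
#' @export
apply_filter <- function(rec, spec, fs = NULL) {
  if (is.numeric(rec)) {
    filt <- if (inherits(spec, "dbs_filter")) spec else design_filter(spec, fs)
    return(apply_filter_signal(rec, filt))
  }
  stopifnot(inherits(rec, "dbs_td"))
  filt <- if (inherits(spec, "dbs_filter")) spec else design_filter(spec, rec$fs)
  out <- rec
  for (ch in seq_len(nrow(rec$samples)))
    out$samples[ch, ] <- apply_filter_signal(rec$samples[ch, ], filt)
  out
}
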