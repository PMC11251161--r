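# Filtering, ECG cleaning, artifact screening.

fs <- 250
tgrid <- seq(1/fs, 60, by = 1/fs)

test_that("highlight filter passes the band and attenuates outside", {
  filt <- design_filter(band_filter_spec(c(13, 35)), fs)
  expect_lt(abs(filt$response(20) - 1), 0.05)
  expect_lte(20 * log10(filt$response(50)), -40)

  f2 <- design_filter(band_filter_spec(list(c(4, 12), c(13, 35))), fs)
  expect_lt(abs(f2$response(8) - 1), 0.05)
  expect_lt(abs(f2$response(20) - 1), 0.05)
  expect_lt(f2$response(50), 0.01)

  expect_error(band_filter_spec(list()), class = "dbsense_validation_error")
  expect_error(design_filter(band_filter_spec(c(13, 130)), fs),
               "Nyquist", class = "dbsense_validation_error")
  # overlapping bands are merged to their union
  spec <- band_filter_spec(list(c(10, 20), c(15, 30)))
  expect_equal(spec$passbands, list(c(10, 30)))
})

test_that("apply_filter is in-band transparent, out-of-band opaque, zero-phase", {
  filt <- design_filter(band_filter_spec(c(13, 35)), fs)
  x20 <- sin(2 * pi * 20 * tgrid)
  x50 <- sin(2 * pi * 50 * tgrid)
  y20 <- apply_filter(x20, filt)
  y50 <- apply_filter(x50, filt)
  expect_lt(abs(rms(y20) / rms(x20) - 1), 0.05)
  # stop-band rejection measured on the settled region (the filter reports
  # its pole-derived edge-settling length; edges carry junction transients,
  # exactly as in scipy/MATLAB filtfilt)
  st <- filt$settle_samples
  steady <- (st + 1):(length(y50) - st)
  expect_lte(rms(y50[steady]) / rms(x50[steady]), 0.01)
  expect_identical(apply_filter(rep(0, 5000), filt), rep(0, 5000))

  # zero-phase: no lag between in-band input and output
  core <- 2000:13000
  cc <- stats::ccf(y20[core], x20[core], lag.max = 25, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # dbs_td in/out preserves shape and labels
  rec <- td_recording(rbind(x20, x50), fs, c("a", "b"))
  out <- apply_filter(rec, filt)
  expect_identical(dim(out$samples), dim(rec$samples))
  expect_identical(rownames(out$samples), c("a", "b"))
  expect_equal(out$fs, fs)

  expect_error(apply_filter(rnorm(10), filt),
               class = "dbsense_padding_error")
})

test_that("filtering is linear (property, seeded)", {
  filt <- design_filter(band_filter_spec(c(13, 35)), fs)
  set.seed(99)
  for (i in 1:5) {
    x <- rnorm(3000); y <- rnorm(3000)
    a <- runif(1, -3, 3); b <- runif(1, -3, 3)
    lhs <- apply_filter(a * x + b * y, filt)
    rhs <- a * apply_filter(x, filt) + b * apply_filter(y, filt)
    expect_lt(max(abs(lhs - rhs)), 1e-8 * max(1, max(abs(lhs))))
  }
})

test_that("detect_ecg finds injected peaks and rejects noise", {
  fx <- fx_default()
  tr <- fx$truth
  x <- fx$session$streamings[[1]]$td$samples[tr$ecg$channel, ]
  rep <- detect_ecg(x, fs)
  expect_true(rep$eligible)
  expect_lte(abs(rep$n_peaks - length(tr$ecg$peak_samples_r)), 1)
  dist <- vapply(tr$ecg$peak_samples_r,
                 function(p) min(abs(rep$peak_indices - p)), 0)
  expect_true(all(dist <= 2))
  expect_gte(rep$mean_rate_bpm, 40); expect_lte(rep$mean_rate_bpm, 120)

  set.seed(12)
  noise <- rnorm(60 * fs, 0, 5)
  expect_false(detect_ecg(noise, fs)$eligible)

  flat <- detect_ecg(rep(0, 20 * fs), fs)
  expect_equal(flat$n_peaks, 0)
  expect_false(flat$eligible)

  expect_error(detect_ecg(rnorm(5 * fs), fs), class = "dbsense_duration_error")
})

test_that("clean_ecg removes most of the artifact and touches nothing else", {
  fx <- fx_default()
  tr <- fx$truth
  rec <- fx$session$streamings[[1]]$td
  res <- clean_ecg(rec, tr$ecg$channel)
  expect_true(res$report$cleaned)
  resid <- res$rec$samples[tr$ecg$channel, ] - tr$ecg$artifact_free_signal
  expect_lte(rms(resid) / rms(tr$ecg$artifact), 0.20)

  # never alters samples farther than one template half-width from a peak
  half <- (length(res$report$template) - 1) / 2
  x <- rec$samples[tr$ecg$channel, ]
  near <- rep(FALSE, length(x))
  for (p in res$report$peak_indices) {
    idx <- max(1, p - half):min(length(x), p + half)
    near[idx] <- TRUE
  }
  expect_identical(res$rec$samples[tr$ecg$channel, !near], x[!near])
  # other channel untouched
  other <- setdiff(rownames(rec$samples), tr$ecg$channel)
  expect_identical(res$rec$samples[other, ], rec$samples[other, ])

  # ineligible inputs come back unchanged
  set.seed(4)
  noise <- rnorm(30 * fs, 0, 5)
  out <- clean_ecg(noise, fs = fs)
  expect_false(out$report$cleaned)
  expect_identical(out$rec, noise)
  sine <- sin(2 * pi * 20 * tgrid)
  out2 <- clean_ecg(sine, fs = fs)
  expect_false(out2$report$cleaned)
  expect_identical(out2$rec, sine)
})

test_that("stim transitions are flagged at every amplitude change", {
  fx <- fx_titration()
  fl <- flag_stim_transitions(fx$session$streamings[[1]])
  expect_equal(fl$stim_transitions$time_s, c(30, 60, 90))
  expect_equal(fl$stim_transitions$end_s - fl$stim_transitions$start_s,
               rep(2, 3))

  # constant stim -> zero transitions
  fx0 <- fx_default()
  fl0 <- flag_stim_transitions(fx0$session$streamings[[1]])
  expect_equal(nrow(fl0$stim_transitions), 0)

  # missing stim trace -> empty + warning
  sr <- fx0$session$streamings[[1]]
  sr$power_stream <- list()
  expect_warning(fle <- flag_stim_transitions(sr),
                 class = "dbsense_missing_warning")
  expect_equal(nrow(fle$stim_transitions), 0)
})

test_that("broadband screen flags injected bursts and is idempotent", {
  set.seed(31)
  x <- rnorm(120 * fs, 0, 2)
  burst <- (60 * fs + 1):(65 * fs)
  x[burst] <- x[burst] + rnorm(length(burst), 0, 12)
  rec <- td_recording(x, fs, start_time = "2024-03-04T09:10:00+00:00")
  fl <- screen_broadband(rec)
  expect_equal(nrow(fl$broadband_epochs), 1)
  ov <- min(fl$broadband_epochs$end_s, 65) - max(fl$broadband_epochs$start_s, 60)
  expect_gte(ov / 5, 0.8)

  fl2 <- screen_broadband(rec)
  expect_identical(fl$broadband_epochs, fl2$broadband_epochs)

  set.seed(32)
  clean <- td_recording(rnorm(60 * fs, 0, 2), fs)
  expect_equal(nrow(screen_broadband(clean)$broadband_epochs), 0)
})

test_that("broadband epochs are annotated with concurrent motion power", {
  # wearable with movement over [55, 70) s, LFP burst at [60, 65) s
  cfg <- synth_config(seed = 41, wearable = list(fs_hz = 50,
                                                 movement_epochs = list(c(55, 70)),
                                                 duration_s = 120))
  wp <- tempfile(fileext = ".csv")
  generate_wearable_csv(cfg, "2024-03-04T09:10:00+00:00", wp)
  w <- load_wearable(wp)
  set.seed(42)
  x <- rnorm(120 * fs, 0, 2)
  burst <- (60 * fs + 1):(65 * fs)
  x[burst] <- x[burst] + rnorm(length(burst), 0, 12)
  rec <- td_recording(x, fs, start_time = "2024-03-04T09:10:00+00:00")
  fl <- screen_broadband(rec, wearable = w)
  expect_equal(nrow(fl$broadband_epochs), 1)
  expect_true(fl$broadband_epochs$motion_overlap[1])
  expect_gt(fl$broadband_epochs$motion_power[1], 0)
})
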