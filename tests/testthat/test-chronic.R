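# Chronic analytics: circadian profile, event histograms, relative offsets,
# event-triggered averages, snapshot summaries.

t0 <- parse_iso8601("2024-03-01T00:00:00+00:00")
ten_min <- 600

test_that("circadian_profile: constant power, single day, day permutation", {
  ts2 <- t0 + (0:287) * ten_min                      # 2 days
  prof <- circadian_profile(make_timeline(ts2, rep(4.2, 288)), 30)
  expect_true(all(prof$mean_power == 4.2))
  expect_true(all(prof$dispersion == 0))
  expect_equal(sum(prof$n), 288)
  expect_equal(prof$bin_start_hours, seq(0, 23.5, by = 0.5))

  # one full day of data: profile equals the day's own binned values
  ts1 <- t0 + (0:143) * ten_min
  v <- seq_len(144) / 10
  p1 <- circadian_profile(make_timeline(ts1, v), 30)
  byhand <- as.numeric(tapply(v, rep(seq_len(48), each = 3), mean))
  expect_equal(unname(p1$mean_power), byhand)
  # under a day -> warning
  expect_warning(circadian_profile(make_timeline(ts1[1:100], v[1:100]), 30),
                 class = "dbsense_data_warning")

  # invariant to permuting days: same (wall-clock, value) multiset
  set.seed(5)
  day1 <- runif(144); day2 <- runif(144)
  pa <- circadian_profile(make_timeline(ts2, c(day1, day2)), 30)
  pb <- circadian_profile(make_timeline(ts2, c(day2, day1)), 30)
  expect_equal(pa, pb)

  expect_error(circadian_profile(make_timeline(t0[0], numeric(0))),
               class = "dbsense_data_error")
  expect_error(circadian_profile(make_timeline(ts2, rep(1, 288)), 35),
               class = "dbsense_validation_error")
})

test_that("circadian_profile recovers the injected diurnal rhythm", {
  fx <- fx_session("circ14", seed = 501, n_days = 14,
                   events = list(list(name = "Medication",
                                      daily_times = c(8, 13, 19),
                                      jitter_min = 5, post_effect = 0,
                                      effect_delay_min = 0, snapshot = FALSE)),
                   streaming = list(duration_s = 15))
  tl <- fx$session$timeline$left
  prof <- circadian_profile(tl, 30, fx$session$utc_offset_min)
  cp <- fx$truth$circadian_params
  ctr <- prof$bin_start_hours + 0.25
  injected <- cp$mean + cp$amplitude * sin(2 * pi * (ctr - cp$acrophase_hour) / 24)
  expect_gte(stats::cor(prof$mean_power, injected), 0.98)
  fit <- harmonic_fit(ctr, prof$mean_power)
  expect_lt(abs(fit$amplitude - cp$amplitude) / cp$amplitude, 0.10)
  dphi <- abs(fit$acrophase_hour - cp$acrophase_hour)
  expect_lte(min(dphi, 24 - dphi) * 60, 30)
})

test_that("event_daily_histogram counts by wall-clock bin", {
  evs <- list()
  for (d in 0:9) {
    for (h in c(6, 11.5, 20.25)) {
      evs[[length(evs) + 1L]] <- make_event("Medication",
        format_iso8601(t0 + d * 86400 + h * 3600))
    }
  }
  h <- event_daily_histogram(evs, "Medication")
  expect_equal(sum(h$counts), 30)
  expect_equal(h$counts[c(7, 12, 21)], rep(10L, 3))   # bins [6,7), [11,12), [20,21)
  expect_true(all(h$counts[-c(7, 12, 21)] == 0))

  expect_true(all(event_daily_histogram(evs, "nope")$counts == 0))

  # exact-midnight event lands in bin [0, 1)
  hm <- event_daily_histogram(list(make_event("X", "2024-03-02T00:00:00+00:00")), "X")
  expect_equal(hm$counts[1], 1L)

  # conservation property over random event sets
  set.seed(77)
  rnd <- lapply(seq_len(50), function(i)
    make_event("R", format_iso8601(t0 + runif(1, 0, 14 * 86400))))
  expect_equal(sum(event_daily_histogram(rnd, "R", 2)$counts), 50)
})

test_that("relative_event_offsets pairs to the nearest reference", {
  mk <- function(name, mins) lapply(mins, function(m)
    make_event(name, format_iso8601(t0 + m * 60)))
  # target always 10 min after reference
  evs <- c(mk("Med", c(0, 100, 200)), mk("Stuck", c(10, 110, 210)))
  r <- relative_event_offsets(evs, "Med", "Stuck", 60)
  expect_equal(r$offsets_min, rep(10, 3))

  # no references -> empty, all excluded
  r0 <- relative_event_offsets(mk("Stuck", c(5, 10)), "Med", "Stuck", 60)
  expect_length(r0$offsets_min, 0)
  expect_equal(r0$n_excluded, 2L)

  # straddling references at -5 / +7 -> nearest is -5; exact tie -> negative
  evs2 <- c(mk("Med", c(105, 93)), mk("Stuck", c(100)))
  expect_equal(relative_event_offsets(evs2, "Med", "Stuck", 60)$offsets_min, -5)
  evs3 <- c(mk("Med", c(95, 105)), mk("Stuck", c(100)))
  expect_equal(relative_event_offsets(evs3, "Med", "Stuck", 60)$offsets_min, -5)

  # matches the all-pairs brute-force oracle exactly on random inputs
  set.seed(123)
  for (i in 1:5) {
    # whole-second instants: event times serialize at second resolution
    refs <- sort(sample.int(5 * 86400, 40)) / 60
    tgts <- sort(sample.int(5 * 86400, 50)) / 60
    evs <- c(lapply(refs, function(m) make_event("A", format_iso8601(t0 + m * 60))),
             lapply(tgts, function(m) make_event("B", format_iso8601(t0 + m * 60))))
    got <- relative_event_offsets(evs, "A", "B", 120)
    want <- brute_offsets(t0 + refs * 60, t0 + tgts * 60, 120)
    expect_equal(got$offsets_min, want$offsets_min, tolerance = 1e-9)
    expect_equal(got$n_excluded, want$n_excluded)
  }
})

test_that("event_triggered_average: flat input, edge exclusion, errors", {
  ts <- t0 + (0:(4 * 144 - 1)) * ten_min
  tl <- make_timeline(ts, rep(5, length(ts)))
  evs <- lapply(c(24, 48, 72), function(h)
    make_event("E", format_iso8601(t0 + h * 3600)))
  eta <- event_triggered_average(tl, evs, "E", window_min = 120, n_boot = 200)
  expect_equal(eta$n_events_used, 3)
  expect_true(all(abs(eta$mean_power) < 1e-12))
  expect_true(all(eta$ci_low <= 0 & eta$ci_high >= 0))
  expect_equal(diff(range(diff(eta$lags_min))), 0)   # uniform lag grid

  # event too close to the timeline start is excluded with reason edge
  evs2 <- c(evs, list(make_event("E", format_iso8601(t0 + 5 * 60))))
  eta2 <- event_triggered_average(tl, evs2, "E", window_min = 120, n_boot = 200)
  expect_equal(eta2$n_events_used, 3)
  expect_equal(unname(eta2$excluded["edge"]), 1)
  expect_equal(eta2$n_events_used + sum(eta2$excluded), length(evs2))

  # only unusable events -> explicit error, never a silent empty result
  expect_error(event_triggered_average(tl, evs2[4], "E", window_min = 120),
               "edge", class = "dbsense_data_error")
  expect_error(event_triggered_average(tl, evs, "nope", window_min = 120),
               class = "dbsense_data_error")
  expect_error(event_triggered_average(tl, evs, "E", window_min = 15),
               class = "dbsense_validation_error")
})

test_that("event_triggered_average never bridges telemetry gaps", {
  ts <- t0 + (0:(2 * 144 - 1)) * ten_min
  gap <- 148:154                                   # ~70 min telemetry dropout
  tl <- make_timeline(ts[-gap], rep(3, length(ts) - length(gap)))
  ev <- list(make_event("E", format_iso8601(ts[145])))
  eta <- event_triggered_average(tl, ev, "E", window_min = 60,
                                 baseline = FALSE, n_boot = 50)
  # lag positions that fall inside the dropout are NA, the rest are filled
  want <- as.numeric(ts[145]) + eta$lags_min * 60
  in_gap <- vapply(want, function(tt)
    min(abs(as.numeric(tl$timestamps) - tt)) > 600, TRUE)
  expect_identical(is.na(eta$per_event[1, ]), in_gap)
  expect_true(any(in_gap) && !all(in_gap))

  # an event whose whole window sits in the gap is unusable -> explicit error
  ev2 <- list(make_event("E", format_iso8601(ts[151])))
  expect_error(event_triggered_average(tl, ev2, "E", window_min = 20),
               class = "dbsense_data_error")
})

test_that("ETA recovers the injected post-event drop (closed-form oracle)", {
  fx <- fx_session("eta14", seed = 601, n_days = 14,
                   events = list(list(name = "Medication",
                                      daily_times = c(8, 13, 19),
                                      jitter_min = 0, post_effect = -2,
                                      effect_delay_min = 10,
                                      snapshot = FALSE)),
                   streaming = list(duration_s = 15))
  s <- fx$session
  eta <- event_triggered_average(s$timeline$left, s$events, "Medication",
                                 window_min = 120)
  pre <- eta$lags_min >= -120 & eta$lags_min < 0
  post <- eta$lags_min > 0 & eta$lags_min <= 60
  measured <- mean(eta$mean_power[pre]) - mean(eta$mean_power[post])

  # closed-form expectation from the generator model, averaged the same way
  ev_times <- parse_iso8601(fx$truth$event_times$Medication)
  lags_s <- eta$lags_min * 60
  expected <- mean(vapply(as.numeric(ev_times), function(te) {
    f <- model_power_at(te + lags_s, fx$truth$circadian_params,
                        fx$truth$utc_offset_min, fx$cfg$events,
                        list(Medication = ev_times))
    f <- f - mean(f[lags_s < 0])
    mean(f[pre]) - mean(f[post])
  }, 0))
  expect_lt(abs(measured - expected) / abs(expected), 0.15)
})

test_that("event_spectra_summary computes pointwise order statistics", {
  freqs <- 1:40
  base <- 10 / freqs
  bump <- exp(-(freqs - 15)^2 / 8)
  snap <- function(p) list(left = list(freqs = freqs, power = p))

  same <- lapply(1:5, function(i)
    make_event("E", format_iso8601(t0 + i * 3600), snap(base)))
  s1 <- event_spectra_summary(same, "E")
  expect_equal(s1$median_power, base)
  expect_equal(s1$q25, s1$median_power)
  expect_equal(s1$q75, s1$median_power)
  expect_equal(s1$n_snapshots, 5)

  graded <- lapply(1:5, function(i)
    make_event("E", format_iso8601(t0 + i * 3600), snap(base + i * bump)))
  s2 <- event_spectra_summary(graded, "E")
  expect_equal(s2$median_power, base + 3 * bump)
  expect_equal(s2$freqs[which.max(s2$q75 - s2$q25)], 15)
  expect_true(all(s2$q25 <= s2$median_power & s2$median_power <= s2$q75))

  # snapshot-less events are counted, not summarized
  mixed <- c(graded, list(make_event("E", format_iso8601(t0))))
  expect_equal(event_spectra_summary(mixed, "E")$n_without, 1L)

  # differing grids are an error, none at all is an error
  bad <- c(graded, list(make_event("E", format_iso8601(t0 + 9 * 3600),
                                   snap(base)[c(1)])))
  bad[[6]]$snapshot$left$freqs <- freqs + 0.5
  expect_error(event_spectra_summary(bad, "E"), "common",
               class = "dbsense_data_error")
  expect_error(event_spectra_summary(list(make_event("E", format_iso8601(t0))), "E"),
               class = "dbsense_data_error")
})
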