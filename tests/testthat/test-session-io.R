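# Parser, batch handling, timeline merging, FieldTrip export.

write_json_session <- function(x, path = tempfile(fileext = ".json")) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  path
}

test_that("parse_session reproduces generator bookkeeping", {
  fx <- fx_session("two_streams", seed = 5, n_days = 3,
                   streaming = list(duration_s = 20, n_recordings = 2))
  s <- fx$session
  expect_length(s$streamings, 2)
  expect_length(s$timeline$left$timestamps, 432)
  expect_length(s$timeline$right$timestamps, 432)
  expect_equal(length(s$events), sum(lengths(fx$truth$event_times)))
  expect_equal(nrow(s$impedances), 6)
  # every sample round-trips exactly (compare against the raw JSON numbers)
  raw <- jsonlite::fromJSON(fx$path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  for (i in 1:2) {
    expect_identical(unname(s$streamings[[i]]$td$samples),
                     raw$streamings[[i]]$time_domain$samples_uv)
  }
  expect_identical(s$timeline$left$band_power,
                   as.numeric(raw$timeline$left$band_power))
})

test_that("metadata-only and truncated files behave per contract", {
  p <- write_json_session(list(device = list(model = "X"),
                               patient = list(id = "P9"),
                               session = list(time = "2024-01-01T00:00:00+00:00")))
  s <- parse_session(p)
  expect_length(s$surveys, 0); expect_length(s$streamings, 0)
  expect_length(s$events, 0); expect_length(s$timeline, 0)
  expect_equal(nrow(s$impedances), 0)
  expect_false(any(available_modes(s)))

  pt <- tempfile(fileext = ".json")
  full <- readLines(fx_default()$path, warn = FALSE)
  writeLines(substr(paste(full, collapse = ""), 1, 500), pt)
  expect_error(parse_session(pt), class = "dbsense_parse_error")
})

test_that("parser is total over deleted sections and warns on unknown keys", {
  raw <- jsonlite::fromJSON(fx_default()$path, simplifyVector = FALSE)
  for (sec in c("impedances", "surveys", "setups", "streamings", "timeline",
                "events")) {
    mut <- raw[setdiff(names(raw), sec)]
    s <- parse_session(write_json_session(mut))
    expect_s3_class(s, "dbs_session")
  }
  raw$firmware_blob <- list(x = 1)
  expect_warning(parse_session(write_json_session(raw)),
                 class = "dbsense_unknown_key_warning")
})

test_that("schema violations give section-level errors naming the field", {
  raw <- jsonlite::fromJSON(fx_default()$path, simplifyVector = FALSE)
  bad <- raw
  bad$impedances[[1]]$impedance_ohm <- -5
  expect_error(parse_session(write_json_session(bad)), "impedance_ohm",
               class = "dbsense_schema_error")
  bad <- raw
  bad$surveys[[1]]$fs_hz <- NULL
  expect_error(parse_session(write_json_session(bad)), "fs_hz",
               class = "dbsense_schema_error")
})

test_that("load_batch groups by patient, orders by time, deduplicates", {
  mk <- function(seed, pid, start) {
    p <- tempfile(fileext = ".json")
    generate_session(synth_config(seed = seed, n_days = 1, patient_id = pid,
                                  start_time = start, events = list(),
                                  streaming = list(duration_s = 10)), p)
    p
  }
  pa2 <- mk(1, "A", "2024-03-10T09:00:00+00:00")
  pa1 <- mk(2, "A", "2024-03-04T09:00:00+00:00")
  pb1 <- mk(3, "B", "2024-03-05T09:00:00+00:00")
  b <- load_batch(c(pa2, pa1, pb1))
  expect_setequal(names(b), c("A", "B"))
  expect_length(b$A, 2); expect_length(b$B, 1)
  expect_lt(as.numeric(b$A[[1]]$session_time), as.numeric(b$A[[2]]$session_time))

  expect_warning(b1 <- load_batch(c(pa1, pa1)),
                 class = "dbsense_duplicate_warning")
  expect_length(b1$A, 1)
  expect_length(load_batch(pb1)$B, 1)
})

test_that("merge_timelines concatenates, sorts, and deduplicates", {
  mk <- function(seed, start) {
    p <- tempfile(fileext = ".json")
    generate_session(synth_config(seed = seed, n_days = 3, patient_id = "M",
                                  start_time = start, events = list(),
                                  streaming = list(duration_s = 10)), p)
    p
  }
  # timelines span the 3 days before each session time: contiguous 6 days
  b <- load_batch(c(mk(1, "2024-03-04T09:00:00+00:00"),
                    mk(2, "2024-03-07T09:00:00+00:00")))
  m <- merge_timelines(b, "M")
  expect_length(m$left$timestamps, 864)
  expect_true(all(diff(as.numeric(m$left$timestamps)) > 0))

  # overlapping day: union of timestamps, duplicates dropped with warning
  b2 <- load_batch(c(mk(1, "2024-03-04T09:00:00+00:00"),
                     mk(2, "2024-03-06T09:00:00+00:00")))
  warns <- testthat::capture_warnings(m2 <- merge_timelines(b2, "M"))
  expect_length(warns, 2)                       # one per hemisphere
  expect_match(warns, "duplicated", all = TRUE)
  u <- unique(c(as.numeric(b2$M[[1]]$timeline$left$timestamps),
                as.numeric(b2$M[[2]]$timeline$left$timestamps)))
  expect_length(m2$left$timestamps, length(u))
  expect_setequal(as.numeric(m2$left$timestamps), u)

  # single file -> identity; absent patient -> lookup error
  b3 <- load_batch(mk(1, "2024-03-04T09:00:00+00:00"))
  m3 <- merge_timelines(b3, "M")
  expect_identical(m3$left$band_power, b3$M[[1]]$timeline$left$band_power)
  expect_error(merge_timelines(b3, "ZZ"), class = "dbsense_lookup_error")
})

test_that("FieldTrip export round-trips bit-exactly with the right keys", {
  fx <- fx_session("ft", seed = 8, n_days = 1,
                   streaming = list(duration_s = 30))
  out <- tempfile(); dir.create(out)
  p <- export_fieldtrip(fx$session, "streaming", out)
  m <- read_mat5(p)
  expect_identical(names(m), c("label", "fsample", "trial", "time"))
  expect_equal(unlist(m$label), c("L_1-3", "R_1-3"))
  expect_equal(dim(m$trial[[1]]), c(2, 7500))
  expect_identical(m$trial[[1]], unname(fx$session$streamings[[1]]$td$samples))
  expect_equal(m$fsample[1, 1], 250)
  expect_equal(m$time[[1]][1, 1], 0)
  expect_equal(m$time[[1]][1, 7500], 29.996)

  ps <- export_fieldtrip(fx$session, "survey", out)
  ms <- read_mat5(ps)
  expect_length(ms$label, 6)
  expect_identical(ms$trial[[1]], unname(fx$session$surveys[[1]]$samples))

  pt <- export_fieldtrip(fx$session, "timeline", out)
  mt <- read_mat5(pt)
  expect_identical(mt$trial[[1]][1, ],
                   fx$session$timeline$left$band_power)

  none <- fx_session("no_events", seed = 3, n_days = 1, events = list(),
                     streaming = list(duration_s = 15))
  expect_warning(res <- export_fieldtrip(none$session, "events", out),
                 class = "dbsense_empty_warning")
  expect_length(res, 0)
})
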