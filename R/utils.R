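#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft filter median quantile mad var sd coef lm rnorm runif
#'   nextn approx cor complete.cases setNames aggregate
#' @importFrom utils read.csv write.csv head tail modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- condition helpers --------------------------------------------------------

dbs_stop <- function(msg, class, ...) {
  stop(structure(class = c(class, "dbsense_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

dbs_warn <- function(msg, class = "dbsense_warning") {
  warning(structure(class = c(class, "dbsense_warning", "warning", "condition"),
                    list(message = msg, call = sys.call(-1))))
}

#' Set or query the dbsense log level
#'
#' Diagnostic messages are emitted through [message()] and filtered by a
#' package-level log level: `"quiet"` suppresses everything, `"info"` (the
#' default) reports major actions, `"debug"` reports every decision
#' (eligibility calls, peak counts, exclusions).
#'
#' @param level one of `"quiet"`, `"info"`, `"debug"`; omit to query.
#' @return the current level, invisibly when setting.
#' @export
dbs_log_level <- function(level) {
  if (missing(level)) return(getOption("dbsense.log_level", "info"))
  level <- match.arg(level, c("quiet", "info", "debug"))
  options(dbsense.log_level = level)
  invisible(level)
}

dbs_log <- function(..., level = "info") {
  ranks <- c(quiet = 0L, info = 1L, debug = 2L)
  if (ranks[[dbs_log_level()]] >= ranks[[level]]) {
    message(sprintf("[dbsense] %s", paste0(...)))
  }
  invisible(NULL)
}

# -- time handling ------------------------------------------------------------
# All timestamps are carried internally as POSIXct in UTC. Session files
# store ISO-8601 strings with an explicit offset; the session's own offset
# (minutes east of UTC) is kept so circadian analyses can fold by the local
# wall clock.

#' Parse ISO-8601 timestamps with explicit offset to POSIXct (UTC)
#'
#' Accepts `YYYY-MM-DDTHH:MM:SS[.ffffff](Z|+HH:MM|-HH:MM)`; a missing offset
#' is treated as UTC.
#'
#' @param x character vector of timestamps.
#' @return POSIXct vector in tz "UTC".
#' @export
parse_iso8601 <- function(x) {
  if (length(x) == 0) return(as.POSIXct(character(0), tz = "UTC"))
  x <- as.character(x)
  # normalize 'Z' and strip the colon in the numeric offset for %z
  has_off <- grepl("([+-][0-9]{2}:?[0-9]{2}|Z)$", x)
  x[!has_off & !is.na(x)] <- paste0(x[!has_off & !is.na(x)], "+0000")
  x <- sub("Z$", "+0000", x)
  x <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", x)
  frac <- grepl("\\.[0-9]+[+-]", x)
  fmt <- ifelse(frac, "%Y-%m-%dT%H:%M:%OS%z", "%Y-%m-%dT%H:%M:%S%z")
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (f in unique(fmt)) {
    sel <- fmt == f & !is.na(x)
    if (any(sel)) out[sel] <- as.POSIXct(x[sel], format = f, tz = "UTC")
  }
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    dbs_stop(sprintf("unparseable ISO-8601 timestamp(s): %s",
                     paste(utils::head(x[bad], 3), collapse = ", ")),
             "dbsense_time_error")
  }
  out
}

#' Format POSIXct as ISO-8601 with explicit offset
#'
#' @param t POSIXct vector (any tz; converted to UTC).
#' @param offset_minutes offset east of UTC used for the textual
#'   representation; the instant is unchanged. Default 0 (a `+00:00` suffix).
#' @return character vector.
#' @export
format_iso8601 <- function(t, offset_minutes = 0L) {
  stopifnot(inherits(t, "POSIXct"))
  shifted <- as.POSIXct(as.numeric(t) + offset_minutes * 60,
                        origin = "1970-01-01", tz = "UTC")
  sgn <- if (offset_minutes < 0) "-" else "+"
  am <- abs(as.integer(offset_minutes))
  suff <- sprintf("%s%02d:%02d", sgn, am %/% 60L, am %% 60L)
  paste0(format(shifted, "%Y-%m-%dT%H:%M:%S", tz = "UTC"), suff)
}

#' Wall-clock hour of day for timestamps under a session offset
#'
#' @param t POSIXct (UTC) vector.
#' @param offset_minutes session local offset, minutes east of UTC.
#' @return numeric hours in `[0, 24)`.
#' @export
wallclock_hours <- function(t, offset_minutes = 0L) {
  secs <- (as.numeric(t) + offset_minutes * 60) %% 86400
  secs / 3600
}

# -- misc ---------------------------------------------------------------------

normalize_hemisphere <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- ifelse(key %in% c("left", "l", "lt", "lefthemisphere", "left_hemisphere"),
                "left",
         ifelse(key %in% c("right", "r", "rt", "righthemisphere", "right_hemisphere"),
                "right", NA_character_))
  if (anyNA(out)) {
    dbs_stop(sprintf("unrecognized hemisphere label(s): %s",
                     paste(unique(x[is.na(out)]), collapse = ", ")),
             "dbsense_schema_error")
  }
  out
}

# Quantize floats before serialization: the session dialect stores values at
# micro-unit resolution so that JSON text round-trips doubles exactly.
quantize6 <- function(x) round(x, 6)

# robust scaled MAD (consistent with sd under normality)
mad_sigma <- function(x) stats::mad(x, constant = 1.4826)

#' Default analysis configuration
#'
#' Every numeric default used by the preprocessing, spectral and chronic
#' tools lives in this one schema so it can be dumped, edited, and reloaded
#' (see [load_run_config()]).
#'
#' @return nested named list of defaults:
#' \describe{
#'   \item{bands}{named passbands in Hz: `theta_alpha` 4-12, `beta` 13-35,
#'     `gamma` 60-90.}
#'   \item{filter}{Butterworth order (4) per band.}
#'   \item{ecg}{detection band 0.5-30 Hz, peak threshold (4 robust SDs),
#'     minimum peak spacing 0.3 s, interval tolerance 0.2, periodicity
#'     score threshold 0.8, plausible rate 40-120 bpm, template half-width
#'     factor 0.3 of the median inter-peak interval capped at 0.2 s.}
#'   \item{screen}{broadband screen: band 1-100 Hz, window 1 s,
#'     threshold median + 5 scaled MADs.}
#'   \item{stim}{transition mark window 2 s.}
#'   \item{welch}{window 2 s, overlap 0.5.}
#'   \item{scalogram}{7 cycles, 60 log-spaced frequencies over 1-100 Hz.}
#'   \item{chronic}{circadian bin 30 min, bootstrap 1000 resamples,
#'     ETA gap tolerance 1 cadence.}
#'   \item{wearable}{high-pass corner 0.5 Hz, motion window 1 s.}
#' }
#' @export
dbsense_defaults <- function() {
  list(
    bands = list(theta_alpha = c(4, 12), beta = c(13, 35), gamma = c(60, 90)),
    filter = list(order = 4L),
    ecg = list(band = c(0.5, 30), threshold_sigmas = 4, min_spacing_s = 0.3,
               interval_tol = 0.2, score_min = 0.8, rate_bpm = c(40, 120),
               template_halfwidth_factor = 0.3, template_halfwidth_max_s = 0.2),
    screen = list(band = c(1, 100), window_s = 1, mad_mult = 5),
    stim = list(transition_window_s = 2),
    welch = list(window_s = 2, overlap = 0.5),
    scalogram = list(cycles = 7, n_freqs = 60L, fmin = 1, fmax = 100),
    chronic = list(circadian_bin_min = 30, n_boot = 1000L, boot_seed = 1L,
                   gap_cadences = 1),
    wearable = list(highpass_hz = 0.5, window_s = 1)
  )
}

#' Load (or round-trip) a run configuration file
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON configuration holding overrides of
#' [dbsense_defaults()]; unknown keys are rejected so typos fail loudly.
#'
#' @param path config file, or `NULL` for pure defaults.
#' @return full configuration list (defaults overlaid with the file).
#' @seealso [dump_run_config()]
#' @export
load_run_config <- function(path = NULL) {
  cfg <- dbsense_defaults()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) dbs_stop(paste0("config file not found: ", path),
                                   "dbsense_config_error")
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    dbs_stop(sprintf("unknown config section(s): %s",
                     paste(unknown, collapse = ", ")), "dbsense_config_error")
  }
  utils::modifyList(cfg, user)
}

#' Write a run configuration to disk
#'
#' @param cfg configuration list (see [dbsense_defaults()]).
#' @param path output path; format chosen by extension (YAML default).
#' @return `path`, invisibly.
#' @export
dump_run_config <- function(cfg, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}
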