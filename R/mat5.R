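# Minimal MAT-file (level 5) writer/reader covering exactly what a
# FieldTrip raw-data container needs: double matrices, 1xN cell arrays of
# double matrices, and char arrays (plus cells of chars for channel
# labels). Little-endian only; matrices are stored column-major as MATLAB
# expects. No compression, no structs, no complex data.
#
# Format constants (MAT-file level 5):
#   data types: miINT8 1, miINT32 5, miUINT32 6, miDOUBLE 9, miMATRIX 14,
#               miUINT16 4
#   array classes: mxCELL 1, mxCHAR 4, mxDOUBLE 6

mi <- list(INT8 = 1L, UINT16 = 4L, INT32 = 5L, UINT32 = 6L, DOUBLE = 9L,
           MATRIX = 14L)
mx <- list(CELL = 1L, CHAR = 4L, DOUBLE = 6L)

pad8 <- function(raw) {
  rem <- length(raw) %% 8
  if (rem) c(raw, as.raw(rep(0L, 8 - rem))) else raw
}

tag_raw <- function(type, nbytes) {
  c(writeBin(as.integer(type), raw(), size = 4, endian = "little"),
    writeBin(as.integer(nbytes), raw(), size = 4, endian = "little"))
}

element_raw <- function(type, payload) {
  c(tag_raw(type, length(payload)), pad8(payload))
}

# one full miMATRIX element (tag included) for an R object
matrix_element <- function(x, name = "") {
  name_bytes <- if (nzchar(name)) charToRaw(name) else raw(0)
  if (is.character(x) && length(x) == 1) {
    codes <- utf8ToInt(x)
    dims <- c(1L, length(codes))
    flags <- as.integer(mx$CHAR)
    data_el <- element_raw(mi$UINT16,
                           writeBin(as.integer(codes), raw(), size = 2,
                                    endian = "little"))
  } else if (is.list(x)) {
    dims <- c(1L, length(x))
    flags <- as.integer(mx$CELL)
    data_el <- do.call(c, c(list(raw(0)),
                            lapply(x, matrix_element, name = "")))
  } else {
    if (!is.matrix(x)) x <- matrix(as.numeric(x), nrow = 1)
    dims <- dim(x)
    flags <- as.integer(mx$DOUBLE)
    data_el <- element_raw(mi$DOUBLE,
                           writeBin(as.numeric(x), raw(), size = 8,
                                    endian = "little"))
  }
  body <- c(
    element_raw(mi$UINT32,
                writeBin(c(flags, 0L), raw(), size = 4, endian = "little")),
    element_raw(mi$INT32,
                writeBin(as.integer(dims), raw(), size = 4, endian = "little")),
    element_raw(mi$INT8, name_bytes),
    data_el)
  c(tag_raw(mi$MATRIX, length(body)), body)
}

#' Write variables to a MAT-file (level 5)
#'
#' Supports double matrices/vectors, single character strings (char arrays),
#' and unnamed lists of those (1xN cell arrays) — the subset a FieldTrip raw
#' container uses. Values round-trip bit-exactly through [read_mat5()].
#'
#' @param vars named list of variables.
#' @param path output `.mat` path.
#' @return `path`, invisibly.
#' @export
write_mat5 <- function(vars, path) {
  stopifnot(is.list(vars), !is.null(names(vars)), all(nzchar(names(vars))))
  desc <- sprintf("MATLAB 5.0 MAT-file, created by dbsense on %s",
                  format(Sys.time(), "%Y-%m-%d", tz = "UTC"))
  header <- charToRaw(formatC(desc, width = -116))
  header <- c(header, as.raw(rep(0x20, 116 - length(header))))[1:116]
  header <- c(header, as.raw(rep(0, 8)))                        # subsys offset
  header <- c(header, writeBin(0x0100L, raw(), size = 2, endian = "little"))
  header <- c(header, charToRaw("IM"))                          # little-endian
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  for (nm in names(vars)) writeBin(matrix_element(vars[[nm]], nm), con)
  invisible(path)
}

# -- reader -------------------------------------------------------------------

read_tag <- function(raw, pos) {
  word <- readBin(raw[pos:(pos + 3)], "integer", size = 4, endian = "little")
  small_type <- bitwAnd(bitwShiftR(word, 16), 0xFFFF)
  if (small_type != 0) {                 # small data element format
    list(type = bitwAnd(word, 0xFFFF), nbytes = small_type, data_at = pos + 4,
         next_at = pos + 8, small = TRUE)
  } else {
    nb <- readBin(raw[(pos + 4):(pos + 7)], "integer", size = 4,
                  endian = "little")
    list(type = word, nbytes = nb, data_at = pos + 8,
         next_at = pos + 8 + nb + (8 - nb %% 8) %% 8, small = FALSE)
  }
}

parse_matrix <- function(raw, pos, end) {
  flags_el <- read_tag(raw, pos)
  flags <- readBin(raw[flags_el$data_at:(flags_el$data_at + 3)], "integer",
                   size = 4, endian = "little")
  klass <- bitwAnd(flags, 0xFF)
  dims_el <- read_tag(raw, flags_el$next_at)
  ndim <- dims_el$nbytes %/% 4
  dims <- readBin(raw[dims_el$data_at:(dims_el$data_at + dims_el$nbytes - 1)],
                  "integer", size = 4, n = ndim, endian = "little")
  name_el <- read_tag(raw, dims_el$next_at)
  name <- if (name_el$nbytes > 0)
    rawToChar(raw[name_el$data_at:(name_el$data_at + name_el$nbytes - 1)])
  else ""
  pos <- if (name_el$small) name_el$next_at else name_el$next_at
  if (klass == mx$DOUBLE) {
    d <- read_tag(raw, pos)
    n <- d$nbytes %/% 8
    vals <- if (n > 0)
      readBin(raw[d$data_at:(d$data_at + d$nbytes - 1)], "double", size = 8,
              n = n, endian = "little") else numeric(0)
    value <- matrix(vals, nrow = dims[1], ncol = dims[2])
  } else if (klass == mx$CHAR) {
    d <- read_tag(raw, pos)
    n <- d$nbytes %/% 2
    codes <- if (n > 0)
      readBin(raw[d$data_at:(d$data_at + d$nbytes - 1)], "integer", size = 2,
              n = n, signed = FALSE, endian = "little") else integer(0)
    value <- intToUtf8(codes)
  } else if (klass == mx$CELL) {
    cells <- list()
    while (pos < end) {
      t <- read_tag(raw, pos)
      if (t$type != mi$MATRIX) break
      sub <- parse_matrix(raw, t$data_at, t$next_at)
      cells[[length(cells) + 1L]] <- sub$value
      pos <- t$next_at
    }
    value <- cells
  } else {
    dbs_stop(sprintf("MAT reader: unsupported array class %d", klass),
             "dbsense_mat_error")
  }
  list(name = name, value = value)
}

#' Read a MAT-file (level 5) written by [write_mat5()]
#'
#' @param path `.mat` file.
#' @return named list of variables (double matrices, strings, cell lists).
#' @export
read_mat5 <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 128 || rawToChar(raw[127:128]) != "IM")
    dbs_stop(sprintf("'%s' is not a little-endian level-5 MAT-file", path),
             "dbsense_mat_error")
  pos <- 129L
  out <- list()
  while (pos + 8 <= length(raw) + 1) {
    t <- read_tag(raw, pos)
    if (t$type != mi$MATRIX)
      dbs_stop(sprintf("MAT reader: unsupported top-level element type %d", t$type),
               "dbsense_mat_error")
    v <- parse_matrix(raw, t$data_at, t$next_at)
    out[[v$name]] <- v$value
    pos <- t$next_at
  }
  out
}

# -- FieldTrip export ---------------------------------------------------------

#' Export one sensing mode as a FieldTrip-compatible MAT container
#'
#' Writes, for the chosen sensing mode, one MAT-file with the FieldTrip
#' raw-data keys:
#' \describe{
#'   \item{label}{cell array of channel-name char arrays}
#'   \item{fsample}{sampling rate, Hz}
#'   \item{trial}{cell array with one `channels x samples` double matrix per
#'     recording}
#'   \item{time}{cell array of per-trial time axes, starting at 0 s}
#' }
#' For `timeline`, each hemisphere is one single-row trial (label =
#' hemisphere), fsample the reciprocal median cadence, time in seconds from
#' each series' first point. For `events`, each FFT-snapshot-bearing event is
#' a trial (`hemispheres x freqs` power matrix) and the `time` axis carries
#' the frequency grid in Hz (fsample = 1 / frequency step); snapshot-less
#' events are skipped.
#'
#' Reloading with [read_mat5()] reproduces every sample bit-exactly.
#'
#' @param session a `dbs_session`.
#' @param mode one of `"survey"`, `"setup"`, `"streaming"`, `"timeline"`,
#'   `"events"`.
#' @param out_dir output directory (created if needed).
#' @return path(s) of files written (character(0) with a warning if the mode
#'   is empty).
#' @export
export_fieldtrip <- function(session, mode, out_dir) {
  mode <- match.arg(mode, c("survey", "setup", "streaming", "timeline", "events"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  empty <- function() {
    dbs_warn(sprintf("export_fieldtrip: session has no '%s' data, nothing written",
                     mode), "dbsense_empty_warning")
    character(0)
  }

  if (mode %in% c("survey", "setup", "streaming")) {
    recs <- switch(mode, survey = session$surveys, setup = session$setups,
                   streaming = lapply(session$streamings, `[[`, "td"))
    if (!length(recs)) return(empty())
    labels <- recs[[1]]$channels
    for (r in recs) {
      if (!identical(r$channels, labels))
        dbs_stop(sprintf("export_fieldtrip(%s): recordings have inconsistent channel sets",
                         mode), "dbsense_export_error")
    }
    fs <- recs[[1]]$fs
    trial <- lapply(recs, function(r) r$samples)
    time <- lapply(recs, function(r)
      matrix((seq_len(ncol(r$samples)) - 1) / r$fs, nrow = 1))
  } else if (mode == "timeline") {
    tls <- session$timeline
    tls <- tls[vapply(tls, function(t) length(t$timestamps) > 0, TRUE)]
    if (!length(tls)) return(empty())
    labels <- names(tls)
    cad <- stats::median(unlist(lapply(tls, function(t)
      diff(as.numeric(t$timestamps)))))
    fs <- 1 / cad
    trial <- lapply(tls, function(t) matrix(t$band_power, nrow = 1))
    time <- lapply(tls, function(t)
      matrix(as.numeric(t$timestamps) - as.numeric(t$timestamps[1]), nrow = 1))
  } else {                                         # events: FFT snapshots
    evs <- Filter(function(e) !is.null(e$snapshot), session$events)
    if (!length(evs)) return(empty())
    labels <- names(evs[[1]]$snapshot)
    freqs <- evs[[1]]$snapshot[[1]]$freqs
    trial <- lapply(evs, function(e)
      do.call(rbind, lapply(e$snapshot[labels], function(s) s$power)))
    time <- lapply(evs, function(e) matrix(freqs, nrow = 1))
    fs <- 1 / stats::median(diff(freqs))
  }

  path <- file.path(out_dir, sprintf("%s_%s_ft.mat",
                                     gsub("[^A-Za-z0-9_-]", "_", session$patient_id),
                                     mode))
  write_mat5(list(label = as.list(labels),
                  fsample = matrix(fs, 1, 1),
                  trial = unname(trial),
                  time = unname(time)),
             path)
  dbs_log(sprintf("exported %d %s trial(s) -> %s", length(trial), mode, path),
          level = "debug")
  path
}
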