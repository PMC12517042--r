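# EEG file i/o and preprocessing.
#
# EDF and BDF are fixed-layout formats: a 256-byte ASCII header, a 256-byte
# ASCII block per signal, then data records of little-endian integers
# (16-bit for EDF, 24-bit for BDF) scaled linearly between digital and
# physical ranges. The reader/writer below covers continuous recordings with
# a uniform sampling rate, which is what this package consumes; EEGLAB .SET
# (a MATLAB v5 container) is not supported.

read_ascii_field <- function(con, nchars) {
  trimws(rawToChar(readBin(con, "raw", nchars)))
}

#' Read an EDF/BDF recording
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format `"edf"`, `"bdf"`, or `NULL` to infer.
#' @return A [mindy_recording()] (no labels); sampling rate and channel
#'   names are taken from the header, data is returned in physical units.
#' @export
load_recording <- function(path, format = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  format <- tolower(format)
  if (format == "set") {
    stop("EEGLAB .SET files are not supported; export to EDF or BDF",
         call. = FALSE)
  }
  if (!format %in% c("edf", "bdf")) {
    stop(sprintf("unknown recording format '%s'", format), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  version <- readBin(con, "raw", 8)
  if (format == "bdf" && version[1] != as.raw(255)) {
    stop(sprintf("'%s' is not a BDF file (bad magic byte)", path),
         call. = FALSE)
  }
  invisible(readBin(con, "raw", 160))      # patient + recording ids
  invisible(readBin(con, "raw", 16))       # start date + time
  header_bytes <- suppressWarnings(as.integer(read_ascii_field(con, 8)))
  invisible(readBin(con, "raw", 44))
  n_records <- suppressWarnings(as.integer(read_ascii_field(con, 8)))
  rec_dur <- suppressWarnings(as.numeric(read_ascii_field(con, 8)))
  ns <- suppressWarnings(as.integer(read_ascii_field(con, 4)))
  if (any(is.na(c(header_bytes, n_records, rec_dur, ns))) || ns < 1) {
    stop(sprintf("'%s' has a corrupt or non-EDF header", path),
         call. = FALSE)
  }
  labels <- vapply(seq_len(ns), function(i) read_ascii_field(con, 16), "")
  invisible(readBin(con, "raw", ns * 80))  # transducer
  invisible(readBin(con, "raw", ns * 8))   # physical dimension
  phys_min <- vapply(seq_len(ns), function(i)
    as.numeric(read_ascii_field(con, 8)), 0)
  phys_max <- vapply(seq_len(ns), function(i)
    as.numeric(read_ascii_field(con, 8)), 0)
  dig_min <- vapply(seq_len(ns), function(i)
    as.numeric(read_ascii_field(con, 8)), 0)
  dig_max <- vapply(seq_len(ns), function(i)
    as.numeric(read_ascii_field(con, 8)), 0)
  invisible(readBin(con, "raw", ns * 80))  # prefilter
  spr <- vapply(seq_len(ns), function(i)
    as.integer(read_ascii_field(con, 8)), 0L)
  invisible(readBin(con, "raw", ns * 32))
  if (any(is.na(c(phys_min, phys_max, dig_min, dig_max, spr)))) {
    stop(sprintf("'%s' has corrupt signal headers", path), call. = FALSE)
  }
  if (length(unique(spr)) != 1L) {
    stop("signals with differing sampling rates are not supported",
         call. = FALSE)
  }
  rate <- spr[1] / rec_dur
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  total <- n_records * spr[1]
  data <- matrix(0, total, ns)
  for (r in seq_len(n_records)) {
    rows <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (j in seq_len(ns)) {
      if (format == "edf") {
        dig <- readBin(con, "integer", spr[1], size = 2, endian = "little",
                       signed = TRUE)
      } else {
        raw3 <- readBin(con, "raw", 3L * spr[1])
        b <- matrix(as.integer(raw3), nrow = 3)
        dig <- b[1, ] + 256L * b[2, ] + 65536L * b[3, ]
        dig <- ifelse(dig >= 8388608, dig - 16777216, dig)
      }
      if (length(dig) < spr[1]) {
        stop(sprintf("'%s' is truncated (record %d)", path, r),
             call. = FALSE)
      }
      data[rows, j] <- phys_min[j] + (dig - dig_min[j]) * scale[j]
    }
  }
  mindy_recording(data, rate_hz = rate, channels = labels)
}

pad_field <- function(x, width) {
  x <- as.character(x)
  vapply(x, function(s) {
    s <- substr(s, 1, width)
    paste0(s, strrep(" ", width - nchar(s)))
  }, "")
}

#' Write a recording as EDF
#'
#' One-second data records, 16-bit samples scaled channel-wise to the data
#' range (the quantisation limit of the format). The recording length is
#' truncated to a whole number of records.
#'
#' @param rec a `mindy_recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  data <- rec$data
  ns <- ncol(data)
  spr <- as.integer(round(rec$rate_hz))
  n_records <- nrow(data) %/% spr
  if (n_records < 1) stop("recording shorter than one EDF record",
                          call. = FALSE)
  data <- data[seq_len(n_records * spr), , drop = FALSE]
  phys_min <- apply(data, 2, min)
  phys_max <- apply(data, 2, max)
  same <- phys_max - phys_min < 1e-12
  phys_max[same] <- phys_min[same] + 1
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeBin(charToRaw(pad_field(s, w)), con)
  wr("0", 8); wr("X", 80); wr("X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256L * (1L + ns)), 8)
  wr("", 44)
  wr(as.character(n_records), 8)
  wr("1", 8)
  wr(as.character(ns), 4)
  for (s in pad_field(rec$channels, 16)) writeBin(charToRaw(s), con)
  for (j in seq_len(ns)) wr("", 80)
  for (j in seq_len(ns)) wr("uV", 8)
  for (v in phys_min) wr(formatC(v, digits = 6, format = "g"), 8)
  for (v in phys_max) wr(formatC(v, digits = 6, format = "g"), 8)
  for (j in seq_len(ns)) wr(as.character(dig_min), 8)
  for (j in seq_len(ns)) wr(as.character(dig_max), 8)
  for (j in seq_len(ns)) wr("", 80)
  for (j in seq_len(ns)) wr(as.character(spr), 8)
  for (j in seq_len(ns)) wr("", 32)
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_records)) {
    rows <- ((r - 1L) * spr + 1L):(r * spr)
    for (j in seq_len(ns)) {
      dig <- round(dig_min + (data[rows, j] - phys_min[j]) * scale[j])
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Band-pass filter and robust-normalise a recording
#'
#' Zero-phase Butterworth band-pass (forward-backward), then per channel:
#' subtract the median and divide by the mean absolute deviation about the
#' median. Output channels have median 0 and mean absolute deviation 1.
#'
#' @param rec a `mindy_recording`.
#' @param low_hz,high_hz band edges in Hz (defaults 0.5 and 15).
#' @param order Butterworth order (default 4).
#' @return Preprocessed `mindy_recording`.
#' @export
preprocess_recording <- function(rec, low_hz = 0.5, high_hz = 15,
                                 order = 4) {
  nyq <- rec$rate_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop(sprintf("band (%g, %g) Hz must satisfy 0 < low < high < %g (Nyquist)",
                 low_hz, high_hz, nyq), call. = FALSE)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- apply(rec$data, 2, function(ch) {
    f <- signal::filtfilt(bf, ch)
    f <- f - median(f)
    m <- mean(abs(f))
    if (m < .Machine$double.eps) m <- 1
    f / m
  })
  mindy_recording(out, rec$rate_hz, rec$channels, rec$labels,
                  rec$boundaries)
}

#' Standard 10-20 scalp montage
#'
#' The classic 19 scalp positions of the international 10-20 system plus
#' `Oz`, giving the 20-channel montage used for low-density clinical EEG.
#' The list is a configuration default, not a hard-coded requirement: any
#' unique, nonempty name list is a valid montage.
#'
#' @return Character vector of 20 channel names.
#' @export
standard_montage <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2", "Oz")
}

#' Select and reorder channels
#'
#' @param rec a `mindy_recording`.
#' @param names ordered channel-name list (e.g. [standard_montage()]).
#' @return Recording restricted to `names`, in that order.
#' @export
select_channels <- function(rec, names) {
  if (!length(names) || anyDuplicated(names)) {
    stop("montage names must be unique and nonempty", call. = FALSE)
  }
  missing <- setdiff(names, rec$channels)
  if (length(missing)) {
    stop(sprintf("channels not present in recording: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  idx <- match(names, rec$channels)
  mindy_recording(rec$data[, idx, drop = FALSE], rec$rate_hz,
                  rec$channels[idx], rec$labels, rec$boundaries)
}

#' Concatenate session recordings with regime labels
#'
#' Stacks recordings in time and labels every timestep with its session's
#' regime id. Session start indices are recorded as boundaries so fit
#' windows never span two sessions.
#'
#' @param recs ordered list of `mindy_recording`s with identical channel
#'   sets and rates.
#' @param state_ids one integer regime id per recording.
#' @return A single labelled `mindy_recording`.
#' @export
concatenate_labeled <- function(recs, state_ids) {
  stopifnot(length(recs) >= 1, length(state_ids) == length(recs))
  ref <- recs[[1]]
  for (r in recs[-1]) {
    if (!identical(r$channels, ref$channels)) {
      stop("all recordings must share the same channel list", call. = FALSE)
    }
    if (r$rate_hz != ref$rate_hz) {
      stop("all recordings must share the same sampling rate", call. = FALSE)
    }
  }
  lens <- vapply(recs, function(r) nrow(r$data), 0L)
  boundaries <- cumsum(c(1L, head(lens, -1L)))
  data <- do.call(rbind, lapply(recs, function(r) r$data))
  labels <- rep(as.integer(state_ids), lens)
  mindy_recording(data, ref$rate_hz, ref$channels, labels,
                  boundaries = boundaries)
}
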