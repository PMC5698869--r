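# Minimal European Data Format (EDF) writer/reader.
# 16-bit little-endian samples with per-channel physical scaling; one data
# record per second.  Covers the subset of the format needed to interchange
# simulated recordings (no annotations, no discontinuities).

edf_pad <- function(s, width) {
  s <- substr(as.character(s), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a continuous EEG recording as EDF
#'
#' Samples are quantized to 16-bit integers over a symmetric physical range
#' covering the data (uV).  The last data record is zero-padded when the
#' recording length is not a whole number of records; the true sample count
#' is returned and also recoverable from the reader via the `n_samples`
#' attribute convention (padding is zeros at the tail).
#'
#' @param eeg a `continuous_eeg`.
#' @param path output file.
#' @param patient_id,recording_id header strings.
#' @param physical_max symmetric physical range bound (uV); defaults to the
#'   data's absolute maximum (minimum 1).
#' @return `path`, invisibly.
#' @export
write_edf <- function(eeg, path, patient_id = "X", recording_id = "simulated",
                      physical_max = NULL) {
  stopifnot(inherits(eeg, "continuous_eeg"))
  x <- eeg$samples
  ns <- nrow(x)
  fs <- eeg$fs_hz
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  spr <- as.integer(fs)                 # samples per record (1 s records)
  n_rec <- ceiling(ncol(x) / spr)
  phys <- physical_max %||% max(1, max(abs(x)))
  dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad(patient_id, 80), edf_pad(recording_id, 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  field(eeg$channel_labels, 16)
  field(rep("AgAgCl electrode", ns), 80)
  field(rep("uV", ns), 8)
  field(rep(sprintf("%.6g", -phys), ns), 8)
  field(rep(sprintf("%.6g", phys), ns), 8)
  field(rep(-dmax, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)
  field(rep(spr, ns), 8)
  field(rep("", ns), 32)

  scale <- dmax / phys
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):min(r * spr, ncol(x))
    for (ch in seq_len(ns)) {
      v <- x[ch, cols]
      if (length(cols) < spr) v <- c(v, numeric(spr - length(cols)))
      d <- as.integer(round(pmin(pmax(v, -phys), phys) * scale))
      writeBin(d, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Parses the header and data records written by [write_edf()] (equal
#' sampling rate across channels, 1-second records) and reconstructs the
#' physical signal.
#'
#' @param path EDF file.
#' @return A `continuous_eeg`; header fields in attribute `edf_header`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8); patient <- rd(80); recording <- rd(80)
  rd(8); rd(8)                        # start date/time
  rd(8); rd(44)                       # header bytes, reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) readChar(con, 16), ""))
  readChar(con, 80 * ns); units <- trimws(vapply(seq_len(ns), function(i) readChar(con, 8), ""))
  pmin <- as.numeric(vapply(seq_len(ns), function(i) readChar(con, 8), ""))
  pmaxv <- as.numeric(vapply(seq_len(ns), function(i) readChar(con, 8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) readChar(con, 8), ""))
  dmaxv <- as.numeric(vapply(seq_len(ns), function(i) readChar(con, 8), ""))
  readChar(con, 80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) readChar(con, 8), ""))
  readChar(con, 32 * ns)
  if (length(unique(spr)) != 1) stop("mixed per-channel rates not supported")
  fs <- spr[1] / rec_dur

  x <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  gain <- (pmaxv - pmin) / (dmaxv - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little")
      cols <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
      x[ch, cols] <- pmin[ch] + (d - dmin[ch]) * gain[ch]
    }
  }
  out <- continuous_eeg(x, fs, labels)
  attr(out, "edf_header") <- list(version = version, patient = patient,
                                  recording = recording, n_records = n_rec,
                                  units = units)
  out
}
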