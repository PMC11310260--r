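# Minimal EDF / BDF codec (continuous recordings, one data record).
#
# EDF stores 16-bit integers with a per-channel linear physical/digital
# mapping; writing is therefore lossy with absolute error bounded by half a
# quantization step, phys_range / (2 * 65534). BDF (the 24-bit BioSemi
# dialect) is supported for reading. The writer emits a single data record
# holding the whole recording, which every compliant reader accepts for
# continuous data.

pad_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

edf_num <- function(x, width = 8) pad_field(formatC(x, format = "g", digits = 6), width)

#' Write an EDF file
#'
#' 16-bit EDF with per-channel physical scaling set to the channel's signed
#' amplitude maximum (so quantization error is at most
#' `max|x| / 65534` per channel).
#'
#' @param rec an `eeg_recording`.
#' @param path output path.
#' @param phys_dim physical dimension label stored per channel.
#' @return the path, invisibly.
#' @export
write_edf <- function(rec, path, phys_dim = "uV") {
  ns <- nrow(rec$data); n <- ncol(rec$data)
  amax <- apply(abs(rec$data), 1, max)
  amax[amax == 0] <- 1
  # quantize against the PRINTED physical range (8-char ASCII fields round
  # the stored limits; using the rounded values keeps writer and reader on
  # the same linear mapping)
  phys_max <- as.numeric(edf_num(amax))
  phys_max <- pmax(phys_max, amax)        # never clip the data range
  phys_max <- as.numeric(edf_num(phys_max * (1 + 1e-6)))
  phys_min <- -phys_max
  dig_min <- -32767L; dig_max <- 32767L
  header_bytes <- 256L + 256L * ns
  dur <- n / rec$fs

  con <- file(path, "wb"); on.exit(close(con))
  writeChar(paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    pad_field(sprintf("Startdate X X X X cond:%s subj:%s sess:%s",
                      rec$condition, rec$subject, rec$session), 80),
    "01.01.00", "00.00.00",
    pad_field(header_bytes, 8),
    pad_field("", 44),
    pad_field(1, 8),
    edf_num(dur, 8),
    pad_field(ns, 4)), con, eos = NULL)
  writeChar(paste0(
    paste(pad_field(rec$channels, 16), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(phys_dim, 8), ns), collapse = ""),
    paste(edf_num(phys_min), collapse = ""),
    paste(edf_num(phys_max), collapse = ""),
    paste(rep(pad_field(dig_min, 8), ns), collapse = ""),
    paste(rep(pad_field(dig_max, 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(n, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = "")), con, eos = NULL)
  for (ch in seq_len(ns)) {
    dig <- round((rec$data[ch, ] - phys_min[ch]) /
                 (phys_max[ch] - phys_min[ch]) * (dig_max - dig_min) + dig_min)
    writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf_header <- function(con, path) {
  h <- readBin(con, "raw", 256L)
  assert_that(length(h) == 256L, "parse_error",
              sprintf("%s: truncated header at byte %d", path, length(h)))
  bdf <- h[1] == as.raw(255)
  txt <- function(from, len) trimws(rawToChar(h[(from + 1):(from + len)]))
  list(bdf = bdf,
       n_records = as.integer(txt(236, 8)),
       record_dur = as.numeric(txt(244, 8)),
       ns = as.integer(txt(252, 4)))
}

#' Read an EDF or BDF file
#'
#' Supports continuous 16-bit EDF and 24-bit BDF recordings with a common
#' sampling rate across channels. Channels whose labels look like EOG /
#' trigger channels are flagged (attribute `is_eeg`), not dropped.
#'
#' @param path file path.
#' @return an `eeg_recording` (physical units).
#' @export
read_edf <- function(path) {
  assert_that(file.exists(path), "parse_error",
              sprintf("file not found: %s", path))
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- read_edf_header(con, path)
  ns <- hdr$ns
  sig <- readBin(con, "raw", 256L * ns)
  assert_that(length(sig) == 256L * ns, "parse_error",
              sprintf("%s: truncated signal headers at byte %d", path,
                      256L + length(sig)))
  # EDF stores each field contiguously for all signals: labels[1..ns], then
  # transducers[1..ns], etc. Field byte offsets within the block:
  # 16 label | 80 transducer | 8 phys dim | 8 phys min | 8 phys max |
  # 8 dig min | 8 dig max | 80 prefilter | 8 n samples | 32 reserved
  field_vec <- function(start_byte, width) {
    vapply(seq_len(ns), function(i) {
      a <- start_byte + (i - 1L) * width
      trimws(rawToChar(sig[(a + 1):(a + width)]))
    }, "")
  }
  labels <- field_vec(0, 16)
  pmin_v <- as.numeric(field_vec(ns * 104L, 8))
  pmax_v <- as.numeric(field_vec(ns * 112L, 8))
  dmin_v <- as.numeric(field_vec(ns * 120L, 8))
  dmax_v <- as.numeric(field_vec(ns * 128L, 8))
  nsamp <- as.integer(field_vec(ns * 216L, 8))

  bytes_per <- if (hdr$bdf) 3L else 2L
  data <- matrix(0, ns, nsamp[1] * hdr$n_records)
  for (r in seq_len(hdr$n_records)) {
    for (ch in seq_len(ns)) {
      if (hdr$bdf) {
        raw3 <- readBin(con, "raw", 3L * nsamp[ch])
        m <- matrix(as.integer(raw3), nrow = 3)
        dig <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
        dig <- ifelse(dig >= 8388608, dig - 16777216, dig)
      } else {
        dig <- readBin(con, "integer", nsamp[ch], size = 2L,
                       endian = "little", signed = TRUE)
      }
      assert_that(length(dig) == nsamp[ch], "parse_error",
                  sprintf("%s: truncated data in record %d channel %d", path, r, ch))
      phys <- pmin_v[ch] + (dig - dmin_v[ch]) *
        (pmax_v[ch] - pmin_v[ch]) / (dmax_v[ch] - dmin_v[ch])
      data[ch, ((r - 1) * nsamp[ch] + 1):(r * nsamp[ch])] <- phys
    }
  }
  fs <- nsamp[1] / hdr$record_dur
  rec <- eeg_recording(data, fs, labels)
  attr(rec, "is_eeg") <- is_eeg_label(labels)
  if (any(!attr(rec, "is_eeg"))) {
    warning(sprintf("non-EEG channels flagged: %s",
                    paste(labels[!attr(rec, "is_eeg")], collapse = ", ")))
  }
  rec
}

#' Read a recording in any supported format
#'
#' Dispatches on `format` (or the file extension): `edf` / `bdf` via
#' [read_edf()], `internal` (`.eegc`) via [read_eegc()].
#'
#' @param path file path.
#' @param format one of `"edf"`, `"bdf"`, `"internal"`, or `NULL` to infer
#'   from the extension.
#' @return an `eeg_recording`.
#' @export
read_recording <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     edf = "edf", bdf = "bdf", eegc = "internal",
                     msr_error("parse_error",
                               sprintf("cannot infer format of %s", path)))
  }
  switch(format,
         edf = , bdf = read_edf(path),
         internal = read_eegc(path),
         msr_error("parse_error", sprintf("unknown format '%s'", format)))
}
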