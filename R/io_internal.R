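# Internal binary container (.eegc): lossless float64 exchange format.
#
# Layout: 8-byte magic "EEGC0001", 4-byte little-endian header length, JSON
# header (labels, fs, dims, tags, clip table), then the sample payload as
# little-endian float64, channel-major (all samples of channel 1, then
# channel 2, ...). Round trips are bit-identical, unlike EDF whose 16-bit
# quantization is lossy by format.

EEGC_MAGIC <- charToRaw("EEGC0001")

#' Write / read the internal recording container
#'
#' @param rec an `eeg_recording`.
#' @param path file path (conventionally `.eegc`).
#' @return `write_eegc` returns the path invisibly; `read_eegc` returns the
#'   `eeg_recording` with float64 data preserved bit-exactly.
#' @export
write_eegc <- function(rec, path) {
  hdr <- list(fs = rec$fs, n_channels = nrow(rec$data),
              n_samples = ncol(rec$data), channels = rec$channels,
              condition = rec$condition, subject = rec$subject,
              session = rec$session)
  if (!is.null(rec$clips)) hdr$clips <- rec$clips
  hjson <- charToRaw(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(EEGC_MAGIC, con)
  writeBin(length(hjson), con, size = 4L, endian = "little")
  writeBin(hjson, con)
  writeBin(as.vector(t(rec$data)), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_eegc
#' @export
read_eegc <- function(path) {
  assert_that(file.exists(path), "parse_error",
              sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  assert_that(identical(magic, EEGC_MAGIC), "parse_error",
              sprintf("%s: bad magic at byte 0 (not an eegc container)", path))
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  x <- readBin(con, "double", hdr$n_channels * hdr$n_samples, size = 8L,
               endian = "little")
  assert_that(length(x) == hdr$n_channels * hdr$n_samples, "parse_error",
              sprintf("%s: truncated payload at byte %d", path, 12L + hlen))
  data <- matrix(x, nrow = hdr$n_channels, ncol = hdr$n_samples, byrow = TRUE)
  clips <- if (!is.null(hdr$clips)) as.data.frame(hdr$clips) else NULL
  eeg_recording(data, hdr$fs, hdr$channels, hdr$condition %||% NA_character_,
                hdr$subject %||% NA_character_, hdr$session %||% NA_character_,
                clips = clips)
}
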