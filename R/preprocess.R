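# Condition-block preprocessing: DC removal, average reference, edge
# trimming and concatenation into the per-condition analysis segment.
# With the standard design (five 24-s clips trimmed by 2 s, or one 120-s
# resting block trimmed by 10 s) every condition yields a 100-s segment.

#' Remove the DC offset of every channel
#'
#' Subtracts each channel's temporal mean.
#'
#' @param rec an `eeg_recording`.
#' @return the recording with zero-mean channels.
#' @export
remove_dc <- function(rec) {
  assert_that(inherits(rec, "eeg_recording") && length(rec$data) > 0,
              "invalid_input", "non-empty eeg_recording required")
  rec$data <- rec$data - rowMeans(rec$data)
  rec
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the mean over all channels. Idempotent. All
#' channels present in the recording participate in the reference; non-EEG
#' channels (EOG etc.) must be excluded upstream via their montage labels.
#'
#' @param rec an `eeg_recording` with at least two channels.
#' @return the average-referenced recording.
#' @export
average_reference <- function(rec) {
  assert_that(inherits(rec, "eeg_recording"), "invalid_input",
              "eeg_recording required")
  assert_that(nrow(rec$data) >= 2, "invalid_input",
              "average reference requires at least 2 channels")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

#' Per-condition analysis segment
#'
#' @param data channels x samples matrix.
#' @param fs Hz.
#' @param condition,subject,session tags.
#' @param provenance data.frame of (block, orig_start, orig_end) 1-based
#'   inclusive sample ranges in the source blocks.
#' @return object of class `condition_segment`.
#' @export
condition_segment <- function(data, fs, condition = NA_character_,
                              subject = NA_character_, session = NA_character_,
                              provenance = NULL) {
  structure(list(data = data, fs = fs, condition = condition,
                 subject = subject, session = session,
                 provenance = provenance),
            class = "condition_segment")
}

#' @export
print.condition_segment <- function(x, ...) {
  cat(sprintf("<condition_segment> %d ch x %d samples (%.1f s) [%s / %s / %s]\n",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$fs,
              x$subject, x$session, x$condition))
  invisible(x)
}

#' Trim block edges and concatenate into one segment
#'
#' Drops `trim_seconds` from both ends of every block (transitions between
#' video clips carry posterior-alpha transients) and concatenates the
#' remainders in input order. Five 24-s action clips trimmed by 2 s, or one
#' 120-s resting block trimmed by 10 s, both yield the standard 100-s
#' analysis segment. Trim times are converted to samples by rounding to the
#' nearest sample.
#'
#' @param blocks list of `eeg_recording` with equal fs and channel sets.
#' @param trim_seconds seconds removed at each end of each block.
#' @return a `condition_segment`; `provenance` maps each retained stretch to
#'   its block index and original sample range.
#' @export
trim_and_concatenate <- function(blocks, trim_seconds) {
  assert_that(length(blocks) >= 1, "invalid_input", "need at least one block")
  fs <- blocks[[1]]$fs
  chans <- blocks[[1]]$channels
  for (b in blocks) {
    assert_that(identical(b$fs, fs) && identical(b$channels, chans),
                "inconsistent_input", "blocks differ in fs or channel set")
  }
  ntrim <- round(trim_seconds * fs)
  pieces <- list(); prov <- list()
  for (i in seq_along(blocks)) {
    n <- ncol(blocks[[i]]$data)
    assert_that(n > 2 * ntrim, "invalid_trim",
                sprintf("block %d (%d samples) not longer than 2*trim (%d samples)",
                        i, n, 2 * ntrim))
    keep <- (ntrim + 1L):(n - ntrim)
    pieces[[i]] <- blocks[[i]]$data[, keep, drop = FALSE]
    prov[[i]] <- data.frame(block = i, orig_start = ntrim + 1L,
                            orig_end = n - ntrim)
  }
  condition_segment(do.call(cbind, pieces), fs,
                    condition = blocks[[1]]$condition,
                    subject = blocks[[1]]$subject,
                    session = blocks[[1]]$session,
                    provenance = do.call(rbind, prov))
}

#' Standard preprocessing of one condition recording
#'
#' DC removal, average reference, then per-clip edge trimming and
#' concatenation — the stage order of the sensor-space pipeline. Action
#' recordings are split at their recorded clip boundaries before trimming.
#'
#' @param rec an `eeg_recording` (multi-clip action block or resting block).
#' @param trim_seconds seconds trimmed from each clip end (2 for action
#'   clips, 10 for resting blocks in the standard configuration).
#' @return a `condition_segment`.
#' @export
preprocess_condition <- function(rec, trim_seconds) {
  rec <- average_reference(remove_dc(rec))
  trim_and_concatenate(split_clips(rec), trim_seconds)
}
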