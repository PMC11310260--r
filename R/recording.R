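#' EEG recording container
#'
#' A minimal in-memory container for one multi-channel EEG block: a real
#' matrix `[channels x samples]`, the sampling rate, channel labels, and
#' subject/session/condition tags. Clip boundaries (for action-video blocks
#' made of several concatenated clips) are carried in `clips` as 1-based
#' inclusive sample ranges.
#'
#' @param data numeric matrix, channels in rows.
#' @param fs sampling rate in Hz.
#' @param channels character vector of channel labels (defaults to rownames).
#' @param condition,subject,session metadata tags.
#' @param clips optional data.frame with columns `clip`, `start`, `end`.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channels = rownames(data),
                          condition = NA_character_, subject = NA_character_,
                          session = NA_character_, clips = NULL) {
  assert_that(is.matrix(data) && is.numeric(data) && length(data) > 0,
              "invalid_input", "data must be a non-empty numeric matrix")
  assert_that(is.numeric(fs) && fs > 0, "invalid_input", "fs must be positive")
  if (is.null(channels)) channels <- sprintf("ch%02d", seq_len(nrow(data)))
  assert_that(length(channels) == nrow(data), "invalid_input",
              "one label per channel row required")
  rownames(data) <- channels
  structure(list(data = data, fs = fs, channels = channels,
                 condition = condition, subject = subject, session = session,
                 clips = clips),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz [%s / %s / %s]\n",
              nrow(x$data), ncol(x$data), x$fs,
              x$subject, x$session, x$condition))
  invisible(x)
}

#' Split a multi-clip recording into per-clip blocks
#'
#' @param rec an `eeg_recording` whose `clips` table is set.
#' @return list of `eeg_recording`, one per clip, in clip order.
#' @export
split_clips <- function(rec) {
  if (is.null(rec$clips)) return(list(rec))
  lapply(seq_len(nrow(rec$clips)), function(i) {
    rng <- rec$clips$start[i]:rec$clips$end[i]
    eeg_recording(rec$data[, rng, drop = FALSE], rec$fs, rec$channels,
                  rec$condition, rec$subject, rec$session)
  })
}
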