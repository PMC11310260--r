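# Four-band threshold neurofeedback protocol.
#
# The feedback signal is a single derived channel (sum of C3 and C4). Band
# amplitudes are estimated by a zero-phase band-pass followed by a sliding
# RMS * sqrt(2) (amplitude convention: a pure sinusoid of amplitude A reads
# as A). Feedback succeeds while ALL trained bands stay strictly below their
# thresholds for at least the hold time. Thresholds are calibrated on a
# baseline span as a common quantile of each band's amplitude distribution,
# with the quantile found by bisection so the baseline success fraction
# lands in the target range.

#' Default trained frequency bands
#'
#' theta 4-7, mu 8-13, beta 14-30, high beta 20-40 Hz.
#'
#' @return data.frame with columns `name`, `lo`, `hi`.
#' @export
nft_bands <- function() {
  data.frame(name = c("theta", "mu", "beta", "high_beta"),
             lo = c(4, 8, 14, 20), hi = c(7, 13, 30, 40),
             stringsAsFactors = FALSE)
}

# zero-phase FFT band-pass (brick wall)
fft_bandpass <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  X[f < lo | f > hi] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Band amplitude envelope
#'
#' Zero-phase band-pass to `[lo, hi]` followed by a centred sliding-window
#' RMS scaled by sqrt(2), returned on the same sampling grid (edges padded
#' by replication). A steady sinusoid of amplitude A in the band reads as
#' approximately A.
#'
#' @param signal single-channel numeric series.
#' @param lo,hi band edges in Hz (hi must be below Nyquist).
#' @param fs sampling rate (Hz).
#' @param window_sec RMS window length in seconds (default 0.25 s, the
#'   standard neurofeedback amplitude estimator scale).
#' @return nonnegative amplitude series, same length as the input.
#' @export
band_amplitude <- function(signal, lo, hi, fs, window_sec = 0.25) {
  assert_that(fs > 2 * hi, "invalid_band",
              sprintf("band edge %g Hz at or above Nyquist (fs = %g)", hi, fs))
  y <- fft_bandpass(signal, fs, lo, hi)
  w <- max(1L, round(window_sec * fs))
  half <- w %/% 2
  y2 <- c(rep(y[1]^2, half), y^2, rep(y[length(y)]^2, w - half - 1L))
  cs <- cumsum(c(0, y2))
  ma <- (cs[(w + 1):length(cs)] - cs[seq_len(length(cs) - w)]) / w
  sqrt(pmax(ma, 0)) * sqrt(2)
}

#' Amplitudes of all trained bands
#'
#' @param signal single-channel series (the C3+C4 montage signal).
#' @param fs sampling rate.
#' @param bands band table as from [nft_bands()].
#' @param window_sec RMS window.
#' @return matrix `[bands x samples]`, row names = band names.
#' @export
multi_band_amplitudes <- function(signal, fs, bands = nft_bands(),
                                  window_sec = 0.25) {
  out <- t(vapply(seq_len(nrow(bands)), function(i)
    band_amplitude(signal, bands$lo[i], bands$hi[i], fs, window_sec),
    numeric(length(signal))))
  rownames(out) <- bands$name
  out
}

#' Fraction of successful feedback samples
#'
#' A sample is successful when it lies inside a run of at least
#' `min_hold * fs` consecutive samples during which EVERY band amplitude is
#' strictly below its threshold. With `min_hold = 0` this reduces to the
#' plain below-threshold sample fraction.
#'
#' @param amplitudes matrix `[bands x samples]`.
#' @param thresholds per-band nonnegative scalars (recycled names checked
#'   when present).
#' @param fs sampling rate.
#' @param min_hold minimum hold time in seconds.
#' @return fraction in `[0, 1]`.
#' @export
success_fraction <- function(amplitudes, thresholds, fs, min_hold = 1) {
  amplitudes <- rbind(amplitudes)
  assert_that(length(thresholds) == nrow(amplitudes), "inconsistent_input",
              "one threshold per band required")
  below <- colSums(amplitudes >= thresholds) == 0   # strict: all bands below
  if (!length(below)) return(0)
  need <- max(1L, ceiling(min_hold * fs))
  r <- rle(below)
  ok <- r$values & r$lengths >= need
  sum(r$lengths[ok]) / length(below)
}

#' Calibrate per-band thresholds to a target success range
#'
#' Thresholds are coupled through a single common quantile q of each band's
#' baseline amplitude distribution (one degree of freedom, since the
#' protocol states one success range, not per-band targets). q is found by
#' bisection so that the baseline success fraction falls inside `target`.
#'
#' @param baseline_amplitudes matrix `[bands x samples]` over the baseline
#'   span (>= 60 s in the standard protocol).
#' @param fs sampling rate.
#' @param target success-fraction interval, e.g. `c(0.75, 0.80)` for early
#'   sessions, `c(0.65, 0.75)` for late ones.
#' @param min_hold hold time passed to [success_fraction()].
#' @param max_iter bisection iteration cap.
#' @return list `thresholds` (named per band), `quantile`, `achieved`
#'   (success fraction at the returned thresholds).
#' @export
calibrate_thresholds <- function(baseline_amplitudes, fs,
                                 target = c(0.75, 0.80), min_hold = 1,
                                 max_iter = 60) {
  baseline_amplitudes <- rbind(baseline_amplitudes)
  f_at <- function(q) {
    thr <- apply(baseline_amplitudes, 1, stats::quantile, probs = q,
                 names = FALSE, type = 7)
    list(thr = thr, frac = success_fraction(baseline_amplitudes, thr, fs, min_hold))
  }
  lo <- 0; hi <- 1
  for (i in seq_len(max_iter)) {
    q <- (lo + hi) / 2
    r <- f_at(q)
    if (r$frac < target[1]) lo <- q
    else if (r$frac > target[2]) hi <- q
    else {
      return(list(thresholds = stats::setNames(r$thr, rownames(baseline_amplitudes)),
                  quantile = q, achieved = r$frac))
    }
  }
  msr_error("calibration_failure",
            sprintf(paste("no quantile reaches the target success range",
                          "[%.2f, %.2f]; last q = %.4f gave %.4f",
                          "(degenerate or discrete amplitude distribution?)"),
                    target[1], target[2], q, r$frac))
}

#' One neurofeedback session record
#'
#' @param amplitudes matrix `[bands x samples]` over the whole session.
#' @param fs sampling rate.
#' @param baseline_span,feedback_span 1-based inclusive sample ranges
#'   `c(start, end)`.
#' @param thresholds optional per-band thresholds in force.
#' @param session session identifier.
#' @return object of class `nft_session`.
#' @export
nft_session <- function(amplitudes, fs, baseline_span, feedback_span,
                        thresholds = NULL, session = NA) {
  for (span in list(baseline_span, feedback_span)) {
    assert_that(length(span) == 2 && span[1] >= 1 &&
                span[2] <= ncol(amplitudes) && span[1] <= span[2],
                "incomplete_session", "invalid baseline/feedback span")
  }
  structure(list(amplitudes = amplitudes, fs = fs,
                 baseline_span = baseline_span,
                 feedback_span = feedback_span,
                 thresholds = thresholds, session = session),
            class = "nft_session")
}

#' Feedback-minus-baseline course over sessions
#'
#' Per band and session: mean amplitude over the feedback span minus mean
#' over the baseline span. The long table feeds [rm_anova()] directly
#' (factors session x band x feedback condition).
#'
#' @param sessions list of `nft_session`.
#' @return data.frame with columns `session`, `band`, `baseline_mean`,
#'   `feedback_mean`, `diff` (microvolts when the input is in microvolts).
#' @export
session_course <- function(sessions) {
  rows <- lapply(sessions, function(s) {
    assert_that(inherits(s, "nft_session"), "incomplete_session",
                "list of nft_session required")
    b <- s$amplitudes[, s$baseline_span[1]:s$baseline_span[2], drop = FALSE]
    f <- s$amplitudes[, s$feedback_span[1]:s$feedback_span[2], drop = FALSE]
    data.frame(session = s$session, band = rownames(s$amplitudes),
               baseline_mean = rowMeans(b), feedback_mean = rowMeans(f),
               diff = rowMeans(f) - rowMeans(b), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
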