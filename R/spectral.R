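# Welch power spectral density, applied identically to channel signals and
# to source time courses.
#
# Normalisation follows the one-sided density convention: with taper w of
# length L, PSD(f) = |X(f)|^2 / (fs * sum(w^2)), doubled at all bins except
# DC and Nyquist, so that sum(PSD) * df approximates the signal variance
# (Parseval-consistent). Per-window spectra are averaged arithmetically.

hamming_window <- function(L) {
  if (L == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
}

#' Welch PSD of a condition segment
#'
#' Overlapping tapered windows are moved across the segment; each window's
#' FFT power is density-normalised and the estimates averaged. With the
#' defaults (2-s Hamming windows, 50% overlap) a 512-Hz segment yields
#' 1024-point transforms on a 0.5-Hz frequency grid.
#'
#' @param seg a `condition_segment` (or any channels-x-samples matrix plus
#'   `fs`) at least one window long.
#' @param window_sec window length in seconds.
#' @param overlap fractional window overlap in `[0, 1)`.
#' @param fs sampling rate; taken from `seg` when it is a segment.
#' @return object of class `spectrum_set`: `psd` `[locations x bins]` in
#'   signal^2/Hz, `freqs` (Hz), `window_sec`, `overlap`, `n_windows`.
#' @export
welch_psd <- function(seg, window_sec = 2, overlap = 0.5, fs = NULL) {
  if (inherits(seg, "condition_segment")) {
    x <- seg$data; fs <- seg$fs
  } else {
    x <- as.matrix(seg)
    assert_that(!is.null(fs), "invalid_input", "fs required for matrix input")
  }
  L <- round(window_sec * fs)
  N <- ncol(x)
  assert_that(N >= L, "invalid_input",
              sprintf("segment (%d samples) shorter than one window (%d)", N, L))
  assert_that(overlap >= 0 && overlap < 1, "invalid_input",
              "overlap must lie in [0, 1)")
  step <- max(1L, round(L * (1 - overlap)))
  starts <- window_starts(N, L, step)
  w <- hamming_window(L)
  scale <- 1 / (fs * sum(w^2))
  nb <- L %/% 2 + 1L
  acc <- matrix(0, nrow(x), nb)
  for (s0 in starts) {
    seg_w <- t(x[, s0:(s0 + L - 1L), drop = FALSE]) * w   # [L x channels]
    X <- stats::mvfft(seg_w)
    P <- (Mod(X[seq_len(nb), , drop = FALSE])^2) * scale
    # one-sided doubling, DC and (even-L) Nyquist excepted
    if (nb > 2) P[2:(nb - 1L + (L %% 2L)), ] <- 2 * P[2:(nb - 1L + (L %% 2L)), ]
    acc <- acc + t(P)
  }
  psd <- acc / length(starts)
  rownames(psd) <- rownames(x)
  structure(list(psd = psd, freqs = (seq_len(nb) - 1) / window_sec,
                 window_sec = window_sec, overlap = overlap,
                 n_windows = length(starts), fs = fs),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d locations x %d bins (0-%g Hz, df = %g), %d windows\n",
              nrow(x$psd), ncol(x$psd), max(x$freqs), 1 / x$window_sec,
              x$n_windows))
  invisible(x)
}

#' Mean band power
#'
#' Arithmetic mean of the PSD over all frequency bins `lo <= f <= hi`
#' (inclusive endpoints: on a 0.5-Hz grid, 8-13 Hz covers 11 bins).
#'
#' @param spec a `spectrum_set`.
#' @param lo,hi band edges in Hz.
#' @return object of class `band_power`: `power` (named per location,
#'   signal^2/Hz), `band`, `n_bins`.
#' @export
band_power <- function(spec, lo = 8, hi = 13) {
  sel <- spec$freqs >= lo - 1e-9 & spec$freqs <= hi + 1e-9
  assert_that(any(sel), "invalid_band",
              sprintf("no frequency bins in [%g, %g] Hz", lo, hi))
  structure(list(power = rowMeans(spec$psd[, sel, drop = FALSE]),
                 band = c(lo, hi), n_bins = sum(sel)),
            class = "band_power")
}
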