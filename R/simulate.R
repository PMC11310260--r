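# Forward-model EEG study generator.
#
# Each oscillatory source is band-limited Gaussian noise (FFT brick-wall
# filtered into its band) normalised to unit RMS, scaled by
# base_amplitude * gain(condition), and projected through the spherical lead
# field. The sensor background is 1/f ("pink") noise plus white sensor noise.
# Because a gain `a` multiplies the source amplitude, band POWER scales as
# a^2 and the true Mu Suppression Index of a gain-`a` condition against a
# gain-1 baseline is exactly 2*log10(a).

#' Oscillatory source specification
#'
#' @param vertex_index mesh vertex carrying the source.
#' @param band_lo,band_hi band edges in Hz (`band_lo < band_hi`).
#' @param base_amplitude RMS amplitude (arbitrary units) at gain 1.
#' @param condition_gains named numeric vector of multiplicative amplitude
#'   gains, one entry per condition label. A gain `a` against a gain-1
#'   baseline corresponds to a true MSI of `2*log10(a)`.
#' @param session_gains optional named list (`pre`, `post`, ...) of
#'   condition-gain vectors overriding `condition_gains` in specific sessions.
#' @return object of class `source_spec`.
#' @export
source_spec <- function(vertex_index, band_lo = 8, band_hi = 13,
                        base_amplitude = 1, condition_gains,
                        session_gains = NULL) {
  assert_that(band_lo < band_hi, "configuration_error", "band_lo must be < band_hi")
  assert_that(base_amplitude > 0, "configuration_error", "base_amplitude must be > 0")
  assert_that(all(condition_gains > 0) || all(condition_gains >= 0),
              "configuration_error", "gains must be >= 0")
  assert_that(!is.null(names(condition_gains)), "configuration_error",
              "condition_gains must be named by condition")
  structure(list(vertex_index = vertex_index, band_lo = band_lo,
                 band_hi = band_hi, base_amplitude = base_amplitude,
                 condition_gains = condition_gains,
                 session_gains = session_gains),
            class = "source_spec")
}

gain_for <- function(spec, condition, session = NULL) {
  g <- spec$condition_gains
  if (!is.null(session) && !is.null(spec$session_gains) &&
      session %in% names(spec$session_gains)) {
    ov <- spec$session_gains[[session]]
    g[names(ov)] <- ov
  }
  assert_that(condition %in% names(g), "configuration_error",
              sprintf("condition '%s' not in source condition_gains", condition))
  unname(g[[condition]])
}

#' Simulation configuration
#'
#' Defaults mirror the study design being emulated: 16 subjects, two sessions
#' (`pre`, `post`), four action-video conditions of five 24-s clips each plus
#' two 120-s resting conditions, 64 channels at 512 Hz.
#'
#' @param n_subjects,n_sessions counts.
#' @param conditions ordered condition labels; labels starting with `rest`
#'   are treated as resting blocks.
#' @param clip_seconds,clips_per_condition action-block substructure.
#' @param rest_seconds resting-block length.
#' @param fs sampling rate (Hz); must exceed twice every source band edge.
#' @param noise_sd white sensor-noise standard deviation (same units as the
#'   projected sources).
#' @param pink_sd RMS of the per-channel 1/f background.
#' @param pink_exponent spectral slope of the background (PSD ~ 1/f^exponent).
#' @param subject_jitter_sd log-normal sdlog of the per-subject amplitude
#'   jitter (drawn once per subject; multiplies every source equally, so it
#'   cancels in power ratios but makes absolute powers subject-specific).
#' @param seed integer RNG seed for the whole study.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 16, n_sessions = 2,
                       conditions = c("balls", "simple", "complex", "social",
                                      "rest_open", "rest_closed"),
                       clip_seconds = 24, clips_per_condition = 5,
                       rest_seconds = 120, fs = 512,
                       noise_sd = 1, pink_sd = 1, pink_exponent = 1,
                       subject_jitter_sd = 0.2, seed = 1L) {
  assert_that(is_count(n_subjects) && is_count(n_sessions) &&
              is_count(clips_per_condition), "configuration_error",
              "counts must be positive integers")
  assert_that(fs > 0 && clip_seconds > 0 && rest_seconds > 0,
              "configuration_error", "durations and fs must be positive")
  structure(list(n_subjects = n_subjects, n_sessions = n_sessions,
                 conditions = conditions, clip_seconds = clip_seconds,
                 clips_per_condition = clips_per_condition,
                 rest_seconds = rest_seconds, fs = fs, noise_sd = noise_sd,
                 pink_sd = pink_sd, pink_exponent = pink_exponent,
                 subject_jitter_sd = subject_jitter_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

session_labels <- function(cfg) {
  if (cfg$n_sessions == 2) c("pre", "post") else sprintf("s%02d", seq_len(cfg$n_sessions))
}

is_rest_condition <- function(condition) startsWith(condition, "rest")

# FFT brick-wall band-pass of white Gaussian noise, unit-RMS normalised.
band_limited_noise <- function(n, fs, lo, hi) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequency map
  X[f < lo | f > hi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- sqrt(mean(y^2))
  if (s == 0) rep(0, n) else y / s
}

# 1/f background, one column per channel, unit RMS per channel. Built
# directly as a random-phase Hermitian spectrum shaped by f^(-exponent/2)
# (one inverse FFT per block instead of a forward/backward pair).
pink_noise <- function(n, n_channels, fs, exponent) {
  nh <- n %/% 2
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  shape <- ifelse(f <= 0, 0, f^(-exponent / 2))
  kpos <- 2:(nh + 1)                      # positive-frequency bins
  npos <- length(kpos)
  X <- matrix(0 + 0i, n, n_channels)
  Z <- matrix(complex(real = stats::rnorm(npos * n_channels),
                      imaginary = stats::rnorm(npos * n_channels)),
              npos, n_channels)
  if (n %% 2 == 0) Z[npos, ] <- complex(real = Re(Z[npos, ]) * sqrt(2))
  X[kpos, ] <- Z * shape[kpos]
  X[n + 2 - kpos[-npos], ] <- Conj(X[kpos[-npos], , drop = FALSE])
  if (n %% 2 == 1) X[n + 2 - kpos[npos], ] <- Conj(X[kpos[npos], ])
  Y <- Re(stats::mvfft(X, inverse = TRUE)) / n
  s <- sqrt(colMeans(Y^2))
  s[s == 0] <- 1
  sweep(Y, 2, s, "/")
}

#' Simulate one condition block
#'
#' Generates a single multi-channel recording for one condition: band-limited
#' unit-RMS source signals scaled by `base_amplitude * gain(condition)`,
#' projected through the model's lead field, plus 1/f background and white
#' sensor noise. Byte-identical output for identical arguments and seed.
#'
#' @param model a `source_model`.
#' @param sources list of `source_spec`.
#' @param condition condition label; must appear in every source's gain map.
#' @param duration block length in seconds (`duration * fs` must be integral).
#' @param cfg a `sim_config` (noise and fs settings are taken from it).
#' @param seed integer seed for this block.
#' @param session optional session label for session-specific gains.
#' @param amplitude_scale extra multiplicative amplitude factor (the
#'   per-subject jitter; default 1).
#' @param subject,clips metadata passed through to the recording.
#' @return an `eeg_recording` `[n_channels x duration*fs]`.
#' @export
simulate_condition <- function(model, sources, condition, duration, cfg,
                               seed = cfg$seed, session = NULL,
                               amplitude_scale = 1, subject = NA_character_,
                               clips = NULL) {
  n <- round(duration * cfg$fs)
  assert_that(abs(duration * cfg$fs - n) < 1e-9, "configuration_error",
              "duration * fs must be an integer number of samples")
  for (s in sources) {
    assert_that(cfg$fs > 2 * s$band_hi, "configuration_error",
                "fs must exceed twice every source band edge")
  }
  nch <- nrow(model$leadfield)
  set.seed(as.integer(seed))
  sensor <- matrix(0, nch, n)
  for (s in sources) {
    g <- gain_for(s, condition, session)
    # the waveform is always drawn so the RNG stream (and hence every other
    # source and the background) is identical across gain settings
    wav <- band_limited_noise(n, cfg$fs, s$band_lo, s$band_hi)
    amp <- s$base_amplitude * g * amplitude_scale
    if (amp != 0) {
      sensor <- sensor + model$leadfield[, s$vertex_index] %o% (amp * wav)
    }
  }
  if (cfg$pink_sd > 0) {
    sensor <- sensor + cfg$pink_sd * t(pink_noise(n, nch, cfg$fs, cfg$pink_exponent))
  }
  if (cfg$noise_sd > 0) {
    sensor <- sensor + matrix(stats::rnorm(nch * n, sd = cfg$noise_sd), nch, n)
  }
  eeg_recording(sensor, cfg$fs, model$channels$label, condition = condition,
                subject = subject, session = session %||% NA_character_,
                clips = clips)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full study
#'
#' One recording per subject x session x condition. Action conditions are one
#' contiguous block of `clips_per_condition * clip_seconds` seconds with clip
#' boundaries recorded in the `clips` table; resting conditions are one
#' `rest_seconds` block. A log-normal amplitude jitter is drawn once per
#' subject and applied to every source. The returned ground truth tabulates
#' the per-cell amplitude gain and the implied true MSI `2*log10(gain)`.
#'
#' @param cfg a `sim_config`.
#' @param sources list of `source_spec`.
#' @param model a `source_model`.
#' @return list with `recordings` (flat list of `eeg_recording`), `index`
#'   (data.frame subject/session/condition/role -> list position) and
#'   `ground_truth` (data.frame with columns subject, session, condition,
#'   source, vertex, gain, true_msi).
#' @export
simulate_study <- function(cfg, sources, model) {
  subjects <- sprintf("sub%02d", seq_len(cfg$n_subjects))
  sessions <- session_labels(cfg)
  set.seed(split_seed(cfg$seed, "subject_jitter"))
  jitter <- stats::rlnorm(cfg$n_subjects, 0, cfg$subject_jitter_sd)

  recs <- list(); idx <- list(); gt <- list(); k <- 0L
  for (si in seq_along(subjects)) {
    for (se in sessions) {
      for (co in cfg$conditions) {
        rest <- is_rest_condition(co)
        dur <- if (rest) cfg$rest_seconds else cfg$clip_seconds * cfg$clips_per_condition
        clips <- NULL
        if (!rest) {
          nclip <- round(cfg$clip_seconds * cfg$fs)
          clips <- data.frame(clip = seq_len(cfg$clips_per_condition),
                              start = (seq_len(cfg$clips_per_condition) - 1L) * nclip + 1L,
                              end = seq_len(cfg$clips_per_condition) * nclip)
        }
        sd_block <- split_seed(cfg$seed, paste(subjects[si], se, co, sep = "/"))
        k <- k + 1L
        recs[[k]] <- simulate_condition(model, sources, co, dur, cfg,
                                        seed = sd_block, session = se,
                                        amplitude_scale = jitter[si],
                                        subject = subjects[si], clips = clips)
        idx[[k]] <- data.frame(subject = subjects[si], session = se,
                               condition = co,
                               role = if (rest) "rest" else "action",
                               position = k, stringsAsFactors = FALSE)
        for (j in seq_along(sources)) {
          g <- gain_for(sources[[j]], co, se)
          gt[[length(gt) + 1L]] <- data.frame(
            subject = subjects[si], session = se, condition = co,
            source = j, vertex = sources[[j]]$vertex_index,
            gain = g, true_msi = 2 * log10(g), stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(recordings = recs, index = do.call(rbind, idx),
       ground_truth = do.call(rbind, gt))
}

#' Default source layout for a mu-suppression study
#'
#' A central mu source at the vertex nearest C3 and an occipital alpha
#' confound at the vertex nearest Oz (the posterior-alpha leakage concern the
#' analysis is designed around). All gains default to 1; pass `mu_gains` /
#' `mu_session_gains` to install condition effects.
#'
#' @param model a `source_model` with labelled montage.
#' @param conditions condition labels to populate gain maps for.
#' @param mu_amplitude,alpha_amplitude base RMS amplitudes. Defaults give the
#'   mu source a band SNR of order 100 at its nearest channel under the
#'   default unit noise levels (a clean but not noise-free world).
#' @param mu_gains,mu_session_gains gain map / per-session overrides for the
#'   mu source.
#' @return list of two `source_spec`.
#' @export
default_sources <- function(model,
                            conditions = c("balls", "simple", "complex",
                                           "social", "rest_open", "rest_closed"),
                            mu_amplitude = 1, alpha_amplitude = 1.5,
                            mu_gains = NULL, mu_session_gains = NULL) {
  unit <- stats::setNames(rep(1, length(conditions)), conditions)
  if (is.null(mu_gains)) mu_gains <- unit
  # canonical C3/Oz directions from the standard montage, so source placement
  # works even when the model's own montage lacks those labels
  std <- standard_montage_64()
  pos <- function(lab) as.numeric(std[std$label == lab, c("x", "y", "z")])
  list(
    mu = source_spec(nearest_vertex(model, pos("C3")), 8, 13, mu_amplitude,
                     mu_gains, mu_session_gains),
    alpha = source_spec(nearest_vertex(model, pos("Oz")), 8, 13,
                        alpha_amplitude, unit)
  )
}
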