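# independent brute-force oracle for the >= min_hold success rule
run_scan_oracle <- function(amplitudes, thresholds, fs, min_hold) {
  below <- apply(rbind(amplitudes) < thresholds, 2, all)
  need <- max(1, ceiling(min_hold * fs))
  good <- logical(length(below))
  i <- 1
  while (i <= length(below)) {
    if (below[i]) {
      j <- i
      while (j < length(below) && below[j + 1]) j <- j + 1
      if (j - i + 1 >= need) good[i:j] <- TRUE
      i <- j + 1
    } else i <- i + 1
  }
  mean(good)
}

test_that("band_amplitude tracks sinusoid amplitude and rejects out-of-band", {
  fs <- 256; t <- (0:(fs * 10 - 1)) / fs
  s <- 2.5 * sin(2 * pi * 10 * t)
  amp <- band_amplitude(s, 8, 13, fs)
  core <- amp[(fs):(length(amp) - fs)]          # steady state
  expect_equal(mean(core), 2.5, tolerance = 0.02)
  theta <- band_amplitude(s, 4, 7, fs)
  expect_lt(mean(theta[(fs):(length(theta) - fs)]) / 2.5, 0.1)  # >= 20 dB down
  expect_true(all(band_amplitude(rep(0, fs), 8, 13, fs) == 0))
  expect_error(band_amplitude(s, 100, 140, fs), class = "invalid_band")
})

test_that("success_fraction limits and oracle equivalence", {
  fs <- 16
  set.seed(30)
  amps <- matrix(abs(rnorm(2 * 200)), 2)
  expect_equal(success_fraction(amps, c(Inf, Inf), fs, 1), 1.0)
  expect_equal(success_fraction(amps, c(0, 0), fs, 1), 0.0)
  for (i in 1:10) {
    a <- matrix(abs(rnorm(2 * 150)), 2)
    thr <- runif(2, 0.3, 2)
    hold <- sample(c(0, 0.25, 0.5, 1), 1)
    expect_equal(success_fraction(a, thr, fs, hold),
                 run_scan_oracle(a, thr, fs, hold))
  }
  # min_hold = 0 reduces to the plain below-threshold fraction
  a <- matrix(abs(rnorm(300)), 1)
  expect_equal(success_fraction(a, 0.8, fs, 0), mean(a < 0.8))
  expect_error(success_fraction(a, c(1, 2), fs), class = "inconsistent_input")
})

test_that("success_fraction is monotone in thresholds", {
  fs <- 16
  set.seed(31)
  a <- matrix(abs(rnorm(4 * 400)), 4)
  thr <- rep(0.5, 4)
  f0 <- success_fraction(a, thr, fs, 0.5)
  for (k in 1:4) {
    up <- thr; up[k] <- 1.5
    expect_gte(success_fraction(a, up, fs, 0.5), f0)
  }
})

test_that("calibration lands in target and is idempotent", {
  fs <- 64
  set.seed(32)
  # continuous single-band case, min_hold 0: q converges near 0.775
  a1 <- matrix(abs(rnorm(fs * 120)) + 0.1, 1)
  cal <- calibrate_thresholds(a1, fs, target = c(0.75, 0.80), min_hold = 0)
  expect_gte(cal$achieved, 0.75); expect_lte(cal$achieved, 0.80)
  # with min_hold 0 and a continuous distribution, success ~ q, so the
  # bisection settles near the target band (entry is at the 0.75 boundary)
  expect_equal(cal$quantile, 0.775, tolerance = 0.05)
  # four-band correlated series (smoothed), target [0.65, 0.75], 1-s hold
  sig <- rnorm(fs * 120)
  a4 <- multi_band_amplitudes(sig, fs, nft_bands()[nft_bands()$hi < fs / 2, ])
  cal4 <- calibrate_thresholds(a4, fs, target = c(0.65, 0.75), min_hold = 1)
  f <- success_fraction(a4, cal4$thresholds, fs, 1)
  expect_equal(f, cal4$achieved)
  expect_gte(f, 0.65); expect_lte(f, 0.75)
  # recalibration with the achieved thresholds stays in target
  expect_equal(run_scan_oracle(a4, cal4$thresholds, fs, 1), cal4$achieved)
  # degenerate constant amplitudes cannot be calibrated
  expect_error(calibrate_thresholds(matrix(1, 1, fs * 60), fs),
               class = "calibration_failure")
})

test_that("session_course differences and trend recovery", {
  fs <- 32
  bands <- c("theta", "mu", "beta", "high_beta")
  mk <- function(level_fb, level_bl, session) {
    amp <- matrix(rep(c(rep(level_bl, fs * 10), rep(level_fb, fs * 30)),
                      each = 4), 4, byrow = FALSE,
                  dimnames = list(bands, NULL))
    nft_session(amp, fs, c(1, fs * 10), c(fs * 10 + 1, fs * 40),
                session = session)
  }
  s0 <- mk(1, 1, 1)
  expect_true(all(session_course(list(s0))$diff == 0))
  s1 <- mk(0.5, 1.0, 2)
  expect_equal(session_course(list(s1))$diff, rep(-0.5, 4))
  # declining mu across 15 sessions: regression slope sign recovered
  set.seed(33)
  sims <- lapply(1:15, function(k) mk(1 - 0.02 * k + rnorm(1, sd = 0.005), 1, k))
  course <- session_course(sims)
  mu <- course[course$band == "mu", ]
  expect_lt(coef(lm(diff ~ session, mu))[2], 0)
  expect_error(nft_session(matrix(1, 4, 10), fs, c(1, 20), c(5, 8)),
               class = "incomplete_session")
})
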