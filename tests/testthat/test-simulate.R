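test_that("all-zero world yields an all-zero recording", {
  m <- tiny_model()
  cfg <- sim_config(fs = 128, noise_sd = 0, pink_sd = 0, seed = 1)
  src <- source_spec(1, 8, 13, 1, c(balls = 0, complex = 0))
  r <- simulate_condition(m, list(src), "complex", 2, cfg, seed = 1)
  expect_true(all(r$data == 0))
})

test_that("fixed seed gives identical output; unknown condition errors", {
  m <- tiny_model()
  cfg <- sim_config(fs = 128, seed = 1)
  src <- source_spec(1, 8, 13, 1, unit_gains())
  r1 <- simulate_condition(m, list(src), "complex", 2, cfg, seed = 9)
  r2 <- simulate_condition(m, list(src), "complex", 2, cfg, seed = 9)
  expect_identical(r1$data, r2$data)
  expect_error(simulate_condition(m, list(src), "nope", 2, cfg, seed = 9),
               class = "configuration_error")
  expect_error(
    simulate_condition(m, list(source_spec(1, 8, 100, 1, unit_gains())),
                       "complex", 2, cfg, seed = 1),
    class = "configuration_error")
})

test_that("projected band power scales as gain^2 (noise off)", {
  m <- tiny_model()
  cfg <- sim_config(fs = 256, noise_sd = 0, pink_sd = 0, seed = 1)
  src1 <- source_spec(3, 8, 13, 1, c(balls = 1, complex = 1))
  srch <- source_spec(3, 8, 13, 1, c(balls = 1, complex = 0.5))
  rA <- simulate_condition(m, list(src1), "complex", 10, cfg, seed = 4)
  rB <- simulate_condition(m, list(srch), "complex", 10, cfg, seed = 4)
  ch <- which.max(apply(rA$data, 1, stats::var))
  ratio <- stats::var(rB$data[ch, ]) / stats::var(rA$data[ch, ])
  expect_equal(ratio, 0.25, tolerance = 0.01)
})

test_that("study layout counts recordings and fills ground truth", {
  m <- tiny_model()
  cfg <- sim_config(n_subjects = 2, n_sessions = 2,
                    conditions = c("balls", "simple", "complex", "social",
                                   "rest_open", "rest_closed"),
                    clip_seconds = 2, clips_per_condition = 2,
                    rest_seconds = 4, fs = 64, noise_sd = 0.1, pink_sd = 0,
                    seed = 2)
  gains <- stats::setNames(rep(1, 6), cfg$conditions)
  src <- source_spec(1, 8, 13, 1, gains,
                     session_gains = list(post = c(complex = 0.8)))
  st <- simulate_study(cfg, list(src), m)
  expect_equal(sum(st$index$role == "action"), 16)
  expect_equal(sum(st$index$role == "rest"), 8)
  # clip substructure recorded on action recordings
  act <- st$recordings[[st$index$position[st$index$role == "action"][1]]]
  expect_equal(nrow(act$clips), 2)
  expect_equal(act$clips$end[2], ncol(act$data))
  # ground truth: true MSI = 2*log10(gain), exact
  gt <- st$ground_truth
  expect_equal(gt$true_msi, 2 * log10(gt$gain))
  post_cx <- gt[gt$session == "post" & gt$condition == "complex", ]
  expect_equal(unique(post_cx$gain), 0.8)
  expect_equal(unique(post_cx$true_msi), 2 * log10(0.8), tolerance = 1e-12)
  # determinism of the whole dataset
  st2 <- simulate_study(cfg, list(src), m)
  expect_identical(st$recordings[[5]]$data, st2$recordings[[5]]$data)
})

test_that("band-limited noise stays in band and at unit RMS", {
  set.seed(3)
  x <- musuppr:::band_limited_noise(4096, 128, 8, 13)
  expect_equal(sqrt(mean(x^2)), 1, tolerance = 1e-12)
  sp <- welch_psd(matrix(x, 1), window_sec = 2, fs = 128)
  inband <- sp$freqs >= 8 & sp$freqs <= 13
  expect_gt(sum(sp$psd[1, inband]), 0.95 * sum(sp$psd[1, ]))
})
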