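test_that("remove_dc zeroes channel means", {
  r <- random_recording(seed = 2)
  r$data[1, ] <- 5                       # constant channel -> all zeros
  out <- remove_dc(r)
  expect_true(all(out$data[1, ] == 0))
  expect_lt(max(abs(rowMeans(out$data))),
            1e-12 * max(sqrt(rowMeans(out$data^2)), 1))
  # zero-mean sinusoid unchanged
  s <- sin(2 * pi * 8 * (0:255) / 128)
  r2 <- eeg_recording(rbind(s, -s), 128)
  expect_equal(remove_dc(r2)$data, r2$data, tolerance = 1e-12)
})

test_that("average_reference zeroes per-sample channel mean and is idempotent", {
  r <- random_recording(n_ch = 6, seed = 3)
  out <- average_reference(r)
  expect_lt(max(abs(colMeans(out$data))), 1e-12)
  expect_equal(average_reference(out)$data, out$data, tolerance = 1e-14)
  # [x, -x] unchanged; [x, x] -> zeros
  x <- rnorm(100)
  ra <- eeg_recording(rbind(x, -x), 100)
  expect_equal(average_reference(ra)$data, ra$data)
  rb <- eeg_recording(rbind(x, x), 100)
  expect_true(all(abs(average_reference(rb)$data) < 1e-14))
  expect_error(average_reference(eeg_recording(matrix(x, 1), 100)),
               class = "invalid_input")
})

test_that("trim_and_concatenate implements the 100-s contract", {
  fs <- 512
  blocks <- lapply(1:5, function(i)
    eeg_recording(matrix(i + 0, 2, 24 * fs), fs, c("C3", "C4"), "complex"))
  seg <- trim_and_concatenate(blocks, 2)
  expect_equal(ncol(seg$data), 51200)            # 100 s at 512 Hz
  rest <- eeg_recording(matrix(0, 2, 120 * fs), fs, c("C3", "C4"), "rest_open")
  expect_equal(ncol(trim_and_concatenate(list(rest), 10)$data), 100 * fs)
  # order preservation + invertible provenance
  expect_equal(unique(as.vector(seg$data[, 1:(20 * fs)])), 1)
  expect_equal(unique(as.vector(seg$data[, (80 * fs + 1):(100 * fs)])), 5)
  expect_equal(seg$provenance$orig_start, rep(2 * fs + 1, 5))
  # trim 0, one block -> identity
  one <- random_recording(seed = 4)
  expect_identical(trim_and_concatenate(list(one), 0)$data, one$data)
})

test_that("trim errors and length conservation", {
  fs <- 128
  b <- eeg_recording(matrix(0, 2, fs), fs)
  expect_error(trim_and_concatenate(list(b), 0.5), class = "invalid_trim")
  b2 <- eeg_recording(matrix(0, 3, fs), fs)
  expect_error(trim_and_concatenate(list(b, b2), 0.1),
               class = "inconsistent_input")
  set.seed(5)
  blocks <- lapply(sample(3:6, 4, replace = TRUE), function(k)
    eeg_recording(matrix(rnorm(2 * k * fs), 2), fs))
  trim <- 0.25
  seg <- trim_and_concatenate(blocks, trim)
  expect_equal(ncol(seg$data),
               sum(vapply(blocks, function(b) ncol(b$data), 1L)) -
                 2 * round(trim * fs) * length(blocks))
})
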