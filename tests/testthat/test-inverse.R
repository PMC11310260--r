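test_that("wMNE closed-form cases", {
  # L = identity, gamma 0, lambda2 0 -> K = identity
  m <- structure(list(leadfield = diag(5), seed = 1L), class = "source_model")
  K <- build_wmne(m, lambda2 = 0, depth_gamma = 0)
  expect_equal(K$kernel, diag(5), tolerance = 1e-12)
  # lambda2 -> infinity: K -> 0 elementwise
  Kinf <- build_wmne(m, lambda2 = 1e12, depth_gamma = 0)
  expect_lt(max(abs(Kinf$kernel)), 1e-10)
  # random square well-conditioned L, lambda2 0: K L ~ I (pseudo-inverse oracle)
  set.seed(6)
  L <- matrix(rnorm(100), 10, 10) + diag(10) * 3
  m2 <- structure(list(leadfield = L, seed = 1L), class = "source_model")
  K0 <- build_wmne(m2, lambda2 = 0, depth_gamma = 0)
  expect_equal(K0$kernel %*% L, diag(10), tolerance = 1e-8)
  expect_equal(K0$kernel, solve(L), tolerance = 1e-8)
  # rank-deficient Gram with lambda2 = 0 is a singular system
  m3 <- structure(list(leadfield = cbind(1, 1:4) %*% t(cbind(1, 1:3)),
                       seed = 1L), class = "source_model")
  expect_error(build_wmne(m3, lambda2 = 0, depth_gamma = 0),
               class = "singular_system")
})

test_that("depth weights follow the column-norm power law", {
  m <- model40()
  K <- build_wmne(m, depth_gamma = 0.5)
  expect_equal(K$depth_weights, colSums(m$leadfield^2)^(-0.5),
               ignore_attr = TRUE)
  expect_gt(K$lambda2, 0)
})

test_that("projection is linear and shape-correct", {
  m <- tiny_model()
  K <- build_wmne(m)
  set.seed(7)
  x <- condition_segment(matrix(rnorm(16 * 256), 16, 256,
                                dimnames = list(m$channels$label, NULL)),
                         128, "complex")
  y <- condition_segment(matrix(rnorm(16 * 256), 16, 256,
                                dimnames = list(m$channels$label, NULL)),
                         128, "complex")
  px <- project_segment(x, K); py <- project_segment(y, K)
  z <- x; z$data <- 2 * x$data - 3 * y$data
  pz <- project_segment(z, K)
  expect_equal(pz$data, 2 * px$data - 3 * py$data, tolerance = 1e-12)
  expect_equal(nrow(px$data), 20)
  # zero in, zero out; identity kernel passes through
  z0 <- x; z0$data[] <- 0
  expect_true(all(project_segment(z0, K)$data == 0))
  expect_equal(project_segment(x, diag(16))$data, x$data,
               ignore_attr = TRUE)
  bad <- x; bad$data <- bad$data[1:4, ]
  expect_error(project_segment(bad, K), class = "inconsistent_input")
})

test_that("source MSI shifts by 2*log10(k) when channel data scale by k", {
  m <- tiny_model()
  K <- build_wmne(m)
  set.seed(8)
  seg <- condition_segment(matrix(rnorm(16 * 512), 16, 512,
                                  dimnames = list(m$channels$label, NULL)),
                           128, "complex")
  base <- seg
  k <- 0.7
  seg2 <- seg; seg2$data <- k * seg$data
  p1 <- band_power(welch_psd(project_segment(seg, K)))$power
  p2 <- band_power(welch_psd(project_segment(seg2, K)))$power
  p0 <- band_power(welch_psd(project_segment(base, K)))$power
  expect_equal(compute_msi(p2, p0) - compute_msi(p1, p0),
               rep(2 * log10(k), 20), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("a simulated mu source localizes to the 1-ring of the true vertex", {
  m <- model40()
  K <- build_wmne(m)
  vtx <- nearest_vertex(m, "C3")
  ring <- one_ring(m, vtx)
  cfg <- sim_config(fs = 256, noise_sd = 1, pink_sd = 1, seed = 1)
  src <- list(source_spec(vtx, 8, 13, 1, c(complex = 1)))
  hits <- 0
  for (s in 1:5) {
    r <- simulate_condition(m, src, "complex", 10, cfg, seed = s)
    seg <- preprocess_condition(r, 0.5)
    bp <- band_power(welch_psd(project_segment(seg, K)))
    if (which.max(bp$power) %in% ring) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
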