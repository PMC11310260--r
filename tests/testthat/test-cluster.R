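grid_adjacency <- function(n) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1L
  A
}

test_that("paired_t_map equals the per-vertex scalar t oracle", {
  set.seed(20)
  A <- matrix(rnorm(16 * 10), 16, 10, dimnames = list(sprintf("s%02d", 1:16), NULL))
  B <- A + matrix(rnorm(160, sd = 0.5), 16, 10)
  t_map <- paired_t_map(A, B)
  expect_equal(attr(t_map, "df"), 15)
  for (v in 1:10) {
    o <- stats::t.test(B[, v] - A[, v])
    expect_equal(unname(t_map[v]), unname(o$statistic), tolerance = 1e-12)
  }
  # direction contract: constant negative difference at one vertex
  # (all-equal columns trigger the documented zero-variance warning)
  B2 <- A; B2[, 3] <- A[, 3] - 1 + rnorm(16, sd = 1e-3)
  expect_warning(t2 <- paired_t_map(A, B2), "zero-variance")
  expect_true(all(t2[-3] == 0))
  expect_lt(t2[3], -50)
  expect_error(paired_t_map(A[1:8, ], B), class = "pairing_error")
  rownames(B) <- rev(rownames(B))
  expect_error(paired_t_map(A, B), class = "pairing_error")
})

test_that("form_clusters matches threshold, sign and the igraph oracle", {
  skip_if_not_installed("igraph")
  df <- 15
  tcrit <- qt(0.975, df)
  expect_equal(tcrit, 2.131, tolerance = 1e-3)    # t quantile oracle
  adj <- grid_adjacency(8)
  # no supra-threshold vertex -> empty
  expect_length(form_clusters(rep(0.5, 8), adj, 0.05, df), 0)
  # isolated vertex
  tm <- c(0, 0, 3.0, 0, 0, 0, 0, 0)
  cl <- form_clusters(tm, adj, 0.05, df)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$vertices, 3)
  expect_equal(cl[[1]]$sum_t, 3.0)
  asym <- adj; asym[1, 2] <- 0L            # break symmetry on one edge
  expect_error(form_clusters(tm, asym, 0.05, df), class = "invalid_graph")

  m <- model40()
  set.seed(21)
  for (rep in 1:10) {
    tmap <- rnorm(40, sd = 2)
    cl <- form_clusters(tmap, m$adjacency, 0.05, df)
    # oracle: components of the same-sign thresholded subgraph via igraph
    g <- igraph::graph_from_adjacency_matrix(m$adjacency, mode = "undirected")
    found <- list()
    for (sgn in c(1, -1)) {
      keep <- which(sgn * tmap > tcrit)
      if (!length(keep)) next
      sub <- igraph::induced_subgraph(g, keep)
      comp <- igraph::components(sub)$membership
      for (k in unique(comp)) {
        found[[length(found) + 1L]] <- sort(keep[comp == k])
      }
    }
    got <- vapply(cl, function(c1) paste(c1$vertices, collapse = ","), "")
    want <- vapply(found, paste, "", collapse = ",")
    expect_identical(sort(got), sort(want))
    for (c1 in cl) expect_equal(c1$sum_t, sum(tmap[c1$vertices]))
  }
})

test_that("permutation_test is deterministic, sign-symmetric and bounded below", {
  m <- tiny_model()
  set.seed(22)
  D <- matrix(rnorm(12 * 20), 12, 20)
  D[, 1:3] <- D[, 1:3] - 1.2
  r1 <- permutation_test(D, m$adjacency, n_perm = 200, seed = 5)
  r2 <- permutation_test(D, m$adjacency, n_perm = 200, seed = 5)
  expect_identical(r1$clusters, r2$clusters)
  expect_identical(r1$null_distribution, r2$null_distribution)
  expect_true(all(r1$clusters$p >= 1 / 201))
  expect_true(all(r1$clusters$p <= 1))
  # sign symmetry: negating all differences negates sums, preserves p
  rn <- permutation_test(-D, m$adjacency, n_perm = 200, seed = 5)
  expect_equal(sort(rn$clusters$sum_t), sort(-r1$clusters$sum_t))
  expect_equal(sort(rn$clusters$p), sort(r1$clusters$p))
  expect_error(permutation_test(D, m$adjacency, n_perm = 0),
               class = "invalid_parameter")
})

test_that("strengthening a negative effect does not increase its p", {
  m <- tiny_model()
  set.seed(23)
  base <- matrix(rnorm(12 * 20), 12, 20)
  verts <- one_ring(m, 5)
  ps <- sapply(c(0.8, 1.6), function(c0) {
    D <- base; D[, verts] <- D[, verts] - c0
    r <- permutation_test(D, m$adjacency, n_perm = 300, seed = 9)
    main <- which.max(sapply(r$members, function(v) length(intersect(v, verts))))
    r$clusters$p[main]
  })
  expect_lte(ps[2], ps[1])
})

test_that("null on identical-with-noise maps yields no clusters", {
  set.seed(24)
  A <- matrix(rnorm(10 * 15), 10, 15)
  B <- A + matrix(rnorm(150, sd = 1e-4), 10, 15)
  tm <- paired_t_map(A, B)
  cl <- form_clusters(tm, grid_adjacency(15), 0.05, 9)
  # tiny symmetric noise: some t may fluctuate, but sums stay small
  if (length(cl)) expect_lt(max(abs(sapply(cl, `[[`, "sum_t"))), 30)
})
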