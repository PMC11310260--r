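# Cluster-based sign-flip permutation contrast of paired MSI maps.
#
# Per vertex: one-sample t on within-subject differences (B - A). Vertices
# with |t| above the two-tailed critical value at the cluster-forming alpha
# are partitioned into maximal connected same-sign components under the mesh
# adjacency; each cluster's statistic is its signed t-sum. The null is built
# by flipping the sign of each subject's whole difference map (the exact
# exchangeability-preserving relabeling for a paired design), recomputing
# clusters, and recording the single signed extreme (max |sum|) cluster sum
# per repetition. Observed clusters are significant when their sum falls
# below the 2.5th or above the 97.5th percentile of that distribution.

# vectorised per-vertex one-sample t on a subjects x vertices matrix;
# zero-variance vertices get t = 0 (keeps null simulations well-defined)
col_t_stats <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  v <- (colSums(D^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  se <- sqrt(v / n)
  t <- ifelse(se > 0, m / se, 0)
  t
}

#' Paired t-map over vertices
#'
#' One-sample t-statistics (df = n - 1) of the within-subject differences
#' `B - A` at every vertex. Vertices with zero difference variance are
#' assigned t = 0 (logged via a warning when it occurs on observed data).
#'
#' @param msi_a,msi_b subjects x vertices matrices of MSI values for the two
#'   sessions, with matching subject row order (row names checked when
#'   present).
#' @return named numeric vector of t values, one per vertex, with attribute
#'   `df`.
#' @export
paired_t_map <- function(msi_a, msi_b) {
  assert_that(all(dim(msi_a) == dim(msi_b)), "pairing_error",
              "MSI tables differ in shape")
  if (!is.null(rownames(msi_a)) && !is.null(rownames(msi_b))) {
    assert_that(identical(rownames(msi_a), rownames(msi_b)), "pairing_error",
                "subject sets / order differ between sessions")
  }
  assert_that(nrow(msi_a) >= 2, "pairing_error", "need at least 2 subjects")
  D <- msi_b - msi_a
  t <- col_t_stats(D)
  if (any(apply(D, 2, stats::sd) == 0)) {
    warning("zero-variance vertex encountered; t set to 0 there")
  }
  names(t) <- colnames(msi_a)
  attr(t, "df") <- nrow(D) - 1L
  t
}

# connected components (BFS) of the vertex subset `keep` under `adj`
components_bfs <- function(keep, adj) {
  comp <- integer(0); out <- list()
  remaining <- keep
  while (length(remaining)) {
    queue <- remaining[1]
    members <- queue
    remaining <- remaining[-1]
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- remaining[adj[v, remaining] != 0L]
      if (length(nb)) {
        members <- c(members, nb)
        queue <- c(queue, nb)
        remaining <- setdiff(remaining, nb)
      }
    }
    out[[length(out) + 1L]] <- sort(members)
  }
  out
}

#' Form supra-threshold clusters
#'
#' Thresholds the t-map at the two-tailed critical value for the given
#' cluster-forming alpha and df, then partitions supra-threshold vertices
#' into maximal connected components of a single sign under the mesh
#' adjacency. The cluster statistic is the signed sum of member t values.
#'
#' @param t_map per-vertex t values.
#' @param adjacency symmetric 0/1 vertex adjacency matrix.
#' @param alpha two-sided cluster-forming threshold probability.
#' @param df degrees of freedom of the t-map.
#' @return list of clusters, each `list(vertices, sum_t)`, ordered by
#'   decreasing |sum_t|; attribute `threshold_t` carries the critical value.
#' @export
form_clusters <- function(t_map, adjacency, alpha = 0.05, df) {
  assert_that(isTRUE(all(adjacency == t(adjacency))), "invalid_graph",
              "adjacency must be symmetric")
  assert_that(df >= 1, "invalid_graph", "df must be >= 1")
  tcrit <- stats::qt(1 - alpha / 2, df)
  out <- list()
  for (sgn in c(1, -1)) {
    keep <- which(sgn * t_map > tcrit)
    for (members in components_bfs(keep, adjacency)) {
      out[[length(out) + 1L]] <- list(vertices = members,
                                      sum_t = sum(t_map[members]))
    }
  }
  if (length(out)) out <- out[order(-abs(vapply(out, `[[`, 1.0, "sum_t")))]
  attr(out, "threshold_t") <- tcrit
  out
}

# signed extreme cluster sum (largest |sum|, sign kept; 0 if no clusters)
extreme_cluster_sum <- function(clusters) {
  if (!length(clusters)) return(0)
  sums <- vapply(clusters, `[[`, 1.0, "sum_t")
  sums[which.max(abs(sums))]
}

#' Cluster-based sign-flip permutation test
#'
#' Given per-subject difference maps (session B minus session A), computes
#' the observed t-map and clusters, then builds the permutation null by
#' independently flipping each subject's map sign, recomputing the t-map and
#' clusters, and recording the signed extreme cluster sum (0 when no cluster
#' forms) at each repetition. An observed cluster is significant when its
#' sum lies below the 2.5th or above the 97.5th percentile of the null
#' distribution; per-cluster p is the two-sided exceedance proportion with
#' the observed statistic included in the null (+1 numerator and
#' denominator), so p >= 1/(n_perm + 1) always.
#'
#' @param differences subjects x vertices matrix of per-subject MSI
#'   difference maps.
#' @param adjacency symmetric vertex adjacency matrix.
#' @param n_perm number of sign-flip repetitions.
#' @param alpha_cluster two-sided cluster-forming threshold.
#' @param alpha_fw family-wise two-sided percentile cut (0.05: 2.5/97.5).
#' @param seed RNG seed for the flips.
#' @return object of class `cluster_result`: `clusters` (data.frame id,
#'   size, sum_t, p, significant), `members` (list of vertex sets), `t_map`,
#'   `threshold_t`, `null_distribution`, `n_permutations`, `seed`.
#' @export
permutation_test <- function(differences, adjacency, n_perm = 1000,
                             alpha_cluster = 0.05, alpha_fw = 0.05,
                             seed = 1L) {
  assert_that(is_count(n_perm), "invalid_parameter", "n_perm must be >= 1")
  n <- nrow(differences)
  assert_that(n >= 2, "invalid_parameter", "need at least 2 subjects")
  df <- n - 1L
  t_obs <- col_t_stats(differences)
  obs_clusters <- form_clusters(t_obs, adjacency, alpha_cluster, df)
  tcrit <- attr(obs_clusters, "threshold_t")

  set.seed(as.integer(seed))
  null_dist <- numeric(n_perm)
  for (r in seq_len(n_perm)) {
    flips <- sample(c(-1, 1), n, replace = TRUE)
    tp <- col_t_stats(differences * flips)
    null_dist[r] <- extreme_cluster_sum(
      form_clusters(tp, adjacency, alpha_cluster, df))
  }

  qs <- stats::quantile(null_dist, c(alpha_fw / 2, 1 - alpha_fw / 2),
                        names = FALSE, type = 7)
  sums <- vapply(obs_clusters, `[[`, 1.0, "sum_t")
  pvals <- vapply(sums, function(s)
    (1 + sum(abs(null_dist) >= abs(s))) / (n_perm + 1), 1.0)
  res <- data.frame(id = seq_along(sums),
                    size = vapply(obs_clusters, function(cl) length(cl$vertices), 1L),
                    sum_t = sums, p = pvals,
                    significant = sums < qs[1] | sums > qs[2])
  if (!length(sums)) res <- res[0, ]
  structure(list(clusters = res,
                 members = lapply(obs_clusters, `[[`, "vertices"),
                 t_map = t_obs, threshold_t = tcrit,
                 null_distribution = null_dist,
                 n_permutations = n_perm,
                 percentiles = qs, seed = as.integer(seed)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d clusters (|t| > %.3f), %d permutations\n",
              nrow(x$clusters), x$threshold_t, x$n_permutations))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Write a cluster report as CSV
#'
#' @param result a `cluster_result`.
#' @param path output CSV path.
#' @return the path, invisibly. Columns: cluster id, size, sum t, p,
#'   significance flag, and the member vertex indices (semicolon-separated).
#' @export
write_cluster_report <- function(result, path) {
  d <- result$clusters
  d$members <- vapply(result$members, paste, "", collapse = ";")
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
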