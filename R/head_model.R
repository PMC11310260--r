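# Spherical single-shell head model.
#
# The forward model is the classical closed-form surface potential of a radial
# current dipole inside a homogeneous conducting sphere (insulating exterior).
# For a dipole at eccentricity f = r_src / r_chan and an electrode at angular
# distance gamma from the dipole axis,
#
#   V(gamma)  propto  2 (cos gamma - f) / d^3  +  (1/f) (1/d - 1),
#   d = sqrt(1 + f^2 - 2 f cos gamma),
#
# which reduces to the familiar 3 cos(gamma) central-dipole potential as
# f -> 0. This preserves the spatial mixing structure a minimum-norm inverse
# needs without any anatomical data.

# quasi-uniform points on the upper hemisphere (Fibonacci lattice), with a
# seed-controlled azimuthal rotation so different seeds give different meshes
fibonacci_hemisphere <- function(n, seed = 1L, z_min = 0.05) {
  i <- seq_len(n) - 0.5
  z <- 1 - (i / n) * (1 - z_min)
  golden <- pi * (3 - sqrt(5))
  set.seed(as.integer(seed))
  phi <- i * golden + stats::runif(1, 0, 2 * pi)
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
}

# Spherical Delaunay triangulation of hemisphere points via stereographic
# projection from the south pole (circle-preserving, so the planar empty-
# circumcircle test is the spherical one). Brute-force over triples; intended
# for desk-scale meshes (n up to a few hundred).
delaunay_triangles <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(matrix(integer(0), ncol = 3))
  p <- pts / sqrt(rowSums(pts^2))
  u <- p[, 1] / (1 + p[, 3])
  v <- p[, 2] / (1 + p[, 3])
  tri <- list()
  combs <- utils::combn(n, 3)
  eps <- 1e-12
  for (t in seq_len(ncol(combs))) {
    i <- combs[1, t]; j <- combs[2, t]; k <- combs[3, t]
    ax <- u[i]; ay <- v[i]; bx <- u[j]; by <- v[j]; cx <- u[k]; cy <- v[k]
    dmat <- 2 * ((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
    if (abs(dmat) < eps) next
    a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
    ux <- ((b2 - a2) * (cy - ay) - (c2 - a2) * (by - ay)) / dmat
    uy <- ((c2 - a2) * (bx - ax) - (b2 - a2) * (cx - ax)) / dmat
    r2 <- (ax - ux)^2 + (ay - uy)^2
    d2 <- (u - ux)^2 + (v - uy)^2
    d2[c(i, j, k)] <- Inf
    if (all(d2 > r2 * (1 - 1e-9))) tri[[length(tri) + 1L]] <- c(i, j, k)
  }
  if (!length(tri)) return(matrix(integer(0), ncol = 3))
  do.call(rbind, tri)
}

adjacency_from_triangles <- function(tri, n) {
  A <- matrix(0L, n, n)
  if (nrow(tri)) {
    e <- rbind(tri[, c(1, 2), drop = FALSE],
               tri[, c(2, 3), drop = FALSE],
               tri[, c(1, 3), drop = FALSE])
    A[e] <- 1L
    A[e[, c(2, 1), drop = FALSE]] <- 1L
  }
  diag(A) <- 0L
  A
}

# closed-form radial-dipole kernel; gamma = angle electrode <-> source
radial_dipole_potential <- function(cos_gamma, f) {
  d <- sqrt(pmax(1 + f^2 - 2 * f * cos_gamma, 1e-12))
  (2 * (cos_gamma - f) / d^3 + (1 / f) * (1 / d - 1)) / (4 * pi)
}

#' Build a spherical single-shell head model
#'
#' Constructs a synthetic source space (quasi-uniform vertices on an upper
#' hemisphere of radius `r_src`), a triangulated mesh with its symmetric
#' adjacency matrix, a channel shell (either the labelled 64-channel montage
#' or a quasi-uniform Fibonacci layout) at radius 1, and the analytic
#' lead-field matrix of radial dipoles in a homogeneous conducting sphere.
#'
#' @param n_vertices number of source vertices (>= 1; meshes with fewer than
#'   3 vertices have an empty triangle set).
#' @param n_channels number of electrodes. When 64 (the default) the labelled
#'   synthetic 10-10 montage of [standard_montage_64()] is used; otherwise
#'   channels are quasi-uniform and labelled `E001`, `E002`, ...
#' @param seed integer seed controlling mesh/channel layout.
#' @param r_src source-shell radius as a fraction of the channel-shell radius
#'   (the dipole eccentricity); must lie in (0, 1).
#' @param montage optional montage data.frame (`label`,`x`,`y`,`z`)
#'   overriding the generated channel layout.
#' @return an object of class `source_model`: list with `vertices`
#'   (n_vertices x 3), `triangles`, `adjacency`, `channels` (montage
#'   data.frame), `leadfield` (n_channels x n_vertices), `r_src`.
#' @export
#' @examples
#' m <- make_head_model(n_vertices = 20, n_channels = 16, seed = 1)
#' dim(m$leadfield)
make_head_model <- function(n_vertices, n_channels = 64, seed = 1L,
                            r_src = 0.8, montage = NULL) {
  assert_that(is_count(n_vertices) && is_count(n_channels),
              "invalid_geometry", "n_vertices and n_channels must be positive integers")
  assert_that(r_src > 0 && r_src < 1, "invalid_geometry",
              "r_src must lie strictly between 0 and 1")
  vert <- fibonacci_hemisphere(n_vertices, seed = seed) * r_src
  rownames(vert) <- sprintf("v%03d", seq_len(n_vertices))
  tri <- delaunay_triangles(vert)
  adj <- adjacency_from_triangles(tri, n_vertices)

  if (is.null(montage)) {
    if (n_channels == 64) {
      montage <- standard_montage_64()
    } else {
      ch <- fibonacci_hemisphere(n_channels, seed = split_seed(seed, "channels"))
      montage <- data.frame(label = sprintf("E%03d", seq_len(n_channels)),
                            x = ch[, 1], y = ch[, 2], z = ch[, 3],
                            stringsAsFactors = FALSE)
    }
  }
  assert_that(nrow(montage) == n_channels, "invalid_geometry",
              "montage size does not match n_channels")

  chpos <- as.matrix(montage[, c("x", "y", "z")])
  chpos <- chpos / sqrt(rowSums(chpos^2))      # unit channel shell
  src_unit <- vert / r_src
  cosg <- chpos %*% t(src_unit)                # [channels x vertices]
  L <- radial_dipole_potential(cosg, f = r_src)
  dimnames(L) <- list(montage$label, rownames(vert))

  structure(list(vertices = vert, triangles = tri, adjacency = adj,
                 channels = montage, leadfield = L, r_src = r_src,
                 seed = as.integer(seed)),
            class = "source_model")
}

#' @export
print.source_model <- function(x, ...) {
  cat(sprintf("<source_model> %d vertices, %d channels, %d triangles, r_src = %.2f\n",
              nrow(x$vertices), nrow(x$channels), nrow(x$triangles), x$r_src))
  invisible(x)
}

#' One-ring neighbourhood of a vertex
#'
#' @param model a `source_model`.
#' @param vertex vertex index.
#' @return integer vector: the vertex and its mesh neighbours.
#' @export
one_ring <- function(model, vertex) {
  sort(unique(c(vertex, which(model$adjacency[vertex, ] != 0L))))
}

#' Nearest mesh vertex to a direction
#'
#' Finds the source vertex whose direction is closest to a target direction
#' (e.g. an electrode position), used to place simulated sources "under" a
#' named electrode.
#'
#' @param model a `source_model`.
#' @param target length-3 numeric position, or a channel label present in the
#'   model's montage.
#' @return vertex index.
#' @export
nearest_vertex <- function(model, target) {
  if (is.character(target)) {
    i <- match(target, model$channels$label)
    assert_that(!is.na(i), "invalid_geometry",
                sprintf("no channel labelled '%s' in montage", target))
    target <- as.numeric(model$channels[i, c("x", "y", "z")])
  }
  tv <- target / sqrt(sum(target^2))
  sv <- model$vertices / sqrt(rowSums(model$vertices^2))
  which.max(sv %*% tv)
}

#' Nearest channel to a source vertex
#'
#' @param model a `source_model`.
#' @param vertex vertex index.
#' @return channel label of the electrode closest (in angle) to the vertex.
#' @export
nearest_channel <- function(model, vertex) {
  vv <- model$vertices[vertex, ]
  vv <- vv / sqrt(sum(vv^2))
  ch <- as.matrix(model$channels[, c("x", "y", "z")])
  ch <- ch / sqrt(rowSums(ch^2))
  model$channels$label[which.max(ch %*% vv)]
}
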