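#' Delaunay triangulation (Bowyer-Watson)
#'
#' Minimal incremental Delaunay triangulation of a set of distinct points,
#' used to build the knot mesh. Adequate for knot counts in the hundreds.
#'
#' @param pts numeric matrix (n x 2) of distinct points.
#' @return integer matrix (m x 3) of triangle vertex indices into `pts`.
#' @keywords internal
delaunay_triangulate <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3) return(matrix(integer(0), 0, 3))
  # super-triangle comfortably containing all points
  cx <- mean(range(pts[, 1])); cy <- mean(range(pts[, 2]))
  r <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1e-6) * 10
  P <- rbind(pts, c(cx - 2 * r, cy - r), c(cx + 2 * r, cy - r), c(cx, cy + 2 * r))
  tri <- matrix(c(n + 1L, n + 2L, n + 3L), 1, 3)
  circ <- .circumcircle(P, tri)
  for (i in seq_len(n)) {
    px <- P[i, 1]; py <- P[i, 2]
    bad <- (px - circ[, 1])^2 + (py - circ[, 2])^2 <= circ[, 3] * (1 + 1e-12)
    if (!any(bad)) next  # numerically degenerate; point skipped (duplicates)
    bt <- tri[bad, , drop = FALSE]
    edges <- rbind(bt[, c(1, 2)], bt[, c(2, 3)], bt[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    keep_edge <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    new_tri <- cbind(keep_edge, i)
    tri <- rbind(tri[!bad, , drop = FALSE], new_tri)
    circ <- rbind(circ[!bad, , drop = FALSE], .circumcircle(P, new_tri))
  }
  keep <- apply(tri <= n, 1, all)
  tri[keep, , drop = FALSE]
}

# circumcenter (cx, cy) and squared radius per triangle row
.circumcircle <- function(P, tri) {
  ax <- P[tri[, 1], 1]; ay <- P[tri[, 1], 2]
  bx <- P[tri[, 2], 1]; by <- P[tri[, 2], 2]
  cx <- P[tri[, 3], 1]; cy <- P[tri[, 3], 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  d[abs(d) < 1e-12] <- 1e-12
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  cbind(ux, uy, (ux - ax)^2 + (uy - ay)^2)
}

.knot_mesh <- function(knots, method) {
  knots <- as.matrix(knots)
  colnames(knots) <- c("x", "y")
  tri <- if (nrow(knots) >= 3) delaunay_triangulate(knots)
         else matrix(integer(0), 0, 3)
  structure(list(knots = knots, triangles = tri, method = method),
            class = "knot_mesh")
}

#' @export
print.knot_mesh <- function(x, ...) {
  cat(sprintf("<knot_mesh> %d knots, %d triangles (%s)\n",
              nrow(x$knots), nrow(x$triangles), x$method))
  invisible(x)
}

#' Select random-field knots by k-means clustering
#'
#' Knot locations are the k-means centroids of the observation
#' coordinates, the standard mesh construction for predictive-process
#' spatiotemporal models; a Delaunay triangulation over the knots supports
#' barycentric (bilinear) interpolation to arbitrary points.
#'
#' @param coords matrix or data.frame of observation x/y (km).
#' @param n_knots number of knots; must not exceed the number of distinct
#'   coordinates.
#' @param seed integer seed making the k-means start deterministic.
#' @return a `knot_mesh` object.
#' @export
select_knots <- function(coords, n_knots, seed = 1) {
  coords <- unique(as.matrix(coords)[, 1:2, drop = FALSE])
  if (n_knots > nrow(coords))
    stop("n_knots exceeds the number of distinct coordinates")
  if (n_knots == nrow(coords)) return(.knot_mesh(coords, "kmeans"))
  km <- withr_seed(seed,
    stats::kmeans(coords, centers = n_knots, iter.max = 200, nstart = 1))
  .knot_mesh(km$centers, "kmeans")
}

#' Select knots by greedy distance-cutoff thinning
#'
#' Thins the observation coordinates so every pair of kept knots is at
#' least `cutoff_km` apart — the "simpler mesh" alternative used to probe
#' sensitivity of the covariate (marginal) variance share.
#'
#' @param coords matrix or data.frame of observation x/y (km).
#' @param cutoff_km minimum knot spacing (km), > 0.
#' @return a `knot_mesh` object.
#' @export
select_knots_by_cutoff <- function(coords, cutoff_km) {
  if (cutoff_km <= 0) stop("cutoff_km must be positive")
  coords <- unique(as.matrix(coords)[, 1:2, drop = FALSE])
  keep <- integer(0)
  for (i in seq_len(nrow(coords))) {
    if (!length(keep) ||
        min((coords[keep, 1] - coords[i, 1])^2 +
            (coords[keep, 2] - coords[i, 2])^2) >= cutoff_km^2)
      keep <- c(keep, i)
  }
  .knot_mesh(coords[keep, , drop = FALSE], "cutoff")
}

#' Barycentric interpolation operator from knots to points
#'
#' Sparse matrix `A` (n_points x n_knots) of bilinear/barycentric weights:
#' a point inside a mesh triangle gets the barycentric weights of its three
#' vertices (nonnegative, summing to 1); a point outside the convex hull of
#' the knots falls back to weight 1 on its nearest knot.
#'
#' @param mesh a `knot_mesh`.
#' @param coords matrix/data.frame of point x/y (km).
#' @return a `Matrix::sparseMatrix` of interpolation weights.
#' @export
mesh_project <- function(mesh, coords) {
  stopifnot(inherits(mesh, "knot_mesh"))
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  n <- nrow(coords); K <- nrow(mesh$knots)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  unassigned <- rep(TRUE, n)
  if (nrow(mesh$triangles) > 0) {
    for (t in seq_len(nrow(mesh$triangles))) {
      v <- mesh$triangles[t, ]
      a <- mesh$knots[v[1], ]; b <- mesh$knots[v[2], ]; c_ <- mesh$knots[v[3], ]
      det <- (b[1] - a[1]) * (c_[2] - a[2]) - (c_[1] - a[1]) * (b[2] - a[2])
      if (abs(det) < 1e-12) next
      idx <- which(unassigned)
      if (!length(idx)) break
      dx <- coords[idx, 1] - a[1]; dy <- coords[idx, 2] - a[2]
      l2 <- (dx * (c_[2] - a[2]) - dy * (c_[1] - a[1])) / det
      l3 <- (dy * (b[1] - a[1]) - dx * (b[2] - a[2])) / det
      l1 <- 1 - l2 - l3
      inside <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
      if (any(inside)) {
        pt <- idx[inside]
        ii <- c(ii, rep(pt, 3))
        jj <- c(jj, rep(v[1], length(pt)), rep(v[2], length(pt)),
                rep(v[3], length(pt)))
        ww <- c(ww, pmax(l1[inside], 0), pmax(l2[inside], 0),
                pmax(l3[inside], 0))
        unassigned[pt] <- FALSE
      }
    }
  }
  if (any(unassigned)) {  # outside hull (or degenerate mesh): nearest knot
    idx <- which(unassigned)
    nn <- vapply(idx, function(i) {
      which.min((mesh$knots[, 1] - coords[i, 1])^2 +
                (mesh$knots[, 2] - coords[i, 2])^2)
    }, 0L)
    ii <- c(ii, idx); jj <- c(jj, nn); ww <- c(ww, rep(1, length(idx)))
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, K))
  # renormalize rows (clipped negatives at triangle edges)
  rs <- Matrix::rowSums(A)
  A / rs
}
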