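#' Convert a mesh to a (sub)sampled point cloud
#'
#' Takes the mesh vertices as the point set; if there are more than
#' `max_points`, a uniform random subsample without replacement is drawn.
#' Coordinates are centred on the cloud centroid and isotropically scaled
#' to unit maximum radius; the transform is recorded for inversion.
#'
#' @param mesh a [tri_mesh()].
#' @param max_points maximum number of points (>= 17 so every class can be
#'   represented).
#' @param seed integer seed for the subsample.
#' @return a `point_cloud`: list with `coords` (m x 3, normalized),
#'   `source_vertex` (indices into the mesh), `center`, `scale`.
#' @export
mesh_to_pointcloud <- function(mesh, max_points = 1024L, seed = 1L) {
  nv <- n_vertices(mesh)
  if (nv == 0L) stop("empty mesh", call. = FALSE)
  if (max_points < 17L) stop("max_points must be >= 17", call. = FALSE)
  idx <- if (nv <= max_points) seq_len(nv) else
    withr::with_seed(as.integer(seed), sort(sample.int(nv, max_points)))
  raw <- mesh$vertices[idx, , drop = FALSE]
  ctr <- colMeans(raw)
  centred <- sweep(raw, 2, ctr)
  sc <- max(sqrt(rowSums(centred^2)))
  structure(list(coords = centred / sc, source_vertex = idx,
                 center = ctr, scale = sc),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat("<point_cloud> ", nrow(x$coords), " points (scale ",
      sprintf("%.2f", x$scale), " mm)\n", sep = "")
  invisible(x)
}

#' Enforce the gingiva point budget
#'
#' After the coarse tooth/gingiva stage, gingiva points typically outnumber
#' dentition points by about two to one on a full arch. Before the
#' seventeen-class stage the gingiva is uniformly subsampled so that its
#' count does not exceed `ratio` times the tooth count; tooth points are
#' always all retained and relative point order is preserved.
#'
#' @param pc a `point_cloud`.
#' @param coarse_labels per-point labels; nonzero/`TRUE` = tooth.
#' @param ratio gingiva budget as a multiple of the tooth count (default 2).
#' @param seed integer seed for the subsample.
#' @return a `point_cloud` of the retained points, with attribute
#'   `"kept"` giving their indices into `pc`.
#' @export
balance_gingiva <- function(pc, coarse_labels, ratio = 2, seed = 1L) {
  stopifnot(inherits(pc, "point_cloud"))
  tooth <- as.logical(coarse_labels != 0)
  if (length(tooth) != nrow(pc$coords))
    stop("coarse_labels length must match point count", call. = FALSE)
  n_tooth <- sum(tooth)
  if (n_tooth == 0L)
    stop("no tooth points: coarse (stage-1) segmentation failed", call. = FALSE)
  gin <- which(!tooth)
  budget <- floor(ratio * n_tooth)
  keep_gin <- if (length(gin) <= budget) gin else
    withr::with_seed(as.integer(seed), sort(sample(gin, budget)))
  kept <- sort(c(which(tooth), keep_gin))
  out <- structure(list(coords = pc$coords[kept, , drop = FALSE],
                        source_vertex = pc$source_vertex[kept],
                        center = pc$center, scale = pc$scale),
                   class = "point_cloud")
  attr(out, "kept") <- kept
  out
}

#' Directed k-nearest-neighbour graph
#'
#' Exact Euclidean kNN: each point gets exactly `k` out-edges to its `k`
#' nearest other points, ties broken toward the smaller index, no
#' self-edges.
#'
#' @param coords m x d numeric matrix (any feature dimension).
#' @param k neighbour count, `k < m`.
#' @return integer matrix m x k; row i holds the neighbour indices of i in
#'   increasing-distance order.
#' @useDynLib dentseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @export
knn_graph <- function(coords, k) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  m <- nrow(coords)
  if (m <= k) stop("need more points than k (m = ", m, ", k = ", k, ")",
                   call. = FALSE)
  if (ncol(coords) <= 4L) return(cpp_knn(coords, as.integer(k)))
  # high-dimensional feature spaces: BLAS distance matrix + C selection
  sq <- rowSums(coords^2)
  D <- outer(sq, sq, "+") - 2 * tcrossprod(coords)
  cpp_knn_from_dist(D, as.integer(k))
}
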