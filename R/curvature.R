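#' Discrete mean curvature of a triangle mesh
#'
#' Computes per-vertex mean curvature H (units 1/mm) from the
#' cotangent-Laplacian mean-curvature normal: for vertex i,
#' K_i = (1 / (2 A_i)) * sum_j (cot a_ij + cot b_ij) (x_i - x_j), where
#' a_ij, b_ij are the angles opposite edge (i, j) in its two incident
#' triangles and A_i is the barycentric vertex area (one third of incident
#' triangle areas). Then H_i = |K_i| / 2, signed by the dot product of K_i
#' with the outward vertex normal, so convex regions (a sphere seen from
#' outside) have H > 0 and concave grooves — the tooth-gingiva junction
#' band — have H < 0.
#'
#' Boundary vertices get H = 0 and are reported in attribute
#' `"boundary"`; isolated vertices likewise default to 0 with a warning.
#'
#' @param mesh a [tri_mesh()] with outward-oriented faces.
#' @return numeric vector of length `n_vertices(mesh)`, class
#'   `curvature_field`, with attribute `boundary` (integer indices).
#' @export
mean_curvature <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  nv <- n_vertices(mesh)

  # cotangent of the angle at corner `a` opposite edge (b, c), per face
  cot_at <- function(a, b, c) {
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[c, , drop = FALSE] - v[a, , drop = FALSE]
    dot <- rowSums(u * w)
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    dot / pmax(sqrt(rowSums(cr^2)), .Machine$double.eps)
  }
  # each face contributes cot(angle at k) to its opposite edge (i, j),
  # pulling x_i - x_j into both endpoint accumulators
  K <- matrix(0, nv, 3)
  corners <- list(c(1L, 2L, 3L), c(2L, 3L, 1L), c(3L, 1L, 2L))
  for (cn in corners) {
    a <- f[, cn[1]]; b <- f[, cn[2]]; cc <- f[, cn[3]]
    ct <- cot_at(a, b, cc)
    d <- v[b, , drop = FALSE] - v[cc, , drop = FALSE]
    for (ax in 1:3) {
      K[, ax] <- K[, ax] + rowsum_vec(ct * d[, ax], b, nv)
      K[, ax] <- K[, ax] - rowsum_vec(ct * d[, ax], cc, nv)
    }
  }
  # mixed Voronoi vertex area: circumcentric area for non-obtuse triangles,
  # T/2 at the obtuse corner and T/4 at the others for obtuse ones
  fn <- face_normals(mesh)
  ct1 <- cot_at(f[, 1], f[, 2], f[, 3])
  ct2 <- cot_at(f[, 2], f[, 3], f[, 1])
  ct3 <- cot_at(f[, 3], f[, 1], f[, 2])
  sq <- function(a, b) rowSums((v[a, , drop = FALSE] - v[b, , drop = FALSE])^2)
  e23 <- sq(f[, 2], f[, 3]); e31 <- sq(f[, 3], f[, 1]); e12 <- sq(f[, 1], f[, 2])
  obtuse <- ct1 < 0 | ct2 < 0 | ct3 < 0
  # Voronoi share of corner i: (|e_ij|^2 cot(k) + |e_ik|^2 cot(j)) / 8
  a1 <- ifelse(obtuse, ifelse(ct1 < 0, fn$areas / 2, fn$areas / 4),
               (e12 * ct3 + e31 * ct2) / 8)
  a2 <- ifelse(obtuse, ifelse(ct2 < 0, fn$areas / 2, fn$areas / 4),
               (e12 * ct3 + e23 * ct1) / 8)
  a3 <- ifelse(obtuse, ifelse(ct3 < 0, fn$areas / 2, fn$areas / 4),
               (e31 * ct2 + e23 * ct1) / 8)
  area <- rowsum_vec(a1, f[, 1], nv) + rowsum_vec(a2, f[, 2], nv) +
    rowsum_vec(a3, f[, 3], nv)

  isolated <- area == 0
  if (any(isolated))
    warning(sum(isolated), " isolated vertex/vertices: curvature set to 0")
  K <- K / pmax(2 * area, .Machine$double.eps)
  nrm <- vertex_normals(mesh)
  H <- sqrt(rowSums(K^2)) / 2 * sign(rowSums(K * nrm))
  H[isolated] <- 0

  bnd <- boundary_vertices(mesh)
  H[bnd] <- 0
  structure(H, boundary = bnd, class = "curvature_field")
}

#' @export
print.curvature_field <- function(x, ...) {
  cat("<curvature_field> ", length(x), " vertices; H in [",
      sprintf("%.3f", min(x)), ", ", sprintf("%.3f", max(x)),
      "] 1/mm; ", length(attr(x, "boundary")), " boundary vertices\n",
      sep = "")
  invisible(x)
}

## ------------------------------------------------ analytic test surfaces

#' Icosphere test solid
#'
#' Recursive subdivision of an icosahedron projected to a sphere of radius
#' `r`. Used for curvature accuracy checks (analytic H = 1/r).
#'
#' @param r radius in mm.
#' @param subdivisions subdivision levels (0 = icosahedron).
#' @return a [tri_mesh()], outward-oriented.
#' @export
icosphere <- function(r = 1, subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * r
  tri_mesh(v, f)
}

#' Open cylinder test surface
#'
#' Lateral surface of a cylinder of radius `r` along z, outward-oriented;
#' analytic mean curvature of interior vertices is 1 / (2 r).
#'
#' @param r radius (mm).
#' @param h height (mm).
#' @param n_theta,n_z grid resolution around / along the axis.
#' @return a [tri_mesh()].
#' @export
cylinder_surface <- function(r = 1, h = 4, n_theta = 48, n_z = 17) {
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  z <- seq(0, h, length.out = n_z)
  g <- expand.grid(ti = seq_len(n_theta), zi = seq_len(n_z))
  v <- cbind(r * cos(theta[g$ti]), r * sin(theta[g$ti]), z[g$zi])
  idx <- function(ti, zi) (zi - 1L) * n_theta + ((ti - 1L) %% n_theta) + 1L
  f <- matrix(0L, 0, 3)
  for (zi in seq_len(n_z - 1)) {
    ti <- seq_len(n_theta)
    a <- idx(ti, zi); b <- idx(ti + 1L, zi)
    cc <- idx(ti, zi + 1L); d <- idx(ti + 1L, zi + 1L)
    f <- rbind(f, cbind(a, b, d), cbind(a, d, cc))
  }
  tri_mesh(v, f)
}

#' Flat grid patch (analytic H = 0)
#'
#' @param nx,ny grid resolution.
#' @param w,h extent in mm.
#' @return a [tri_mesh()] in the z = 0 plane, normals +z.
#' @export
grid_patch <- function(nx = 12, ny = 12, w = 10, h = 10) {
  xs <- seq(0, w, length.out = nx)
  ys <- seq(0, h, length.out = ny)
  g <- expand.grid(xi = seq_len(nx), yi = seq_len(ny))
  v <- cbind(xs[g$xi], ys[g$yi], 0)
  idx <- function(xi, yi) (yi - 1L) * nx + xi
  f <- matrix(0L, 0, 3)
  for (yi in seq_len(ny - 1)) {
    xi <- seq_len(nx - 1)
    a <- idx(xi, yi); b <- idx(xi + 1L, yi)
    cc <- idx(xi, yi + 1L); d <- idx(xi + 1L, yi + 1L)
    f <- rbind(f, cbind(a, b, d), cbind(a, d, cc))
  }
  tri_mesh(v, f)
}
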