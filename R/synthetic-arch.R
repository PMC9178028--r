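#' Configuration for the synthetic dental-arch generator
#'
#' Encodes the study conditions the generator emulates: a full
#' permanent-dentition arch (14 teeth, second molar to second molar; third
#' molars excluded), mild-to-moderate crowding at most, no tooth or
#' gingival defects, and a concave tooth-gingiva junction band whose depth
#' gives the margin-refinement stage its curvature signal.
#'
#' Default tooth sizes are Wheeler-style per-position means with uniform
#' spread; crowding draws signed interproximal gaps (negative = overlap).
#'
#' @param n_teeth number of teeth per arch (1..16; default 14).
#' @param crowding one of `"none"`, `"mild"`, `"moderate"`.
#' @param margin_depth depth (mm) of the junction groove around each crown.
#' @param margin_width width (mm) of the groove band.
#' @param noise_sd sd (mm) of per-vertex surface displacement noise.
#' @param grid_step surface sampling step (mm) of the generated mesh.
#' @param molar_shear occlusal-view parallelogram shear factor applied to
#'   second-molar footprints (0 = off); reproduces the direction of the
#'   mesiodistal overestimation seen on sheared molars.
#' @param size_table optional tibble with columns `class`
#'   (1..8 intra-quadrant position), `md`, `cch`, `bl` (means, mm) and
#'   `spread` (half-width of the uniform draw, mm); defaults built in.
#' @return a list of class `arch_config`.
#' @export
arch_config <- function(n_teeth = 14, crowding = c("none", "mild", "moderate"),
                        margin_depth = 0.6, margin_width = 1.4,
                        noise_sd = 0, grid_step = 0.45, molar_shear = 0,
                        size_table = NULL) {
  crowding <- match.arg(crowding)
  if (n_teeth < 1 || n_teeth > 16) stop("n_teeth must be in 1..16", call. = FALSE)
  if (margin_depth <= 0 || margin_width <= 0 || grid_step <= 0)
    stop("margin_depth, margin_width and grid_step must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  size_table <- size_table %||% default_size_table()
  stopifnot(all(c("class", "md", "cch", "bl", "spread") %in% names(size_table)))
  if (any(size_table$md <= 0) || any(size_table$cch <= 0) ||
      any(size_table$bl <= 0) || any(size_table$spread < 0))
    stop("tooth size intervals must be positive and finite", call. = FALSE)
  structure(list(n_teeth = as.integer(n_teeth), crowding = crowding,
                 margin_depth = margin_depth, margin_width = margin_width,
                 noise_sd = noise_sd, grid_step = grid_step,
                 molar_shear = molar_shear, size_table = size_table),
            class = "arch_config")
}

# per-position (intra-quadrant 1..8) crown dimensions, mm
default_size_table <- function() {
  tibble::tibble(
    class  = 1:8,
    md     = c(8.6, 6.9, 7.6, 7.1, 6.9, 10.4, 9.8, 9.2),
    cch    = c(9.5, 8.5, 9.0, 7.8, 7.5, 7.0, 6.8, 6.5),
    bl     = c(7.0, 6.3, 7.8, 8.8, 8.9, 10.8, 10.6, 10.2),
    spread = c(0.5, 0.5, 0.4, 0.4, 0.4, 0.5, 0.5, 0.5)
  )
}

tooth_class_of_position <- function(position) {
  # intra-arch positions: 1..8 right quadrant, 9..16 left; class = 1..8
  ifelse(position <= 8L, position, position - 8L)
}

#' Tooth-type grouping used in error summaries
#' @param position intra-arch position code 1..16.
#' @return factor with levels incisal, canine, premolar, molar.
#' @export
tooth_group_of_position <- function(position) {
  cl <- tooth_class_of_position(as.integer(position))
  grp <- c("incisal", "incisal", "canine", "premolar", "premolar",
           "molar", "molar", "molar")[cl]
  factor(grp, levels = c("incisal", "canine", "premolar", "molar"))
}

## ----------------------------------------------------- single tooth crown

#' Generate one synthetic tooth crown
#'
#' Builds a closed crown as a deformed superellipsoid: superellipse
#' cross-sections from a constricted cervical rim through the height of
#' contour, capped by an occlusal surface carrying an incisal edge
#' (classes 1-3) or two-to-four cusps (classes 4-8), and closed underneath
#' by a flat cervical cap at z = 0. After generation the mesh is rescaled
#' so the mesiodistal (x) extent equals `md`, the buccolingual (y) extent
#' equals `bl`, and the crown height above the cervical rim equals `cch`,
#' all exactly.
#'
#' @param position intra-arch tooth position 1..16.
#' @param size_draw numeric `c(md, cch, bl)` in mm.
#' @param seed integer seed controlling shape jitter (cusp layout,
#'   superellipse exponent); same seed gives a bit-identical mesh.
#' @param n_u,n_rings angular / vertical resolution.
#' @return list with `mesh` (a closed [tri_mesh()]), `rim` (vertex indices
#'   of the cervical rim ring at z = 0), `tip` (index of the highest
#'   vertex), `axis` (crown axis, +z), `md`, `cch`, `bl`.
#' @export
generate_tooth <- function(position, size_draw, seed = 1L,
                           n_u = 28, n_rings = 9) {
  md <- size_draw[1]; cch <- size_draw[2]; bl <- size_draw[3]
  if (any(size_draw <= 0)) stop("tooth sizes must be positive", call. = FALSE)
  cl <- tooth_class_of_position(position)
  withr::with_seed(as.integer(seed), {
    p_exp <- stats::runif(1, 2.2, 2.6) + (cl >= 6) * 0.8   # molars boxier
    bulge_t <- stats::runif(1, 0.38, 0.5)
    cusp_jit <- stats::runif(4, -0.06, 0.06)
  })
  u <- seq(0, 2 * pi, length.out = n_u + 1)[-(n_u + 1)]
  tgrid <- seq(0, 1, length.out = n_rings + 1)[-(n_rings + 1)]
  # radial bulge profile: constricted rim, widest at bulge_t, tapered top
  prof <- function(t) {
    lo <- 0.82 + 0.18 * sin(pi * pmin(t / bulge_t, 1) / 2)
    hi <- 1 - (1 - 0.58) * ((pmax(t - bulge_t, 0) / (1 - bulge_t))^1.6)
    ifelse(t <= bulge_t, lo, hi)
  }
  se_r <- function(u, p) (abs(cos(u))^p + abs(sin(u))^p)^(-1 / p)
  verts <- matrix(0, 0, 3)
  for (t in tgrid) {
    r <- prof(t) * se_r(u, p_exp)
    verts <- rbind(verts, cbind(r * cos(u) * md / 2, r * sin(u) * bl / 2,
                                t * cch * 0.82))
  }
  n_side <- nrow(verts)
  # occlusal cap: rings shrinking to centre, height = dome + cusp relief
  cap_rings <- 5
  occl <- function(x, y) {
    sx <- x / (md / 2); sy <- y / (bl / 2)       # normalized footprint coords
    if (cl <= 3) {                                # incisal edge along MD
      relief <- exp(-(sy / 0.22)^2) * (1 - 0.25 * sx^2)
    } else {
      nc <- if (cl >= 6) 4 else 2
      cx <- if (nc == 2) c(0, 0) else c(-0.38, 0.38, -0.38, 0.38) + cusp_jit
      cy <- if (nc == 2) c(-0.42, 0.42) + cusp_jit[1:2] else
        c(-0.42, -0.42, 0.42, 0.42)
      relief <- 0
      for (i in seq_len(nc))
        relief <- relief + exp(-((sx - cx[i])^2 + (sy - cy[i])^2) / (2 * 0.14^2))
      relief <- relief / max(1, nc / 3.2)
    }
    0.82 + 0.18 * pmin(relief, 1)
  }
  top_scale <- prof(utils::tail(tgrid, 1))
  for (k in seq_len(cap_rings)) {
    shrink <- (cap_rings - k) / cap_rings
    r <- top_scale * shrink * se_r(u, p_exp)
    x <- r * cos(u) * md / 2; y <- r * sin(u) * bl / 2
    if (shrink == 0) { x <- 0; y <- 0 }
    z <- occl(x, y) * cch
    verts <- rbind(verts, cbind(x, y, z))
    if (shrink == 0) break
  }
  # bottom cap centre
  verts <- rbind(verts, c(0, 0, 0))
  ctr_bot <- nrow(verts)
  ring <- function(i) (i - 1L) * n_u + seq_len(n_u)
  n_ring_total <- n_side / n_u + cap_rings - 1   # stacked full rings
  faces <- matrix(0L, 0, 3)
  for (i in seq_len(n_ring_total - 1)) {
    a <- ring(i); b <- c(a[-1], a[1])
    cc <- ring(i + 1); d <- c(cc[-1], cc[1])
    faces <- rbind(faces, cbind(a, d, b), cbind(a, cc, d))
  }
  apex <- n_ring_total * n_u + 1L     # cap centre vertex
  a <- ring(n_ring_total); b <- c(a[-1], a[1])
  faces <- rbind(faces, cbind(a, apex, b))
  a <- ring(1); b <- c(a[-1], a[1])
  faces <- rbind(faces, cbind(a, b, ctr_bot))
  # exact rescale to requested extents
  for (ax in 1:2) {
    ext <- diff(range(verts[, ax]))
    verts[, ax] <- verts[, ax] * (c(md, bl)[ax] / ext)
  }
  verts[, 3] <- verts[, 3] * (cch / max(verts[, 3]))
  mesh <- tri_mesh(verts, faces)
  list(mesh = mesh, rim = ring(1), tip = which.max(verts[, 3]),
       axis = c(0, 0, 1), md = md, cch = cch, bl = bl)
}

## --------------------------------------------------------- the full arch

# parabolic arch curve y = depth - a x^2, arc-length parameterized;
# returns interpolators for point, unit tangent and outward (buccal) normal
arch_curve <- function(a = 0.028, half_span = 60, step = 0.05) {
  x <- seq(-half_span, half_span, by = step)
  y <- -a * x^2
  ds <- sqrt(1 + (2 * a * x)^2) * step
  s <- cumsum(ds) - sum(ds[x < 0])          # s = 0 at the apex (x = 0)
  list(
    point = function(sq) {
      xi <- stats::approx(s, x, xout = sq, rule = 2)$y
      cbind(xi, -a * xi^2)
    },
    tangent = function(sq) {
      xi <- stats::approx(s, x, xout = sq, rule = 2)$y
      t <- cbind(1, -2 * a * xi)
      t / sqrt(rowSums(t^2))
    },
    normal = function(sq) {
      xi <- stats::approx(s, x, xout = sq, rule = 2)$y
      t <- cbind(1, -2 * a * xi)
      t <- t / sqrt(rowSums(t^2))
      cbind(-t[, 2], t[, 1])               # rotate +90 deg: buccal side
    },
    max_s = max(s), min_s = min(s)
  )
}

#' Generate a labelled synthetic dental arch
#'
#' Places `n_teeth` crowns along a parabolic arch curve with their
#' mesiodistal axes following the curve tangent, embeds them in a gingival
#' ridge swept along the curve, and carves a concave junction moat of depth
#' `margin_depth` around every crown. The surface is built as a structured
#' sheet over arch-following coordinates (arc length x lateral offset), so
#' each tooth region is a single connected component and the moat carries
#' negative mean curvature by construction. Cusp tips are coplanar (the
#' virtual occlusal plane) up to the configured noise.
#'
#' @param config an [arch_config()].
#' @param seed integer; same (config, seed) gives identical output.
#' @return list with `mesh` (a [tri_mesh()]), `truth` (a `ground_truth`:
#'   `labels` [label_map()], per-tooth tibble `teeth`, occlusal plane,
#'   interproximal gaps), and `config`.
#' @export
generate_arch <- function(config = arch_config(), seed = 1L) {
  stopifnot(inherits(config, "arch_config"))
  n <- config$n_teeth
  # positions: distal right -> central -> distal left (classes mirror)
  per_side <- ceiling(n / 2)
  pos_right <- rev(seq_len(per_side))                    # e.g. 7..1
  pos_left <- seq_len(n - per_side) + 8L                 # 9..15 -> L1..L7
  positions <- c(pos_right, pos_left)
  classes <- tooth_class_of_position(positions)
  st <- config$size_table
  withr::with_seed(as.integer(seed), {
    draw <- function(cl, col) st[[col]][match(cl, st$class)] +
      stats::runif(length(cl), -1, 1) * st$spread[match(cl, st$class)]
    md <- draw(classes, "md"); cch <- draw(classes, "cch")
    bl <- draw(classes, "bl")
    gaps <- switch(config$crowding,
                   none = rep(0.02, n - 1),
                   mild = stats::runif(n - 1, -0.25, 0.05),
                   moderate = stats::runif(n - 1, -0.7, -0.05))
    shape_seed <- sample.int(1e6, n)
    p_exp <- stats::runif(n, 2.3, 2.7) + (classes >= 6) * 0.7
    noise_state <- stats::runif(1)
  })
  if (any(-gaps > 1.5))
    stop("requested overlap exceeds bound; use smaller teeth or less crowding",
         call. = FALSE)
  # arc-length stations of tooth centres; s increases right -> left
  widths <- md
  centers_s <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    centers_s[i] <- acc + widths[i] / 2
    if (i < n) acc <- acc + widths[i] + gaps[i]
  }
  centers_s <- centers_s - (acc + widths[n] / 2) / 2      # centre the run
  curve <- arch_curve()
  C <- curve$point(centers_s); Tg <- curve$tangent(centers_s)
  Nrm <- curve$normal(centers_s)
  # occlusal plane height: tips coplanar; rim height varies per tooth
  H_plane <- max(cch)
  z_rim <- H_plane - cch
  shear <- ifelse(classes == 7L | classes == 8L, config$molar_shear, 0)

  # structured sheet grid over (s, v)
  pad <- 6
  sg <- seq(min(centers_s) - widths[1] / 2 - pad,
            max(centers_s) + widths[n] / 2 + pad, by = config$grid_step)
  vg <- seq(-8.5, 8.5, by = config$grid_step)
  G <- expand.grid(si = seq_along(sg), vi = seq_along(vg))
  P2 <- curve$point(sg[G$si]) + curve$normal(sg[G$si]) * vg[G$vi]
  nvtx <- nrow(P2)

  # per-tooth superellipse footprint radius rho at every grid vertex
  w <- config$margin_width
  rho <- matrix(Inf, nvtx, n)
  for (i in seq_len(n)) {
    d <- cbind(P2[, 1] - C[i, 1], P2[, 2] - C[i, 2])
    sl <- d[, 1] * Tg[i, 1] + d[, 2] * Tg[i, 2]
    tl <- d[, 1] * Nrm[i, 1] + d[, 2] * Nrm[i, 2]
    sl <- sl - shear[i] * tl                    # parallelogram shear
    near <- abs(sl) < widths[i] / 2 + w + 2 & abs(tl) < bl[i] / 2 + w + 2
    r <- rep(Inf, nvtx)
    r[near] <- ((abs(sl[near]) / (widths[i] / 2))^p_exp[i] +
                  (abs(tl[near]) / (bl[i] / 2))^p_exp[i])^(1 / p_exp[i])
    rho[, i] <- r
  }
  owner <- max.col(-rho, ties.method = "first")     # nearest footprint
  rho_min <- rho[cbind(seq_len(nvtx), owner)]
  labels <- ifelse(rho_min <= 1, positions[owner], 0L)

  # ridge baseline: rim height under each tooth, interpolated between,
  # falling off away from the ridge crest
  interp_rim <- function(xout) {
    if (n == 1L) rep(z_rim, length(xout))
    else stats::approx(centers_s, z_rim, xout = xout, rule = 2)$y
  }
  rim_at <- interp_rim(sg[G$si])
  vv <- abs(vg[G$vi])
  # falloff begins beyond the widest moat so it cannot cancel the moat's
  # concavity
  z_ridge <- rim_at - 0.12 * pmax(vv - 6.8, 0)^2

  z <- z_ridge
  # moat: concave junction band around every footprint, expressed in mm
  # via the mean footprint semi-axis
  for (i in seq_len(n)) {
    scale_mm <- (widths[i] + bl[i]) / 4
    band <- rho[, i] > 1 & (rho[, i] - 1) * scale_mm <= w
    frac <- (rho[band, i] - 1) * scale_mm / w
    dip <- interp_rim(sg[G$si][band]) - config$margin_depth * sin(pi * frac)
    z[band] <- pmin(z[band], dip)
  }
  # crowns
  for (i in seq_len(n)) {
    inside <- rho[, i] <= 1
    if (!any(inside)) next
    sl <- (P2[inside, 1] - C[i, 1]) * Tg[i, 1] +
      (P2[inside, 2] - C[i, 2]) * Tg[i, 2]
    tl <- (P2[inside, 1] - C[i, 1]) * Nrm[i, 1] +
      (P2[inside, 2] - C[i, 2]) * Nrm[i, 2]
    sl <- sl - shear[i] * tl
    sx <- sl / (widths[i] / 2); sy <- tl / (bl[i] / 2)
    r <- rho[inside, i]
    dome <- (1 - pmin(r, 1)^2.3)^1.35
    cl <- classes[i]
    if (cl <= 3) {
      relief <- exp(-(sy / 0.25)^2) * (1 - 0.2 * sx^2)
    } else {
      nc <- if (cl >= 6) 4 else 2
      withr::with_seed(shape_seed[i], jit <- stats::runif(4, -0.05, 0.05))
      cx <- if (nc == 2) c(0, 0) else c(-0.38, 0.38, -0.38, 0.38) + jit
      cy <- if (nc == 2) c(-0.42, 0.42) + jit[1:2] else c(-0.42, -0.42, 0.42, 0.42)
      relief <- 0
      for (k in seq_len(nc))
        relief <- relief + exp(-((sx - cx[k])^2 + (sy - cy[k])^2) / (2 * 0.16^2))
      relief <- pmin(relief, 1)
    }
    # relief fades toward the footprint edge so the cervical wall stays
    # gentle enough for the junction groove to read as one concave band
    hshape <- 0.72 * dome + 0.28 * relief * pmax(0, 1 - pmin(r, 1)^4)^0.5
    hshape <- hshape / max(hshape)                      # discrete tip = cch
    zc <- z_rim[i] + cch[i] * hshape
    z[inside] <- pmax(z[inside], zc)
  }
  if (config$noise_sd > 0) {
    withr::with_seed(as.integer(seed) + 77L,
                     z <- z + stats::rnorm(nvtx, 0, config$noise_sd))
  }
  verts <- cbind(P2, z)
  ns <- length(sg); nv_ <- length(vg)
  idx <- function(si, vi) (vi - 1L) * ns + si
  faces <- matrix(0L, 0, 3)
  for (vi in seq_len(nv_ - 1)) {
    si <- seq_len(ns - 1)
    a <- idx(si, vi); b <- idx(si + 1L, vi)
    cc <- idx(si, vi + 1L); d <- idx(si + 1L, vi + 1L)
    faces <- rbind(faces, cbind(a, b, d), cbind(a, d, cc))
  }
  # grid built as (si fast, vi slow) matches expand.grid order
  mesh <- tri_mesh(verts, faces)
  labels <- label_map(labels, mesh)

  teeth <- tibble::tibble(
    position = positions,
    group = tooth_group_of_position(positions),
    md_requested = md, cch_requested = cch, bl = bl,
    md = NA_real_, cch = NA_real_,
    tip = NA_integer_, mesial = NA_integer_, distal = NA_integer_
  )
  for (i in seq_len(n)) {
    vi <- which(unclass(labels) == positions[i])
    proj <- verts[vi, 1] * Tg[i, 1] + verts[vi, 2] * Tg[i, 2]
    teeth$md[i] <- diff(range(proj))
    teeth$mesial[i] <- vi[which.max(proj)]
    teeth$distal[i] <- vi[which.min(proj)]
    teeth$tip[i] <- vi[which.max(verts[vi, 3])]
    teeth$cch[i] <- verts[teeth$tip[i], 3] - min(verts[vi, 3])
  }
  truth <- structure(list(labels = labels, teeth = teeth,
                          plane_point = c(0, 0, H_plane),
                          plane_normal = c(0, 0, 1),
                          md_axes = Tg, bl_axes = Nrm,
                          gaps = if (n > 1) gaps else numeric(0),
                          seed = as.integer(seed)),
                     class = "ground_truth")
  stopifnot(all(teeth$md > 0), all(teeth$cch > 0))
  list(mesh = mesh, truth = truth, config = config)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", nrow(x$teeth), " teeth; positions ",
      paste(x$teeth$position, collapse = " "), "\n", sep = "")
  invisible(x)
}

## ------------------------------------------------------------- datasets

#' Generate a dataset of synthetic arches on disk
#'
#' Writes `n_models` independent arches (per-model seed = `seed + index - 1`)
#' as labelled ASCII PLY plus a label sidecar and a per-tooth ground-truth
#' table, and a manifest listing the triples.
#'
#' @param n_models number of arches (>= 1).
#' @param config an [arch_config()].
#' @param seed base seed.
#' @param dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return the manifest as a tibble (also written to `manifest.tsv`):
#'   columns `model`, `mesh`, `labels`, `truth`, `seed` (paths relative to
#'   `dir`), with the generating config hash as attribute `config_hash`.
#' @export
generate_dataset <- function(n_models, config = arch_config(), seed = 1L,
                             dir = tempfile("dentseg_data_"),
                             overwrite = FALSE) {
  if (n_models < 1) stop("n_models must be >= 1", call. = FALSE)
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    stop("output directory exists and is not empty: ", dir,
         " (set overwrite = TRUE)", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n_models)
  for (i in seq_len(n_models)) {
    si <- as.integer(seed) + i - 1L
    g <- generate_arch(config, seed = si)
    mesh_f <- sprintf("model_%03d.ply", i)
    lab_f <- sprintf("model_%03d.labels.txt", i)
    tru_f <- sprintf("model_%03d.truth.tsv", i)
    write_mesh(g$mesh, file.path(dir, mesh_f), labels = g$truth$labels)
    write_labels(g$truth$labels, file.path(dir, lab_f))
    utils::write.table(
      g$truth$teeth[, c("position", "group", "md", "cch", "md_requested",
                        "cch_requested")],
      file.path(dir, tru_f), sep = "\t", row.names = FALSE, quote = FALSE)
    rows[[i]] <- tibble::tibble(model = i, mesh = mesh_f, labels = lab_f,
                                truth = tru_f, seed = si)
  }
  manifest <- dplyr::bind_rows(rows)
  hash <- rlang::hash(config)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines(hash, file.path(dir, "config_hash.txt"))
  attr(manifest, "config_hash") <- hash
  attr(manifest, "dir") <- dir
  manifest
}

#' Read a dataset manifest written by [generate_dataset()]
#' @param dir dataset directory.
#' @return manifest tibble with attribute `dir`.
#' @export
read_manifest <- function(dir) {
  m <- tibble::as_tibble(utils::read.table(file.path(dir, "manifest.tsv"),
                                           header = TRUE, sep = "\t"))
  attr(m, "dir") <- dir
  hf <- file.path(dir, "config_hash.txt")
  if (file.exists(hf)) attr(m, "config_hash") <- readLines(hf)[1]
  m
}
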