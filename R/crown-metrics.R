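#' Fit a virtual occlusal frame to a labelled arch
#'
#' The occlusal plane is a least-squares fit through the per-tooth apical
#' occlusal landmarks (incisal tips / buccal cusp tips: the highest vertex
#' of each tooth along a provisional jaw axis). The per-tooth mesiodistal
#' axis is the tangent of a quadratic arch curve fitted through the tooth
#' centroids projected into the plane; the buccolingual axis completes a
#' right-handed orthonormal triple with the plane normal.
#'
#' @param mesh a [tri_mesh()] of the arch.
#' @param labels a [label_map()]; at least 3 teeth must be present.
#' @param jaw_axis provisional occlusal direction (default +z).
#' @return an `occlusal_frame`: list with `plane_point`, `normal`, and a
#'   tibble `axes` (position, md_axis, bl_axis as list columns of unit
#'   3-vectors).
#' @export
fit_occlusal_frame <- function(mesh, labels, jaw_axis = c(0, 0, 1)) {
  labels <- as.integer(labels)
  teeth <- sort(unique(labels[labels > 0L]))
  if (length(teeth) < 3L)
    stop("need at least 3 teeth to fit an occlusal frame", call. = FALSE)
  jaw_axis <- jaw_axis / sqrt(sum(jaw_axis^2))
  v <- mesh$vertices
  tips <- t(vapply(teeth, function(t) {
    vi <- which(labels == t)
    v[vi[which.max(v[vi, ] %*% jaw_axis)], ]
  }, numeric(3)))
  ctr <- colMeans(tips)
  eg <- eigen(crossprod(sweep(tips, 2, ctr)), symmetric = TRUE)
  normal <- eg$vectors[, 3]
  if (sum(normal * jaw_axis) < 0) normal <- -normal
  # in-plane basis from the tip spread (e1 = widest direction)
  e1 <- eg$vectors[, 1]; e2 <- eg$vectors[, 2]
  cents <- t(vapply(teeth, function(t) colMeans(v[labels == t, , drop = FALSE]),
                    numeric(3)))
  pc <- sweep(cents, 2, ctr)
  u <- pc %*% e1; w <- pc %*% e2
  # quadratic arch curve w(u); its tangent gives the mesiodistal direction
  fit <- stats::lm.fit(cbind(1, u, u^2), w)
  b <- fit$coefficients
  axes <- lapply(seq_along(teeth), function(i) {
    slope <- b[2] + 2 * b[3] * u[i]
    md <- e1 + slope * e2
    md <- md - sum(md * normal) * normal
    md <- md / sqrt(sum(md^2))
    bl <- c(normal[2] * md[3] - normal[3] * md[2],
            normal[3] * md[1] - normal[1] * md[3],
            normal[1] * md[2] - normal[2] * md[1])
    list(md = md, bl = bl / sqrt(sum(bl^2)))
  })
  structure(list(
    plane_point = ctr, normal = normal,
    axes = tibble::tibble(position = teeth,
                          md_axis = lapply(axes, `[[`, "md"),
                          bl_axis = lapply(axes, `[[`, "bl"))),
    class = "occlusal_frame")
}

#' @export
print.occlusal_frame <- function(x, ...) {
  cat("<occlusal_frame> ", nrow(x$axes), " teeth; normal (",
      paste(sprintf("%.3f", x$normal), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

frame_axes <- function(frame, position) {
  i <- match(position, frame$axes$position)
  if (is.na(i)) stop("frame has no axes for tooth ", position, call. = FALSE)
  list(md = frame$axes$md_axis[[i]], bl = frame$axes$bl_axis[[i]])
}

#' Occlusal frame from generator ground truth
#'
#' In the synthetic setting the reference coordinates are shared between
#' segmentation and ground truth, so the measurement frame can be taken
#' directly from the generator (occlusal plane and per-tooth arch-tangent
#' axes) instead of the best-fit superimposition used on real scans.
#'
#' @param truth a `ground_truth` from [generate_arch()].
#' @return an `occlusal_frame`.
#' @export
truth_frame <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  n <- nrow(truth$teeth)
  axes_md <- lapply(seq_len(n), function(i) c(truth$md_axes[i, ], 0))
  normal <- truth$plane_normal
  axes_bl <- lapply(axes_md, function(md) {
    bl <- c(normal[2] * md[3] - normal[3] * md[2],
            normal[3] * md[1] - normal[1] * md[3],
            normal[1] * md[2] - normal[2] * md[1])
    bl / sqrt(sum(bl^2))
  })
  structure(list(plane_point = truth$plane_point, normal = normal,
                 axes = tibble::tibble(position = truth$teeth$position,
                                       md_axis = axes_md, bl_axis = axes_bl)),
            class = "occlusal_frame")
}

#' Occlusal frame of a standalone generated tooth
#'
#' [generate_tooth()] builds crowns in a canonical pose: mesiodistal axis
#' +x, buccolingual +y, crown axis +z, cusp tips at z = CCH.
#'
#' @param tooth the list returned by [generate_tooth()].
#' @return an `occlusal_frame` with that single tooth's axes.
#' @export
tooth_frame <- function(tooth) {
  structure(list(plane_point = c(0, 0, tooth$cch), normal = c(0, 0, 1),
                 axes = tibble::tibble(position = 1L,
                                       md_axis = list(c(1, 0, 0)),
                                       bl_axis = list(c(0, 1, 0)))),
            class = "occlusal_frame")
}

#' Apply a rigid transform to a mesh or occlusal frame
#'
#' @param x a [tri_mesh()] or `occlusal_frame`.
#' @param R 3 x 3 rotation matrix.
#' @param t length-3 translation.
#' @return the transformed object.
#' @export
rigid_transform <- function(x, R = diag(3), t = c(0, 0, 0)) {
  if (inherits(x, "tri_mesh")) {
    out <- x
    out$vertices <- sweep(x$vertices %*% t(R), 2, t, "+")
    if (!is.null(out$normals)) out$normals <- x$normals %*% t(R)
    return(out)
  }
  if (inherits(x, "occlusal_frame")) {
    out <- x
    out$plane_point <- as.vector(R %*% x$plane_point + t)
    out$normal <- as.vector(R %*% x$normal)
    out$axes$md_axis <- lapply(x$axes$md_axis, function(a) as.vector(R %*% a))
    out$axes$bl_axis <- lapply(x$axes$bl_axis, function(a) as.vector(R %*% a))
    return(out)
  }
  stop("cannot rigidly transform objects of class ", class(x)[1], call. = FALSE)
}

#' Mesiodistal width of a segmented tooth
#'
#' Width = extent (max minus min) of the tooth's vertex projections onto
#' its mesiodistal axis from the occlusal frame.
#'
#' @param tooth a [tri_mesh()] (the extracted tooth submesh).
#' @param frame an `occlusal_frame`.
#' @param position the tooth's position code (selects the axis).
#' @return width in mm.
#' @export
measure_md_width <- function(tooth, frame, position) {
  if (n_vertices(tooth) == 0L) stop("empty tooth mesh", call. = FALSE)
  ax <- frame_axes(frame, position)
  proj <- tooth$vertices %*% ax$md
  max(proj) - min(proj)
}

#' Clinical crown height of a segmented tooth
#'
#' CCH = distance along the occlusal plane normal from the plane to the
#' cervical-rim vertex farthest from it (the lowest visible point of the
#' gingival margin).
#'
#' @param tooth a [tri_mesh()].
#' @param frame an `occlusal_frame`.
#' @param rim optional integer vertex indices of the cervical rim; by
#'   default the boundary loop of the (open) crown submesh.
#' @return height in mm.
#' @export
measure_cch <- function(tooth, frame, rim = NULL) {
  rim <- rim %||% boundary_vertices(tooth)
  if (length(rim) == 0L)
    stop("tooth has no boundary rim; pass `rim` explicitly", call. = FALSE)
  d <- sweep(tooth$vertices[rim, , drop = FALSE], 2, frame$plane_point) %*%
    frame$normal
  max(-d)
}

#' Judge segmentation success of one tooth against its reference
#'
#' A segmentation fails when (a) any point of its cervical margin deviates
#' from the reference cervical margin by more than 25% of the reference
#' crown height, measured along the crown axis (the occlusal plane
#' normal); or (b) part of the reference occlusal/incisal cap (top
#' `cap_frac` of the crown height) is missing from the segmented tooth;
#' for the most posterior molars the defect check also covers the labial,
#' lingual and distal surface sectors. The deviation test uses a strict
#' inequality, so a margin displaced by exactly the 25% allowance still
#' counts as success.
#'
#' @param seg_idx integer vertex indices (into `mesh`) of the segmented
#'   tooth.
#' @param ref_idx integer vertex indices of the reference tooth.
#' @param mesh the shared arch [tri_mesh()].
#' @param frame an `occlusal_frame`.
#' @param position tooth position code.
#' @param tolerance_frac margin allowance as a fraction of reference CCH.
#' @param cap_frac height fraction defining the occlusal/incisal cap.
#' @param posterior is this the most posterior molar of its side?
#' @param defect_allowance fraction of cap/sector vertices that may be
#'   missing before a defect is declared (discretization guard).
#' @return list with `success` (logical), `reasons` (character vector,
#'   subset of margin_deviation / occlusal_defect / missing), and the
#'   measured `margin_deviation_mm` and reference `cch_mm`.
#' @export
judge_success <- function(seg_idx, ref_idx, mesh, frame, position,
                          tolerance_frac = 0.25, cap_frac = 0.2,
                          posterior = FALSE, defect_allowance = 0.02) {
  if (length(ref_idx) == 0L) stop("empty reference tooth", call. = FALSE)
  reasons <- character()
  if (length(seg_idx) == 0L)
    return(list(success = FALSE, reasons = "missing",
                margin_deviation_mm = NA_real_, cch_mm = NA_real_))
  v <- mesh$vertices
  depth <- function(idx)      # depth below the occlusal plane, mm
    as.vector(-(sweep(v[idx, , drop = FALSE], 2, frame$plane_point) %*%
                  frame$normal))
  ref_cch <- max(depth(ref_idx))
  # cervical margin = deepest rim of each region; compare along the crown
  # axis at matched in-plane locations
  seg_margin <- region_margin(mesh, seg_idx)
  ref_margin <- region_margin(mesh, ref_idx)
  ax <- frame_axes(frame, position)
  plane_xy <- function(idx)
    cbind(v[idx, , drop = FALSE] %*% ax$md, v[idx, , drop = FALSE] %*% ax$bl)
  nearest <- nearest_point_index(plane_xy(seg_margin), plane_xy(ref_margin))
  dev_mm <- max(abs(depth(seg_margin) - depth(ref_margin)[nearest]))
  if (dev_mm > tolerance_frac * ref_cch) reasons <- c(reasons, "margin_deviation")
  # occlusal / incisal cap coverage
  cap <- ref_idx[depth(ref_idx) <= cap_frac * ref_cch]
  if (length(cap) > 0L &&
      mean(!(cap %in% seg_idx)) > defect_allowance)
    reasons <- c(reasons, "occlusal_defect")
  if (posterior) {
    # labial/lingual/distal sectors of the crown sides
    ctr <- colMeans(v[ref_idx, , drop = FALSE])
    rel <- sweep(v[ref_idx, , drop = FALSE], 2, ctr)
    s_md <- rel %*% ax$md; s_bl <- rel %*% ax$bl
    ang <- atan2(as.vector(s_bl), as.vector(s_md))
    sector <- abs(ang) > pi / 4           # exclude the mesial quadrant
    side <- ref_idx[sector & depth(ref_idx) > cap_frac * ref_cch &
                      depth(ref_idx) < 0.8 * ref_cch]
    if (length(side) > 0L && mean(!(side %in% seg_idx)) > defect_allowance)
      reasons <- c(reasons, "occlusal_defect")
  }
  reasons <- unique(reasons)
  list(success = length(reasons) == 0L, reasons = reasons,
       margin_deviation_mm = dev_mm, cch_mm = ref_cch)
}

# margin (outline) vertices of a labelled region: region vertices with a
# neighbour outside the region; falls back to the region's deepest ring
region_margin <- function(mesh, idx) {
  adj <- build_adjacency(mesh)
  inr <- logical(n_vertices(mesh)); inr[idx] <- TRUE
  m <- idx[vapply(idx, function(v) any(!inr[adj[[v]]]), logical(1))]
  if (length(m) == 0L) idx else m
}

#' Measure every tooth of a labelled arch
#'
#' Batch wrapper producing one record per tooth: position, tooth group,
#' MD width and CCH against the fitted (or supplied) occlusal frame, and —
#' when reference labels are given — the success judgement.
#'
#' @param mesh arch [tri_mesh()].
#' @param labels segmentation [label_map()].
#' @param reference optional reference [label_map()] for success
#'   judgement.
#' @param frame optional `occlusal_frame`; fitted from `reference` (if
#'   given) or `labels` otherwise.
#' @return a tibble with columns `position`, `group`, `md_width`, `cch`,
#'   `success`, `reasons` (list column; `NA` entries when no reference).
#' @export
measure_teeth <- function(mesh, labels, reference = NULL, frame = NULL) {
  frame <- frame %||% fit_occlusal_frame(mesh, reference %||% labels)
  labs <- as.integer(labels)
  positions <- sort(unique(labs[labs > 0L]))
  post <- posterior_positions(if (is.null(reference)) positions else
    sort(unique(as.integer(reference)[as.integer(reference) > 0L])))
  rows <- lapply(positions, function(p) {
    sub <- extract_labeled_submesh(mesh, labels, p)
    md <- tryCatch(measure_md_width(sub$mesh, frame, p), error = function(e) NA_real_)
    cch <- tryCatch(measure_cch(sub$mesh, frame), error = function(e) NA_real_)
    if (is.null(reference)) {
      ok <- NA; rs <- list(NA_character_)
    } else {
      j <- judge_success(which(labs == p), which(as.integer(reference) == p),
                         mesh, frame, p, posterior = p %in% post)
      ok <- j$success; rs <- list(j$reasons)
    }
    tibble::tibble(position = p, group = tooth_group_of_position(p),
                   md_width = md, cch = cch, success = ok, reasons = rs)
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(reference)) {
    missing_pos <- setdiff(sort(unique(as.integer(reference)[as.integer(reference) > 0L])),
                           positions)
    if (length(missing_pos))
      out <- dplyr::bind_rows(out, tibble::tibble(
        position = missing_pos, group = tooth_group_of_position(missing_pos),
        md_width = NA_real_, cch = NA_real_, success = FALSE,
        reasons = lapply(missing_pos, function(p) "missing")))
  }
  dplyr::arrange(out, .data$position)
}

# most posterior tooth present on each side (right: 1..8, left: 9..16)
posterior_positions <- function(positions) {
  out <- integer()
  r <- positions[positions <= 8L]
  l <- positions[positions > 8L]
  if (length(r)) out <- c(out, max(r))
  if (length(l)) out <- c(out, max(l))
  out
}
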