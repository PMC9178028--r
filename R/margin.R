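#' Margin-refinement configuration
#'
#' Thresholds of the curvature-based margin extraction, in one place.
#'
#' @param band_width geodesic band (mm) around each tooth's labelled region
#'   searched for feature vertices.
#' @param tau feature threshold: a candidate needs
#'   `H < mean(H_tooth) - tau * sd(H_tooth)`.
#' @param min_branch minimum surviving branch length (vertices) during
#'   skeleton pruning.
#' @param loop_floor_mm minimum accepted loop length (mm).
#' @param min_overlap minimum fraction of one tooth's labelled vertices the
#'   enclosed region must contain for the loop to be accepted.
#' @return list of class `margin_config`.
#' @export
margin_config <- function(band_width = 2, tau = 0.5, min_branch = 4L,
                          loop_floor_mm = 3, min_overlap = 0.5) {
  structure(list(band_width = band_width, tau = tau,
                 min_branch = as.integer(min_branch),
                 loop_floor_mm = loop_floor_mm, min_overlap = min_overlap),
            class = "margin_config")
}

# multi-source graph distance (edge lengths in mm) from a seed vertex set,
# cut off at `limit`; Dijkstra via igraph with a virtual source
geodesic_band <- function(mesh, seeds, limit) {
  me <- mesh_edges(mesh)
  nv <- n_vertices(mesh)
  g <- igraph::make_empty_graph(n = nv + 1L, directed = FALSE)
  g <- igraph::add_edges(g, t(me$edges), weight = me$lengths)
  g <- igraph::add_edges(g, rbind(nv + 1L, seeds), weight = 0)
  d <- igraph::distances(g, v = nv + 1L, weights = igraph::E(g)$weight)[1, ]
  which(d[seq_len(nv)] <= limit)
}

#' Select curvature feature vertices per tooth
#'
#' The cervical margin reads as a concave groove: feature vertices are
#' those in a geodesic band around each tooth's labelled region whose mean
#' curvature falls below the tooth's own curvature statistics
#' (`mean - tau * sd`).
#'
#' @param mesh a [tri_mesh()].
#' @param H a `curvature_field` from [mean_curvature()].
#' @param labels a [label_map()].
#' @param config a [margin_config()].
#' @return named list: per tooth label (as character), the integer vertex
#'   set of selected feature vertices. Teeth with fewer than 10 labelled
#'   vertices are skipped with a warning.
#' @export
select_feature_vertices <- function(mesh, H, labels, config = margin_config()) {
  labels <- as.integer(labels)
  adj <- build_adjacency(mesh)
  out <- list()
  for (t in sort(unique(labels[labels > 0L]))) {
    region <- which(labels == t)
    if (length(region) < 10L) {
      warning("tooth ", t, " has fewer than 10 labelled vertices; skipped")
      next
    }
    sdH <- stats::sd(H[region])
    if (is.na(sdH) || sdH < 1e-3) {     # uniform curvature: no margin signal
      out[[as.character(t)]] <- integer(0)
      next
    }
    thr <- mean(H[region]) - config$tau * sdH
    if (is.nan(thr)) next
    # the band grows from the region outline (the putative margin), so
    # occlusal grooves deep inside the crown stay out of the candidates
    rim <- region[vapply(region, function(v)
      any(labels[adj[[v]]] != t), logical(1))]
    if (length(rim) == 0L) rim <- region
    band <- geodesic_band(mesh, rim, config$band_width)
    sel <- band[H[band] < thr]
    out[[as.character(t)]] <- sel
  }
  out
}

## --------------------------------------------------- skeleton / pruning

# induced adjacency (within `keep`) as a list of integer vectors keyed by
# vertex id
induced_adj <- function(adj, keep) {
  keepset <- logical(length(adj))
  keepset[keep] <- TRUE
  lapply(stats::setNames(keep, keep), function(v) adj[[v]][keepset[adj[[v]]]])
}

#' Thin a feature-vertex set into closed margin loops
#'
#' Morphological thinning on the feature-vertex subgraph: repeatedly delete
#' degree-1 vertices and vertices whose neighbourhood within the set stays
#' connected after their removal, until stable; prune residual branches
#' shorter than `min_branch`; return the remaining simple cycles as ordered
#' closed loops. An empty result is legitimate (the groove curvature may be
#' too weak to close a loop).
#'
#' @param feature_set integer vertex indices.
#' @param adj adjacency list from [build_adjacency()].
#' @param min_branch minimum branch length kept before cycle extraction.
#' @return list of `margin_loop`s: integer vertex cycles with first ==
#'   last, consecutive entries mesh-adjacent.
#' @export
skeletonize_prune_loops <- function(feature_set, adj, min_branch = 4L) {
  if (length(feature_set) == 0L) return(list())
  keep <- logical(length(adj))
  keep[feature_set] <- TRUE
  deg <- function(v) sum(keep[adj[[v]]])
  nbrs <- function(v) adj[[v]][keep[adj[[v]]]]
  # is the induced subgraph on N(v) connected (and nonempty)?
  nbhd_connected <- function(v) {
    nb <- nbrs(v)
    if (length(nb) == 0L) return(TRUE)      # isolated: removable
    if (length(nb) == 1L) return(TRUE)      # endpoint: removable
    seen <- nb[1]; frontier <- nb[1]
    while (length(frontier) > 0L) {
      nxt <- unique(unlist(lapply(frontier, function(u) {
        w <- adj[[u]]
        w[w %in% nb]
      })))
      nxt <- setdiff(nxt, seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    length(seen) == length(nb)
  }
  repeat {
    changed <- FALSE
    for (v in sort(which(keep))) {
      if (!keep[v]) next
      d <- deg(v)
      if (d <= 1L) { keep[v] <- FALSE; changed <- TRUE; next }
      # simple-point test: only boundary vertices of the set (those with a
      # neighbour outside it) whose in-set neighbourhood stays connected
      # may go; deleting interior vertices would create holes and spawn
      # spurious micro-loops
      on_boundary <- length(adj[[v]]) > d
      if (on_boundary && nbhd_connected(v)) { keep[v] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  # branches attached to cycles: erode degree-1 chains below min_branch
  # (deg-1 deletion above already removes them; kept for clarity on inputs
  # where thinning stabilizes with short spurs)
  repeat {
    d1 <- which(keep & vapply(seq_along(keep), function(v)
      keep[v] && sum(keep[adj[[v]]]) <= 1L, logical(1)))
    if (length(d1) == 0L) break
    keep[d1] <- FALSE
  }
  surv <- which(keep)
  if (length(surv) == 0L) return(list())
  # per component, return the longest fundamental cycle (spanning tree +
  # one non-tree edge); the thinned skeleton may retain a few short chords
  # next to the main ring, which the tree construction sidesteps
  el <- do.call(rbind, lapply(surv, function(v) {
    nb <- nbrs(v); nb <- nb[nb > v]
    if (length(nb)) cbind(v, nb) else NULL
  }))
  if (is.null(el)) return(list())
  g <- igraph::graph_from_edgelist(matrix(as.character(el), ncol = 2),
                                   directed = FALSE)
  memb <- igraph::components(g)$membership
  loops <- list()
  for (cid in unique(memb)) {
    sub <- igraph::induced_subgraph(g, which(memb == cid))
    if (igraph::vcount(sub) < max(3L, min_branch)) next
    mst <- igraph::mst(sub)
    extra <- igraph::difference(sub, mst)
    eel <- igraph::as_edgelist(extra)
    if (nrow(eel) == 0L) next
    best <- NULL
    for (r in seq_len(nrow(eel))) {
      p <- igraph::shortest_paths(mst, from = eel[r, 1], to = eel[r, 2],
                                  output = "vpath")$vpath[[1]]
      cyc <- as.integer(igraph::as_ids(p))
      if (length(cyc) < 3L) next
      if (is.null(best) || length(cyc) > length(best)) best <- cyc
    }
    if (!is.null(best) && length(best) >= max(3L, min_branch))
      loops[[length(loops) + 1L]] <-
        structure(c(best, best[1]), class = "margin_loop")
  }
  loops
}

# graph components of the mesh after removing `cut` vertices; returns the
# component id per vertex (0 for cut vertices)
components_without <- function(mesh, cut) {
  me <- mesh_edges(mesh)
  nv <- n_vertices(mesh)
  cutset <- logical(nv); cutset[cut] <- TRUE
  keep_e <- !cutset[me$edges[, 1]] & !cutset[me$edges[, 2]]
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  g <- igraph::add_edges(g, t(me$edges[keep_e, , drop = FALSE]))
  memb <- igraph::components(g)$membership
  memb[cutset] <- 0L
  memb
}

# enclosed side of a loop: the adjacent component with the smaller face
# count; returns vertex indices (excluding the loop itself) or NULL
enclosed_region <- function(mesh, loop, memb = NULL) {
  cyc <- unique(unclass(loop))
  if (is.null(memb)) memb <- components_without(mesh, cyc)
  nbr_comp <- unique(memb[unlist(build_adjacency(mesh)[cyc])])
  nbr_comp <- nbr_comp[nbr_comp != 0L]
  if (length(nbr_comp) < 2L) return(NULL)    # loop does not separate
  f <- mesh$faces
  face_comp <- pmax(memb[f[, 1]], memb[f[, 2]], memb[f[, 3]])
  fc <- tabulate(face_comp, nbins = max(memb))
  side <- nbr_comp[which.min(fc[nbr_comp])]
  which(memb == side)
}

loop_length_mm <- function(mesh, loop) {
  p <- mesh$vertices[unclass(loop), , drop = FALSE]
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Validate margin-loop candidates against the point labels
#'
#' A loop is accepted when the smaller mesh region it encloses contains at
#' least `min_overlap` of exactly one tooth's labelled vertices and its
#' length exceeds the floor; small loops around occlusal grooves fail the
#' overlap test and are rejected.
#'
#' @param loops list of `margin_loop`s.
#' @param labels a [label_map()].
#' @param mesh a [tri_mesh()].
#' @param config a [margin_config()].
#' @return tibble with columns `tooth`, `loop` (list), `enclosed` (list of
#'   vertex sets), `length_mm`; zero rows when nothing is accepted.
#' @export
validate_loops <- function(loops, labels, mesh, config = margin_config()) {
  labels <- as.integer(labels)
  rows <- list()
  for (lp in loops) {
    len <- loop_length_mm(mesh, lp)
    if (len <= config$loop_floor_mm) next
    enc <- enclosed_region(mesh, lp)
    if (is.null(enc)) next
    enc_lab <- labels[enc]
    cover <- vapply(sort(unique(labels[labels > 0L])), function(t)
      sum(enc_lab == t) / sum(labels == t), numeric(1))
    names(cover) <- sort(unique(labels[labels > 0L]))
    hit <- which(cover >= config$min_overlap)
    if (length(hit) != 1L) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      tooth = as.integer(names(cover)[hit]),
      loop = list(lp), enclosed = list(enc), length_mm = len)
  }
  if (length(rows) == 0L)
    return(tibble::tibble(tooth = integer(), loop = list(),
                          enclosed = list(), length_mm = numeric()))
  dplyr::bind_rows(rows)
}

#' Merge network labels with accepted margin loops
#'
#' For every tooth with an accepted loop, the tooth's final region becomes
#' the loop-enclosed region (the loop overrides point labels near the
#' margin); its former vertices outside the loop revert to gingiva. Teeth
#' without a loop keep their network labels unchanged. When two accepted
#' regions overlap, the vertex goes to the tooth with the higher network
#' vote fraction in its enclosed region (logged via a warning).
#'
#' @param dgcnn_labels a [label_map()] from [two_stage_segment()].
#' @param accepted tibble from [validate_loops()].
#' @param mesh a [tri_mesh()].
#' @return a refined [label_map()].
#' @export
merge_segmentation <- function(dgcnn_labels, accepted, mesh) {
  labels <- as.integer(dgcnn_labels)
  if (nrow(accepted) == 0L) return(label_map(labels, mesh))
  out <- labels
  claimed <- integer(length(labels))       # which tooth claimed each vertex
  vote <- numeric(length(labels))
  for (i in seq_len(nrow(accepted))) {
    t <- accepted$tooth[i]
    enc <- accepted$enclosed[[i]]
    frac <- mean(labels[enc] == t)
    # release the tooth's old region, then claim the enclosed one
    out[labels == t & out == t] <- 0L
    conflict <- claimed[enc] != 0L
    if (any(conflict))
      warning("overlapping margin loops for teeth ",
              unique(claimed[enc][conflict]), " and ", t,
              "; resolved by network vote")
    take <- enc[!conflict | vote[enc] < frac]
    out[take] <- t
    claimed[take] <- t
    vote[take] <- frac
  }
  label_map(out, mesh)
}

#' Export margin loops as a polyline OBJ (debug aid)
#'
#' @param loops list of `margin_loop`s (or the `loop` column of an
#'   accepted-loops tibble).
#' @param mesh the source [tri_mesh()].
#' @param path output OBJ path.
#' @return invisibly, `path`.
#' @export
export_loops_obj <- function(loops, mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  offset <- 0L
  for (lp in loops) {
    v <- mesh$vertices[unclass(lp), , drop = FALSE]
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(paste("l", paste(offset + seq_len(nrow(v)), collapse = " ")),
               con)
    offset <- offset + nrow(v)
  }
  invisible(path)
}

#' Export per-vertex curvature as an ASCII PLY property (debug aid)
#'
#' Writes the mesh with a per-vertex float property `H`.
#'
#' @param mesh a [tri_mesh()].
#' @param H a `curvature_field` from [mean_curvature()].
#' @param path output PLY path.
#' @return invisibly, `path`.
#' @export
export_curvature_ply <- function(mesh, H, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property float x", "property float y", "property float z",
               "property float H",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g %.6g", v[, 1], v[, 2], v[, 3],
                     as.numeric(H)), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
             con)
  invisible(path)
}

#' Refine a two-stage segmentation with curvature margin loops
#'
#' Convenience wrapper: curvature, feature vertices, skeleton loops,
#' validation, merge.
#'
#' @param mesh a [tri_mesh()].
#' @param labels a [label_map()] (e.g. from [two_stage_segment()]).
#' @param config a [margin_config()].
#' @return refined [label_map()] with attribute `"loops"` (the accepted
#'   loops tibble).
#' @export
refine_margins <- function(mesh, labels, config = margin_config()) {
  H <- mean_curvature(mesh)
  feats <- select_feature_vertices(mesh, H, labels, config)
  adj <- build_adjacency(mesh)
  loops <- list()
  for (fs in feats)
    loops <- c(loops, skeletonize_prune_loops(fs, adj, config$min_branch))
  accepted <- validate_loops(loops, labels, mesh, config)
  out <- merge_segmentation(labels, accepted, mesh)
  attr(out, "loops") <- accepted
  out
}
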