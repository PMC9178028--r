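#' Two-stage automatic tooth segmentation of a dental model
#'
#' Stage 1 labels a sampled point cloud tooth/gingiva with the two-class
#' network; the gingiva point budget is then enforced (at most `ratio`
#' times the tooth count) and stage 2 assigns one of seventeen classes on
#' the balanced cloud. Gingiva points dropped by the balancing are restored
#' with label 0, and labels are propagated to every mesh vertex by nearest
#' sampled point (Euclidean).
#'
#' @param mesh a [tri_mesh()].
#' @param model2 trained 2-class `dgcnn_model`.
#' @param model17 trained 17-class `dgcnn_model`.
#' @param max_points point budget of the sampled cloud at inference.
#'   Denser sampling than the training clouds pays off directly: label
#'   propagation to unsampled vertices is nearest-point, so vertex-level
#'   accuracy is capped by sampling density.
#' @param ratio gingiva budget multiple (default 2).
#' @param seed sampling seed.
#' @return a [label_map()] covering all mesh vertices, with attribute
#'   `"point_labels"` (labels on the sampled cloud) and `"cloud"`.
#' @export
two_stage_segment <- function(mesh, model2, model17, max_points = 2048L,
                              ratio = 2, seed = 1L) {
  stopifnot(model2$params$n_classes == 2L, model17$params$n_classes == 17L)
  pc <- mesh_to_pointcloud(mesh, max_points, seed = seed)
  coarse <- predict_point_labels(model2, pc)$labels
  if (!any(coarse != 0L))
    stop("stage 1 found no tooth points: cannot proceed", call. = FALSE)
  bal <- balance_gingiva(pc, coarse, ratio = ratio, seed = seed)
  # stage 2 on the balanced cloud, renormalized to its own centroid/radius
  ctr <- colMeans(bal$coords)
  centred <- sweep(bal$coords, 2, ctr)
  sc <- max(sqrt(rowSums(centred^2)))
  fine <- predict_point_labels(model17, centred / sc)$labels
  point_labels <- integer(nrow(pc$coords))          # dropped gingiva -> 0
  point_labels[attr(bal, "kept")] <- fine
  # propagate to every vertex via nearest sampled point
  full <- point_labels[nearest_point_index(mesh$vertices,
                                           mesh$vertices[pc$source_vertex, ,
                                                         drop = FALSE])]
  out <- label_map(full, mesh)
  attr(out, "point_labels") <- point_labels
  attr(out, "cloud") <- pc
  out
}

# index of the nearest row of `ref` for each row of `query` (Euclidean,
# ties toward the smaller index)
nearest_point_index <- function(query, ref) {
  storage.mode(query) <- "double"
  storage.mode(ref) <- "double"
  cpp_nearest(query, ref)
}

#' Per-vertex segmentation accuracy against ground truth
#' @param predicted,reference [label_map()]s of equal length.
#' @return fraction of vertices with matching labels.
#' @export
label_accuracy <- function(predicted, reference) {
  if (length(predicted) != length(reference))
    stop("label maps differ in length", call. = FALSE)
  mean(as.integer(predicted) == as.integer(reference))
}
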