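test_that("feature selection hits the junction band, spares the crown top", {
  g <- generate_arch(arch_config(n_teeth = 1, grid_step = 0.4), seed = 5)
  H <- mean_curvature(g$mesh)
  labs <- as.integer(g$truth$labels)
  feats <- select_feature_vertices(g$mesh, H, g$truth$labels)
  sel <- feats[[1]]
  expect_gt(length(sel), 0)
  # crown top (top 40% of the crown) nearly untouched
  ztop <- stats::quantile(g$mesh$vertices[labs == 1, 3], 0.6)
  top <- which(labs == 1 & g$mesh$vertices[, 3] >= ztop)
  expect_lte(mean(top %in% sel), 0.05)
  # the generator's moat trough is selected: gingiva vertices adjacent to
  # the tooth outline
  adj <- build_adjacency(g$mesh)
  trough <- which(vapply(seq_along(adj), function(v)
    labs[v] == 0L && any(labs[adj[[v]]] == 1L), logical(1)))
  expect_gte(mean(trough %in% sel), 0.9)
})

test_that("tau = Inf empties the feature set; uniform curvature selects none", {
  g <- generate_arch(arch_config(n_teeth = 1, grid_step = 0.4), seed = 5)
  H <- mean_curvature(g$mesh)
  feats <- select_feature_vertices(g$mesh, H, g$truth$labels,
                                   margin_config(tau = Inf))
  expect_equal(length(feats[[1]]), 0L)
  # a sphere labelled as one tooth has (numerically) uniform curvature
  s <- icosphere(2, 3)
  Hs <- mean_curvature(s)
  labs <- label_map(rep(1L, n_vertices(s)), s)
  fs <- select_feature_vertices(s, Hs, labs, margin_config(tau = 0.5))
  # nothing sits below mean - 0.5 sd by more than discretization jitter
  expect_lte(length(fs[["1"]]) / n_vertices(s), 0.2)
})

test_that("skeleton thinning produces closed loops from annuli only", {
  gp <- grid_patch(30, 30, 29, 29)
  adj <- build_adjacency(gp)
  ctr <- c(14.5, 14.5)
  r <- sqrt((gp$vertices[, 1] - ctr[1])^2 + (gp$vertices[, 2] - ctr[2])^2)
  # annulus -> exactly one loop winding once around the centre
  loops <- skeletonize_prune_loops(which(r > 5 & r < 9), adj)
  expect_length(loops, 1)
  lp <- loops[[1]]
  expect_equal(lp[1], lp[length(lp)])
  for (i in seq_len(length(lp) - 1))
    expect_true(lp[i + 1] %in% adj[[lp[i]]])
  ang <- atan2(gp$vertices[lp, 2] - ctr[2], gp$vertices[lp, 1] - ctr[1])
  d <- diff(ang)
  d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
  expect_equal(abs(sum(d)) / (2 * pi), 1, tolerance = 1e-9)
  # tree (no cycle) -> nothing
  tree <- which(abs(gp$vertices[, 1] - 14.5) < 0.6)
  expect_length(skeletonize_prune_loops(tree, adj), 0)
  # two disjoint annuli -> two loops
  gp2 <- grid_patch(50, 26, 49, 25)
  adj2 <- build_adjacency(gp2)
  r1 <- sqrt((gp2$vertices[, 1] - 12)^2 + (gp2$vertices[, 2] - 12.5)^2)
  r2 <- sqrt((gp2$vertices[, 1] - 37)^2 + (gp2$vertices[, 2] - 12.5)^2)
  two <- which((r1 > 4 & r1 < 8) | (r2 > 4 & r2 < 8))
  expect_length(skeletonize_prune_loops(two, adj2), 2)
  expect_length(skeletonize_prune_loops(integer(0), adj), 0)
})

test_that("thinning terminates and never grows the set", {
  g <- generate_arch(arch_config(n_teeth = 3, grid_step = 0.4), seed = 2)
  H <- mean_curvature(g$mesh)
  adj <- build_adjacency(g$mesh)
  feats <- select_feature_vertices(g$mesh, H, g$truth$labels)
  for (fs in feats) {
    loops <- skeletonize_prune_loops(fs, adj)
    expect_true(all(unlist(loops) %in% fs))
  }
})

test_that("loop validation accepts neck annuli and rejects groove loops", {
  g <- generate_arch(arch_config(n_teeth = 1, grid_step = 0.4), seed = 5)
  H <- mean_curvature(g$mesh)
  adj <- build_adjacency(g$mesh)
  labs <- as.integer(g$truth$labels)
  feats <- select_feature_vertices(g$mesh, H, g$truth$labels)
  loops <- skeletonize_prune_loops(feats[[1]], adj)
  acc <- validate_loops(loops, g$truth$labels, g$mesh)
  expect_equal(nrow(acc), 1L)
  expect_equal(acc$tooth, 1L)
  # enclosed region covers most of the tooth
  expect_gte(mean(which(labs == 1) %in% acc$enclosed[[1]]), 0.5)

  # constructed groove loop: small cycle high on the crown
  tip <- g$mesh$vertices[which(labs == 1), , drop = FALSE]
  ctr2 <- colMeans(tip[, 1:2])
  rr <- sqrt((g$mesh$vertices[, 1] - ctr2[1])^2 +
               (g$mesh$vertices[, 2] - ctr2[2])^2)
  groove <- which(labs == 1 & rr > 1.2 & rr < 2.6)
  gl <- skeletonize_prune_loops(groove, adj)
  if (length(gl) > 0) {
    accg <- validate_loops(gl, g$truth$labels, g$mesh)
    expect_equal(nrow(accg), 0L)
  }
  # empty in, empty out
  expect_equal(nrow(validate_loops(list(), g$truth$labels, g$mesh)), 0L)
})

test_that("debug exports write readable loop OBJ and curvature PLY", {
  gp <- grid_patch(20, 20, 19, 19)
  adj <- build_adjacency(gp)
  r <- sqrt((gp$vertices[, 1] - 9.5)^2 + (gp$vertices[, 2] - 9.5)^2)
  loops <- skeletonize_prune_loops(which(r > 4 & r < 7), adj)
  p1 <- withr::local_tempfile(fileext = ".obj")
  export_loops_obj(loops, gp, p1)
  lines <- readLines(p1)
  expect_equal(sum(grepl("^l ", lines)), length(loops))
  expect_equal(sum(grepl("^v ", lines)), sum(lengths(loops)))
  H <- mean_curvature(gp)
  p2 <- withr::local_tempfile(fileext = ".ply")
  export_curvature_ply(gp, H, p2)
  back <- read_mesh(p2)    # x/y/z parse; extra property tolerated
  expect_equal(n_vertices(back), n_vertices(gp))
})

test_that("merge with no loops is the identity; bleed is repaired", {
  g <- generate_arch(arch_config(n_teeth = 1, grid_step = 0.4), seed = 5)
  labs <- g$truth$labels
  merged <- merge_segmentation(labs, validate_loops(list(), labs, g$mesh),
                               g$mesh)
  expect_identical(as.integer(merged), as.integer(labs))

  # bleed fixture: dilate the tooth label ~0.5 mm onto the gingiva
  adj <- build_adjacency(g$mesh)
  bled <- as.integer(labs)
  grow <- which(vapply(seq_along(adj), function(v)
    bled[v] == 0L && any(bled[adj[[v]]] == 1L), logical(1)))
  bled[grow] <- 1L
  bled_map <- label_map(bled, g$mesh)
  refined <- refine_margins(g$mesh, bled_map)
  truth <- as.integer(labs)
  band <- unique(c(grow, which(vapply(seq_along(adj), function(v)
    truth[v] == 1L && any(truth[adj[[v]]] == 0L), logical(1)))))
  f1 <- function(pred) {
    tp <- sum(pred[band] == 1L & truth[band] == 1L)
    fp <- sum(pred[band] == 1L & truth[band] == 0L)
    fn <- sum(pred[band] == 0L & truth[band] == 1L)
    2 * tp / (2 * tp + fp + fn)
  }
  expect_gte(f1(as.integer(refined)), f1(bled))
})

test_that("merge only relabels near the margin on clean input", {
  g <- generate_arch(arch_config(n_teeth = 1, grid_step = 0.4), seed = 5)
  refined <- refine_margins(g$mesh, g$truth$labels)
  changed <- which(as.integer(refined) != as.integer(g$truth$labels))
  if (length(changed) > 0) {
    # every changed vertex lies within the band width of the margin
    labs <- as.integer(g$truth$labels)
    adj <- build_adjacency(g$mesh)
    rim <- which(vapply(seq_along(adj), function(v)
      labs[v] == 1L && any(labs[adj[[v]]] == 0L), logical(1)))
    band <- dentseg:::geodesic_band(g$mesh, rim, margin_config()$band_width)
    expect_true(all(changed %in% band))
  }
  expect_true(TRUE)
})
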