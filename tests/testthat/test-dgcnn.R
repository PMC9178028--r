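naive_edge_conv <- function(x, edges, W, b, relu = TRUE) {
  m <- nrow(x); dp <- ncol(W)
  out <- matrix(-Inf, m, dp)
  for (i in seq_len(m)) {
    for (j in edges[i, ]) {
      z <- as.vector(c(x[i, ], x[j, ] - x[i, ]) %*% W) + b
      if (relu) z <- pmax(z, 0)
      out[i, ] <- pmax(out[i, ], z)
    }
  }
  out
}

test_that("edge convolution equals the literal per-edge oracle", {
  set.seed(5)
  for (rep in 1:5) {
    m <- sample(8:20, 1); d <- sample(2:4, 1); dp <- sample(3:6, 1)
    k <- sample(2:4, 1)
    x <- matrix(rnorm(m * d), m, d)
    W <- matrix(rnorm(2 * d * dp, 0, 0.7), 2 * d, dp)
    b <- rnorm(dp)
    edges <- knn_graph(x, k)
    got <- edge_conv(x, edges, list(W = W, b = b))
    expect_equal(unclass(got), naive_edge_conv(x, edges, W, b),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("edge convolution degenerate cases behave as specified", {
  # identity weights, single neighbour: output is the (x_i, x_j - x_i) pair
  x <- cbind(c(0, 1, 3), 0, 0)
  edges <- knn_graph(x, 1)
  W <- diag(6); b <- rep(0, 6)
  out <- edge_conv(x, edges, list(W = W, b = b), activation = "identity")
  expect_equal(unclass(out)[1, ], c(0, 0, 0, 1, 0, 0), ignore_attr = TRUE)
  # all points identical: x_j - x_i = 0 everywhere
  xx <- matrix(1, 6, 3)
  ee <- matrix(rep(c(2:6, 1), 2), 6, 2)
  out <- edge_conv(xx, ee, list(W = W, b = b), activation = "identity")
  expect_true(all(abs(out[, 4:6]) < 1e-12))
  expect_error(edge_conv(x, edges, list(W = diag(4), b = rep(0, 4))),
               "width")
})

test_that("the dynamic graph changes when features change", {
  set.seed(3)
  x <- matrix(rnorm(30), 10, 3)
  g1 <- knn_graph(x, 3)
  # a feature map that reorders distances
  f <- cbind(-x[, 1], x[, 2] * 5, x[, 3])
  g2 <- knn_graph(f, 3)
  expect_false(identical(g1, g2))
})

test_that("training is deterministic, logged, and serializable", {
  arch <- small_arch()
  pc <- mesh_to_pointcloud(arch$mesh, 400, seed = 1)
  labs <- as.integer(arch$truth$labels)[pc$source_vertex]
  cloud <- list(coords = pc$coords, labels = as.integer(labs > 0))
  p <- seg_model_params(2, "tiny", k = 6, edgeconv_widths = c(16, 16),
                        embedding_width = 32, head_width = 24,
                        epochs = 3, seed = 5)
  m_a <- train_segmenter(list(cloud), p, seed = 5)
  m_b <- train_segmenter(list(cloud), p, seed = 5)
  expect_identical(tail(m_a$log$loss, 1), tail(m_b$log$loss, 1))
  expect_equal(nrow(m_a$log), 3L)
  expect_true(all(diff(m_a$log$loss) < 0.5))   # loss roughly decreasing

  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m_a, path)
  m_c <- load_model(path)
  pr_a <- predict_point_labels(m_a, pc)
  pr_c <- predict_point_labels(m_c, pc)
  expect_identical(pr_a$labels, pr_c$labels)
  expect_identical(pr_a$scores, pr_c$scores)

  # zero-epoch model predicts from initialization and reloads identically
  p0 <- seg_model_params(2, "tiny", k = 6, edgeconv_widths = c(16, 16),
                         embedding_width = 32, head_width = 24,
                         epochs = 0, seed = 5)
  m0 <- train_segmenter(list(cloud), p0, seed = 5)
  save_model(m0, path)
  expect_identical(predict_point_labels(load_model(path), pc)$labels,
                   predict_point_labels(m0, pc)$labels)
})

test_that("prediction scores normalize and ties break to the lower class", {
  arch <- small_arch()
  pc <- mesh_to_pointcloud(arch$mesh, 300, seed = 2)
  labs <- as.integer(arch$truth$labels)[pc$source_vertex]
  p <- seg_model_params(2, "tiny", k = 6, edgeconv_widths = c(16, 16),
                        embedding_width = 32, head_width = 24,
                        epochs = 80, lr = 0.02, seed = 6)
  m <- train_segmenter(list(list(coords = pc$coords,
                                 labels = as.integer(labs > 0))), p, seed = 6)
  pr <- predict_point_labels(m, pc)
  expect_equal(rowSums(pr$scores), rep(1, 300), tolerance = 1e-6)
  # a converged tiny model reproduces its memorized training labels
  expect_gte(mean(pr$labels == as.integer(labs > 0)), 0.95)
  # single-point cloud fails the m > k precondition
  expect_error(predict_point_labels(m, pc$coords[1, , drop = FALSE]),
               "k = ")
})

test_that("predictions are permutation-equivariant", {
  arch <- small_arch()
  pc <- mesh_to_pointcloud(arch$mesh, 200, seed = 3)
  expect_false(any(duplicated(pc$coords)))     # distinct coords: no ties
  p <- seg_model_params(17, "tiny", k = 5, edgeconv_widths = c(8, 8),
                        embedding_width = 16, head_width = 16,
                        epochs = 0, seed = 2)
  m <- train_segmenter(list(list(
    coords = pc$coords,
    labels = as.integer(arch$truth$labels)[pc$source_vertex])), p, seed = 2)
  perm <- withr::with_seed(4, sample(200))
  pr <- predict_point_labels(m, pc$coords)
  pr_perm <- predict_point_labels(m, pc$coords[perm, ])
  expect_identical(pr_perm$labels, pr$labels[perm])
})

test_that("balancing inside the pipeline never drops tooth points", {
  arch <- small_arch()
  pc <- mesh_to_pointcloud(arch$mesh, 800, seed = 4)
  labs <- as.integer(arch$truth$labels)[pc$source_vertex]
  bal <- balance_gingiva(pc, as.integer(labs > 0), ratio = 1.2, seed = 1)
  kept <- attr(bal, "kept")
  expect_true(all(which(labs > 0) %in% kept))
  expect_lte(length(kept), 800L)
  expect_lte(sum(labs[kept] == 0), floor(1.2 * sum(labs > 0)))
})

test_that("a tooth-free mesh makes the pipeline fail loudly", {
  p <- seg_model_params(2, "tiny", k = 4, edgeconv_widths = c(8, 8),
                        embedding_width = 16, head_width = 8, epochs = 0,
                        seed = 1)
  gp <- grid_patch(12, 12, 10, 10)
  cloud <- list(coords = mesh_to_pointcloud(gp, 200)$coords,
                labels = rep(0:1, length.out = 144))
  m2 <- train_segmenter(list(cloud), p, seed = 1)
  # force stage 1 to see pure gingiva by thresholding scores of an
  # untrained model is unreliable; instead call the balancing contract
  pc <- mesh_to_pointcloud(gp, 144)
  expect_error(balance_gingiva(pc, rep(0L, 144)), "no tooth")
})
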