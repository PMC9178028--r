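#' Parameters of the edge-convolution segmentation network
#'
#' The segmenter is a dynamic-graph edge-convolution network: each layer
#' recomputes a k-nearest-neighbour graph in its input feature space,
#' applies a shared nonlinear map to every directed edge's feature
#' `(x_i, x_j - x_i)`, and max-aggregates over each point's neighbours.
#' Edge-convolution outputs are concatenated, lifted to a global embedding
#' by max pooling, and classified per point by a small head.
#'
#' Two presets are provided: `"full"` follows the canonical edge-convolution
#' segmentation recipe (k = 20, widths 64/64/128, embedding 1024); `"tiny"`
#' (k = 8, widths 32/32, embedding 128) is sized for CPU-scale training on
#' synthetic arches.
#'
#' @param n_classes 2 (tooth/gingiva) or 17 (gingiva + 16 positions).
#' @param preset `"tiny"` or `"full"`; individual arguments override.
#' @param k neighbour count of the dynamic graph.
#' @param edgeconv_widths integer vector of layer widths.
#' @param embedding_width global embedding width.
#' @param head_width hidden width of the classification head.
#' @param dropout dropout fraction in the head (training only); defaults
#'   to 0.5 for the full preset (the canonical recipe) and 0.1 for the
#'   tiny preset, whose 64-wide head is over-regularized at 0.5.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return list of class `seg_model_params`.
#' @export
seg_model_params <- function(n_classes, preset = c("tiny", "full"),
                             k = NULL, edgeconv_widths = NULL,
                             embedding_width = NULL, head_width = NULL,
                             dropout = NULL, lr = 0.01, epochs = 40,
                             seed = 1L) {
  preset <- match.arg(preset)
  if (!n_classes %in% c(2L, 17L)) stop("n_classes must be 2 or 17", call. = FALSE)
  def <- if (preset == "tiny")
    list(k = 8L, widths = c(32L, 32L), emb = 128L, head = 64L, drop = 0.1)
  else list(k = 20L, widths = c(64L, 64L, 128L), emb = 1024L, head = 256L,
            drop = 0.5)
  dropout <- dropout %||% def$drop
  p <- list(n_classes = as.integer(n_classes), preset = preset,
            k = as.integer(k %||% def$k),
            edgeconv_widths = as.integer(edgeconv_widths %||% def$widths),
            embedding_width = as.integer(embedding_width %||% def$emb),
            head_width = as.integer(head_width %||% def$head),
            dropout = dropout, lr = lr, epochs = as.integer(epochs),
            seed = as.integer(seed))
  if (p$k < 1L) stop("k must be >= 1", call. = FALSE)
  structure(p, class = "seg_model_params")
}

## ----------------------------------------------------------- edge conv

#' One edge-convolution layer
#'
#' For each point i with neighbours j given by `edges`, computes
#' `max_j relu(W [x_i, x_j - x_i] + b)`: a shared nonlinear map on every
#' directed edge, max-aggregated per point. The graph must be built on the
#' layer's own input features (the dynamic-graph contract).
#'
#' @param point_features m x d matrix.
#' @param edges integer m x k matrix from [knn_graph()] over
#'   `point_features` (or earlier features, at the caller's choice).
#' @param weights list with `W` (2d x d') and `b` (length d').
#' @param activation `"relu"` or `"identity"`.
#' @return m x d' matrix of aggregated features. With
#'   `attr(, "argmax")` (m x d' integer neighbour-slot indices) for
#'   backpropagation.
#' @export
edge_conv <- function(point_features, edges, weights,
                      activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  x <- as.matrix(point_features)
  m <- nrow(x); d <- ncol(x); k <- ncol(edges)
  if (nrow(weights$W) != 2 * d)
    stop("weight matrix expects input width ", nrow(weights$W) / 2,
         ", got ", d, call. = FALSE)
  dp <- ncol(weights$W)
  i_rep <- rep(seq_len(m), times = k)
  xi <- x[i_rep, , drop = FALSE]
  xj <- x[as.vector(edges), , drop = FALSE]
  ef <- cbind(xi, xj - xi)
  z <- ef %*% weights$W
  z <- sweep(z, 2, weights$b, "+")
  if (activation == "relu") z <- pmax(z, 0)
  agg <- cpp_edge_max(z, m, k)
  structure(agg$best, argmax = agg$argmax)
}

## ------------------------------------------------- full network forward

dense_init <- function(n_in, n_out) {
  s <- sqrt(2 / n_in)
  list(W = matrix(stats::rnorm(n_in * n_out, 0, s), n_in, n_out),
       b = numeric(n_out))
}

init_weights <- function(params) {
  widths <- params$edgeconv_widths
  withr::with_seed(params$seed, {
    w <- list()
    d <- 3L
    for (l in seq_along(widths)) {
      w[[paste0("ec", l)]] <- dense_init(2L * d, widths[l])
      d <- widths[l]
    }
    cat_w <- sum(widths)
    w$emb <- dense_init(cat_w, params$embedding_width)
    w$head1 <- dense_init(cat_w + params$embedding_width, params$head_width)
    w$head2 <- dense_init(params$head_width, params$n_classes)
    w
  })
}

# forward pass; returns per-point class probabilities plus a cache for
# backprop when train = TRUE
dgcnn_forward <- function(weights, params, coords, train = FALSE,
                          dropout_mask = NULL, graph1 = NULL) {
  m <- nrow(coords)
  if (m <= params$k)
    stop("cloud has ", m, " points but the dynamic graph needs more than k = ",
         params$k, call. = FALSE)
  feats <- list(); edges <- list(); x <- coords
  for (l in seq_along(params$edgeconv_widths)) {
    # layer 1 sees the raw coordinates, so its graph can be precomputed;
    # deeper layers recompute the graph on their input features
    g <- if (l == 1L && !is.null(graph1)) graph1 else knn_graph(x, params$k)
    f <- edge_conv(x, g, weights[[paste0("ec", l)]])
    edges[[l]] <- g; feats[[l]] <- f
    x <- unclass(f); attr(x, "argmax") <- NULL
  }
  cat_f <- do.call(cbind, lapply(feats, function(f) {
    f <- unclass(f); attr(f, "argmax") <- NULL; f
  }))
  emb_pre <- sweep(cat_f %*% weights$emb$W, 2, weights$emb$b, "+")
  emb <- pmax(emb_pre, 0)
  gidx <- max.col(t(emb), ties.method = "first")   # argmax row per column
  gmax <- emb[cbind(gidx, seq_len(ncol(emb)))]
  h_in <- cbind(cat_f, matrix(gmax, m, length(gmax), byrow = TRUE))
  h_pre <- sweep(h_in %*% weights$head1$W, 2, weights$head1$b, "+")
  h <- pmax(h_pre, 0)
  if (train && params$dropout > 0) {
    if (is.null(dropout_mask))
      dropout_mask <- matrix(stats::runif(length(h)) > params$dropout,
                             nrow(h), ncol(h)) / (1 - params$dropout)
    h <- h * dropout_mask
  }
  logits <- sweep(h %*% weights$head2$W, 2, weights$head2$b, "+")
  logits <- logits - apply(logits, 1, max)
  ex <- exp(logits)
  probs <- ex / rowSums(ex)
  list(probs = probs, cache = list(coords = coords, feats = feats,
                                   edges = edges, cat_f = cat_f,
                                   emb_pre = emb_pre, emb = emb, gidx = gidx,
                                   h_in = h_in, h_pre = h_pre, h = h,
                                   dropout_mask = dropout_mask))
}

# gradients of mean weighted cross-entropy wrt all weights
dgcnn_backward <- function(weights, params, cache, probs, y, class_w) {
  m <- nrow(probs)
  Y <- matrix(0, m, params$n_classes)
  Y[cbind(seq_len(m), y + 1L)] <- 1
  wv <- class_w[y + 1L]
  dlogits <- (probs - Y) * wv / sum(wv)
  g <- list()
  g$head2 <- list(W = crossprod(cache$h, dlogits), b = colSums(dlogits))
  dh <- tcrossprod(dlogits, weights$head2$W)
  if (!is.null(cache$dropout_mask)) dh <- dh * cache$dropout_mask
  dh_pre <- dh * (cache$h_pre > 0)
  g$head1 <- list(W = crossprod(cache$h_in, dh_pre), b = colSums(dh_pre))
  dh_in <- tcrossprod(dh_pre, weights$head1$W)
  nc <- ncol(cache$cat_f)
  dcat <- dh_in[, seq_len(nc), drop = FALSE]
  dgmax <- colSums(dh_in[, -seq_len(nc), drop = FALSE])
  demb <- matrix(0, m, ncol(cache$emb))
  demb[cbind(cache$gidx, seq_along(cache$gidx))] <- dgmax
  demb_pre <- demb * (cache$emb_pre > 0)
  g$emb <- list(W = crossprod(cache$cat_f, demb_pre), b = colSums(demb_pre))
  dcat <- dcat + tcrossprod(demb_pre, weights$emb$W)
  # split the concatenated gradient back to edge-conv layers, then walk
  # the layers in reverse, routing through the per-channel argmax
  widths <- params$edgeconv_widths
  offs <- c(0L, cumsum(widths))
  dfeat <- vector("list", length(widths))
  for (l in seq_along(widths))
    dfeat[[l]] <- dcat[, (offs[l] + 1L):offs[l + 1L], drop = FALSE]
  for (l in rev(seq_along(widths))) {
    f <- cache$feats[[l]]
    arg <- attr(f, "argmax")
    x_in <- if (l == 1L) cache$coords else {
      xx <- unclass(cache$feats[[l - 1L]]); attr(xx, "argmax") <- NULL; xx
    }
    d_in <- ncol(x_in); dp <- widths[l]
    ed <- cache$edges[[l]]; k <- ncol(ed)
    # scatter output grads to the winning edge of each (point, channel)
    dz <- matrix(0, m * k, dp)
    row_of <- (arg - 1L) * m + seq_len(m)     # m x dp edge-row indices
    act <- unclass(f) > 0                     # relu mask at the max
    dval <- dfeat[[l]] * act
    for (ch in seq_len(dp))
      dz[row_of[, ch], ch] <- dz[row_of[, ch], ch] + dval[, ch]
    i_rep <- rep(seq_len(m), times = k)
    j_idx <- as.vector(ed)
    xi <- x_in[i_rep, , drop = FALSE]
    xj <- x_in[j_idx, , drop = FALSE]
    ef <- cbind(xi, xj - xi)
    g[[paste0("ec", l)]] <- list(W = crossprod(ef, dz), b = colSums(dz))
    if (l > 1L) {
      def <- tcrossprod(dz, weights[[paste0("ec", l)]]$W)
      d_xi <- def[, seq_len(d_in), drop = FALSE] -
        def[, d_in + seq_len(d_in), drop = FALSE]
      d_xj <- def[, d_in + seq_len(d_in), drop = FALSE]
      dx <- rowsum(d_xi, i_rep, reorder = TRUE) +
        rowsum_mat(d_xj, j_idx, m)
      # dx lands on the previous layer's post-activation output, so no
      # extra relu mask here (that mask lives inside the previous layer)
      dfeat[[l - 1L]] <- dfeat[[l - 1L]] + dx
    }
  }
  g
}

rowsum_mat <- function(mat, group, n) {
  out <- matrix(0, n, ncol(mat))
  s <- rowsum(mat, group)
  out[as.integer(rownames(s)), ] <- s
  out
}

adam_step <- function(weights, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    for (part in c("W", "b")) {
      gkey <- paste0(nm, ".", part)
      gr <- grads[[nm]][[part]]
      if (is.null(state$m[[gkey]])) {
        state$m[[gkey]] <- gr * 0
        state$v[[gkey]] <- gr * 0
      }
      state$m[[gkey]] <- beta1 * state$m[[gkey]] + (1 - beta1) * gr
      state$v[[gkey]] <- beta2 * state$v[[gkey]] + (1 - beta2) * gr^2
      mhat <- state$m[[gkey]] / (1 - beta1^t)
      vhat <- state$v[[gkey]] / (1 - beta2^t)
      weights[[nm]][[part]] <- weights[[nm]][[part]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(weights = weights, state = state)
}

## ------------------------------------------------------------- training

#' Train a segmentation network on labelled point clouds
#'
#' @param samples either a manifest tibble from [generate_dataset()] (with
#'   attribute `dir`), or a list of `list(coords = m x 3 normalized
#'   coordinates, labels = integer per-point labels)`.
#' @param params a [seg_model_params()].
#' @param seed integer training seed (shuffling, dropout); weight
#'   initialization uses `params$seed`.
#' @param max_points per-sample point budget when sampling from meshes.
#' @param verbose print per-epoch progress.
#' @return a `dgcnn_model`: list with `params`, `weights`, `class_weights`,
#'   `log` (tibble epoch/loss/accuracy and per-class accuracy), `version`.
#' @export
train_segmenter <- function(samples, params, seed = 1L, max_points = 1024L,
                            verbose = FALSE) {
  stopifnot(inherits(params, "seg_model_params"))
  clouds <- as_training_clouds(samples, params, max_points, seed)
  all_lab <- unlist(lapply(clouds, `[[`, "labels"))
  counts <- tabulate(all_lab + 1L, nbins = params$n_classes)
  if (any(counts == 0L) && params$n_classes == 2L)
    stop("a class is absent from the training data", call. = FALSE)
  class_w <- ifelse(counts > 0, sum(counts) / (params$n_classes * pmax(counts, 1)), 0)
  class_w <- class_w / mean(class_w[class_w > 0])
  weights <- init_weights(params)
  graphs1 <- lapply(clouds, function(cl) knn_graph(cl$coords, params$k))
  state <- list(m = list(), v = list())
  log_rows <- vector("list", params$epochs)
  t_step <- 0L
  withr::with_seed(as.integer(seed), {
    for (ep in seq_len(params$epochs)) {
      ord <- sample(seq_along(clouds))
      ep_loss <- 0; ep_n <- 0; ep_correct <- 0
      cls_corr <- numeric(params$n_classes); cls_n <- numeric(params$n_classes)
      for (ci in ord) {
        cl <- clouds[[ci]]
        fw <- dgcnn_forward(weights, params, cl$coords, train = TRUE,
                            graph1 = graphs1[[ci]])
        y <- cl$labels
        wv <- class_w[y + 1L]
        p_true <- fw$probs[cbind(seq_along(y), y + 1L)]
        ep_loss <- ep_loss - sum(wv * log(pmax(p_true, 1e-12)))
        ep_n <- ep_n + sum(wv)
        pred <- max.col(fw$probs, ties.method = "first") - 1L
        ep_correct <- ep_correct + sum(pred == y)
        for (cc in unique(y)) {
          cls_n[cc + 1L] <- cls_n[cc + 1L] + sum(y == cc)
          cls_corr[cc + 1L] <- cls_corr[cc + 1L] + sum(pred[y == cc] == cc)
        }
        grads <- dgcnn_backward(weights, params, fw$cache, fw$probs, y, class_w)
        t_step <- t_step + 1L
        upd <- adam_step(weights, grads, state, params$lr, t_step)
        weights <- upd$weights; state <- upd$state
      }
      acc <- ep_correct / sum(vapply(clouds, function(c) length(c$labels), 1))
      log_rows[[ep]] <- tibble::tibble(
        epoch = ep, loss = ep_loss / ep_n, accuracy = acc,
        class_accuracy = list(ifelse(cls_n > 0, cls_corr / cls_n, NA_real_)))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.4f", ep,
                        ep_loss / ep_n, acc))
    }
  })
  structure(list(params = params, weights = weights, class_weights = class_w,
                 log = dplyr::bind_rows(log_rows), version = 1L),
            class = "dgcnn_model")
}

as_training_clouds <- function(samples, params, max_points, seed) {
  if (inherits(samples, "data.frame")) {
    dir <- attr(samples, "dir")
    if (is.null(dir)) stop("manifest lacks a 'dir' attribute", call. = FALSE)
    samples <- lapply(seq_len(nrow(samples)), function(i) {
      mesh <- read_mesh(file.path(dir, samples$mesh[i]))
      labs <- read_labels(file.path(dir, samples$labels[i]), mesh)
      pc <- mesh_to_pointcloud(mesh, max_points, seed = seed + i)
      list(coords = pc$coords, labels = as.integer(labs)[pc$source_vertex])
    })
  }
  lapply(samples, function(s) {
    lab <- as.integer(s$labels)
    if (params$n_classes == 2L) lab <- as.integer(lab != 0L)
    if (any(lab < 0L | lab >= params$n_classes))
      stop("label outside 0..", params$n_classes - 1L, call. = FALSE)
    list(coords = as.matrix(s$coords), labels = lab)
  })
}

#' @export
print.dgcnn_model <- function(x, ...) {
  fin <- utils::tail(x$log, 1)
  cat("<dgcnn_model> ", x$params$n_classes, "-class ", x$params$preset,
      " preset; ", nrow(x$log), " epochs",
      if (nrow(x$log) > 0)
        sprintf("; final loss %.4f, accuracy %.3f", fin$loss, fin$accuracy),
      "\n", sep = "")
  invisible(x)
}

#' Predict per-point labels with a trained model
#'
#' @param model a `dgcnn_model` from [train_segmenter()].
#' @param pc a `point_cloud` (normalized coordinates) or an m x 3 matrix.
#' @return list with `labels` (integer, argmax with ties toward the lower
#'   class index) and `scores` (m x n_classes, rows sum to 1).
#' @export
predict_point_labels <- function(model, pc) {
  stopifnot(inherits(model, "dgcnn_model"))
  coords <- if (inherits(pc, "point_cloud")) pc$coords else as.matrix(pc)
  if (ncol(coords) != 3L) stop("expected 3-column coordinates", call. = FALSE)
  fw <- dgcnn_forward(model$weights, model$params, coords, train = FALSE)
  list(labels = max.col(fw$probs, ties.method = "first") - 1L,
       scores = fw$probs)
}

#' Save / load a trained model
#'
#' The file is a single serialized object with a versioned params header.
#' Reloading reproduces bit-identical predictions.
#'
#' @param model a `dgcnn_model`.
#' @param path file path.
#' @return `load_model()` returns the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dgcnn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "dgcnn_model")) stop("not a dgcnn_model file", call. = FALSE)
  m
}

#' Write a training log as CSV
#' @param model a `dgcnn_model`.
#' @param path CSV path.
#' @export
write_training_log <- function(model, path) {
  log <- model$log
  ca <- do.call(rbind, log$class_accuracy)
  colnames(ca) <- paste0("acc_class_", seq_len(ncol(ca)) - 1L)
  utils::write.csv(cbind(log[, c("epoch", "loss", "accuracy")], ca), path,
                   row.names = FALSE)
  invisible(path)
}
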