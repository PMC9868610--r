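# The multi-view GCN forward computation and its analytic gradients.
#
# Each view i contributes a two-layer graph convolution with weights shared
# across views:
#   Z_i = ReLU( A_i ReLU( A_i X W0 ) W1 ),   A_i the normalized adjacency.
# The five gene embeddings are fused by element-wise max pooling, a gene
# pair (u, v) is featurized symmetrically as [Z_u * Z_v, |Z_u - Z_v|], and
# a three-hidden-layer feed-forward head emits a logit squashed to a
# probability. Binary cross-entropy is the loss. Backpropagation is written
# out explicitly below (dense/sparse matrix algebra); max pooling routes
# each gradient entry to the first view attaining the maximum.

#' Initialise model weights
#'
#' Weights are drawn uniformly on `[-1/sqrt(fan_in), 1/sqrt(fan_in)]`;
#' graph-convolution layers carry no bias (the convolution is a pure
#' weighted neighborhood average), head layers do.
#'
#' @param n_features Number of node-feature columns (4).
#' @param gcn_dims Widths `c(K1, K2)` of the two shared convolution layers.
#' @param head_dims Widths of the three hidden head layers.
#' @param seed Integer seed for the initialisation stream.
#' @return A list of class `"sl_model_state"`: `W0` (R x K1), `W1`
#'   (K1 x K2), `head` (four `(W, b)` layers ending in one logit unit),
#'   `rng_seed`.
#' @export
init_model <- function(n_features = 4, gcn_dims = c(128L, 64L),
                       head_dims = c(64L, 32L, 16L), seed = 1L) {
  set.seed(seed)
  u <- function(n_in, n_out) {
    matrix(stats::runif(n_in * n_out, -1, 1) / sqrt(n_in), n_in, n_out)
  }
  dims <- c(2L * gcn_dims[2], head_dims, 1L)
  head <- lapply(seq_len(length(dims) - 1L), function(l) {
    list(W = u(dims[l], dims[l + 1L]), b = rep(0, dims[l + 1L]))
  })
  structure(list(W0 = u(n_features, gcn_dims[1]),
                 W1 = u(gcn_dims[1], gcn_dims[2]),
                 head = head, rng_seed = as.integer(seed)),
            class = "sl_model_state")
}

#' One graph-convolution layer
#'
#' Computes `ReLU(A_hat %*% H %*% W)`: each node's new representation is
#' the degree-weighted average of its own and its neighbors'
#' representations, linearly mapped by `W` and rectified.
#'
#' @param A_hat N x N normalized adjacency (see [normalize_adjacency()]).
#' @param H N x d input representations.
#' @param W d x d' weight matrix.
#' @return N x d' matrix.
#' @export
gcn_layer <- function(A_hat, H, W) {
  if (ncol(A_hat) != nrow(H)) abort("A_hat and H dimensions do not conform")
  if (ncol(H) != nrow(W)) abort("H and W dimensions do not conform")
  relu(as.matrix(A_hat %*% (H %*% W)))
}

#' Encode every view with the shared two-layer convolution
#'
#' All views use the single weight pair `(W0, W1)`; a view's embedding
#' depends on its own adjacency only.
#'
#' @param A_hats List of normalized adjacencies (one per view, same
#'   universe ordering).
#' @param X N x R node-feature matrix.
#' @param state `"sl_model_state"`.
#' @return List of N x K2 non-negative embedding matrices, one per view.
#' @export
encode_views <- function(A_hats, X, state) {
  lapply(A_hats, function(A) gcn_layer(A, gcn_layer(A, X, state$W0), state$W1))
}

#' Fuse view embeddings by element-wise max pooling
#'
#' @param Z_views List of same-shape embedding matrices.
#' @return Matrix of the element-wise maxima.
#' @export
max_pool_views <- function(Z_views) {
  shapes <- vapply(Z_views, function(z) paste(dim(z), collapse = "x"), character(1))
  if (length(unique(shapes)) != 1) abort("view embeddings must share one shape")
  Reduce(pmax, Z_views)
}

#' Symmetric pair featurization
#'
#' A gene pair's feature vector is the concatenation of the element-wise
#' product `Z_u * Z_v` and the absolute difference `|Z_u - Z_v|`, so the
#' features (and hence any score built on them) are invariant to the order
#' of the two genes.
#'
#' @param Z N x K2 pooled embedding.
#' @param u,v Equal-length integer vectors of gene indices, `u[i] != v[i]`.
#' @return Matrix `length(u)` x `2*K2`.
#' @export
pair_features <- function(Z, u, v) {
  if (length(u) != length(v)) abort("u and v must have equal length")
  if (any(u == v)) abort("a pair must join two distinct genes")
  Zu <- Z[u, , drop = FALSE]
  Zv <- Z[v, , drop = FALSE]
  cbind(Zu * Zv, abs(Zu - Zv))
}

head_forward <- function(Feat, head, masks = NULL) {
  act <- list(Feat)
  n_hidden <- length(head) - 1L
  S <- vector("list", n_hidden)
  for (l in seq_len(n_hidden)) {
    S[[l]] <- sweep(act[[l]] %*% head[[l]]$W, 2, head[[l]]$b, `+`)
    A <- relu(S[[l]])
    if (!is.null(masks)) A <- A * masks[[l]]
    act[[l + 1L]] <- A
  }
  out <- head[[n_hidden + 1L]]
  logit <- drop(act[[n_hidden + 1L]] %*% out$W + out$b)
  list(p = stats::plogis(logit), act = act, S = S)
}

#' Score one gene pair's feature vector
#'
#' Runs the prediction head: three ReLU hidden layers then an affine map to
#' a single logit and a logistic squashing, so the output lies strictly in
#' (0, 1).
#'
#' @param features Numeric vector (or matrix of rows) of length `2*K2`.
#' @param state `"sl_model_state"`.
#' @return Probability vector.
#' @export
predict_pair <- function(features, state) {
  if (is.vector(features)) features <- matrix(features, nrow = 1)
  if (!all(is.finite(features))) abort("non-finite pair features")
  if (ncol(features) != nrow(state$head[[1]]$W)) {
    abort(sprintf("feature length %d does not match head input %d",
                  ncol(features), nrow(state$head[[1]]$W)))
  }
  head_forward(features, state$head)$p
}

#' Binary cross-entropy loss
#'
#' `L = -(1/M) * sum(y*log p + (1-y)*log(1-p))`. Probabilities at exactly 0
#' or 1 are clamped to `[eps, 1-eps]` (logged) before taking logs.
#'
#' @param p Predicted probabilities.
#' @param y 0/1 labels, same length.
#' @param eps Clamping guard, default 1e-7.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(p, y, eps = 1e-7) {
  if (length(p) != length(y)) abort("p and y must have equal length")
  if (any(p <= 0 | p >= 1)) {
    sl_log(sprintf("clamped %d probability value(s) to [eps, 1-eps]",
                   sum(p <= 0 | p >= 1)), "warn")
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Full forward + backward pass for a batch of pairs.
# uv: M x 2 integer matrix of gene indices. Returns loss, probabilities and
# gradients in the same shape as the state. Caches per-view pre-activations
# so ReLU and max-pool gradient routing is exact.
model_loss_grads <- function(A_hats, X, uv, y, state, masks = NULL) {
  n_views <- length(A_hats)
  N <- nrow(X)
  XW0 <- X %*% state$W0

  S1 <- H1 <- S2 <- Z <- vector("list", n_views)
  for (i in seq_len(n_views)) {
    S1[[i]] <- as.matrix(A_hats[[i]] %*% XW0)
    H1[[i]] <- relu(S1[[i]])
    S2[[i]] <- as.matrix(A_hats[[i]] %*% (H1[[i]] %*% state$W1))
    Z[[i]] <- relu(S2[[i]])
  }
  Zp <- Reduce(pmax, Z)
  K2 <- ncol(Zp)

  u <- uv[, 1]; v <- uv[, 2]
  Zu <- Zp[u, , drop = FALSE]
  Zv <- Zp[v, , drop = FALSE]
  Feat <- cbind(Zu * Zv, abs(Zu - Zv))

  hf <- head_forward(Feat, state$head, masks)
  p <- hf$p
  M <- length(y)
  loss <- bce_loss(p, y)
  if (!is.finite(loss)) abort("non-finite training loss")

  # ---- backward: head ----
  n_hidden <- length(state$head) - 1L
  dlogit <- matrix((p - y) / M, ncol = 1)
  out <- state$head[[n_hidden + 1L]]
  g_head <- vector("list", n_hidden + 1L)
  g_head[[n_hidden + 1L]] <- list(W = base::t(hf$act[[n_hidden + 1L]]) %*% dlogit,
                                  b = colSums(dlogit))
  dA <- dlogit %*% base::t(out$W)
  for (l in rev(seq_len(n_hidden))) {
    if (!is.null(masks)) dA <- dA * masks[[l]]
    dS <- dA * (hf$S[[l]] > 0)
    g_head[[l]] <- list(W = base::t(hf$act[[l]]) %*% dS, b = colSums(dS))
    dA <- dS %*% base::t(state$head[[l]]$W)
  }
  dFeat <- dA

  # ---- backward: pair featurization into the pooled embedding ----
  dProd <- dFeat[, seq_len(K2), drop = FALSE]
  dAbs <- dFeat[, K2 + seq_len(K2), drop = FALSE]
  sg <- sign(Zu - Zv)
  contrib <- rbind(dProd * Zv + dAbs * sg,
                   dProd * Zu - dAbs * sg)
  agg <- rowsum(contrib, group = c(u, v))
  dZp <- matrix(0, N, K2)
  dZp[as.integer(rownames(agg)), ] <- agg

  # ---- backward: max pooling routes to the first argmax view ----
  dW0 <- matrix(0, nrow(state$W0), ncol(state$W0))
  dW1 <- matrix(0, nrow(state$W1), ncol(state$W1))
  active <- matrix(TRUE, N, K2)
  for (i in seq_len(n_views)) {
    take <- active & (Z[[i]] == Zp)
    dZi <- dZp * take
    active <- active & !take
    dS2 <- dZi * (S2[[i]] > 0)
    AdS2 <- as.matrix(A_hats[[i]] %*% dS2)       # A symmetric
    dW1 <- dW1 + base::t(H1[[i]]) %*% AdS2
    dH1 <- AdS2 %*% base::t(state$W1)
    dS1 <- dH1 * (S1[[i]] > 0)
    dW0 <- dW0 + base::t(X) %*% as.matrix(A_hats[[i]] %*% dS1)
  }

  list(loss = loss, p = p,
       grads = list(W0 = dW0, W1 = dW1, head = g_head))
}

# Forward-only scores for a batch of pairs under a given state.
model_scores <- function(A_hats, X, uv, state) {
  Z <- max_pool_views(encode_views(A_hats, X, state))
  predict_pair(pair_features(Z, uv[, 1], uv[, 2]), state)
}
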