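relu <- function(x) pmax(x, 0)

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Graph isomorphism (GIN) layer
#'
#' Node update `x_v_new = phi((1 + epsilon) * x_v + sum_{u in N(v)} x_u)`,
#' where `phi` is a two-layer perceptron (affine, rectifier, affine). With
#' `W1 = NULL` the layer runs in test mode with `phi` the identity, which
#' reduces to `(A + (1 + epsilon) I) %*% features`.
#'
#' @param features `N x F` node feature matrix.
#' @param adjacency `N x N` binary symmetric adjacency.
#' @param params List with `epsilon` (scalar, default 0) and, unless
#'   `phi` is the identity, `W1` (`F x H`), `b1` (`H`), `W2` (`H x H`),
#'   `b2` (`H`).
#' @return `N x H` matrix (or `N x F` in identity mode).
#' @export
gin_layer <- function(features, adjacency, params = list(epsilon = 0)) {
  features <- as.matrix(features)
  adjacency <- as.matrix(adjacency)
  if (nrow(features) != nrow(adjacency) || nrow(adjacency) != ncol(adjacency)) {
    stop("dimension mismatch between features and adjacency")
  }
  eps <- if (is.null(params$epsilon)) 0 else params$epsilon
  agg <- (adjacency + (1 + eps) * diag(nrow(adjacency))) %*% features
  if (is.null(params$W1)) return(agg)
  h <- relu(sweep(agg %*% params$W1, 2, params$b1, "+"))
  sweep(h %*% params$W2, 2, params$b2, "+")
}

#' Graph attention (GAT) layer
#'
#' Transforms node features with `z_u = t(W) %*% x_u`, computes attention
#' logits `leaky_relu(a . (z_u || z_v))` over `u in N(v) + {v}` (the self
#' node participates in both the softmax normalization and the
#' aggregation sum), normalizes them with a per-node softmax and returns
#' `x_v_new = sum_u alpha[u,v] * z_u`. Attention entries for non-neighbors
#' are 0.
#'
#' @param features `N x Fin` node feature matrix.
#' @param adjacency `N x N` binary symmetric adjacency.
#' @param params List with `W` (`Fin x Dout`), `a` (length `2 * Dout`
#'   attention kernel), `leaky_slope` (default 0.2).
#' @param return_attention If `TRUE`, attach the `N x N` attention matrix
#'   (`alpha[u, v]`) as attribute `"attention"`.
#' @return `N x Dout` matrix.
#' @export
gat_layer <- function(features, adjacency, params, return_attention = FALSE) {
  features <- as.matrix(features)
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (nrow(features) != n || ncol(adjacency) != n) {
    stop("dimension mismatch between features and adjacency")
  }
  W <- as.matrix(params$W)
  if (nrow(W) != ncol(features)) stop("W rows must match feature dimension")
  dout <- ncol(W)
  a <- as.numeric(params$a)
  if (length(a) != 2L * dout) stop("attention kernel must have length 2 * output dim")
  slope <- if (is.null(params$leaky_slope)) 0.2 else params$leaky_slope

  z <- features %*% W
  s1 <- drop(z %*% a[seq_len(dout)])          # source term  a1 . z_u
  s2 <- drop(z %*% a[dout + seq_len(dout)])   # target term  a2 . z_v
  mask <- (adjacency > 0) | diag(n) > 0
  alpha <- matrix(0, n, n)
  for (v in seq_len(n)) {
    nb <- which(mask[, v])
    logits <- leaky_relu(s1[nb] + s2[v], slope)
    alpha[nb, v] <- softmax_vec(logits)
  }
  out <- t(alpha) %*% z
  if (return_attention) attr(out, "attention") <- alpha
  out
}

#' Graph convolutional (GCN) layer
#'
#' Symmetric-normalized convolution: with `A~ = A + I` and degree matrix
#' `D~`, returns `activation(D~^{-1/2} A~ D~^{-1/2} %*% features %*% W)`.
#' Used as the ablation replacing the GIN layer.
#'
#' @param features `N x Fin` node feature matrix.
#' @param adjacency `N x N` binary symmetric adjacency.
#' @param weight `Fin x Dout` weight matrix.
#' @param activation Elementwise activation function (default identity).
#' @return `N x Dout` matrix.
#' @export
gcn_layer <- function(features, adjacency, weight, activation = identity) {
  features <- as.matrix(features)
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (nrow(features) != n) stop("dimension mismatch between features and adjacency")
  weight <- as.matrix(weight)
  if (nrow(weight) != ncol(features)) stop("weight rows must match feature dimension")
  a_tilde <- adjacency + diag(n)
  dinv <- 1 / sqrt(rowSums(a_tilde))
  a_norm <- a_tilde * outer(dinv, dinv)
  activation(a_norm %*% features %*% weight)
}

#' Attention-based graph readout
#'
#' Graph-level pooling `x_G = sum_v softmax_v(gate(x_v)) * x_v`, where the
#' gate is an affine map of each node's features to a scalar score and the
#' softmax runs over nodes.
#'
#' @param node_features `N x D` matrix.
#' @param params List with `w` (length `D` gate weights) and `b` (scalar
#'   gate bias).
#' @param return_weights If `TRUE`, attach the length-`N` softmax weights
#'   as attribute `"weights"`.
#' @return Length-`D` numeric vector.
#' @export
attention_readout <- function(node_features, params, return_weights = FALSE) {
  node_features <- as.matrix(node_features)
  if (nrow(node_features) == 0L) stop("empty graph: no nodes to pool")
  g <- drop(node_features %*% as.numeric(params$w)) + params$b
  beta <- softmax_vec(g)
  out <- drop(crossprod(node_features, beta))
  if (return_weights) attr(out, "weights") <- beta
  out
}

#' Sum-pooling graph readout
#'
#' Columnwise sum of node features; the simpler aggregation used in the
#' readout ablation.
#'
#' @param node_features `N x D` matrix.
#' @return Length-`D` numeric vector.
#' @export
sum_readout <- function(node_features) {
  node_features <- as.matrix(node_features)
  if (nrow(node_features) == 0L) stop("empty graph: no nodes to pool")
  colSums(node_features)
}
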