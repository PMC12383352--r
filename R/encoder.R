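#' @keywords internal
variant_spec <- function(variant, n_nodes) {
  variants <- c("baseline", "sum_pool", "gin_only", "gcn_variant", "gat_only")
  variant <- match.arg(variant, variants)
  use_gin <- variant %in% c("baseline", "sum_pool", "gin_only")
  use_gcn <- variant == "gcn_variant"
  use_gat <- variant %in% c("baseline", "sum_pool", "gcn_variant", "gat_only")
  readout <- if (variant == "sum_pool") "sum" else "attention"
  gat_in <- if (use_gin || use_gcn) 128L else n_nodes
  d_embed <- if (use_gat) 64L else 128L
  list(variant = variant, use_gin = use_gin, use_gcn = use_gcn,
       use_gat = use_gat, readout = readout, gat_in = gat_in,
       d_embed = d_embed)
}

init_mat <- function(nr, nc, fan_in) {
  matrix(runif(nr * nc, -1, 1) / sqrt(fan_in), nr, nc)
}

init_vec <- function(len, fan_in) runif(len, -1, 1) / sqrt(fan_in)

#' Initialize a graph encoder model
#'
#' Builds the parameter set for one architectural variant of the
#' connectome encoder. The baseline composes a GIN layer (128-d output,
#' two-layer perceptron update, rectifier after the layer), a
#' single-head GAT layer (64-d output, leaky slope 0.2) and an
#' attention-based readout, giving 64-d graph embeddings; a two-layer
#' perceptron head (hidden 32, softmax over 2 classes) is attached for
#' supervised training. Ablation variants replace the readout with
#' sum-pooling (`sum_pool`), drop the GAT (`gin_only`, 128-d embeddings),
#' replace GIN with a GCN (`gcn_variant`) or drop the GIN (`gat_only`).
#'
#' Parameters are drawn uniformly with fan-in scaling,
#' `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`, from the current RNG state
#' (seed with `set.seed()` for reproducibility). The GIN `epsilon` is
#' fixed at 0 and not trained.
#'
#' @param variant One of `"baseline"`, `"sum_pool"`, `"gin_only"`,
#'   `"gcn_variant"`, `"gat_only"`.
#' @param n_nodes Number of graph nodes (also the one-hot feature
#'   dimension).
#' @param epsilon GIN self-weight offset (default 0).
#' @return An object of class `encoder_model`.
#' @export
encoder_init <- function(variant = "baseline", n_nodes, epsilon = 0) {
  sp <- variant_spec(variant, n_nodes)
  params <- list()
  if (sp$use_gin) {
    params$gin_W1 <- init_mat(n_nodes, 128L, n_nodes)
    params$gin_b1 <- init_vec(128L, n_nodes)
    params$gin_W2 <- init_mat(128L, 128L, 128L)
    params$gin_b2 <- init_vec(128L, 128L)
  }
  if (sp$use_gcn) {
    params$gcn_W <- init_mat(n_nodes, 128L, n_nodes)
  }
  if (sp$use_gat) {
    params$gat_W <- init_mat(sp$gat_in, 64L, sp$gat_in)
    params$gat_a <- init_vec(128L, 64L)
  }
  if (sp$readout == "attention") {
    params$ro_w <- init_vec(sp$d_embed, sp$d_embed)
    params$ro_b <- init_vec(1L, sp$d_embed)
  }
  params$h_W1 <- init_mat(sp$d_embed, 32L, sp$d_embed)
  params$h_b1 <- init_vec(32L, sp$d_embed)
  params$h_W2 <- init_mat(32L, 2L, 32L)
  params$h_b2 <- init_vec(2L, 32L)
  structure(
    list(variant = sp$variant, n_nodes = as.integer(n_nodes),
         d_embed = sp$d_embed, epsilon = epsilon, leaky_slope = 0.2,
         params = params, spec = sp, train_info = NULL),
    class = "encoder_model"
  )
}

#' @export
print.encoder_model <- function(x, ...) {
  cat(sprintf("<encoder_model> variant %s: %d nodes -> %d-d embedding%s\n",
              x$variant, x$n_nodes, x$d_embed,
              if (is.null(x$train_info)) " (untrained)" else " (trained)"))
  invisible(x)
}

#' Embed one binarized graph
#'
#' Reference composition of the encoder variant's layers and readout,
#' producing the graph-level embedding used for manifold analysis: for
#' the baseline, `GIN(128) -> rectifier -> GAT(64) -> attention readout`
#' (64-d output). This pure-R path mirrors the compiled training path
#' exactly and accepts arbitrary node features.
#'
#' @param graph A [binarize()]d graph (or any list with `adjacency` and
#'   `features`).
#' @param model An [encoder_init()] model whose node count matches.
#' @return Length-`D` embedding vector.
#' @export
embed_graph <- function(graph, model) {
  adj <- as.matrix(graph$adjacency)
  x <- as.matrix(graph$features)
  if (nrow(adj) != model$n_nodes) {
    stop("graph has ", nrow(adj), " nodes but model expects ", model$n_nodes)
  }
  p <- model$params
  sp <- model$spec
  h <- x
  if (sp$use_gin) {
    h <- relu(gin_layer(h, adj, list(epsilon = model$epsilon,
                                     W1 = p$gin_W1, b1 = p$gin_b1,
                                     W2 = p$gin_W2, b2 = p$gin_b2)))
  }
  if (sp$use_gcn) {
    h <- gcn_layer(h, adj, p$gcn_W, activation = relu)
  }
  if (sp$use_gat) {
    h <- gat_layer(h, adj, list(W = p$gat_W, a = p$gat_a,
                                leaky_slope = model$leaky_slope))
  }
  if (sp$readout == "attention") {
    attention_readout(h, list(w = p$ro_w, b = p$ro_b))
  } else {
    sum_readout(h)
  }
}

# flags list handed to the compiled path
encoder_flags <- function(model) {
  sp <- model$spec
  list(use_gin = sp$use_gin, use_gcn = sp$use_gcn, use_gat = sp$use_gat,
       att_readout = sp$readout == "attention",
       eps = model$epsilon, leaky = model$leaky_slope)
}
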