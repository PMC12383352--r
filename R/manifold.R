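embedding_matrix <- function(embeddings) {
  if (inherits(embeddings, "embedding_set")) embeddings$embeddings
  else as.matrix(embeddings)
}

#' Fit the PCA progression manifold
#'
#' Centers the embeddings and computes the principal axes of their
#' covariance (1/(n-1) normalization). The fitted model is reusable on
#' unseen samples without refitting. Signs are fixed deterministically:
#' PC1 is oriented so that the anchor group's mean projection is
#' nonnegative (the late-stage group by default, so disease progression
#' runs left to right); every other component has its largest-magnitude
#' loading positive.
#'
#' @param embeddings An `embedding_set` or an `n x D` matrix.
#' @param k Number of components to retain (default 2).
#' @param anchor_label Group whose PC1 mean is oriented positive; used
#'   only when labels are available.
#' @param labels Optional labels when `embeddings` is a plain matrix.
#' @return An object of class `manifold_model` with fields `mean`,
#'   `components` (`k x D`, row-orthonormal), `explained_variance_ratios`
#'   (length `k`), `full_spectrum` (length `D`, sums to 1), `k`,
#'   `anchor_label`.
#' @export
fit_pca <- function(embeddings, k = 2L, anchor_label = "G2", labels = NULL) {
  x <- embedding_matrix(embeddings)
  if (inherits(embeddings, "embedding_set") && is.null(labels)) {
    labels <- embeddings$labels
  }
  n <- nrow(x); d <- ncol(x)
  if (n < 2L) stop("need at least 2 samples to fit the manifold")
  if (k > min(n - 1L, d)) {
    stop("k = ", k, " exceeds the maximal rank min(n-1, D) = ", min(n - 1L, d))
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  spectrum <- c(eig, rep(0, d - length(eig)))[seq_len(d)]
  ratios <- spectrum / sum(spectrum)
  comps <- t(pc$rotation[, seq_len(k), drop = FALSE])
  center <- pc$center

  for (j in seq_len(k)) {
    flip <- FALSE
    if (j == 1L && !is.null(labels) && anchor_label %in% labels) {
      sc <- (x[labels == anchor_label, , drop = FALSE] -
               matrix(center, sum(labels == anchor_label), d, byrow = TRUE)) %*%
        comps[1, ]
      flip <- mean(sc) < 0
    } else {
      flip <- comps[j, which.max(abs(comps[j, ]))] < 0
    }
    if (flip) comps[j, ] <- -comps[j, ]
  }
  structure(list(mean = center, components = comps,
                 explained_variance_ratios = ratios[seq_len(k)],
                 full_spectrum = ratios, k = k, anchor_label = anchor_label),
            class = "manifold_model")
}

#' @export
print.manifold_model <- function(x, ...) {
  cat(sprintf("<manifold_model> %d components over %d dims; explained: %s\n",
              x$k, length(x$mean),
              paste(sprintf("%.1f%%", 100 * x$explained_variance_ratios),
                    collapse = ", ")))
  invisible(x)
}

#' Project embeddings onto a fitted manifold
#'
#' Computes `(x - mean) %*% t(components)`. Projections of the fitting
#' set have zero mean per axis.
#'
#' @param model A [fit_pca()] model.
#' @param embeddings An `embedding_set`, matrix, or single vector with
#'   dimension matching the model.
#' @return `n x k` coordinate matrix with columns `PC1..PCk`; when an
#'   `embedding_set` is supplied, subject ids become row names.
#' @export
project <- function(model, embeddings) {
  x <- if (!inherits(embeddings, "embedding_set") && is.null(dim(embeddings))) {
    matrix(embeddings, nrow = 1)
  } else {
    embedding_matrix(embeddings)
  }
  if (ncol(x) != length(model$mean)) {
    stop("embedding dimension ", ncol(x), " does not match manifold (",
         length(model$mean), ")")
  }
  coords <- sweep(x, 2, model$mean) %*% t(model$components)
  colnames(coords) <- paste0("PC", seq_len(model$k))
  if (inherits(embeddings, "embedding_set")) {
    rownames(coords) <- embeddings$subject_ids
  }
  coords
}

#' Intrinsic dimensionality at a variance threshold
#'
#' Smallest number of principal components whose cumulative explained
#' variance reaches `variance_threshold`. Used to contrast the compact
#' manifold of trained connectome embeddings with the higher-dimensional
#' spread of sparsity-matched random networks.
#'
#' @param embeddings An `embedding_set` or matrix, `n >= 2`.
#' @param variance_threshold Threshold in `(0, 1]` (default 0.99).
#' @return Integer dimensionality.
#' @export
intrinsic_dim <- function(embeddings, variance_threshold = 0.99) {
  if (variance_threshold <= 0 || variance_threshold > 1) {
    stop("variance_threshold must lie in (0, 1]")
  }
  x <- embedding_matrix(embeddings)
  if (nrow(x) < 2L) stop("need at least 2 samples")
  eig <- prcomp(x, center = TRUE, scale. = FALSE)$sdev^2
  ratios <- eig / sum(eig)
  as.integer(which(cumsum(ratios) >= variance_threshold - 1e-12)[1])
}
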