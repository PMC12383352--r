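#' Training configuration
#'
#' Hyperparameters for the supervised encoder+head training stage:
#' Adam-type adaptive gradient optimization of the softmax cross-entropy
#' on a binary stage-discrimination task, full batch (the cohorts are
#' small), fully determined by `seed`.
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param weight_decay L2 weight decay added to the gradient
#'   (default 0.001).
#' @param epochs Number of full-batch epochs (default 100).
#' @param seed Integer seed for parameter initialization.
#' @param class_pair Ordered pair of group labels `(positive, negative)`
#'   defining the task, e.g. `c("G2", "G0")`; `NULL` infers the positive
#'   class as the later stage present in the data.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, weight_decay = 0.001,
                         epochs = 100L, seed = 0L, class_pair = NULL) {
  if (learning_rate <= 0 || epochs < 1) {
    stop("learning_rate and epochs must be positive")
  }
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 class_pair = class_pair),
            class = "train_config")
}

graph_labels <- function(graphs, labels = NULL) {
  if (is.null(labels)) {
    labels <- vapply(graphs, function(g) g$group, character(1))
  }
  as.character(labels)
}

binary_targets <- function(labels, class_pair = NULL) {
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("need exactly two classes, got ", length(classes))
  }
  if (length(classes) > 2L) {
    stop("need exactly two classes, got ", length(classes), ": ",
         paste(classes, collapse = ", "))
  }
  positive <- if (!is.null(class_pair)) {
    if (!all(class_pair %in% classes)) {
      stop("class_pair ", paste(class_pair, collapse = "/"),
           " not found among labels ", paste(classes, collapse = "/"))
    }
    class_pair[1]
  } else {
    classes[2]  # later stage label sorts last (G2 > G0)
  }
  list(y = as.integer(labels == positive), positive = positive)
}

#' Train the encoder + MLP head on a binary staging task
#'
#' Jointly optimizes the graph encoder and its two-layer softmax head by
#' full-batch Adam on the cross-entropy, for `config$epochs` epochs. The
#' run is fully determined by `config$seed` (parameter initialization;
#' the optimization itself is deterministic).
#'
#' @param graphs List of [binarize()]d graphs, all with the same node
#'   count, covering exactly two classes.
#' @param labels Optional label vector (defaults to the graphs' `group`).
#' @param config A [train_config()].
#' @param variant Encoder variant, see [encoder_init()].
#' @return A trained `encoder_model`; `$train_info` holds the loss
#'   history, the positive class and the config.
#' @export
train_classifier <- function(graphs, labels = NULL, config = train_config(),
                             variant = "baseline") {
  if (length(graphs) == 0L) stop("empty dataset")
  labels <- graph_labels(graphs, labels)
  tgt <- binary_targets(labels, config$class_pair)
  ns <- vapply(graphs, function(g) nrow(g$adjacency), integer(1))
  if (length(unique(ns)) > 1L) stop("graphs have inconsistent node counts")
  set.seed(config$seed)
  model <- encoder_init(variant, n_nodes = ns[1])
  fit <- cpp_train_encoder(lapply(graphs, `[[`, "adjacency"),
                           tgt$y, model$params, encoder_flags(model),
                           config$learning_rate, config$weight_decay,
                           config$epochs)
  model$params <- fit$params
  model$train_info <- list(loss_history = as.numeric(fit$loss_history),
                           positive_class = tgt$positive,
                           config = config, variant = variant)
  model
}

#' Class probabilities for a set of graphs
#'
#' @param model A trained `encoder_model`.
#' @param graphs List of binarized graphs.
#' @return `n x 2` matrix of softmax probabilities; column 2 is the
#'   positive class of the training task.
#' @export
predict_probs <- function(model, graphs) {
  ns <- vapply(graphs, function(g) nrow(g$adjacency), integer(1))
  if (any(ns != model$n_nodes)) {
    stop("graph node count does not match model (", model$n_nodes, ")")
  }
  p <- cpp_predict_probs(lapply(graphs, `[[`, "adjacency"),
                         model$params, encoder_flags(model))
  colnames(p) <- c("negative", "positive")
  p
}

#' Extract graph embeddings for a dataset
#'
#' Runs every graph through the encoder (head discarded) and collects the
#' D-dimensional readout vectors, preserving input order.
#'
#' @param graphs List of binarized graphs with a common node count.
#' @param model An `encoder_model` (typically trained).
#' @return An `embedding_set`: list with `embeddings` (`n x D` matrix),
#'   `subject_ids`, `labels`.
#' @export
embed_dataset <- function(graphs, model) {
  if (length(graphs) == 0L) stop("empty dataset")
  ns <- vapply(graphs, function(g) nrow(g$adjacency), integer(1))
  if (length(unique(ns)) > 1L || ns[1] != model$n_nodes) {
    stop("graphs must all match the model's node count (", model$n_nodes, ")")
  }
  emb <- cpp_embed_dataset(lapply(graphs, `[[`, "adjacency"),
                           model$params, encoder_flags(model))
  ids <- vapply(graphs, function(g) g$subject_id %||% "", character(1))
  rownames(emb) <- ids
  structure(list(embeddings = emb,
                 subject_ids = ids,
                 labels = vapply(graphs, function(g) g$group %||% NA_character_,
                                 character(1))),
            class = "embedding_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("<embedding_set> %d subjects x %d dimensions\n",
              nrow(x$embeddings), ncol(x$embeddings)))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimate: the probability that a random
#' positive is scored above a random negative, counting ties as one half.
#'
#' @param labels Binary labels (logical, or 0/1).
#' @param scores Numeric scores, higher meaning more positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary (0/1 or logical)")
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  r <- rank(scores)  # average ranks handle ties
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Leave-one-out cross-validated ROC-AUC
#'
#' For each of `n_runs` runs (seed `config$seed + run - 1`), every sample
#' is held out once, the model is retrained from scratch on the
#' remainder, and the held-out positive-class probability is recorded;
#' the run's pooled scores give one ROC-AUC. Pooling is used because a
#' per-fold AUC is undefined with a single test sample.
#'
#' @param graphs List of binarized graphs covering exactly two classes.
#' @param labels Optional label vector (defaults to the graphs' groups).
#' @param config A [train_config()].
#' @param n_runs Number of independent runs (default 10).
#' @param variant Encoder variant.
#' @return List with `mean`, `sd` and `runs` (per-run AUCs).
#' @export
loocv_auc <- function(graphs, labels = NULL, config = train_config(),
                      n_runs = 10L, variant = "baseline") {
  labels <- graph_labels(graphs, labels)
  tgt <- binary_targets(labels, config$class_pair)
  if (min(table(tgt$y)) < 2L) {
    stop("need at least two samples per class for leave-one-out folds")
  }
  n <- length(graphs)
  adjs <- lapply(graphs, `[[`, "adjacency")
  n_nodes <- nrow(adjs[[1]])
  aucs <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- config$seed + r - 1L
    scores <- numeric(n)
    for (i in seq_len(n)) {
      set.seed(run_seed)
      model <- encoder_init(variant, n_nodes = n_nodes)
      flags <- encoder_flags(model)
      fit <- cpp_train_encoder(adjs[-i], tgt$y[-i], model$params, flags,
                               config$learning_rate, config$weight_decay,
                               config$epochs)
      scores[i] <- cpp_predict_probs(adjs[i], fit$params, flags)[1, 2]
    }
    aucs[r] <- roc_auc(tgt$y, scores)
  }
  list(mean = mean(aucs), sd = stats::sd(aucs), runs = aucs)
}

#' Architectural ablation grid
#'
#' Evaluates encoder variants on the late-versus-intermediate and
#' late-versus-early staging tasks by pooled leave-one-out ROC-AUC.
#'
#' @param graphs List of binarized graphs covering the three stages.
#' @param labels Optional label vector.
#' @param config A [train_config()]; its `class_pair` is overridden per
#'   task.
#' @param variants Character vector of encoder variants to evaluate.
#' @param tasks List of ordered class pairs `(positive, negative)`.
#' @param n_runs Runs per cell (default 10).
#' @return Data frame with columns `variant`, `task`, `auc_mean`,
#'   `auc_sd`.
#' @export
run_ablation <- function(graphs, labels = NULL, config = train_config(),
                         variants = c("baseline", "sum_pool", "gin_only",
                                      "gcn_variant", "gat_only"),
                         tasks = list(c("G2", "G1"), c("G2", "G0")),
                         n_runs = 10L) {
  labels <- graph_labels(graphs, labels)
  needed <- unique(unlist(tasks))
  missing <- setdiff(needed, unique(labels))
  if (length(missing)) stop("missing group(s): ", paste(missing, collapse = ", "))
  rows <- list()
  for (variant in variants) {
    for (task in tasks) {
      keep <- labels %in% task
      cfg <- config
      cfg$class_pair <- task
      res <- loocv_auc(graphs[keep], labels[keep], cfg, n_runs = n_runs,
                       variant = variant)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = variant, task = paste(task, collapse = "/"),
        auc_mean = res$mean, auc_sd = res$sd, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
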