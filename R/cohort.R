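#' Fit per-group Gaussian cohort regions on PC1
#'
#' Fits a univariate Gaussian (sample mean and 1/(n-1) standard
#' deviation) to each group's first-principal-component values and
#' defines the group's cohort region as the one-standard-deviation band
#' `[mu - sigma, mu + sigma]`.
#'
#' @param pc1_values Numeric vector of PC1 coordinates.
#' @param groups Group label per value.
#' @return An object of class `cohort_model`: data frame with columns
#'   `group`, `mu`, `sigma`, `lower`, `upper`, one row per group in
#'   stage order.
#' @export
fit_group_gaussians <- function(pc1_values, groups) {
  groups <- as.character(groups)
  stopifnot(length(pc1_values) == length(groups))
  glev <- intersect(stage_labels(), unique(groups))
  if (length(glev) == 0L) glev <- sort(unique(groups))
  rows <- lapply(glev, function(g) {
    v <- pc1_values[groups == g]
    if (length(v) < 2L) stop("group ", g, " has fewer than 2 values")
    s <- sd(v)
    if (s == 0) stop("group ", g, " has zero variance")
    data.frame(group = g, mu = mean(v), sigma = s,
               lower = mean(v) - s, upper = mean(v) + s,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("cohort_model", "data.frame"))
}

#' @export
print.cohort_model <- function(x, ...) {
  cat("<cohort_model> per-group PC1 Gaussians:\n")
  print.data.frame(x)
  invisible(x)
}

#' Manifold-defined cohort membership
#'
#' A subject belongs to a group's cohort iff its PC1 coordinate falls in
#' that group's one-standard-deviation band. A subject may fall in
#' several cohorts, or in none; membership is reported as-is.
#'
#' @param model A [fit_group_gaussians()] model.
#' @param pc1_values Numeric PC1 coordinates.
#' @param ids Subject identifiers (defaults to the value indices).
#' @return Named list, one character vector of member ids per group.
#' @export
cohort_membership <- function(model, pc1_values, ids = NULL) {
  if (is.null(ids)) ids <- as.character(seq_along(pc1_values))
  out <- lapply(seq_len(nrow(model)), function(i) {
    ids[pc1_values >= model$lower[i] & pc1_values <= model$upper[i]]
  })
  names(out) <- model$group
  out
}

#' Naive Bayes stage assignment on PC1
#'
#' Assigns each PC1 value to the group with the highest Gaussian density
#' under equal priors (the held-out group's size should not influence
#' staging). Ties are broken toward the earlier stage (lower group
#' index). When `source_group` is given, the percentage of values
#' assigned to each group is reported to two decimals — the staging
#' fractions for a projected held-out cohort.
#'
#' @param model A [fit_group_gaussians()] model.
#' @param pc1_values Numeric PC1 coordinates to stage.
#' @param source_group Optional label naming the cohort the values come
#'   from (only used to annotate the output).
#' @return List with `labels` (assigned group per value) and `fractions`
#'   (named percentages summing to 100 up to rounding; `NULL` when
#'   `source_group` is `NULL`).
#' @export
naive_bayes_assign <- function(model, pc1_values, source_group = NULL) {
  dens <- vapply(seq_len(nrow(model)),
                 function(i) dnorm(pc1_values, model$mu[i], model$sigma[i]),
                 numeric(length(pc1_values)))
  dens <- matrix(dens, nrow = length(pc1_values))
  pick <- apply(dens, 1, which.max)  # which.max takes the first (lower) index on ties
  labels <- model$group[pick]
  fractions <- NULL
  if (!is.null(source_group)) {
    fractions <- round(100 * vapply(model$group,
                                    function(g) mean(labels == g), numeric(1)), 2)
    names(fractions) <- model$group
  }
  list(labels = labels, fractions = fractions, source_group = source_group)
}

#' Permutation test of manifold separability
#'
#' Observed statistic: macro one-vs-rest ROC-AUC of a multinomial
#' logistic model fit and evaluated on the 2-D manifold coordinates (the
#' identical in-sample procedure is applied to every label permutation,
#' so the test is exchangeable and valid). The p-value uses the plus-one
#' estimator `p = (1 + #(null >= observed)) / (1 + n_permutations)` and
#' therefore never returns 0.
#'
#' @param coordinates `n x 2` coordinate matrix.
#' @param labels Class label per row (2 or more classes, at least 2 each).
#' @param n_permutations Number of label shuffles (default 10000).
#' @param seed RNG seed.
#' @return List with `observed`, `p_value`, `n_permutations`, `seed`.
#' @export
permutation_test_separability <- function(coordinates, labels,
                                          n_permutations = 10000L,
                                          seed = 0L) {
  coordinates <- as.matrix(coordinates)
  labels <- as.character(labels)
  if (n_permutations < 1L) stop("n_permutations must be at least 1")
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least two classes")
  if (min(table(labels)) < 2L) stop("need at least two samples per class")
  y <- as.integer(factor(labels, levels = classes)) - 1L
  set.seed(seed)
  res <- cpp_permtest(coordinates, y, length(classes),
                      as.integer(n_permutations), 1e-4, 50L)
  obs <- res$observed
  pval <- (1 + sum(res$null >= obs)) / (1 + n_permutations)
  list(observed = obs, p_value = pval,
       n_permutations = as.integer(n_permutations), seed = as.integer(seed))
}

# in-sample macro one-vs-rest AUC of the multinomial logistic classifier
# (the observed statistic of the permutation test, exposed for reuse)
multiclass_logit_auc <- function(coordinates, labels) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  y <- as.integer(factor(labels, levels = classes)) - 1L
  cpp_multinom_macro_auc(as.matrix(coordinates), y, length(classes), 1e-4, 50L)
}
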