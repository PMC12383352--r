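#' Build the normative edge-weight template from a reference cohort
#'
#' For every unordered region pair, fits a Gaussian to the edge weights
#' across the reference subjects (sample mean and 1/(n-1) SD). Standard
#' deviations are floored at `sigma_floor` so that zero-variance edges
#' (e.g. absent in every reference subject) cannot produce infinite
#' divergence scores. Weighted (not binarized) connectomes are used.
#'
#' @param reference List of at least two [connectome()]s, the normative
#'   cohort (typically the manifold-defined early-stage cohort).
#' @param sigma_floor SD floor; default `1e-6` times the global mean
#'   positive weight of the reference.
#' @return An object of class `divergence_template`: list with `mu` and
#'   `sigma` (`N x N` symmetric matrices), `n_ref`, `sigma_floor`,
#'   `region_labels`.
#' @export
build_template <- function(reference, sigma_floor = NULL) {
  if (length(reference) < 2L) stop("need at least 2 reference subjects")
  ws <- lapply(reference, `[[`, "weights")
  n <- nrow(ws[[1]])
  if (any(vapply(ws, nrow, integer(1)) != n)) {
    stop("reference connectomes have inconsistent node counts")
  }
  arr <- array(unlist(ws), dim = c(n, n, length(ws)))
  mu <- apply(arr, c(1, 2), mean)
  sigma <- apply(arr, c(1, 2), sd)
  if (is.null(sigma_floor)) {
    pos <- unlist(lapply(ws, function(w) w[w > 0]))
    sigma_floor <- 1e-6 * mean(pos)
  }
  if (sigma_floor <= 0) stop("sigma_floor must be positive")
  sigma <- pmax(sigma, sigma_floor)
  structure(list(mu = mu, sigma = sigma, n_ref = length(reference),
                 sigma_floor = sigma_floor,
                 region_labels = reference[[1]]$region_labels),
            class = "divergence_template")
}

#' @export
print.divergence_template <- function(x, ...) {
  cat(sprintf("<divergence_template> %d regions, %d reference subjects\n",
              nrow(x$mu), x$n_ref))
  invisible(x)
}

#' Per-edge deviation probabilities against the template
#'
#' For each edge, the two-sided Gaussian tail probability that the
#' subject's weight deviates at least as far from the template mean:
#' `p_e = 2 * (1 - Phi(|w_e - mu_e| / sigma_e))`, clipped to
#' `[p_floor, 1]`. A weight exactly at the template mean gives `p = 1`.
#'
#' @param subject A [connectome()] with the template's node count.
#' @param template A [build_template()] result.
#' @param p_floor Lower clip for probabilities (default `1e-12`).
#' @return `N x N` symmetric matrix of probabilities (diagonal 1).
#' @export
edge_deviation_probs <- function(subject, template, p_floor = 1e-12) {
  w <- subject$weights
  if (nrow(w) != nrow(template$mu)) {
    stop("subject has ", nrow(w), " regions but template has ",
         nrow(template$mu))
  }
  z <- abs(w - template$mu) / template$sigma
  p <- 2 * pnorm(z, lower.tail = FALSE)
  p <- pmin(pmax(p, p_floor), 1)
  diag(p) <- 1
  p
}

#' Regional divergence scores by logarithmic accumulation
#'
#' Accumulates edge-wise evidence of deviation into a composite score per
#' region: `S_r = -sum over edges incident to r of log(p_e)` (Fisher-style
#' evidence accumulation; each edge contributes to both endpoints).
#' Scores are nonnegative and zero only when every incident edge sits at
#' the template mean.
#'
#' @param edge_probs `N x N` symmetric matrix from
#'   [edge_deviation_probs()].
#' @param n_nodes Number of regions (defaults to `nrow(edge_probs)`).
#' @param mode `"sum"` (default), `"mean"` (degree-normalized mean of
#'   `-log p` over incident edges).
#' @return Numeric vector of length `n_nodes`.
#' @export
region_scores <- function(edge_probs, n_nodes = nrow(edge_probs),
                          mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  lp <- -log(edge_probs)
  diag(lp) <- 0
  s <- rowSums(lp)
  if (mode == "mean") s <- s / (n_nodes - 1L)
  s[seq_len(n_nodes)]
}

#' Group-level regional divergence map
#'
#' Scores every subject against the normative template and aggregates
#' per-region group means — the tabular analogue of cortical-surface
#' divergence maps.
#'
#' @param subjects List of [connectome()]s to compare.
#' @param template A [build_template()] result.
#' @param assignments Group label per subject (defaults to each
#'   connectome's `group`).
#' @param p_floor Probability floor, see [edge_deviation_probs()].
#' @return An object of class `region_score_table`: list with
#'   `subject_scores` (one row per subject x region) and `group_means`
#'   (per group, sorted by descending mean score).
#' @export
group_divergence_map <- function(subjects, template, assignments = NULL,
                                 p_floor = 1e-12) {
  if (length(subjects) == 0L) stop("empty cohort")
  if (is.null(assignments)) {
    assignments <- vapply(subjects, function(s) s$group, character(1))
  }
  n <- nrow(template$mu)
  labels <- template$region_labels
  rows <- lapply(seq_along(subjects), function(i) {
    s <- region_scores(edge_deviation_probs(subjects[[i]], template, p_floor))
    data.frame(subject_id = subjects[[i]]$subject_id,
               group = assignments[i],
               region_index = seq_len(n) - 1L,
               region_label = labels,
               score = s, stringsAsFactors = FALSE)
  })
  subject_scores <- do.call(rbind, rows)
  agg <- stats::aggregate(score ~ group + region_index + region_label,
                          data = subject_scores, FUN = mean)
  agg <- agg[order(agg$group, -agg$score), ]
  names(agg)[names(agg) == "score"] <- "mean_score"
  rownames(agg) <- NULL
  structure(list(subject_scores = subject_scores, group_means = agg),
            class = "region_score_table")
}

#' @export
print.region_score_table <- function(x, ...) {
  cat("<region_score_table> top regions by group mean score:\n")
  print.data.frame(head(x$group_means, 10))
  invisible(x)
}
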