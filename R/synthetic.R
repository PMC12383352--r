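#' Synthetic cohort configuration
#'
#' Describes the generative model for a three-group cohort of synthetic
#' structural connectomes with a planted progression axis. Groups share a
#' population skeleton; edges incident to a designated vulnerable region
#' set are progressively attenuated and removed along a per-subject
#' progression score `t`, so that binarized topology differs by stage.
#'
#' Defaults mirror the clinical cohort the generator stands in for:
#' group sizes 24/46/18 (`G0`/`G1`/`G2`), 148 cortical regions.
#'
#' @param n_per_group Integer vector of three group sizes (G0, G1, G2).
#' @param n_nodes Number of regions.
#' @param base_density Skeleton edge probability in (0,1).
#' @param n_vulnerable_regions Size of the vulnerable region set (the
#'   first `n_vulnerable_regions` node indices).
#' @param group_progression_means Mean progression score per group.
#' @param progression_sd SD of the per-subject progression score (scores
#'   are clipped to `[0,1]`).
#' @param attenuation_strength Attenuation coefficient `beta` in `[0,1]`:
#'   vulnerable edge weights are scaled by `1 - beta * t`.
#' @param weight_noise_cv Coefficient of variation of multiplicative
#'   subject-level edge noise.
#' @param dropout_cutoff Fraction of the base-weight scale (mean skeleton
#'   base weight) below which a subject's edge weight is set to exactly 0.
#' @param base_weight_sdlog sdlog of the log-normal skeleton base weights
#'   (meanlog 0); heavy-tailed like streamline counts.
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(24L, 46L, 18L),
                          n_nodes = 148L,
                          base_density = 0.30,
                          n_vulnerable_regions = 12L,
                          group_progression_means = c(0.0, 0.5, 1.0),
                          progression_sd = 0.15,
                          attenuation_strength = 0.6,
                          weight_noise_cv = 0.2,
                          dropout_cutoff = 0.05,
                          base_weight_sdlog = 1.5,
                          seed = 0L) {
  cfg <- list(n_per_group = as.integer(n_per_group),
              n_nodes = as.integer(n_nodes),
              base_density = base_density,
              n_vulnerable_regions = as.integer(n_vulnerable_regions),
              group_progression_means = group_progression_means,
              progression_sd = progression_sd,
              attenuation_strength = attenuation_strength,
              weight_noise_cv = weight_noise_cv,
              dropout_cutoff = dropout_cutoff,
              base_weight_sdlog = base_weight_sdlog,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(length(cfg$n_per_group) == 3L, all(cfg$n_per_group >= 1L))
  if (cfg$base_density <= 0 || cfg$base_density >= 1) {
    stop("base_density must be in (0,1)")
  }
  if (cfg$attenuation_strength < 0 || cfg$attenuation_strength > 1) {
    stop("attenuation_strength must be in [0,1]")
  }
  if (cfg$n_vulnerable_regions >= cfg$n_nodes) {
    stop("n_vulnerable_regions must be smaller than n_nodes")
  }
  if (cfg$progression_sd < 0 || cfg$weight_noise_cv < 0 || cfg$dropout_cutoff < 0) {
    stop("progression_sd, weight_noise_cv and dropout_cutoff must be nonnegative")
  }
  invisible(cfg)
}

#' Generate a synthetic three-group cohort of connectomes
#'
#' Fully seeded generative model:
#' \enumerate{
#'   \item one population skeleton: undirected graph on `n_nodes` with
#'     edge probability `base_density`, log-normal base weights `W0`
#'     (meanlog 0, sdlog `base_weight_sdlog`) per skeleton edge;
#'   \item vulnerable set = the first `n_vulnerable_regions` node indices;
#'     an edge is vulnerable iff either endpoint is vulnerable;
#'   \item per subject, progression `t ~ Normal(group mean, progression_sd)`
#'     clipped to `[0,1]`;
#'   \item subject edge weight
#'     `W0_e * (1 - beta*t if vulnerable else 1) * (1 + cv*z_e)`, floored
#'     at 0, with `z_e ~ Normal(0,1)` drawn independently per subject;
#'   \item weights below `dropout_cutoff * mean(W0)` set to exactly 0, so
#'     the binarized topology changes with stage.
#' }
#'
#' @param config A [cohort_config()].
#' @return List of [connectome()] objects in group order (G0, G1, G2),
#'   with attributes `progression` (per-subject `t`) and
#'   `vulnerable_regions` (0-based indices of the vulnerable set).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_nodes
  ut <- upper.tri(matrix(0, n, n))
  n_pairs <- n * (n - 1L) / 2L

  skel <- runif(n_pairs) < config$base_density
  w0 <- ifelse(skel, rlnorm(n_pairs, meanlog = 0, sdlog = config$base_weight_sdlog), 0)
  cutoff <- config$dropout_cutoff * mean(w0[skel])

  vuln <- seq_len(config$n_vulnerable_regions)  # 1-based internally
  row_idx <- row(diag(n))[ut]
  col_idx <- col(diag(n))[ut]
  edge_vuln <- (row_idx %in% vuln) | (col_idx %in% vuln)

  groups <- rep(stage_labels(), times = config$n_per_group)
  means <- rep(config$group_progression_means, times = config$n_per_group)
  n_sub <- length(groups)
  prog <- numeric(n_sub)
  out <- vector("list", n_sub)
  beta <- config$attenuation_strength
  counter <- stats::setNames(rep(0L, 3L), stage_labels())
  for (s in seq_len(n_sub)) {
    t_s <- min(max(rnorm(1, means[s], config$progression_sd), 0), 1)
    prog[s] <- t_s
    att <- ifelse(edge_vuln, 1 - beta * t_s, 1)
    noise <- 1 + config$weight_noise_cv * rnorm(n_pairs)
    wv <- pmax(w0 * att * noise, 0)
    wv[wv < cutoff] <- 0
    w <- matrix(0, n, n)
    w[ut] <- wv
    w <- w + t(w)
    counter[groups[s]] <- counter[groups[s]] + 1L
    out[[s]] <- connectome(
      w,
      subject_id = sprintf("%s_%03d", tolower(groups[s]), counter[groups[s]]),
      group = groups[s]
    )
  }
  attr(out, "progression") <- prog
  attr(out, "vulnerable_regions") <- vuln - 1L
  out
}

#' Generate sparsity-matched random control networks
#'
#' Each graph is an independent Erdos-Renyi random graph whose edge
#' probability is drawn with replacement from `density_samples` (e.g. the
#' empirical densities of a real or synthetic cohort), with unit weights
#' on present edges. These carry no group structure and serve as the
#' control for the manifold-dimensionality experiment.
#'
#' @param n_graphs Number of graphs.
#' @param density_samples Numeric vector of edge probabilities in (0,1].
#' @param n_nodes Nodes per graph.
#' @param seed Integer RNG seed.
#' @return List of [connectome()] objects (group label `G0`).
#' @export
generate_random_networks <- function(n_graphs, density_samples, n_nodes,
                                     seed = 0L) {
  if (length(density_samples) == 0L) stop("density_samples must be nonempty")
  if (any(density_samples < 0 | density_samples > 1)) {
    stop("density_samples must lie in [0,1]")
  }
  set.seed(seed)
  ut <- upper.tri(matrix(0, n_nodes, n_nodes))
  n_pairs <- n_nodes * (n_nodes - 1L) / 2L
  lapply(seq_len(n_graphs), function(g) {
    p <- sample(density_samples, 1L, replace = TRUE)
    w <- matrix(0, n_nodes, n_nodes)
    w[ut] <- as.numeric(runif(n_pairs) < p)
    w <- w + t(w)
    connectome(w, subject_id = sprintf("rand_%03d", g), group = "G0")
  })
}

#' Per-graph empirical binarized densities
#'
#' Fraction of unordered node pairs whose weight exceeds `threshold`,
#' the matching statistic used to build sparsity-matched controls.
#'
#' @param dataset Nonempty list of [connectome()].
#' @param threshold Weight threshold (default 0).
#' @return Numeric vector, one density per graph.
#' @export
empirical_densities <- function(dataset, threshold = 0) {
  if (length(dataset) == 0L) stop("dataset must be nonempty")
  vapply(dataset, function(cn) {
    w <- cn$weights[upper.tri(cn$weights)]
    mean(w > threshold)
  }, numeric(1))
}
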