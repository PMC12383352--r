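#' Full-study configuration
#'
#' Bundles every knob of the end-to-end study into one serializable
#' object. All randomness derives from `seed`: the cohort generator uses
#' `seed`, training `seed + 1`, the permutation test `seed + 2`, the
#' random-network control `seed + 3` and the LOOCV/ablation base
#' `seed + 10`.
#'
#' @param out_dir Output directory for tables and the summary JSON.
#' @param cohort A [cohort_config()] (its `seed` is overridden).
#' @param train A [train_config()] (its `seed` is overridden).
#' @param k Manifold dimensionality (default 2).
#' @param variance_threshold Intrinsic-dimensionality threshold.
#' @param n_permutations Label shuffles for the separability test.
#' @param include_loocv Run the three-task LOOCV evaluation.
#' @param include_ablation Run the five-variant ablation grid.
#' @param loocv_runs Runs per LOOCV/ablation cell.
#' @param seed Master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir = "connstage_run",
                       cohort = cohort_config(),
                       train = train_config(),
                       k = 2L,
                       variance_threshold = 0.99,
                       n_permutations = 1000L,
                       include_loocv = FALSE,
                       include_ablation = FALSE,
                       loocv_runs = 3L,
                       seed = 0L) {
  structure(list(out_dir = out_dir, cohort = cohort, train = train,
                 k = as.integer(k), variance_threshold = variance_threshold,
                 n_permutations = as.integer(n_permutations),
                 include_loocv = include_loocv,
                 include_ablation = include_ablation,
                 loocv_runs = as.integer(loocv_runs),
                 seed = as.integer(seed)),
            class = "run_config")
}

write_tsv <- function(df, dir, name) {
  data.table::fwrite(df, file.path(dir, name), sep = "\t")
}

#' Run the full staging study end to end
#'
#' Executes, in order: synthetic cohort generation; supervised training
#' of the baseline encoder on the two clinical endpoints (G2 vs G0);
#' embedding of all subjects; PCA manifold fit on the endpoint
#' embeddings; projection of the held-out intermediate group; Gaussian
#' cohort regions and Naive Bayes staging of G1; the permutation test of
#' manifold separability; the sparsity-matched random-network control
#' with its intrinsic dimensionality; divergence maps of the G1 and G2
#' manifold cohorts against the G0-cohort template; and (optionally) the
#' LOOCV evaluation and ablation grid. Writes TSV tables plus a
#' machine-readable `summary.json`; a rerun with the same config is
#' identical.
#'
#' @param config A [run_config()].
#' @return The summary list, invisibly.
#' @export
run_full_study <- function(config = run_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  cohort_cfg <- config$cohort
  cohort_cfg$seed <- seed
  train_cfg <- config$train
  train_cfg$seed <- seed + 1L

  # --- simulate ---
  cohort <- generate_cohort(cohort_cfg)
  groups <- vapply(cohort, `[[`, character(1), "group")
  graphs <- lapply(cohort, binarize)

  # --- train on the two endpoints, embed everything ---
  endpoints <- groups %in% c("G0", "G2")
  train_cfg$class_pair <- c("G2", "G0")
  model <- train_classifier(graphs[endpoints], config = train_cfg)
  emb_all <- embed_dataset(graphs, model)
  emb_fit <- embed_dataset(graphs[endpoints], model)

  # --- manifold ---
  manifold <- fit_pca(emb_fit, k = config$k, anchor_label = "G2")
  coords <- project(manifold, emb_all)
  coord_tab <- data.frame(subject_id = emb_all$subject_ids,
                          group = emb_all$labels, coords,
                          stringsAsFactors = FALSE)
  write_tsv(coord_tab, config$out_dir, "manifold_coordinates.tsv")
  two_pc_var <- sum(manifold$full_spectrum[seq_len(min(2L, config$k))])

  # --- cohorts + staging of the held-out group ---
  cmodel <- fit_group_gaussians(coord_tab$PC1, coord_tab$group)
  members <- cohort_membership(cmodel, coord_tab$PC1, coord_tab$subject_id)
  staging <- naive_bayes_assign(cmodel, coord_tab$PC1[coord_tab$group == "G1"],
                                source_group = "G1")
  write_tsv(data.frame(subject_id = coord_tab$subject_id[coord_tab$group == "G1"],
                       assigned = staging$labels),
            config$out_dir, "staging_g1.tsv")

  # --- permutation test ---
  ptest <- permutation_test_separability(coords[, 1:2, drop = FALSE],
                                         coord_tab$group,
                                         config$n_permutations,
                                         seed = seed + 2L)

  # --- random-network control ---
  dens <- empirical_densities(cohort)
  rand <- generate_random_networks(length(cohort), dens, cohort_cfg$n_nodes,
                                   seed = seed + 3L)
  rand_graphs <- lapply(rand, binarize)
  rand_labels <- groups  # same group sizes, no real structure
  rand_cfg <- train_cfg
  rand_model <- train_classifier(rand_graphs[endpoints],
                                 labels = rand_labels[endpoints],
                                 config = rand_cfg)
  # intrinsic dimensionality over all random networks, held-out class included
  rand_emb <- embed_dataset(rand_graphs, rand_model)
  rand_dim <- intrinsic_dim(rand_emb, config$variance_threshold)
  real_dim <- intrinsic_dim(emb_fit, config$variance_threshold)

  # --- divergence maps against the G0 manifold cohort ---
  # cohorts are manifold-defined (PC1 bands), not raw diagnostic labels;
  # a subject inside two bands contributes to both cohorts
  ids <- vapply(cohort, `[[`, character(1), "subject_id")
  ref <- cohort[ids %in% members[["G0"]]]
  if (length(ref) < 2L) ref <- cohort[groups == "G0"]  # degenerate band fallback
  template <- build_template(ref)
  cmp_subjects <- list(); cmp_assign <- character(0)
  for (g in c("G1", "G2")) {
    sel <- cohort[ids %in% members[[g]]]
    cmp_subjects <- c(cmp_subjects, sel)
    cmp_assign <- c(cmp_assign, rep(g, length(sel)))
  }
  divmap <- group_divergence_map(cmp_subjects, template, cmp_assign)
  write_tsv(divmap$group_means, config$out_dir, "divergence_group_means.tsv")

  # --- optional heavy evaluations ---
  loocv <- NULL
  if (config$include_loocv) {
    loocv_cfg <- train_cfg
    loocv_cfg$seed <- seed + 10L
    loocv <- lapply(list(c("G2", "G0"), c("G2", "G1"), c("G1", "G0")),
                    function(task) {
                      keep <- groups %in% task
                      cfg <- loocv_cfg
                      cfg$class_pair <- task
                      res <- loocv_auc(graphs[keep], groups[keep], cfg,
                                       n_runs = config$loocv_runs)
                      list(task = paste(task, collapse = "/"),
                           mean = res$mean, sd = res$sd)
                    })
  }
  ablation <- NULL
  if (config$include_ablation) {
    abl_cfg <- train_cfg
    abl_cfg$seed <- seed + 10L
    ablation <- run_ablation(graphs, groups, abl_cfg,
                             n_runs = config$loocv_runs)
    write_tsv(ablation, config$out_dir, "ablation.tsv")
  }

  summary <- list(
    seed = seed,
    n_subjects = length(cohort),
    group_sizes = as.list(table(groups)),
    final_training_loss = tail(model$train_info$loss_history, 1),
    two_pc_explained_variance = two_pc_var,
    intrinsic_dim_real = real_dim,
    intrinsic_dim_random = rand_dim,
    pc1_group_means = as.list(setNames(cmodel$mu, cmodel$group)),
    staging_fractions_g1 = as.list(staging$fractions),
    permutation_test = list(observed = ptest$observed,
                            p_value = ptest$p_value,
                            n_permutations = ptest$n_permutations),
    top_divergent_regions_g2 = head(
      divmap$group_means$region_index[divmap$group_means$group == "G2"], 15),
    loocv = loocv,
    ablation = if (is.null(ablation)) NULL else
      split(ablation[c("variant", "task", "auc_mean", "auc_sd")],
            seq_len(nrow(ablation)))
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
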