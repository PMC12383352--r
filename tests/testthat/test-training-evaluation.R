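test_that("roc_auc matches hand-enumerated pair counting", {
  expect_equal(roc_auc(c(0, 1), c(0.2, 0.9)), 1.0)
  # 3 of 4 positive-negative pairs concordant
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_error(roc_auc(c(1, 1), c(0.1, 0.2)), "both classes")
  expect_error(roc_auc(c(0, 2), c(0.1, 0.2)), "binary")
})

test_that("roc_auc equals brute-force enumeration and is rank-invariant", {
  brute <- function(labels, scores) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(71)
  for (i in 1:100) {
    n <- sample(4:20, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n), 1)  # rounding induces ties
    a <- roc_auc(labels, scores)
    expect_identical(a, brute(labels, scores))
    # invariance under a strictly monotone transform
    expect_equal(roc_auc(labels, exp(2 * scores)), a)
  }
})

test_that("training separates a trivially separable toy task", {
  toy <- toy_task(n_per_class = 10, n_nodes = 20)
  cfg <- train_config(seed = 0)
  model <- train_classifier(toy$graphs, toy$labels, cfg)
  lh <- model$train_info$loss_history
  expect_lte(lh[length(lh)], lh[1])
  probs <- predict_probs(model, toy$graphs)
  acc <- mean((probs[, "positive"] > 0.5) == (toy$labels == "B"))
  expect_equal(acc, 1.0)
})

test_that("training is fully determined by the seed", {
  toy <- toy_task(n_per_class = 4, n_nodes = 12)
  cfg <- train_config(epochs = 20, seed = 5)
  m1 <- train_classifier(toy$graphs, toy$labels, cfg)
  m2 <- train_classifier(toy$graphs, toy$labels, cfg)
  for (nm in names(m1$params)) {
    expect_lt(max(abs(m1$params[[nm]] - m2$params[[nm]])), 1e-10)
  }
})

test_that("degenerate training inputs are rejected", {
  toy <- toy_task(n_per_class = 3, n_nodes = 10)
  expect_error(train_classifier(toy$graphs[1:3], toy$labels[1:3]),
               "two classes")
  expect_error(train_classifier(list()), "empty")
  expect_error(train_classifier(toy$graphs, toy$labels,
                                train_config(class_pair = c("X", "Y"))),
               "class_pair")
})

test_that("embed_dataset preserves order and validates dimensions", {
  toy <- toy_task(n_per_class = 3, n_nodes = 10)
  set.seed(1)
  model <- encoder_init("baseline", 10)
  es <- embed_dataset(toy$graphs, model)
  expect_equal(dim(es$embeddings), c(6, 64))
  expect_equal(es$subject_ids[1:3], c("e1", "e2", "e3"))
  single <- embed_dataset(toy$graphs[1], model)
  expect_equal(dim(single$embeddings), c(1, 64))
  mixed <- c(toy$graphs[1], list(random_bin_graph(5)))
  expect_error(embed_dataset(mixed, model), "node count")
})

test_that("leave-one-out AUC is perfect on the separable toy task", {
  toy <- toy_task(n_per_class = 5, n_nodes = 12)
  # reduced epochs: the task is trivially separable and converges early
  cfg <- train_config(learning_rate = 0.005, epochs = 40, seed = 0)
  res <- loocv_auc(toy$graphs, toy$labels, cfg, n_runs = 3)
  expect_equal(res$mean, 1.0)
  expect_equal(res$sd, 0.0)
  expect_error(loocv_auc(toy$graphs[c(1, 2, 6)], toy$labels[c(1, 2, 6)], cfg),
               "two samples per class")
})

test_that("label-permuted leave-one-out AUC shows no positive skill", {
  # Pooled LOOCV is pessimistically biased under the null: the held-out
  # sample is always the minority of its training fold, so permuted labels
  # drive the AUC at or below chance — never above it.
  toy <- toy_task(n_per_class = 5, n_nodes = 12)
  cfg <- train_config(learning_rate = 0.005, epochs = 25, seed = 3)
  set.seed(99)
  aucs <- vapply(1:5, function(i) {
    shuffled <- sample(toy$labels)
    while (length(unique(shuffled)) < 2) shuffled <- sample(toy$labels)
    loocv_auc(toy$graphs, shuffled, cfg, n_runs = 1)$mean
  }, numeric(1))
  expect_lte(mean(aucs), 0.65)
})

test_that("supervised training collapses embedding dimensionality", {
  # Untrained encoders spread random graphs over many effective dimensions;
  # training concentrates the representation along the classification
  # discriminant, even when the labels are arbitrary (memorization). This
  # is why low intrinsic dimensionality of trained embeddings cannot by
  # itself distinguish structured from random inputs.
  nets <- generate_random_networks(40, c(0.25, 0.3, 0.35), n_nodes = 40,
                                   seed = 9)
  graphs <- lapply(nets, binarize)
  labels <- rep(c("G0", "G2"), 20)
  set.seed(2)
  untrained <- encoder_init("baseline", 40)
  d_un <- intrinsic_dim(embed_dataset(graphs, untrained), 0.99)
  trained <- train_classifier(graphs, labels,
                              train_config(learning_rate = 0.005,
                                           epochs = 80, seed = 2))
  d_tr <- intrinsic_dim(embed_dataset(graphs, trained), 0.99)
  expect_gte(d_un, 10L)
  expect_lte(d_tr, 3L)
})

test_that("the ablation grid covers variants x tasks with valid cells", {
  set.seed(8)
  cohort <- generate_cohort(cohort_config(n_per_group = c(4L, 4L, 4L),
                                          n_nodes = 24L,
                                          n_vulnerable_regions = 4L,
                                          seed = 8))
  graphs <- lapply(cohort, binarize)
  cfg <- train_config(epochs = 10, seed = 1)
  tab <- run_ablation(graphs, config = cfg, variants = "baseline",
                      n_runs = 1)
  expect_equal(dim(tab), c(2L, 4L))
  expect_true(all(tab$auc_mean >= 0 & tab$auc_mean <= 1))
  expect_setequal(tab$task, c("G2/G1", "G2/G0"))
  groups <- vapply(cohort, `[[`, character(1), "group")
  expect_error(run_ablation(graphs[groups != "G1"], config = cfg,
                            variants = "baseline", n_runs = 1),
               "missing group")
})
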