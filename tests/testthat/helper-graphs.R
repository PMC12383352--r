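# Fixture builders shared across the suite. Everything is generated in
# code; no stored data.

# adjacency from an unordered edge list (1-based indices)
adj_from_edges <- function(n, edges) {
  a <- matrix(0, n, n)
  for (e in edges) {
    a[e[1], e[2]] <- 1
    a[e[2], e[1]] <- 1
  }
  a
}

# minimal binarized-graph list (identity features unless given)
bin_graph <- function(adjacency, features = NULL, subject_id = "s",
                      group = "G0") {
  if (is.null(features)) features <- diag(nrow(adjacency))
  list(adjacency = adjacency, features = features,
       subject_id = subject_id, group = group)
}

random_bin_graph <- function(n, p = 0.4, subject_id = "s", group = "G0") {
  a <- matrix(0, n, n)
  ut <- upper.tri(a)
  a[ut] <- rbinom(sum(ut), 1, p)
  bin_graph(a + t(a), subject_id = subject_id, group = group)
}

random_connectome <- function(n, p = 0.4, subject_id = "s", group = "G0") {
  a <- matrix(0, n, n)
  ut <- upper.tri(a)
  a[ut] <- ifelse(runif(sum(ut)) < p, rlnorm(sum(ut)), 0)
  connectome(a + t(a), subject_id = subject_id, group = group)
}

# trivially separable toy task: empty vs complete graphs
toy_task <- function(n_per_class = 10, n_nodes = 20) {
  empty <- matrix(0, n_nodes, n_nodes)
  full <- matrix(1, n_nodes, n_nodes); diag(full) <- 0
  graphs <- c(
    lapply(seq_len(n_per_class), function(i)
      bin_graph(empty, subject_id = paste0("e", i), group = "A")),
    lapply(seq_len(n_per_class), function(i)
      bin_graph(full, subject_id = paste0("f", i), group = "B"))
  )
  list(graphs = graphs, labels = rep(c("A", "B"), each = n_per_class))
}

# small synthetic cohort for fast end-to-end tests
small_cohort_config <- function(seed = 0L) {
  cohort_config(n_per_group = c(6L, 8L, 6L), n_nodes = 40L,
                n_vulnerable_regions = 5L, seed = seed)
}

write_matrix_file <- function(text) {
  f <- tempfile(fileext = ".csv")
  writeLines(text, f)
  f
}
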