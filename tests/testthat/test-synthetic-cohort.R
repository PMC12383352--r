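test_that("default cohort has the stated composition and valid connectomes", {
  cohort <- generate_cohort(cohort_config(seed = 0))
  expect_length(cohort, 88)
  groups <- vapply(cohort, `[[`, character(1), "group")
  expect_equal(as.integer(table(factor(groups, stage_labels()))),
               c(24L, 46L, 18L))
  for (cn in cohort[c(1, 30, 88)]) expect_silent(validate_connectome(cn))
  expect_equal(nrow(cohort[[1]]$weights), 148)
})

test_that("generation is seed-deterministic and seed-sensitive", {
  cfg <- small_cohort_config(seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(lapply(a, `[[`, "weights"), lapply(b, `[[`, "weights"))
  cfg2 <- small_cohort_config(seed = 8)
  c2 <- generate_cohort(cfg2)
  expect_false(identical(a[[1]]$weights > 0, c2[[1]]$weights > 0))
})

test_that("planted effect attenuates vulnerable-node connectivity with stage", {
  cohort <- generate_cohort(cohort_config(seed = 0))
  groups <- vapply(cohort, `[[`, character(1), "group")
  vuln <- attr(cohort, "vulnerable_regions") + 1L
  mean_vuln_degree <- function(subset) {
    mean(vapply(subset, function(cn)
      mean(rowSums(cn$weights[vuln, , drop = FALSE] > 0)), numeric(1)))
  }
  expect_lt(mean_vuln_degree(cohort[groups == "G2"]),
            mean_vuln_degree(cohort[groups == "G0"]))
})

test_that("the effect is confined to vulnerable-incident edges", {
  cohort <- generate_cohort(cohort_config(seed = 0))
  groups <- vapply(cohort, `[[`, character(1), "group")
  vuln <- attr(cohort, "vulnerable_regions") + 1L
  nonvuln_density <- function(cn) {
    w <- cn$weights[-vuln, -vuln]
    mean(w[upper.tri(w)] > 0)
  }
  d0 <- vapply(cohort[groups == "G0"], nonvuln_density, numeric(1))
  d2 <- vapply(cohort[groups == "G2"], nonvuln_density, numeric(1))
  se <- sqrt(var(d0) / length(d0) + var(d2) / length(d2))
  expect_lt(abs(mean(d0) - mean(d2)), 2 * se)
})

test_that("attenuation_strength 0 removes the group effect entirely", {
  cohort <- generate_cohort(cohort_config(attenuation_strength = 0, seed = 1))
  groups <- vapply(cohort, `[[`, character(1), "group")
  d <- empirical_densities(cohort)
  d0 <- d[groups == "G0"]; d2 <- d[groups == "G2"]
  se <- sqrt(var(d0) / length(d0) + var(d2) / length(d2))
  expect_lt(abs(mean(d0) - mean(d2)), 2 * se)
})

test_that("random control networks match the requested density", {
  nets <- generate_random_networks(10, rep(0.3, 10), n_nodes = 50, seed = 1)
  d <- empirical_densities(nets)
  se_graph <- sqrt(0.3 * 0.7 / choose(50, 2))
  expect_lt(abs(mean(d) - 0.3), 3 * se_graph / sqrt(10))

  full <- generate_random_networks(2, 1.0, n_nodes = 10, seed = 2)
  expect_equal(empirical_densities(full), c(1, 1))
  near_empty <- generate_random_networks(2, 1e-9, n_nodes = 10, seed = 3)
  expect_equal(empirical_densities(near_empty), c(0, 0))
  expect_error(generate_random_networks(2, numeric(0), 10), "nonempty")
})

test_that("random networks carry no group structure", {
  nets <- generate_random_networks(40, c(0.2, 0.3, 0.4), n_nodes = 60,
                                   seed = 5)
  d <- empirical_densities(nets)
  a <- d[1:20]; b <- d[21:40]
  se <- sqrt(var(a) / 20 + var(b) / 20)
  expect_lt(abs(mean(a) - mean(b)), 2 * se)
})

test_that("empirical densities count positive unordered pairs", {
  full <- connectome({w <- matrix(1, 4, 4); diag(w) <- 0; w})
  expect_equal(empirical_densities(list(full)), 1.0)
  expect_equal(empirical_densities(list(connectome(matrix(0, 4, 4)))), 0.0)
  half <- connectome(adj_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4))))
  expect_equal(empirical_densities(list(half)), 0.5)
  expect_error(empirical_densities(list()), "nonempty")
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(base_density = 1.2), "base_density")
  expect_error(cohort_config(attenuation_strength = 1.5), "attenuation")
  expect_error(cohort_config(n_vulnerable_regions = 200), "smaller")
})
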