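test_that("GIN layer matches hand evaluation in identity mode", {
  # path graph 0-1-2 with scalar features
  a <- adj_from_edges(3, list(c(1, 2), c(2, 3)))
  x <- matrix(c(1, 2, 3), ncol = 1)
  expect_equal(drop(gin_layer(x, a, list(epsilon = 0))), c(3, 6, 5))

  # isolated node: empty neighborhood, (1 + eps) self term only
  expect_equal(drop(gin_layer(matrix(c(2, 4), 1), matrix(0, 1, 1),
                              list(epsilon = 0.5))),
               c(3, 6))

  # triangle with one-hot features: every row sums all one-hots
  tri <- adj_from_edges(3, list(c(1, 2), c(1, 3), c(2, 3)))
  expect_equal(gin_layer(diag(3), tri, list(epsilon = 0)),
               matrix(1, 3, 3))
})

test_that("GIN identity mode equals (A + I) %*% X on random graphs", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    g <- random_bin_graph(n, 0.5)
    x <- matrix(rnorm(n * 4), n, 4)
    expect_equal(gin_layer(x, g$adjacency, list(epsilon = 0)),
                 (g$adjacency + diag(n)) %*% x)
  }
})

test_that("GAT layer matches hand-computed attention", {
  # isolated node: softmax over the singleton {v}, output = W x
  W <- matrix(c(1, 2, 0, 1), 2, 2)
  x <- matrix(c(3, 1), 1, 2)
  out <- gat_layer(x, matrix(0, 1, 1), list(W = W, a = rep(0, 4)))
  expect_equal(out, x %*% W)

  # zero attention kernel: uniform weights; identical features pass through
  a2 <- adj_from_edges(2, list(c(1, 2)))
  xx <- matrix(c(1, 2, 1, 2), 2, 2, byrow = TRUE)
  out2 <- gat_layer(xx, a2, list(W = diag(2), a = rep(0, 4)),
                    return_attention = TRUE)
  expect_equal(unname(out2[1, ]), c(1, 2))
  expect_equal(attr(out2, "attention"), matrix(0.5, 2, 2))

  # engineered logits (ln 2, 0) for (self, neighbor) of node 0
  xs <- rbind(c(log(2), 1), c(0, 1))
  kern <- c(1, 0, 0, 0)  # s1 = z[,1], s2 = 0
  out3 <- gat_layer(xs, a2, list(W = diag(2), a = kern),
                    return_attention = TRUE)
  alpha <- attr(out3, "attention")
  expect_equal(alpha[, 1], c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(unname(out3[1, ]), drop(2 / 3 * xs[1, ] + 1 / 3 * xs[2, ]))
})

test_that("GCN layer applies symmetric degree normalization", {
  # isolated node, identity weight and activation
  x <- matrix(c(5, 7), 1, 2)
  expect_equal(gcn_layer(x, matrix(0, 1, 1), diag(2)), x)

  # two connected nodes with identical features: 1/2 + 1/2 leaves them fixed
  a2 <- adj_from_edges(2, list(c(1, 2)))
  xx <- matrix(c(3, 1, 3, 1), 2, 2, byrow = TRUE)
  expect_equal(gcn_layer(xx, a2, diag(2)), xx)

  # star K1,3: center-leaf coefficient is 1 / (sqrt(4) * sqrt(2))
  star <- adj_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4)))
  a_norm <- gcn_layer(diag(4), star, diag(4))
  expect_equal(a_norm[1, 2], 1 / (sqrt(4) * sqrt(2)))
  expect_equal(a_norm[1, 1], 1 / 4)
  expect_equal(a_norm[2, 2], 1 / 2)
})

test_that("attention readout matches hand-computed softmax pooling", {
  h <- rbind(c(1, 0), c(0, 1))
  # constant gate scores: arithmetic mean
  expect_equal(attention_readout(h, list(w = c(0, 0), b = 3)), c(0.5, 0.5))

  # saturated gate: dominant node wins
  h3 <- rbind(c(1, 2), c(5, 6), c(9, 10))
  out <- attention_readout(h3, list(w = c(50, 0), b = 0))
  expect_equal(out, c(9, 10), tolerance = 1e-6)

  # gate scores (ln 2, 0) on unit features
  out2 <- attention_readout(h, list(w = c(log(2), 0), b = 0),
                            return_weights = TRUE)
  expect_equal(unname(out2[1:2]), c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(sum(attr(out2, "weights")), 1)

  expect_error(attention_readout(matrix(0, 0, 2), list(w = c(0, 0), b = 0)),
               "empty")
})

test_that("sum readout is the columnwise sum", {
  expect_equal(sum_readout(rbind(c(1, 2), c(3, 4))), c(4, 6))
  expect_equal(sum_readout(matrix(c(7, 8), 1)), c(7, 8))
  expect_equal(sum_readout(matrix(0, 3, 2)), c(0, 0))
  expect_error(sum_readout(matrix(0, 0, 2)), "empty")
})

test_that("embed_graph honors the variant contracts", {
  set.seed(31)
  g <- random_bin_graph(9, 0.5)
  empty <- bin_graph(matrix(0, 9, 9))
  for (v in c("baseline", "sum_pool", "gcn_variant", "gat_only")) {
    m <- encoder_init(v, 9)
    expect_length(embed_graph(g, m), 64)
    expect_true(all(is.finite(embed_graph(empty, m))))  # self-loop-only paths
  }
  m128 <- encoder_init("gin_only", 9)
  expect_length(embed_graph(g, m128), 128)
  expect_error(embed_graph(random_bin_graph(5), m128), "nodes")
})

test_that("attention weights are normalized over their softmax sets", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    g <- random_bin_graph(n, runif(1, 0.1, 0.9))
    W <- matrix(rnorm(n * 4), n, 4)
    out <- gat_layer(g$features, g$adjacency,
                     list(W = W, a = rnorm(8)), return_attention = TRUE)
    alpha <- attr(out, "attention")
    expect_true(all(alpha >= 0))
    expect_equal(colSums(alpha), rep(1, n), tolerance = 1e-8)
    # non-neighbors carry zero attention
    mask <- (g$adjacency > 0) | diag(n) > 0
    expect_true(all(alpha[!mask] == 0))

    ro <- attention_readout(out, list(w = rnorm(4), b = rnorm(1)),
                            return_weights = TRUE)
    expect_equal(sum(attr(ro, "weights")), 1, tolerance = 1e-8)
  }
})

test_that("embed_graph is invariant to joint node relabeling", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    g <- random_bin_graph(n, 0.5)
    perm <- sample(n)
    P <- diag(n)[perm, ]
    g_perm <- bin_graph(P %*% g$adjacency %*% t(P), features = P)
    for (v in c("baseline", "sum_pool", "gin_only")) {
      m <- encoder_init(v, n)
      expect_equal(embed_graph(g_perm, m), embed_graph(g, m),
                   tolerance = 1e-6)
    }
  }
})

test_that("the reference layers and the compiled path agree", {
  set.seed(61)
  gs <- lapply(1:4, function(i) random_bin_graph(11, 0.4))
  for (v in c("baseline", "sum_pool", "gin_only", "gcn_variant", "gat_only")) {
    m <- encoder_init(v, 11)
    ref <- t(vapply(gs, embed_graph, numeric(m$d_embed), model = m))
    fast <- connstage:::cpp_embed_dataset(lapply(gs, `[[`, "adjacency"),
                                          m$params,
                                          connstage:::encoder_flags(m))
    expect_equal(ref, fast, tolerance = 1e-5, ignore_attr = TRUE)
  }
})
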