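test_that("graph embeddings are invariant to node permutation", {
  cfg <- encoder_config("target", n_layers = 3L, hidden_size = 12L,
                        seed = 5L)
  params <- gin_init(cfg)
  set.seed(11)
  for (rep in 1:100) {
    g <- random_graph(sample(2:30, 1L))
    perm <- sample.int(g$n_nodes)
    e1 <- gin_forward(g, cfg, params)$graph_embedding
    e2 <- gin_forward(permute_graph(g, perm), cfg, params)$graph_embedding
    expect_equal(e1, e2, tolerance = 1e-6)
  }
})

test_that("node embeddings permute along with the nodes", {
  cfg <- encoder_config("target", n_layers = 2L, hidden_size = 8L, seed = 3L)
  params <- gin_init(cfg)
  set.seed(21)
  g <- random_graph(12L)
  perm <- sample.int(12L)
  n1 <- gin_forward(g, cfg, params)$node_embeddings
  n2 <- gin_forward(permute_graph(g, perm), cfg, params)$node_embeddings
  expect_equal(n2[perm, ], n1, tolerance = 1e-6)
})

test_that("a zero discriminator gives the closed-form JSD loss 2 ln 2", {
  set.seed(2)
  d <- 7L
  Hn <- matrix(rnorm(5 * d), 5, d)
  Hg <- matrix(rnorm(2 * d), 2, d)
  disc <- list(W = matrix(0, d, d))
  loss <- jsd_mi_loss(list(Hn[1:3, ], Hn[4:5, ]), list(Hg[1, ], Hg[2, ]),
                      disc)
  expect_equal(loss, 2 * log(2), tolerance = 1e-6)
})

test_that("JSD loss matches a hand-evaluated two-graph batch", {
  # graph 1: nodes u1, u2; graph 2: node v1. Scores s = h' W g.
  W <- matrix(c(0.5, -0.2, 0.1, 0.3), 2, 2)
  u1 <- c(1, 0); u2 <- c(0, 1); v1 <- c(1, 1)
  g1 <- c(0.5, 0.5); g2 <- c(-1, 2)
  score <- function(h, g) drop(t(h) %*% W %*% g)
  pos <- c(score(u1, g1), score(u2, g1), score(v1, g2))
  neg <- c(score(u1, g2), score(u2, g2), score(v1, g1))
  by_hand <- mean(softplus_ref(-pos)) + mean(softplus_ref(neg))
  loss <- jsd_mi_loss(list(rbind(u1, u2), rbind(v1)),
                      list(g1, g2), list(W = W))
  expect_equal(loss, by_hand, tolerance = 1e-6)
})

test_that("JSD loss requires at least two graphs for negatives", {
  expect_error(jsd_mi_loss(list(matrix(1, 1, 2)), list(c(1, 2)),
                           list(W = diag(2))),
               "at least 2")
})

test_that("pretraining decreases the InfoGraph loss on a small corpus", {
  set.seed(33)
  graphs <- lapply(1:20, function(i) random_graph(sample(5:15, 1L)))
  cfg <- encoder_config("target", n_layers = 2L, hidden_size = 10L)
  st <- pretrain_encoder(graphs, cfg, epochs = 8L, batch_size = 10L,
                         lr = 1e-2, seed = 4L)
  expect_s3_class(st, "pretrain_state")
  expect_length(st$loss_history, 8L)
  expect_lt(st$loss_history[8L], st$loss_history[1L])
})

test_that("pretraining is deterministic in the seed", {
  graphs <- lapply(1:8, function(i) build_fragment_graph(
    paste(rep(LETTERS[i], 6), collapse = "")))
  cfg <- encoder_config("target", n_layers = 2L, hidden_size = 6L)
  s1 <- pretrain_encoder(graphs, cfg, epochs = 3L, seed = 9L)
  s2 <- pretrain_encoder(graphs, cfg, epochs = 3L, seed = 9L)
  expect_identical(s1$loss_history, s2$loss_history)
  expect_identical(s1$params, s2$params)
})
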