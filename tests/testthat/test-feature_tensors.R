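# A small random encoder is enough: the contracts under test concern
# shapes and padding, not embedding quality.
tiny_drug_encoder <- function(d = 6L) {
  cfg <- encoder_config("drug", n_layers = 2L, hidden_size = d, seed = 2L)
  list(config = cfg, params = gin_init(cfg))
}
tiny_target_encoder <- function(d = 6L) {
  cfg <- encoder_config("target", n_layers = 2L, hidden_size = d, seed = 2L)
  list(config = cfg, params = gin_init(cfg))
}

test_that("drug features are always n_rows x d with zero padding rows", {
  enc <- tiny_drug_encoder()
  f <- extract_drug_features("CCO", enc, n_rows = 64L)
  expect_s3_class(f, "drug_features")
  expect_identical(dim(f$matrix), c(64L, 6L))
  expect_identical(f$n_real, 3L)
  expect_true(all(f$matrix[4:64, ] == 0))
  expect_false(all(f$matrix[1:3, ] == 0))
})

test_that("oversized molecules truncate to the first n_rows atoms", {
  enc <- tiny_drug_encoder()
  smi70 <- strrep("C", 70L)   # 70-carbon chain
  f <- extract_drug_features(smi70, enc, n_rows = 64L)
  expect_identical(dim(f$matrix), c(64L, 6L))
  expect_identical(f$n_real, 64L)
  # truncation keeps a prefix of the full-graph node embeddings
  g <- build_drug_graph(smi70)
  full <- gin_forward(g, enc$config, enc$params)$node_embeddings
  expect_equal(f$matrix, full[1:64, ], tolerance = 1e-12)
})

test_that("target features are K x d with zero rows for padding windows", {
  enc <- tiny_target_encoder()
  wc <- window_config(window_length = 8L, k_fragments = 16L)
  f <- extract_target_features("ACDEF", enc, wc)  # L = 5 < window length
  expect_s3_class(f, "target_features")
  expect_identical(dim(f$matrix), c(16L, 6L))
  expect_true(any(f$padding))
  expect_true(all(f$matrix[f$padding, ] == 0))
  expect_false(any(apply(f$matrix[!f$padding, , drop = FALSE], 1L,
                         function(r) all(r == 0))))
})

test_that("target feature rows follow window order", {
  enc <- tiny_target_encoder()
  wc <- window_config(window_length = 4L, k_fragments = 4L)
  s <- "ACDEFGHIKL"  # L = 10 -> starts 0, 2, 4, 6
  f <- extract_target_features(s, enc, wc)
  fs <- segment_overlapping(s, wc)
  for (i in 1:4) {
    g <- build_fragment_graph(fs$fragments[[i]]$sequence)
    expect_equal(f$matrix[i, ],
                 gin_forward(g, enc$config, enc$params)$graph_embedding,
                 tolerance = 1e-12)
  }
})

test_that("encoder kind is enforced", {
  expect_error(extract_drug_features("CCO", tiny_target_encoder()))
  expect_error(extract_target_features("ACDE", tiny_drug_encoder()))
})
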