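# Naive 2D convolution oracle: stride 1, zero "same" padding, ReLU.
conv2d_naive <- function(img, Wk, b) {
  kh <- dim(Wk)[1]; kw <- dim(Wk)[2]
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  H <- nrow(img); W <- ncol(img)
  pad <- matrix(0, H + 2 * ph, W + 2 * pw)
  pad[ph + seq_len(H), pw + seq_len(W)] <- img
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      out[i, j] <- sum(pad[i:(i + kh - 1), j:(j + kw - 1)] * Wk) + b
    }
  }
  pmax(out, 0)
}

test_that("one conv layer matches the naive 2D convolution oracle", {
  set.seed(14)
  cfg <- cnn_config(n_layers = 1L, filters = 1L, kernels = 3L, pool = 1L,
                    input_rows = 7L, input_cols = 5L)
  params <- cnn_init(cfg, seed = 3L)
  img <- matrix(rnorm(35), 7, 5)
  hl <- cnn_high_level(img, list(config = cfg, params = params))
  # weight rows are patch-element-major: row index = u + v * kh (0-based)
  Wk <- matrix(params$layers[[1]]$W[, 1], 3, 3)
  ref <- conv2d_naive(img, Wk, params$layers[[1]]$b[1])
  expect_equal(hl, max(ref), tolerance = 1e-10)   # global max pool on top
})

test_that("max pooling after a conv layer matches the naive oracle", {
  set.seed(15)
  cfg <- cnn_config(n_layers = 1L, filters = 2L, kernels = 3L, pool = 2L,
                    input_rows = 6L, input_cols = 4L)
  params <- cnn_init(cfg, seed = 8L)
  img <- matrix(rnorm(24), 6, 4)
  hl <- cnn_high_level(img, list(config = cfg, params = params))
  for (f in 1:2) {
    Wk <- matrix(params$layers[[1]]$W[, f], 3, 3)
    conv <- conv2d_naive(img, Wk, params$layers[[1]]$b[f])
    pooled <- matrix(0, 3, 2)
    for (i in 1:3) for (j in 1:2) {
      pooled[i, j] <- max(conv[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
    }
    expect_equal(hl[f], max(pooled), tolerance = 1e-10)
  }
})

test_that("1D variant reads embedding columns as channels", {
  set.seed(16)
  cfg <- cnn_config(n_layers = 1L, filters = 1L, kernels = 3L, pool = 1L,
                    variant = "1d", input_rows = 9L, input_cols = 2L)
  params <- cnn_init(cfg, seed = 4L)
  mat <- matrix(rnorm(18), 9, 2)
  hl <- cnn_high_level(mat, list(config = cfg, params = params))
  # naive 1D conv: weight rows are k-major with Cin inside each k
  Wf <- params$layers[[1]]$W[, 1]
  pad <- rbind(0, mat, 0)
  conv <- vapply(seq_len(9), function(i) {
    patch <- as.vector(t(pad[i:(i + 2), ]))  # (k, channel) pairs, k-major
    sum(patch * Wf) + params$layers[[1]]$b[1]
  }, numeric(1))
  expect_equal(hl, max(pmax(conv, 0)), tolerance = 1e-10)
})

test_that("CNN gradients agree with central finite differences", {
  set.seed(17)
  cfg <- cnn_config(n_layers = 2L, filters = c(2L, 3L), kernels = c(3L, 3L),
                    pool = c(2L, 1L), input_rows = 8L, input_cols = 6L)
  params <- cnn_init(cfg, seed = 5L)
  B <- 2L
  mats <- list(matrix(rnorm(48), 8, 6), matrix(rnorm(48), 8, 6))
  X <- gindta:::cnn_batch_layout(mats, cfg)
  loss_of <- function(p) {
    out <- gindta:::cnn_forward_batch(X, p, cfg, B, keep_cache = FALSE)
    sum(out$F^2)
  }
  out <- gindta:::cnn_forward_batch(X, params, cfg, B, keep_cache = TRUE)
  grads <- gindta:::cnn_backward_batch(2 * out$F, out, params, cfg, B)
  eps <- 1e-6
  for (l in 1:2) {
    idx <- sample(length(params$layers[[l]]$W), 4L)
    for (ii in idx) {
      p1 <- params; p1$layers[[l]]$W[ii] <- p1$layers[[l]]$W[ii] + eps
      p2 <- params; p2$layers[[l]]$W[ii] <- p2$layers[[l]]$W[ii] - eps
      fd <- (loss_of(p1) - loss_of(p2)) / (2 * eps)
      expect_equal(grads$layers[[l]]$W[ii], fd, tolerance = 1e-4)
    }
  }
})

test_that("cnn_high_level rejects inputs of the wrong shape", {
  cnn <- list(config = cnn_config(input_rows = 64L, input_cols = 60L),
              params = cnn_init(cnn_config(), seed = 1L))
  expect_error(cnn_high_level(matrix(0, 10, 60), cnn),
               "expected 64x60, got 10x60")
})

test_that("default architectures match the published layer shapes", {
  cfg <- cnn_config()
  expect_identical(cfg$filters, c(32L, 64L, 128L))
  expect_identical(cfg$kernels, c(5L, 5L, 3L))
  expect_identical(cfg$out_dim, 128L)
  params <- cnn_init(cfg, seed = 1L)
  expect_identical(dim(params$layers[[1]]$W), c(25L, 32L))    # 5*5*1
  expect_identical(dim(params$layers[[2]]$W), c(25L * 32L, 64L))
  expect_identical(dim(params$layers[[3]]$W), c(9L * 64L, 128L))
})
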