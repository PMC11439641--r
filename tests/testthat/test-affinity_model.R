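# A deliberately tiny configuration so the whole fit runs in seconds; the
# model-quality properties are exercised in the acceptance suite.
tiny_config <- function(seed = 7L, epochs = 3L, ...) {
  run_config(
    window = list(window_length = 8L, k_fragments = 8L,
                  min_fragment_length = 4L),
    drug_encoder = list(n_layers = 2L, hidden_size = 8L),
    target_encoder = list(n_layers = 2L, hidden_size = 8L),
    drug_cnn = list(n_layers = 2L, filters = c(4L, 8L),
                    kernels = c(3L, 3L), pool = c(2L, 1L)),
    target_cnn = list(n_layers = 2L, filters = c(4L, 8L),
                      kernels = c(3L, 3L), pool = c(2L, 1L)),
    predictor = list(hidden = c(8L, 1L)),
    drug_rows = 16L,
    pretrain = list(epochs = 2L),
    train = list(epochs = epochs, batch_size = 16L, seed = seed),
    ...)
}

tiny_data <- function(seed = 5L) {
  sp <- synthetic_spec(n_drugs = 8L, n_targets = 6L, n_pairs = 40L,
                       target_length_range = c(30L, 60L), seed = seed)
  drugs <- generate_drugs(sp)
  targets <- generate_targets(sp)
  list(drugs = drugs, targets = targets,
       aff = generate_affinities(drugs, targets, sp))
}

tiny_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- tiny_data()
      cache <<- list(fit = gindta(d$aff, d$drugs, d$targets,
                                  config = tiny_config()),
                     data = d)
    }
    cache
  }
})

test_that("gindta returns a classed fit with coherent split and history", {
  tf <- tiny_fit()
  fit <- tf$fit
  expect_s3_class(fit, "gindta")
  sp <- fit$split
  expect_identical(sort(c(sp$train, sp$val, sp$test)), seq_len(40L))
  expect_identical(nrow(fit$history), 3L)
  expect_true(all(is.finite(fit$history$train_mse)))
  expect_s3_class(fit$test, "evaluation_result")
  expect_identical(nrow(fit$predictions), length(sp$test))
})

test_that("print, summary and plot methods run and describe the fit", {
  fit <- tiny_fit()$fit
  expect_output(print(fit), "Two-stage drug-target affinity model")
  s <- summary(fit)
  expect_s3_class(s, "summary.gindta")
  expect_output(print(s), "trainable parameters")
  expect_gt(s$n_parameters, 0L)
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("coef returns the trained head parameters", {
  fit <- tiny_fit()$fit
  cf <- coef(fit)
  expect_named(cf, c("drug_cnn", "target_cnn", "predictor"))
  expect_identical(dim(cf$predictor$layers[[1]]$W), c(16L, 8L))  # 8 + 8
})

test_that("predict on the fit records reproduces the stored predictions", {
  fit <- tiny_fit()$fit
  pr <- predict(fit)   # defaults to the held-out test pairs
  expect_equal(pr$y_pred, fit$predictions$y_pred, tolerance = 1e-12)
  expect_equal(pr$y_true, fit$predictions$y_true, tolerance = 1e-12)
})

test_that("predict handles unseen entities supplied alongside newdata", {
  tf <- tiny_fit()
  nd <- data.frame(drug_id = "DNEW", target_id = tf$data$targets$id[1L],
                   stringsAsFactors = FALSE)
  pr <- predict(tf$fit, newdata = nd,
                drugs = data.frame(id = "DNEW", smiles = "CCOCC"))
  expect_identical(nrow(pr), 1L)
  expect_true(is.finite(pr$y_pred))
  expect_error(predict(tf$fit, newdata = data.frame(
    drug_id = "DMISSING", target_id = "T001")), "unresolvable")
})

test_that("residuals and simulate are consistent with predictions", {
  fit <- tiny_fit()$fit
  r <- residuals(fit, "test")
  expect_equal(r, fit$predictions$y_true - fit$predictions$y_pred,
               tolerance = 1e-12)
  expect_length(residuals(fit, "all"), 40L)
  sims <- simulate(fit, nsim = 3L, seed = 1L)
  expect_identical(dim(sims), c(length(fit$split$test), 3L))
  sims2 <- simulate(fit, nsim = 3L, seed = 1L)
  expect_identical(sims, sims2)
})

test_that("the no-pretraining ablation trains without pretrained encoders", {
  d <- tiny_data(seed = 6L)
  cfg <- tiny_config(seed = 8L, epochs = 2L,
                     ablation = list(no_pretrain = TRUE))
  fit <- gindta(d$aff, d$drugs, d$targets, config = cfg)
  expect_s3_class(fit, "gindta")
  expect_false(inherits(fit$bundle$drug_encoder, "pretrain_state"))
})

test_that("the 1D-CNN ablation trains end to end", {
  d <- tiny_data(seed = 9L)
  cfg <- tiny_config(seed = 9L, epochs = 2L,
                     ablation = list(use_1d_cnn = TRUE))
  fit <- gindta(d$aff, d$drugs, d$targets, config = cfg)
  expect_identical(fit$bundle$drug_cnn$config$variant, "1d")
  expect_true(all(is.finite(fit$predictions$y_pred)))
})

test_that("feature standardisation preserves the zero-padding contract", {
  mats <- list(a = rbind(matrix(rnorm(12, mean = 3), 2, 6),
                         matrix(0, 2, 6)),
               b = rbind(matrix(rnorm(12, mean = 3), 2, 6),
                         matrix(0, 2, 6)))
  st <- gindta:::feature_norm_stats(mats)
  # statistics come from the real (non-zero) rows only
  real <- rbind(mats$a[1:2, ], mats$b[1:2, ])
  expect_equal(st$mu, colMeans(real), tolerance = 1e-12)
  out <- gindta:::norm_apply(mats$a, st)
  expect_true(all(out[3:4, ] == 0))                  # padding rows stay zero
  expect_equal(out[1:2, ], sweep(sweep(mats$a[1:2, ], 2, st$mu), 2,
                                 st$sd, "/"), tolerance = 1e-12)
})

test_that("model_bundle wires the published default dimensions", {
  b <- model_bundle(run_config(), seed = 1L)
  expect_identical(b$drug_cnn$config$input_rows, 64L)
  expect_identical(b$target_cnn$config$input_rows, 64L)
  expect_identical(b$drug_cnn$config$input_cols, 60L)
  expect_identical(nrow(b$predictor$params$layers[[1]]$W), 256L)
  expect_false(b$trained)
})
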