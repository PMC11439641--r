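#' Build pretraining graph corpora from entity tables
#'
#' Drug corpus: one canonical atom graph per SMILES. Target corpus: residue
#' chain graphs of the non-overlapping windows of every sequence (windows
#' shorter than `min_fragment_length` are dropped).
#'
#' @param drugs Data frame with `id`, `smiles`.
#' @param targets Data frame with `id`, `sequence`.
#' @param window A [window_config()].
#' @return A list with `drug` and `target` graph lists.
#' @export
build_corpora <- function(drugs = NULL, targets = NULL,
                          window = window_config()) {
  out <- list()
  if (!is.null(drugs)) {
    vocab <- token_vocabulary("drug")
    out$drug <- lapply(seq_len(nrow(drugs)), function(i) {
      build_drug_graph(drugs$smiles[i], vocab, source_id = drugs$id[i])
    })
  }
  if (!is.null(targets)) {
    vocab <- token_vocabulary("target")
    out$target <- unlist(lapply(seq_len(nrow(targets)), function(i) {
      fs <- segment_nonoverlapping(targets$sequence[i], window,
                                   parent_id = targets$id[i])
      lapply(fs$fragments, build_fragment_graph, vocab = vocab)
    }), recursive = FALSE)
  }
  out
}

#' Pretrain both encoders on unlabeled drug and target corpora
#'
#' Stage one of the pipeline: the drug encoder is trained on drug atom
#' graphs and the target encoder on residue-fragment chain graphs, each
#' independently with the InfoGraph objective. Parameters are never shared
#' between the two encoders.
#'
#' @param drugs,targets Entity tables (either may be `NULL` to skip a
#'   side).
#' @param config A [run_config()].
#' @param epochs,batch_size,lr Overrides of `config$pretrain`.
#' @param seed Base seed; the drug and target stages use `seed + 1` and
#'   `seed + 2`.
#' @return A list with `pretrain_state` elements `drug` and/or `target`.
#' @export
pretrain_encoders <- function(drugs = NULL, targets = NULL,
                              config = run_config(),
                              epochs = config$pretrain$epochs,
                              batch_size = config$pretrain$batch_size,
                              lr = config$pretrain$lr,
                              seed = config$train$seed) {
  corp <- build_corpora(drugs, targets, window_config_from(config))
  out <- list()
  if (!is.null(corp$drug)) {
    out$drug <- pretrain_encoder(corp$drug,
                                 encoder_config_from(config, "drug"),
                                 epochs = epochs, batch_size = batch_size,
                                 lr = lr, seed = seed + 1L)
  }
  if (!is.null(corp$target)) {
    out$target <- pretrain_encoder(corp$target,
                                   encoder_config_from(config, "target"),
                                   epochs = epochs, batch_size = batch_size,
                                   lr = lr, seed = seed + 2L)
  }
  out
}

#' Fit the two-stage drug-target affinity model
#'
#' The main entry point. Takes labeled affinity records plus the drug and
#' target tables, holds out a random test fraction, trains the supervised
#' head (two shallow CNNs and the fully connected predictor, encoders
#' frozen) under mean squared error, selects the best epoch by validation
#' MSE, and evaluates concordance index and MSE on the held-out test set.
#'
#' When `pretrained` is `NULL` (or `config$ablation$no_pretrain` is set)
#' the encoders are randomly initialised and frozen — the no-pretraining
#' ablation. Pass the result of [pretrain_encoders()] to use pretrained
#' low-level features.
#'
#' @param affinities An `affinity_records` data frame (`drug_id`,
#'   `target_id`, `affinity`).
#' @param drugs Data frame with `id`, `smiles`.
#' @param targets Data frame with `id`, `sequence`.
#' @param pretrained Optional list with `pretrain_state` elements `drug`
#'   and `target`.
#' @param config A [run_config()].
#' @param test_fraction Held-out fraction (default from config, 0.2).
#' @param seed Seed for splitting, initialisation and shuffling (default
#'   from config).
#' @return An object of class `gindta` with components `bundle` (trained
#'   parameters), `history`, `split`, `test` (an `evaluation_result`),
#'   `predictions` (test-set data frame), `config`, `call`.
#' @seealso [predict.gindta()], [summary.gindta()], [plot.gindta()]
#' @export
gindta <- function(affinities, drugs, targets, pretrained = NULL,
                   config = run_config(),
                   test_fraction = config$train$test_fraction,
                   seed = config$train$seed) {
  cl <- match.call()
  stopifnot(nrow(affinities) >= 5L)
  check_ids(affinities, drugs, targets)
  if (config$ablation$no_pretrain) pretrained <- NULL
  bundle <- model_bundle(config,
                         drug_encoder = pretrained$drug,
                         target_encoder = pretrained$target,
                         seed = seed)
  n <- nrow(affinities)
  set.seed(seed)
  perm <- sample.int(n)
  n_test <- floor(test_fraction * n)
  test_idx <- if (n_test > 0L) sort(perm[seq_len(n_test)]) else integer(0)
  rest <- sort(perm[seq.int(n_test + 1L, n)])
  n_val <- floor(config$train$val_fraction * length(rest))
  val_idx <- if (n_val > 0L) sort(sample(rest, n_val)) else integer(0)
  train_idx <- setdiff(rest, val_idx)
  fit <- train_supervised(affinities, drugs, targets, bundle,
                          split = list(train = train_idx, val = val_idx),
                          seed = seed + 100L)
  preds_test <- NULL
  test_eval <- NULL
  if (length(test_idx) >= 2L) {
    yhat <- predict_records(test_idx, affinities, fit$feats,
                            list(dcnn = fit$bundle$drug_cnn$params,
                                 tcnn = fit$bundle$target_cnn$params,
                                 pred = fit$bundle$predictor$params),
                            fit$bundle)
    preds_test <- data.frame(
      drug_id = affinities$drug_id[test_idx],
      target_id = affinities$target_id[test_idx],
      y_true = affinities$affinity[test_idx], y_pred = yhat,
      stringsAsFactors = FALSE)
    test_eval <- tryCatch(
      evaluate_predictions(preds_test$y_true, preds_test$y_pred),
      error = function(e) NULL)
  }
  structure(
    list(bundle = fit$bundle, history = fit$history,
         best_epoch = fit$best_epoch,
         split = list(train = train_idx, val = val_idx, test = test_idx),
         records = affinities, drugs = drugs, targets = targets,
         feats = fit$feats, test = test_eval, predictions = preds_test,
         config = config, seed = seed, call = cl),
    class = "gindta"
  )
}

#' @export
print.gindta <- function(x, ...) {
  cat("Two-stage drug-target affinity model\n")
  cat(sprintf("  %d records (%d train / %d val / %d test), %d drugs, %d targets\n",
              nrow(x$records), length(x$split$train), length(x$split$val),
              length(x$split$test), length(unique(x$records$drug_id)),
              length(unique(x$records$target_id))))
  cat(sprintf("  encoders: %s; CNN: %s; best epoch %d/%d\n",
              if (inherits(x$bundle$drug_encoder, "pretrain_state"))
                "pretrained" else "random (no-pretrain)",
              x$bundle$drug_cnn$config$variant, x$best_epoch,
              nrow(x$history)))
  if (!is.null(x$test)) {
    cat(sprintf("  test: CI = %.3f, MSE = %.3f\n", x$test$ci, x$test$mse))
  }
  invisible(x)
}

#' Summarise a fitted affinity model
#' @param object A `gindta` model.
#' @param ... Unused.
#' @method summary gindta
#' @export
summary.gindta <- function(object, ...) {
  out <- list(
    n_records = nrow(object$records),
    split_sizes = lengths(object$split),
    n_parameters = count_params(coef(object)),
    best_epoch = object$best_epoch,
    history = object$history,
    test = object$test
  )
  class(out) <- "summary.gindta"
  out
}

#' @export
print.summary.gindta <- function(x, ...) {
  cat(sprintf("records: %d (train %d / val %d / test %d)\n", x$n_records,
              x$split_sizes[["train"]], x$split_sizes[["val"]],
              x$split_sizes[["test"]]))
  cat(sprintf("trainable parameters: %d; best epoch: %d\n",
              x$n_parameters, x$best_epoch))
  h <- utils::tail(x$history, 3L)
  cat("last epochs:\n")
  print(h, row.names = FALSE)
  if (!is.null(x$test)) { cat("held-out test: "); print(x$test) }
  invisible(x)
}

#' Trained parameters of the supervised head
#'
#' Returns the CNN and predictor parameter arrays (the components trained
#' in stage two; the frozen encoder parameters live in
#' `object$bundle$*_encoder$params`).
#'
#' @param object A `gindta` model.
#' @param ... Unused.
#' @method coef gindta
#' @export
coef.gindta <- function(object, ...) {
  list(drug_cnn = object$bundle$drug_cnn$params,
       target_cnn = object$bundle$target_cnn$params,
       predictor = object$bundle$predictor$params)
}

#' Predict affinities for drug-target pairs
#'
#' @param object A fitted `gindta` model.
#' @param newdata Optional data frame with `drug_id`, `target_id` (and
#'   optionally `affinity`); defaults to the held-out test pairs.
#' @param drugs,targets Entity tables for ids not seen at fit time.
#' @param ... Unused.
#' @return Data frame with `drug_id`, `target_id`, `y_pred` (and `y_true`
#'   when affinities are available).
#' @method predict gindta
#' @export
predict.gindta <- function(object, newdata = NULL, drugs = NULL,
                           targets = NULL, ...) {
  b <- object$bundle
  params <- list(dcnn = b$drug_cnn$params, tcnn = b$target_cnn$params,
                 pred = b$predictor$params)
  if (is.null(newdata)) {
    newdata <- object$records[object$split$test, , drop = FALSE]
  }
  drugs <- rbind(object$drugs[, c("id", "smiles")],
                 if (!is.null(drugs)) drugs[, c("id", "smiles")])
  targets <- rbind(object$targets[, c("id", "sequence")],
                   if (!is.null(targets)) targets[, c("id", "sequence")])
  drugs <- drugs[!duplicated(drugs$id), ]
  targets <- targets[!duplicated(targets$id), ]
  check_ids(newdata, drugs, targets)
  feats <- object$feats
  wcfg <- window_config_from(object$config)
  for (id in setdiff(unique(newdata$drug_id), names(feats$drug))) {
    feats$drug[[id]] <- extract_drug_features(
      drugs$smiles[match(id, drugs$id)], b$drug_encoder,
      n_rows = object$config$drug_rows, drug_id = id)$matrix
  }
  for (id in setdiff(unique(newdata$target_id), names(feats$target))) {
    feats$target[[id]] <- extract_target_features(
      targets$sequence[match(id, targets$id)], b$target_encoder,
      cfg = wcfg, target_id = id)$matrix
  }
  yhat <- predict_records(seq_len(nrow(newdata)), newdata, feats, params,
                          b)
  out <- data.frame(drug_id = newdata$drug_id,
                    target_id = newdata$target_id, y_pred = yhat,
                    stringsAsFactors = FALSE)
  if ("affinity" %in% names(newdata)) out$y_true <- newdata$affinity
  out
}

#' Residuals of a fitted affinity model
#'
#' Observed minus fitted affinity over the training records (or all
#' records with `which = "all"`).
#'
#' @param object A `gindta` model.
#' @param which `"train"`, `"test"` or `"all"`.
#' @param ... Unused.
#' @method residuals gindta
#' @export
residuals.gindta <- function(object, which = c("train", "test", "all"),
                             ...) {
  which <- match.arg(which)
  idx <- switch(which, train = object$split$train,
                test = object$split$test,
                all = seq_len(nrow(object$records)))
  b <- object$bundle
  yhat <- predict_records(idx, object$records, object$feats,
                          list(dcnn = b$drug_cnn$params,
                               tcnn = b$target_cnn$params,
                               pred = b$predictor$params), b)
  object$records$affinity[idx] - yhat
}

#' Simulate affinity observations from the fitted model
#'
#' Draws `nsim` replicates of the test-set affinities as model prediction
#' plus Gaussian noise with the training residual standard deviation.
#'
#' @param object A `gindta` model.
#' @param nsim Number of replicates.
#' @param seed Optional seed.
#' @param ... Unused.
#' @method simulate gindta
#' @export
simulate.gindta <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(object$predictions)) stop("model has no held-out test set")
  mu <- object$predictions$y_pred
  sd <- stats::sd(residuals(object, "train"))
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, sd)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot training history of a fitted affinity model
#'
#' Training and validation MSE per epoch (left axis) and validation CI
#' (right axis).
#'
#' @param x A `gindta` model.
#' @param ... Passed to [graphics::matplot()].
#' @method plot gindta
#' @export
plot.gindta <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_mse, h$val_mse), type = "l",
                    lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "MSE", ...)
  graphics::abline(v = x$best_epoch, lty = 3, col = "grey40")
  if (any(is.finite(h$val_ci))) {
    graphics::par(new = TRUE)
    graphics::plot(h$epoch, h$val_ci, type = "l", col = "steelblue",
                   axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
    graphics::axis(4)
    graphics::mtext("validation CI", side = 4, line = 2, cex = 0.8)
  }
  graphics::legend("topright", c("train MSE", "val MSE", "val CI"),
                   col = c("black", "firebrick", "steelblue"), lty = 1,
                   bty = "n", cex = 0.8)
  invisible(x)
}
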