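#' Assemble an untrained model bundle
#'
#' Collects the two (pretrained or randomly initialised) encoders with
#' freshly initialised CNNs and predictor under one configuration. The
#' encoders stay frozen during supervised training; only the CNNs and the
#' predictor are trained.
#'
#' @param config A [run_config()].
#' @param drug_encoder,target_encoder `pretrain_state` objects (or
#'   `list(config, params)`); when `NULL`, encoders are randomly
#'   initialised from the config seeds (the no-pretraining ablation).
#' @param seed Seed for CNN/predictor initialisation.
#' @return An object of class `model_bundle`.
#' @export
model_bundle <- function(config = run_config(), drug_encoder = NULL,
                         target_encoder = NULL, seed = config$train$seed) {
  stopifnot(inherits(config, "run_config"))
  decfg <- encoder_config_from(config, "drug")
  tecfg <- encoder_config_from(config, "target")
  if (is.null(drug_encoder)) {
    drug_encoder <- list(config = decfg, params = gin_init(decfg))
  }
  if (is.null(target_encoder)) {
    target_encoder <- list(config = tecfg, params = gin_init(tecfg))
  }
  stopifnot(identical(drug_encoder$config$kind, "drug"),
            identical(target_encoder$config$kind, "target"))
  dcnn_cfg <- cnn_config_from(config, "drug")
  tcnn_cfg <- cnn_config_from(config, "target")
  pred_cfg <- predictor_config(config$predictor$hidden,
                               config$predictor$activation)
  bundle <- list(
    config = config,
    drug_encoder = drug_encoder,
    target_encoder = target_encoder,
    drug_cnn = list(config = dcnn_cfg,
                    params = cnn_init(dcnn_cfg, seed = seed + 11L)),
    target_cnn = list(config = tcnn_cfg,
                      params = cnn_init(tcnn_cfg, seed = seed + 12L)),
    predictor = list(config = pred_cfg,
                     params = mlp_init(dcnn_cfg$out_dim + tcnn_cfg$out_dim,
                                       pred_cfg, seed = seed + 13L)),
    trained = FALSE
  )
  class(bundle) <- "model_bundle"
  bundle
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> %strained; cnn %s; predictor %s\n",
              if (x$trained) "" else "un", x$drug_cnn$config$variant,
              paste(x$predictor$config$hidden, collapse = "/")))
  invisible(x)
}

# Extract and cache low-level features for the unique entities referenced
# by a record table. Returns list(drug = named list of matrices, target =
# named list of matrices).
extract_feature_tables <- function(records, drugs, targets, bundle,
                                   verbose = FALSE) {
  wcfg <- window_config_from(bundle$config)
  n_rows <- bundle$config$drug_rows
  did <- unique(records$drug_id)
  tid <- unique(records$target_id)
  feat_d <- vector("list", length(did)); names(feat_d) <- did
  for (id in did) {
    smi <- drugs$smiles[match(id, drugs$id)]
    feat_d[[id]] <- extract_drug_features(smi, bundle$drug_encoder,
                                          n_rows = n_rows,
                                          drug_id = id)$matrix
  }
  if (verbose) gindta_log("extracted features for %d drugs", length(did))
  feat_t <- vector("list", length(tid)); names(feat_t) <- tid
  for (id in tid) {
    sq <- targets$sequence[match(id, targets$id)]
    feat_t[[id]] <- extract_target_features(sq, bundle$target_encoder,
                                            cfg = wcfg,
                                            target_id = id)$matrix
  }
  if (verbose) gindta_log("extracted features for %d targets", length(tid))
  list(drug = feat_d, target = feat_t)
}

# Per-embedding-column standardisation statistics over the real
# (non-padding) rows of a set of feature matrices. Padding rows are exactly
# zero and stay zero after normalisation, preserving the padding contract.
feature_norm_stats <- function(mats) {
  rows <- do.call(rbind, mats)
  real <- rowSums(abs(rows)) > 0
  rows <- rows[real, , drop = FALSE]
  mu <- colMeans(rows)
  sd <- apply(rows, 2L, stats::sd)
  sd[!is.finite(sd) | sd < 1e-8] <- 1
  list(mu = mu, sd = sd)
}

norm_apply <- function(mat, st) {
  if (is.null(st)) return(mat)
  real <- rowSums(abs(mat)) > 0
  out <- sweep(sweep(mat, 2L, st$mu, "-"), 2L, st$sd, "/")
  out[!real, ] <- 0
  out
}

# Forward the supervised head for a set of record indices.
head_forward <- function(idx, records, feats, params, bundle,
                         keep_cache = FALSE) {
  B <- length(idx)
  dcfg <- bundle$drug_cnn$config
  tcfg <- bundle$target_cnn$config
  nd <- bundle$norm$drug
  nt <- bundle$norm$target
  Xd <- cnn_batch_layout(lapply(feats$drug[records$drug_id[idx]],
                                norm_apply, st = nd), dcfg)
  Xt <- cnn_batch_layout(lapply(feats$target[records$target_id[idx]],
                                norm_apply, st = nt), tcfg)
  od <- cnn_forward_batch(Xd, params$dcnn, dcfg, B, keep_cache = keep_cache)
  ot <- cnn_forward_batch(Xt, params$tcnn, tcfg, B, keep_cache = keep_cache)
  P <- cbind(od$F, ot$F)
  om <- mlp_forward(P, params$pred, bundle$predictor$config)
  list(pred = as.vector(om$out), od = od, ot = ot, om = om, P = P, B = B)
}

predict_records <- function(idx, records, feats, params, bundle,
                            chunk = 64L) {
  out <- numeric(length(idx))
  for (s in seq.int(1L, length(idx), by = chunk)) {
    take <- s:min(s + chunk - 1L, length(idx))
    out[take] <- head_forward(idx[take], records, feats, params, bundle)$pred
  }
  out
}

#' Train the supervised stage of the model
#'
#' Trains the two CNNs and the predictor under mean squared error on the
#' training split with Adam; the encoders stay frozen. Per-epoch training
#' MSE and validation MSE/CI are recorded; the returned parameters are
#' those of the epoch with the lowest validation MSE (final epoch when no
#' validation split is available).
#'
#' @param records An `affinity_records` data frame.
#' @param drugs,targets Entity tables with columns `id` + `smiles` /
#'   `sequence`.
#' @param bundle A [model_bundle()].
#' @param split Optional list with integer row indices `train` and
#'   optionally `val`; by default all records train and
#'   `config$train$val_fraction` of them are carved out for validation.
#' @param epochs,batch_size,lr Training options (defaults from
#'   `bundle$config$train`).
#' @param seed Seed controlling the split and batch shuffling.
#' @param feats Optional precomputed feature tables from an earlier call
#'   (skips encoder re-extraction).
#' @return A list: `bundle` (trained), `history` (data frame with epoch,
#'   train_mse, val_mse, val_ci), `best_epoch`, `feats`.
#' @export
train_supervised <- function(records, drugs, targets, bundle, split = NULL,
                             epochs = bundle$config$train$epochs,
                             batch_size = bundle$config$train$batch_size,
                             lr = bundle$config$train$lr,
                             seed = bundle$config$train$seed,
                             feats = NULL) {
  stopifnot(inherits(bundle, "model_bundle"), nrow(records) >= 2L)
  check_ids(records, drugs, targets)
  if (is.null(feats)) {
    feats <- extract_feature_tables(records, drugs, targets, bundle)
  }
  set.seed(seed)
  n <- nrow(records)
  if (is.null(split)) {
    idx <- sample.int(n)
    n_val <- floor(bundle$config$train$val_fraction * n)
    split <- list(train = sort(idx[seq.int(n_val + 1L, n)]),
                  val = if (n_val > 0L) sort(idx[seq_len(n_val)]) else
                    integer(0))
  }
  if (length(split$train) == 0L) stop("empty training split")
  if (is.null(bundle$norm)) {
    tr <- split$train
    bundle$norm <- list(
      drug = feature_norm_stats(
        feats$drug[unique(records$drug_id[tr])]),
      target = feature_norm_stats(
        feats$target[unique(records$target_id[tr])]))
  }
  params <- list(dcnn = bundle$drug_cnn$params,
                 tcnn = bundle$target_cnn$params,
                 pred = bundle$predictor$params)
  opt <- adam_init(params, lr = lr)
  y <- records$affinity
  hist <- data.frame(epoch = seq_len(epochs), train_mse = NA_real_,
                     val_mse = NA_real_, val_ci = NA_real_)
  best <- list(val = Inf, params = params, epoch = 0L)
  has_val <- length(split$val %||% integer(0)) > 0L
  for (ep in seq_len(epochs)) {
    ord <- sample(split$train)
    ep_loss <- 0; ep_n <- 0L
    for (s in seq.int(1L, length(ord), by = batch_size)) {
      bt <- ord[s:min(s + batch_size - 1L, length(ord))]
      B <- length(bt)
      fw <- head_forward(bt, records, feats, params, bundle,
                         keep_cache = TRUE)
      resid <- fw$pred - y[bt]
      ep_loss <- ep_loss + sum(resid^2); ep_n <- ep_n + B
      dOut <- matrix(2 * resid / B, B, 1L)
      mb <- mlp_backward(dOut, fw$om, params$pred, bundle$predictor$config)
      dP <- mb$dX
      ddim <- bundle$drug_cnn$config$out_dim
      gd <- cnn_backward_batch(dP[, seq_len(ddim), drop = FALSE], fw$od,
                               params$dcnn, bundle$drug_cnn$config, B)
      gt <- cnn_backward_batch(dP[, -seq_len(ddim), drop = FALSE], fw$ot,
                               params$tcnn, bundle$target_cnn$config, B)
      st <- adam_step(params, list(dcnn = gd, tcnn = gt, pred = mb$grads),
                      opt)
      params <- st$params
      opt <- st$state
    }
    hist$train_mse[ep] <- ep_loss / ep_n
    if (has_val) {
      pv <- predict_records(split$val, records, feats, params, bundle)
      hist$val_mse[ep] <- mean_squared_error(y[split$val], pv)
      hist$val_ci[ep] <- tryCatch(concordance_index(y[split$val], pv),
                                  error = function(e) NA_real_)
      if (hist$val_mse[ep] < best$val) {
        best <- list(val = hist$val_mse[ep], params = params, epoch = ep)
      }
    }
  }
  if (!has_val || best$epoch == 0L) {
    best <- list(val = NA_real_, params = params, epoch = epochs)
  }
  bundle$drug_cnn$params <- best$params$dcnn
  bundle$target_cnn$params <- best$params$tcnn
  bundle$predictor$params <- best$params$pred
  bundle$trained <- TRUE
  list(bundle = bundle, history = hist, best_epoch = best$epoch,
       split = split, feats = feats)
}
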