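#' Full pipeline configuration
#'
#' Collects every tunable of the two-stage pipeline with the published
#' architecture as defaults: GIN encoders with 5 graph convolutional layers
#' and hidden size 60 (drug vocabulary 62 tokens, target vocabulary 25),
#' K = 64 overlapping windows of 64 residues per target, 64 atom rows per
#' drug, CNNs with 32/64/128 filters and kernel sizes 5/5/3, predictor
#' hidden sizes 512/128/1. Ablation switches: `no_pretrain` (randomly
#' initialised, frozen encoders) and `use_1d_cnn` (convolution along the
#' fragment/atom axis only).
#'
#' @param window,drug_encoder,target_encoder,drug_cnn,target_cnn,predictor,
#'   pretrain,train,ablation Named lists overriding individual defaults.
#' @param drug_rows Fixed drug feature row count (default 64).
#' @return An object of class `run_config` (a nested list).
#' @export
run_config <- function(window = list(), drug_encoder = list(),
                       target_encoder = list(), drug_cnn = list(),
                       target_cnn = list(), predictor = list(),
                       pretrain = list(), train = list(),
                       ablation = list(), drug_rows = 64L) {
  merge1 <- function(defaults, over) {
    stopifnot(all(names(over) %in% names(defaults)))
    utils::modifyList(defaults, over)
  }
  cfg <- list(
    window = merge1(list(window_length = 64L, k_fragments = 64L,
                         min_fragment_length = 8L), window),
    drug_encoder = merge1(list(n_layers = 5L, hidden_size = 60L,
                               activation = "relu", epsilon = 0,
                               readout_layers = "final", seed = 101L),
                          drug_encoder),
    target_encoder = merge1(list(n_layers = 5L, hidden_size = 60L,
                                 activation = "relu", epsilon = 0,
                                 readout_layers = "final", seed = 102L),
                            target_encoder),
    drug_cnn = merge1(list(n_layers = 3L, filters = c(32L, 64L, 128L),
                           kernels = c(5L, 5L, 3L), pool = c(4L, 2L, 1L)),
                      drug_cnn),
    target_cnn = merge1(list(n_layers = 3L, filters = c(32L, 64L, 128L),
                             kernels = c(5L, 5L, 3L), pool = c(4L, 2L, 1L)),
                        target_cnn),
    predictor = merge1(list(hidden = c(512L, 128L, 1L),
                            activation = "relu"), predictor),
    drug_rows = as.integer(drug_rows),
    pretrain = merge1(list(epochs = 30L, batch_size = 32L, lr = 1e-3),
                      pretrain),
    train = merge1(list(epochs = 30L, batch_size = 32L, lr = 1e-3,
                        test_fraction = 0.2, val_fraction = 0.1,
                        seed = 1L), train),
    ablation = merge1(list(no_pretrain = FALSE, use_1d_cnn = FALSE),
                      ablation)
  )
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  window: l=%d K=%d min=%d; drug_rows=%d\n",
              x$window$window_length, x$window$k_fragments,
              x$window$min_fragment_length, x$drug_rows))
  cat(sprintf("  encoders: %d layers, hidden %d\n",
              x$drug_encoder$n_layers, x$drug_encoder$hidden_size))
  cat(sprintf("  cnn: filters %s kernels %s pool %s%s\n",
              paste(x$drug_cnn$filters, collapse = "/"),
              paste(x$drug_cnn$kernels, collapse = "/"),
              paste(x$drug_cnn$pool, collapse = "/"),
              if (x$ablation$use_1d_cnn) " (1D)" else ""))
  cat(sprintf("  predictor: %s\n", paste(x$predictor$hidden, collapse = "/")))
  cat(sprintf("  train: epochs=%d batch=%d lr=%g seed=%d%s\n",
              x$train$epochs, x$train$batch_size, x$train$lr, x$train$seed,
              if (x$ablation$no_pretrain) " (no pretrain)" else ""))
  invisible(x)
}

#' Write a run configuration to a YAML file
#' @param cfg A [run_config()].
#' @param path Output path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a run configuration from a YAML file
#' @param path YAML path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(raw), c(known, "drug_rows"))
  if (length(extra)) stop("unknown config fields: ",
                          paste(extra, collapse = ", "), " in ", path)
  do.call(run_config, raw)
}

# Build typed sub-configs from the flat run_config lists.
encoder_config_from <- function(cfg, kind) {
  e <- cfg[[paste0(kind, "_encoder")]]
  encoder_config(kind = kind, n_layers = e$n_layers,
                 hidden_size = e$hidden_size, activation = e$activation,
                 epsilon = e$epsilon, readout_layers = e$readout_layers,
                 seed = e$seed)
}

window_config_from <- function(cfg) {
  w <- cfg$window
  window_config(w$window_length, w$k_fragments, w$min_fragment_length)
}

cnn_config_from <- function(cfg, side = c("drug", "target")) {
  side <- match.arg(side)
  cc <- cfg[[paste0(side, "_cnn")]]
  enc <- cfg[[paste0(side, "_encoder")]]
  emb <- if (identical(enc$readout_layers, "concat")) {
    enc$n_layers * enc$hidden_size
  } else enc$hidden_size
  rows <- if (side == "drug") cfg$drug_rows else cfg$window$k_fragments
  cnn_config(n_layers = cc$n_layers, filters = cc$filters,
             kernels = cc$kernels, pool = cc$pool,
             variant = if (cfg$ablation$use_1d_cnn) "1d" else "2d",
             input_rows = rows, input_cols = emb)
}
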