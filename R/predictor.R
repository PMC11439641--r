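#' Configuration of the affinity predictor head
#'
#' A fully connected network applied to the concatenated drug/target
#' high-level feature vector. Defaults follow the published architecture:
#' hidden sizes 512, 128, 1 with ReLU between hidden layers and a linear
#' scalar output.
#'
#' @param hidden Integer vector of layer sizes; the last entry must be 1.
#' @param activation Hidden activation name (default `"relu"`).
#' @return An object of class `predictor_config`.
#' @export
predictor_config <- function(hidden = c(512L, 128L, 1L),
                             activation = "relu") {
  hidden <- as.integer(hidden)
  stopifnot(length(hidden) >= 1L, hidden[length(hidden)] == 1L)
  structure(list(hidden = hidden, activation = activation),
            class = "predictor_config")
}

#' @export
print.predictor_config <- function(x, ...) {
  cat(sprintf("<predictor_config> sizes=%s act=%s\n",
              paste(x$hidden, collapse = "/"), x$activation))
  invisible(x)
}

#' Initialise predictor parameters
#'
#' @param input_dim Length of the pair feature vector (e.g. 256).
#' @param cfg A [predictor_config()].
#' @param seed Integer seed.
#' @return List `$layers[[i]]` with `W`, `b`.
#' @export
mlp_init <- function(input_dim, cfg, seed = 1L) {
  stopifnot(inherits(cfg, "predictor_config"))
  set.seed(seed)
  sizes <- c(as.integer(input_dim), cfg$hidden)
  layers <- vector("list", length(cfg$hidden))
  for (i in seq_along(cfg$hidden)) {
    layers[[i]] <- list(W = glorot(sizes[i], sizes[i + 1L]),
                        b = numeric(sizes[i + 1L]))
  }
  list(layers = layers)
}

mlp_forward <- function(X, params, cfg) {
  L <- length(params$layers)
  act <- activation_fun(cfg$activation)
  cache <- vector("list", L)
  H <- X
  for (i in seq_len(L)) {
    p <- params$layers[[i]]
    Z <- sweep(H %*% p$W, 2L, p$b, "+")
    cache[[i]] <- list(H_in = H, Z = Z)
    H <- if (i < L) act(Z) else Z   # linear output layer
  }
  list(out = H, cache = cache)
}

mlp_backward <- function(dOut, fw, params, cfg) {
  L <- length(params$layers)
  agrad <- activation_grad(cfg$activation)
  grads <- list(layers = vector("list", L))
  dH <- dOut
  for (i in rev(seq_len(L))) {
    cc <- fw$cache[[i]]
    dZ <- if (i < L) dH * agrad(cc$Z) else dH
    grads$layers[[i]] <- list(W = crossprod(cc$H_in, dZ), b = colSums(dZ))
    dH <- dZ %*% t(params$layers[[i]]$W)
  }
  list(grads = grads, dX = dH)
}

#' Concatenate drug and target high-level features into a pair vector
#'
#' Drug features first, then target features.
#'
#' @param drug_vec,target_vec Numeric vectors.
#' @return Numeric vector of length `length(drug_vec) + length(target_vec)`.
#' @export
concat_pair <- function(drug_vec, target_vec) {
  if (is.null(drug_vec) || is.null(target_vec) ||
      length(drug_vec) == 0L || length(target_vec) == 0L) {
    stop("both drug and target feature vectors are required")
  }
  c(drug_vec, target_vec)
}

#' Predict affinity from a pair feature vector
#'
#' Applies the fully connected predictor (default 512 -> 128 -> 1, ReLU
#' between hidden layers, linear output).
#'
#' @param pair_vec Numeric pair feature vector.
#' @param predictor A list with `config` (a [predictor_config()]) and
#'   `params` (from [mlp_init()]).
#' @return A single numeric affinity score.
#' @export
predict_affinity <- function(pair_vec, predictor) {
  expected <- nrow(predictor$params$layers[[1L]]$W)
  if (length(pair_vec) != expected) {
    stop(sprintf("pair vector length mismatch: expected %d, got %d",
                 expected, length(pair_vec)))
  }
  as.numeric(mlp_forward(matrix(pair_vec, 1L), predictor$params,
                         predictor$config)$out)
}
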