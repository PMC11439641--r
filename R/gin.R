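#' Configuration of a GIN encoder
#'
#' A graph isomorphism network: each layer aggregates a node's neighbours by
#' summation, adds the node's own state weighted by `(1 + epsilon)`, and
#' passes the result through a two-layer perceptron. The whole-graph
#' embedding is the activation of the mean over node embeddings (mean
#' readout). Defaults follow the published architecture: 5 graph
#' convolutional layers, hidden size 60.
#'
#' @param kind `"drug"` or `"target"`; fixes the input one-hot width to the
#'   matching vocabulary size (62 or 25).
#' @param n_layers Number of graph convolutional layers (default 5).
#' @param hidden_size Width d of every hidden layer and of the embeddings
#'   (default 60).
#' @param activation Activation name for the readout and layer perceptrons
#'   (`"relu"`).
#' @param epsilon GIN self-loop weight offset, fixed (non-learnable),
#'   default 0.
#' @param readout_layers `"final"` uses the last layer's node embeddings for
#'   readout; `"concat"` concatenates every layer's readout (embedding
#'   length becomes `n_layers * hidden_size`).
#' @param seed Integer seed used when initialising parameters.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(kind = c("drug", "target"), n_layers = 5L,
                           hidden_size = 60L, activation = "relu",
                           epsilon = 0, readout_layers = c("final", "concat"),
                           seed = 1L) {
  kind <- match.arg(kind)
  readout_layers <- match.arg(readout_layers)
  n_layers <- as.integer(n_layers)
  hidden_size <- as.integer(hidden_size)
  stopifnot(n_layers >= 1L, hidden_size >= 1L)
  vocab_size <- if (kind == "drug") 62L else 25L
  emb_dim <- if (readout_layers == "concat") n_layers * hidden_size else
    hidden_size
  structure(
    list(kind = kind, n_layers = n_layers, hidden_size = hidden_size,
         activation = activation, epsilon = epsilon, readout = "mean",
         readout_layers = readout_layers, vocab_size = vocab_size,
         emb_dim = emb_dim, seed = as.integer(seed)),
    class = "encoder_config"
  )
}

#' @export
print.encoder_config <- function(x, ...) {
  cat(sprintf(
    "<encoder_config> kind=%s layers=%d d=%d act=%s eps=%g readout=%s/%s\n",
    x$kind, x$n_layers, x$hidden_size, x$activation, x$epsilon, x$readout,
    x$readout_layers))
  invisible(x)
}

#' Initialise GIN encoder parameters
#'
#' Glorot-uniform weights, zero biases; each layer holds a two-layer
#' perceptron (`W1`, `b1`, `W2`, `b2`). Seeded by `cfg$seed` unless
#' overridden.
#'
#' @param cfg An [encoder_config()].
#' @param seed Optional seed overriding `cfg$seed`.
#' @return A parameter list: `$layers[[i]]` with `W1`, `b1`, `W2`, `b2`.
#' @export
gin_init <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "encoder_config"))
  set.seed(seed)
  d <- cfg$hidden_size
  layers <- vector("list", cfg$n_layers)
  d_in <- cfg$vocab_size
  for (i in seq_len(cfg$n_layers)) {
    layers[[i]] <- list(
      W1 = glorot(d_in, d), b1 = numeric(d),
      W2 = glorot(d, d), b2 = numeric(d)
    )
    d_in <- d
  }
  list(layers = layers)
}

# Forward pass with cache for backprop.
gin_forward_cache <- function(graph, cfg, params) {
  if (graph$n_nodes == 0L) stop("empty graph")
  act <- activation_fun(cfg$activation)
  A <- graph_adjacency(graph)
  H <- graph_onehot(graph, cfg$vocab_size)
  eps <- cfg$epsilon
  L <- cfg$n_layers
  cache <- vector("list", L)
  layer_H <- vector("list", L)
  for (i in seq_len(L)) {
    p <- params$layers[[i]]
    M <- (1 + eps) * H + A %*% H
    Z1 <- sweep(M %*% p$W1, 2L, p$b1, "+")
    H1 <- relu(Z1)
    Z2 <- sweep(H1 %*% p$W2, 2L, p$b2, "+")
    Hn <- relu(Z2)
    cache[[i]] <- list(H_in = H, M = M, Z1 = Z1, H1 = H1, Z2 = Z2)
    H <- Hn
    layer_H[[i]] <- Hn
  }
  if (cfg$readout_layers == "concat") {
    node_emb <- do.call(cbind, layer_H)
    m <- unlist(lapply(layer_H, colMeans), use.names = FALSE)
  } else {
    node_emb <- H
    m <- colMeans(H)
  }
  graph_emb <- act(m)
  list(node_embeddings = node_emb, graph_embedding = graph_emb,
       cache = list(layers = cache, layer_H = layer_H, A = A, m = m,
                    n = graph$n_nodes))
}

#' GIN encoder forward pass
#'
#' Computes per-node embeddings after `cfg$n_layers` GIN updates and the
#' whole-graph embedding, which is the activation of the node-embedding row
#' mean. Sum aggregation makes both invariant to node-order permutation.
#'
#' @param graph A `molecular_graph`.
#' @param cfg An [encoder_config()].
#' @param params Parameters from [gin_init()] or a pretrained encoder.
#' @return A list with `node_embeddings` (one row per node) and
#'   `graph_embedding` (numeric vector).
#' @export
gin_forward <- function(graph, cfg, params) {
  out <- gin_forward_cache(graph, cfg, params)
  list(node_embeddings = out$node_embeddings,
       graph_embedding = out$graph_embedding)
}

# Backward pass: given gradients w.r.t. node embeddings (dNode) and the
# graph embedding (dGraph), accumulate parameter gradients.
gin_backward <- function(cfg, params, fwd, dNode, dGraph) {
  cache <- fwd$cache
  L <- cfg$n_layers
  d <- cfg$hidden_size
  n <- cache$n
  agrad <- activation_grad(cfg$activation)
  dm <- dGraph * agrad(cache$m)
  grads <- list(layers = vector("list", L))
  eps <- cfg$epsilon
  A <- cache$A
  if (cfg$readout_layers == "concat") {
    dH_next <- matrix(0, n, d)
  } else {
    dH_next <- dNode + matrix(dm / n, n, d, byrow = TRUE)
  }
  for (i in rev(seq_len(L))) {
    cc <- cache$layers[[i]]
    p <- params$layers[[i]]
    dH <- dH_next
    if (cfg$readout_layers == "concat") {
      cols <- ((i - 1L) * d + 1L):(i * d)
      dH <- dH + dNode[, cols, drop = FALSE] +
        matrix(dm[cols] / n, n, d, byrow = TRUE)
    }
    dZ2 <- dH * drelu(cc$Z2)
    dW2 <- crossprod(cc$H1, dZ2)
    db2 <- colSums(dZ2)
    dH1 <- dZ2 %*% t(p$W2)
    dZ1 <- dH1 * drelu(cc$Z1)
    dW1 <- crossprod(cc$M, dZ1)
    db1 <- colSums(dZ1)
    dM <- dZ1 %*% t(p$W1)
    dH_next <- (1 + eps) * dM + A %*% dM
    grads$layers[[i]] <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
  }
  grads
}
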