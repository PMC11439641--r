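#' Initialise the bilinear InfoGraph discriminator
#'
#' Scores a (node embedding, graph embedding) pair as `t(h_n) %*% W %*% H_g`.
#' The bilinear form is the canonical discriminator for node-graph mutual
#' information maximisation.
#'
#' @param emb_dim Embedding dimension (`cfg$emb_dim` of the encoder).
#' @return A list with weight matrix `W` (`emb_dim x emb_dim`).
#' @export
discriminator_init <- function(emb_dim) {
  list(W = glorot(emb_dim, emb_dim))
}

# Core Jensen-Shannon MI objective with gradients.
# Hn: stacked node embeddings (N x D); gid: graph index per node (1..G);
# Hg: graph embeddings (G x D); W: discriminator weight.
# loss = mean_pos softplus(-T) + mean_neg softplus(T), positives pair each
# node with its own graph, negatives pair each node with every other graph.
jsd_mi_core <- function(Hn, gid, Hg, W, want_grads = TRUE) {
  G <- nrow(Hg)
  if (G < 2L) stop("need at least 2 graphs in a batch (no negatives)")
  N <- nrow(Hn)
  HgW <- Hg %*% t(W)              # G x D, rows: W %*% H_g
  S <- Hn %*% t(HgW)              # N x G scores
  pos <- cbind(seq_len(N), gid)
  posmask <- matrix(FALSE, N, G)
  posmask[pos] <- TRUE
  n_pos <- N
  n_neg <- N * (G - 1L)
  loss <- sum(softplus(-S[posmask])) / n_pos +
    sum(softplus(S[!posmask])) / n_neg
  if (!want_grads) return(list(loss = loss))
  dS <- sigmoid(S) / n_neg
  dS[posmask] <- -sigmoid(-S[posmask]) / n_pos
  dHn <- dS %*% HgW
  dHg <- crossprod(dS, Hn) %*% W
  dW <- crossprod(crossprod(dS, Hn), Hg)  # t(Hn %*% ... ) -> D x D
  list(loss = loss, dS = dS, dHn = dHn, dHg = dHg, dW = dW)
}

#' Jensen-Shannon mutual-information loss for a batch of graphs
#'
#' Positive pairs are each node with its own graph embedding; negative pairs
#' are each node with every other graph embedding in the batch. With a zero
#' discriminator every score is 0 and the loss equals `2 * log(2)`.
#'
#' @param node_embeddings A list with one node-embedding matrix per graph.
#' @param graph_embeddings Matrix with one row per graph (same order).
#' @param discriminator A list with bilinear weight `W`
#'   (see [discriminator_init()]).
#' @return The scalar loss.
#' @examples
#' d <- 4
#' ne <- list(matrix(rnorm(8), 2), matrix(rnorm(4), 1))
#' ge <- matrix(rnorm(8), 2)
#' jsd_mi_loss(ne, ge, list(W = matrix(0, d, d))) # 2 * log(2)
#' @export
jsd_mi_loss <- function(node_embeddings, graph_embeddings, discriminator) {
  stopifnot(is.list(node_embeddings))
  if (length(node_embeddings) < 2L) {
    stop("need at least 2 graphs in a batch (no negatives)")
  }
  if (is.list(graph_embeddings)) {
    graph_embeddings <- do.call(rbind, graph_embeddings)
  }
  Hn <- do.call(rbind, node_embeddings)
  gid <- rep(seq_along(node_embeddings),
             vapply(node_embeddings, nrow, integer(1)))
  jsd_mi_core(Hn, gid, graph_embeddings, discriminator$W,
              want_grads = FALSE)$loss
}

#' Pretrain a GIN encoder with the InfoGraph objective
#'
#' Maximises Jensen-Shannon mutual information between node embeddings and
#' whole-graph embeddings over an unlabeled graph corpus. Encoder and
#' discriminator are trained jointly with Adam; the discriminator is
#' discarded downstream (only the encoder is reused for feature
#' extraction). Fully seeded: the same seed reproduces the loss history
#' bit-for-bit.
#'
#' @param graphs A list of `molecular_graph` objects (at least 2).
#' @param cfg An [encoder_config()] matching the graphs' vocabulary.
#' @param epochs Number of passes over the corpus (default 30).
#' @param batch_size Minibatch size in graphs (default 32). Negative pairs
#'   are drawn within the minibatch; a trailing singleton batch is merged
#'   into its predecessor.
#' @param lr Adam learning rate (default 1e-3).
#' @param seed Integer seed for initialisation and shuffling.
#' @return An object of class `pretrain_state`: `params` (encoder),
#'   `discriminator`, `config`, `loss_history` (one mean loss per epoch),
#'   `epochs`, `seed`.
#' @export
pretrain_encoder <- function(graphs, cfg, epochs = 30L, batch_size = 32L,
                             lr = 1e-3, seed = 1L) {
  stopifnot(inherits(cfg, "encoder_config"))
  if (!is.list(graphs) || length(graphs) < 2L) {
    stop("pretraining corpus must contain at least 2 graphs")
  }
  n <- length(graphs)
  params <- gin_init(cfg, seed = seed)  # seeds the RNG stream
  disc <- discriminator_init(cfg$emb_dim)
  all_params <- list(enc = params, disc = disc)
  opt <- adam_init(all_params, lr = lr)
  loss_history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq.int(1L, n, by = batch_size)
    batches <- lapply(starts, function(s) ord[s:min(s + batch_size - 1L, n)])
    nb <- length(batches)
    if (nb > 1L && length(batches[[nb]]) < 2L) {
      batches[[nb - 1L]] <- c(batches[[nb - 1L]], batches[[nb]])
      batches[[nb]] <- NULL
    }
    ep_loss <- 0
    for (bt in batches) {
      fwd <- lapply(graphs[bt], gin_forward_cache, cfg = cfg,
                    params = all_params$enc)
      Hn <- do.call(rbind, lapply(fwd, `[[`, "node_embeddings"))
      Hg <- do.call(rbind, lapply(fwd, `[[`, "graph_embedding"))
      gid <- rep(seq_along(fwd),
                 vapply(fwd, function(f) nrow(f$node_embeddings), integer(1)))
      res <- jsd_mi_core(Hn, gid, Hg, all_params$disc$W)
      # backprop through each graph's encoder pass
      enc_grads <- NULL
      row0 <- 0L
      for (gi in seq_along(fwd)) {
        nn <- nrow(fwd[[gi]]$node_embeddings)
        g <- gin_backward(cfg, all_params$enc, fwd[[gi]],
                          res$dHn[row0 + seq_len(nn), , drop = FALSE],
                          res$dHg[gi, ])
        enc_grads <- if (is.null(enc_grads)) g else
          map2_params(enc_grads, g, `+`)
        row0 <- row0 + nn
      }
      grads <- list(enc = enc_grads, disc = list(W = res$dW))
      st <- adam_step(all_params, grads, opt)
      all_params <- st$params
      opt <- st$state
      ep_loss <- ep_loss + res$loss
    }
    loss_history[ep] <- ep_loss / length(batches)
  }
  structure(
    list(params = all_params$enc, discriminator = all_params$disc,
         config = cfg, loss_history = loss_history,
         epochs = as.integer(epochs), seed = as.integer(seed)),
    class = "pretrain_state"
  )
}

#' @export
print.pretrain_state <- function(x, ...) {
  cat(sprintf(
    "<pretrain_state> kind=%s epochs=%d loss %.4f -> %.4f\n",
    x$config$kind, x$epochs,
    if (x$epochs) x$loss_history[1] else NA_real_,
    if (x$epochs) x$loss_history[x$epochs] else NA_real_))
  invisible(x)
}
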