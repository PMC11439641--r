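#' Extract the fixed-size low-level feature matrix of a target
#'
#' Segments the sequence into exactly K overlapping windows, builds a
#' residue chain graph per window, and stacks the K whole-graph embeddings
#' (in window order) into a `K x d` matrix. Padding windows (emitted when
#' the sequence is shorter than the window length) contribute all-zero rows.
#'
#' @param sequence Amino-acid string.
#' @param encoder A `pretrain_state`, or a list with elements `config`
#'   (an [encoder_config()]) and `params` (e.g. a randomly initialised
#'   encoder for the no-pretraining ablation).
#' @param cfg A [window_config()].
#' @param target_id Identifier stored on the result.
#' @return An object of class `target_features`: `matrix` (`K x d`),
#'   `padding` (logical vector of padding rows), `target_id`.
#' @export
extract_target_features <- function(sequence, encoder,
                                    cfg = window_config(),
                                    target_id = "") {
  stopifnot(!is.null(encoder$config), !is.null(encoder$params))
  ecfg <- encoder$config
  stopifnot(ecfg$kind == "target")
  fs <- segment_overlapping(sequence, cfg, parent_id = target_id)
  K <- cfg$k_fragments
  mat <- matrix(0, K, ecfg$emb_dim)
  padding <- vapply(fs$fragments, function(f) f$is_padding, logical(1))
  vocab <- token_vocabulary("target")
  for (i in seq_len(K)) {
    if (padding[i]) next
    g <- build_fragment_graph(fs$fragments[[i]], vocab)
    mat[i, ] <- gin_forward(g, ecfg, encoder$params)$graph_embedding
  }
  structure(
    list(matrix = mat, padding = padding, target_id = target_id),
    class = "target_features"
  )
}

#' Extract the fixed-size low-level feature matrix of a drug
#'
#' Builds the canonical atom graph, runs the drug encoder, and stacks the
#' per-atom node embeddings in canonical atom order. The matrix is fixed at
#' `n_rows` rows (default 64): molecules with fewer heavy atoms are
#' zero-padded, larger molecules are truncated to their first `n_rows`
#' atoms in canonical order (logged).
#'
#' @param smiles A single SMILES string.
#' @param encoder A `pretrain_state` (or `list(config, params)`) of kind
#'   `"drug"`.
#' @param n_rows Fixed row count of the output matrix (default 64).
#' @param drug_id Identifier stored on the result.
#' @return An object of class `drug_features`: `matrix` (`n_rows x d`),
#'   `n_real` (number of non-padding rows), `drug_id`.
#' @export
extract_drug_features <- function(smiles, encoder, n_rows = 64L,
                                  drug_id = smiles) {
  stopifnot(!is.null(encoder$config), !is.null(encoder$params))
  ecfg <- encoder$config
  stopifnot(ecfg$kind == "drug")
  g <- build_drug_graph(smiles, source_id = drug_id)
  emb <- gin_forward(g, ecfg, encoder$params)$node_embeddings
  n <- nrow(emb)
  if (n > n_rows) {
    gindta_log("drug %s: %d atoms truncated to %d rows", drug_id, n, n_rows)
    emb <- emb[seq_len(n_rows), , drop = FALSE]
    n <- n_rows
  }
  mat <- matrix(0, n_rows, ecfg$emb_dim)
  mat[seq_len(n), ] <- emb
  structure(
    list(matrix = mat, n_real = n, drug_id = drug_id),
    class = "drug_features"
  )
}

#' @export
print.target_features <- function(x, ...) {
  cat(sprintf("<target_features> %s %dx%d (%d padding rows)\n", x$target_id,
              nrow(x$matrix), ncol(x$matrix), sum(x$padding)))
  invisible(x)
}

#' @export
print.drug_features <- function(x, ...) {
  cat(sprintf("<drug_features> %s %dx%d (%d real rows)\n", x$drug_id,
              nrow(x$matrix), ncol(x$matrix), x$n_real))
  invisible(x)
}
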