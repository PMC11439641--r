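# Shallow 2D (or 1D) convolutional feature extractors.
#
# Internal tensor layout: a minibatch of B single-"image" inputs of spatial
# size H x W with C channels is a matrix with (H*W*B) rows (position index
# fastest, column-major in (row, col), then batch) and C columns (channels).
# Convolutions are evaluated as one dense matrix product per layer via an
# im2col gather with precomputed row selectors, which keeps the training
# loop inside BLAS.

#' Configuration of a shallow CNN feature extractor
#'
#' Defaults follow the published architecture: 3 convolutional layers with
#' 32/64/128 filters and kernel sizes 5/5/3 (stride 1, zero "same"
#' padding), each followed by a ReLU. Max pooling of size `pool[i]` follows
#' layer i (1 = none); a global max pool over the remaining positions
#' yields the high-level feature vector of length `filters[n_layers]`.
#' `variant = "1d"` convolves along the row axis only, reading the d
#' embedding columns as input channels (the 1D-CNN ablation).
#'
#' @param n_layers Number of conv layers (default 3).
#' @param filters Integer vector of filter counts per layer.
#' @param kernels Integer vector of (odd) kernel sizes per layer.
#' @param pool Integer vector of max-pool sizes applied after each layer
#'   (default `c(4, 2, 1)`; use `c(1, 1, 1)` for global-pool-only).
#' @param variant `"2d"` (default) or `"1d"`.
#' @param input_rows,input_cols Shape of the low-level feature matrix this
#'   CNN consumes (64 rows; columns = embedding width d, default 60).
#' @return An object of class `cnn_config` with a precomputed per-layer
#'   geometry table.
#' @export
cnn_config <- function(n_layers = 3L, filters = c(32L, 64L, 128L),
                       kernels = c(5L, 5L, 3L), pool = c(4L, 2L, 1L),
                       variant = c("2d", "1d"),
                       input_rows = 64L, input_cols = 60L) {
  variant <- match.arg(variant)
  n_layers <- as.integer(n_layers)
  filters <- as.integer(filters); kernels <- as.integer(kernels)
  pool <- as.integer(pool)
  stopifnot(length(filters) == n_layers, length(kernels) == n_layers,
            length(pool) == n_layers, all(kernels %% 2L == 1L),
            all(pool >= 1L))
  if (variant == "2d") {
    H <- as.integer(input_rows); W <- as.integer(input_cols); C <- 1L
  } else {
    H <- as.integer(input_rows); W <- 1L; C <- as.integer(input_cols)
  }
  geom <- vector("list", n_layers)
  for (i in seq_len(n_layers)) {
    kh <- kernels[i]
    kw <- if (variant == "2d") kernels[i] else 1L
    geom[[i]] <- list(H = H, W = W, Cin = C, Cout = filters[i],
                      kh = kh, kw = kw, pool = pool[i])
    H <- H %/% pool[i]
    W <- if (variant == "2d") max(1L, W %/% pool[i]) else W
    C <- filters[i]
    stopifnot(H >= 1L, W >= 1L)
  }
  structure(
    list(n_layers = n_layers, filters = filters, kernels = kernels,
         pool = pool, variant = variant,
         input_rows = as.integer(input_rows),
         input_cols = as.integer(input_cols),
         out_dim = filters[n_layers], geom = geom,
         final_positions = H * W),
    class = "cnn_config"
  )
}

#' @export
print.cnn_config <- function(x, ...) {
  cat(sprintf(
    "<cnn_config> %s layers=%d filters=%s kernels=%s pool=%s in=%dx%d out=%d\n",
    x$variant, x$n_layers, paste(x$filters, collapse = "/"),
    paste(x$kernels, collapse = "/"), paste(x$pool, collapse = "/"),
    x$input_rows, x$input_cols, x$out_dim))
  invisible(x)
}

#' Initialise CNN parameters
#'
#' @param cfg A [cnn_config()].
#' @param seed Integer seed.
#' @return List `$layers[[i]]` with weight `W` (`kh*kw*Cin x Cout`, patch
#'   element-major row order) and bias `b`.
#' @export
cnn_init <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "cnn_config"))
  set.seed(seed)
  layers <- vector("list", cfg$n_layers)
  for (i in seq_len(cfg$n_layers)) {
    g <- cfg$geom[[i]]
    fan_in <- g$kh * g$kw * g$Cin
    layers[[i]] <- list(W = glorot(fan_in, g$Cout), b = numeric(g$Cout))
  }
  list(layers = layers)
}

# Memoised selector tables (deterministic functions of layer geometry and
# batch size; rebuilt lazily per session).
.sel_cache <- new.env(parent = emptyenv())

# Row selectors for the im2col gather of one layer at batch size B.
# Returns list(padrows, rowsel = list per patch element k, Hp, Wp).
conv_selectors <- function(g, B) {
  key <- paste("c", g$H, g$W, g$Cin, g$kh, g$kw, B, sep = "_")
  hit <- .sel_cache[[key]]
  if (!is.null(hit)) return(hit)
  .sel_cache[[key]] <- conv_selectors_build(g, B)
}

conv_selectors_build <- function(g, B) {
  ph <- (g$kh - 1L) %/% 2L
  pw <- (g$kw - 1L) %/% 2L
  Hp <- g$H + 2L * ph
  Wp <- g$W + 2L * pw
  npos <- g$H * g$W
  boff <- rep((seq_len(B) - 1L) * (Hp * Wp), each = npos)
  base <- as.vector(outer(seq_len(g$H) - 1L + ph,
                          (seq_len(g$W) - 1L + pw) * Hp, "+"))
  padrows <- rep(base, B) + boff + 1L
  rowsel <- vector("list", g$kh * g$kw)
  k <- 0L
  for (v in seq_len(g$kw) - 1L) {
    for (u in seq_len(g$kh) - 1L) {
      k <- k + 1L
      bk <- as.vector(outer(seq_len(g$H) - 1L + u,
                            (seq_len(g$W) - 1L + v) * Hp, "+"))
      rowsel[[k]] <- rep(bk, B) + boff + 1L
    }
  }
  list(padrows = padrows, rowsel = rowsel, Hp = Hp, Wp = Wp, npos = npos)
}

conv_forward <- function(X, p, g, sel, B) {
  .conv_fwd_cpp(X, sel$padrows, sel$rowsel, sel$Hp * sel$Wp * B, p$W, p$b)
}

conv_backward <- function(dA, fw, p, g, sel, B, want_dX = TRUE) {
  out <- .conv_bwd_cpp(dA, fw$A, fw$M, p$W, sel$padrows, sel$rowsel,
                       sel$Hp * sel$Wp * B, want_dX)
  list(dW = out$dW, db = as.vector(out$db), dX = out$dX)
}

# s x s max pooling (s x 1 for 1D). Caches argmax masks for backprop.
pool_selectors <- function(H, W, s, sw, B) {
  key <- paste("p", H, W, s, sw, B, sep = "_")
  hit <- .sel_cache[[key]]
  if (!is.null(hit)) return(hit)
  .sel_cache[[key]] <- pool_selectors_build(H, W, s, sw, B)
}

pool_selectors_build <- function(H, W, s, sw, B) {
  Ho <- H %/% s
  Wo <- max(1L, W %/% sw)
  npos_o <- Ho * Wo
  boff <- rep((seq_len(B) - 1L) * (H * W), each = npos_o)
  sels <- vector("list", s * sw)
  k <- 0L
  for (b2 in seq_len(sw) - 1L) {
    for (a in seq_len(s) - 1L) {
      k <- k + 1L
      base <- as.vector(outer((seq_len(Ho) - 1L) * s + a,
                              ((seq_len(Wo) - 1L) * sw + b2) * H, "+"))
      sels[[k]] <- rep(base, B) + boff + 1L
    }
  }
  list(sels = sels, Ho = Ho, Wo = Wo)
}

pool_forward <- function(X, ps) {
  .pool_fwd_cpp(X, ps$sels)
}

pool_backward <- function(dP, fw, ps, n_in_rows, C) {
  .pool_bwd_cpp(dP, fw$argk, ps$sels, n_in_rows)
}

# Global max pool over positions: X (npos*B) x C -> (B x C).
gmax_forward <- function(X, npos, B) {
  C <- ncol(X)
  tX <- t(matrix(as.vector(X), npos))      # (B*C) x npos
  idx <- max.col(tX, ties.method = "first")
  vals <- tX[cbind(seq_len(B * C), idx)]
  list(F = matrix(vals, B, C), idx = idx)
}

gmax_backward <- function(dF, fw, npos, B) {
  C <- ncol(dF)
  r <- seq_len(B * C)
  b <- (r - 1L) %% B + 1L
  ch <- (r - 1L) %/% B + 1L
  dX <- matrix(0, npos * B, C)
  dX[cbind(fw$idx + (b - 1L) * npos, ch)] <- as.vector(dF)
  dX
}

# Full forward pass for a batch; X is (npos0*B) x C0.
cnn_forward_batch <- function(X, params, cfg, B, keep_cache = TRUE) {
  caches <- vector("list", cfg$n_layers)
  for (i in seq_len(cfg$n_layers)) {
    g <- cfg$geom[[i]]
    sel <- conv_selectors(g, B)
    fw <- conv_forward(X, params$layers[[i]], g, sel, B)
    A <- fw$A
    pfw <- NULL; ps <- NULL
    if (g$pool > 1L) {
      sw <- if (cfg$variant == "2d" && g$W > 1L) g$pool else 1L
      ps <- pool_selectors(g$H, g$W, g$pool, sw, B)
      pfw <- pool_forward(A, ps)
      X <- pfw$P
    } else {
      X <- A
    }
    caches[[i]] <- if (keep_cache) {
      list(sel = sel, fw = fw, ps = ps, pfw = pfw,
           n_act_rows = nrow(A))
    } else NULL
  }
  npos_f <- cfg$final_positions
  gm <- gmax_forward(X, npos_f, B)
  list(F = gm$F, gm = gm, caches = caches)
}

# Backward pass; returns parameter grads (dX of the input is not needed
# because the encoders are frozen during supervised training).
cnn_backward_batch <- function(dF, out, params, cfg, B) {
  dX <- gmax_backward(dF, out$gm, cfg$final_positions, B)
  grads <- list(layers = vector("list", cfg$n_layers))
  for (i in rev(seq_len(cfg$n_layers))) {
    g <- cfg$geom[[i]]
    cc <- out$caches[[i]]
    if (g$pool > 1L) {
      dA <- pool_backward(dX, cc$pfw, cc$ps, cc$n_act_rows, g$Cout)
    } else {
      dA <- dX
    }
    cb <- conv_backward(dA, cc$fw, params$layers[[i]], g, cc$sel, B,
                        want_dX = (i > 1L))
    grads$layers[[i]] <- list(W = cb$dW, b = cb$db)
    dX <- cb$dX
  }
  grads
}

#' High-level features from a low-level feature matrix
#'
#' Runs one fixed-size low-level matrix (64 x d drug node features or
#' K x d target fragment features) through a shallow CNN and returns the
#' global-max-pooled feature vector (length `cfg$filters[n_layers]`,
#' default 128).
#'
#' @param features A `drug_features` / `target_features` object, or a bare
#'   numeric matrix of the configured input shape.
#' @param cnn A list with `config` (a [cnn_config()]) and `params`
#'   (from [cnn_init()]).
#' @return Numeric vector of high-level features.
#' @export
cnn_high_level <- function(features, cnn) {
  mat <- if (is.matrix(features)) features else features$matrix
  cfg <- cnn$config
  if (nrow(mat) != cfg$input_rows || ncol(mat) != cfg$input_cols) {
    stop(sprintf("input shape mismatch: expected %dx%d, got %dx%d",
                 cfg$input_rows, cfg$input_cols, nrow(mat), ncol(mat)))
  }
  X <- cnn_input_layout(mat, cfg)
  out <- cnn_forward_batch(X, cnn$params, cfg, B = 1L, keep_cache = FALSE)
  as.vector(out$F)
}

# Convert one feature matrix to the internal batched layout (B = 1).
cnn_input_layout <- function(mat, cfg) {
  if (cfg$variant == "2d") {
    matrix(as.vector(mat), ncol = 1L)   # column-major positions, 1 channel
  } else {
    mat                                  # rows = positions, cols = channels
  }
}

# Stack a list of feature matrices into the batched layout.
cnn_batch_layout <- function(mats, cfg) {
  if (cfg$variant == "2d") {
    matrix(unlist(lapply(mats, as.vector), use.names = FALSE), ncol = 1L)
  } else {
    do.call(rbind, mats)
  }
}
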