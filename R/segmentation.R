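#' Sliding-window configuration for target segmentation
#'
#' Target sequences are cut into residue windows before encoding. Two modes
#' exist: non-overlapping windows build the pretraining corpus (no shared
#' residues, so no information leaks between pretraining examples), and
#' overlapping windows produce exactly `k_fragments` windows per sequence at
#' feature-extraction time, so every target yields a fixed-size feature
#' matrix.
#'
#' @param window_length Window length in residues (default 64).
#' @param k_fragments Number of overlapping windows per sequence, K
#'   (default 64).
#' @param min_fragment_length In non-overlapping mode, a trailing partial
#'   window is kept only if at least this long (default 8); shorter tails
#'   are dropped.
#' @return An object of class `window_config`.
#' @export
window_config <- function(window_length = 64L, k_fragments = 64L,
                          min_fragment_length = min(8L, window_length)) {
  window_length <- as.integer(window_length)
  k_fragments <- as.integer(k_fragments)
  min_fragment_length <- as.integer(min_fragment_length)
  stopifnot(window_length >= 1L, k_fragments >= 1L,
            min_fragment_length >= 1L,
            min_fragment_length <= window_length)
  structure(
    list(window_length = window_length, k_fragments = k_fragments,
         min_fragment_length = min_fragment_length),
    class = "window_config"
  )
}

#' @export
print.window_config <- function(x, ...) {
  cat(sprintf("<window_config> l=%d K=%d min=%d\n", x$window_length,
              x$k_fragments, x$min_fragment_length))
  invisible(x)
}

new_fragment_set <- function(parent_id, fragments, mode) {
  structure(
    list(parent_id = parent_id, fragments = fragments, mode = mode),
    class = "fragment_set"
  )
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> parent=%s mode=%s n=%d\n", x$parent_id,
              x$mode, length(x$fragments)))
  invisible(x)
}

#' @export
length.fragment_set <- function(x) length(x$fragments)

#' Cut a sequence into non-overlapping windows (pretraining corpus mode)
#'
#' Consecutive windows of `window_length` residues starting at offset 0. A
#' trailing partial window is kept iff its length is at least
#' `min_fragment_length`, otherwise it is dropped.
#'
#' @param sequence Amino-acid string.
#' @param cfg A [window_config()].
#' @param parent_id Identifier recorded on every fragment.
#' @return A `fragment_set` with `mode = "non_overlapping"`.
#' @examples
#' fs <- segment_nonoverlapping(strrep("A", 10), window_config(4, 4, 2))
#' vapply(fs$fragments, function(f) f$start, integer(1)) # 0 4 8
#' @export
segment_nonoverlapping <- function(sequence, cfg = window_config(),
                                   parent_id = "") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  L <- nchar(sequence)
  if (L == 0L) stop("empty sequence")
  l <- cfg$window_length
  starts <- seq.int(0L, L - 1L, by = l)
  frags <- list()
  for (s in starts) {
    e <- min(s + l, L)
    if (e - s < l && e - s < cfg$min_fragment_length) {
      gindta_log("%s: dropped length-%d tail at [%d,%d)", parent_id,
                 e - s, s, e)
      next
    }
    frags[[length(frags) + 1L]] <- residue_fragment(
      substr(sequence, s + 1L, e), parent_id, s, e)
  }
  new_fragment_set(parent_id, frags, "non_overlapping")
}

#' Cut a sequence into exactly K overlapping windows (feature mode)
#'
#' For a sequence of length L and window length l: if `L > l`, window starts
#' are `min(i * s, L - l)` for `i = 0, ..., K-1` with stride
#' `s = max(1, ceiling((L - l) / (K - 1)))`, so the K windows always cover
#' the whole sequence and the last window ends exactly at L. If `L <= l`,
#' window 0 is the full sequence and windows 1..K-1 are empty padding
#' fragments (their feature rows are zero).
#'
#' @inheritParams segment_nonoverlapping
#' @return A `fragment_set` with `mode = "overlapping"` and exactly
#'   `cfg$k_fragments` fragments.
#' @examples
#' fs <- segment_overlapping(strrep("A", 10), window_config(4, 4))
#' vapply(fs$fragments, function(f) f$start, integer(1)) # 0 2 4 6
#' @export
segment_overlapping <- function(sequence, cfg = window_config(),
                                parent_id = "") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  L <- nchar(sequence)
  if (L == 0L) stop("empty sequence")
  l <- cfg$window_length
  K <- cfg$k_fragments
  frags <- vector("list", K)
  if (L <= l) {
    frags[[1L]] <- residue_fragment(sequence, parent_id, 0L, L)
    if (K > 1L) {
      for (i in 2:K) {
        frags[[i]] <- residue_fragment("", parent_id, L, L, is_padding = TRUE)
      }
    }
  } else {
    s <- max(1L, as.integer(ceiling((L - l) / (K - 1))))
    for (i in seq_len(K)) {
      st <- min((i - 1L) * s, L - l)
      frags[[i]] <- residue_fragment(
        substr(sequence, st + 1L, st + l), parent_id, st, st + l)
    }
  }
  new_fragment_set(parent_id, frags, "overlapping")
}

#' Serialize a fragment set to a data frame
#'
#' One row per fragment: `parent_id`, `index` (0-based window index),
#' `start`, `end`, `is_padding`. Useful for writing a TSV for inspection.
#'
#' @param x A `fragment_set`.
#' @return A data frame.
#' @export
fragment_table <- function(x) {
  stopifnot(inherits(x, "fragment_set"))
  data.frame(
    parent_id = x$parent_id,
    index = seq_along(x$fragments) - 1L,
    start = vapply(x$fragments, function(f) f$start, integer(1)),
    end = vapply(x$fragments, function(f) f$end, integer(1)),
    is_padding = vapply(x$fragments, function(f) f$is_padding, logical(1)),
    stringsAsFactors = FALSE
  )
}
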