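#' Token vocabularies for drug atoms and target residues
#'
#' The two GIN encoders consume graphs whose nodes are tokenized over small,
#' fixed vocabularies: 62 tokens for drug atoms and 25 tokens for target
#' residues. Initial node features are one-hot vectors over these tokens, so
#' the vocabulary size is also the input width of the first encoder layer.
#'
#' The drug vocabulary is a documented reconstruction (the token count is
#' fixed at 62 but individual tokens are a design choice of this package):
#' 49 element symbols covering the organic subset plus metals common in
#' screening libraries, 6 aromatic forms (`c`, `n`, `o`, `s`, `p`, `se`),
#' 6 charged forms (`N+`, `N-`, `O-`, `O+`, `S+`, `S-`), and a reserved
#' `UNK` token. Token assignment precedence for an atom is:
#' aromatic form > charged form > plain element > `UNK`.
#'
#' The target vocabulary is the 20 standard amino acids plus selenocysteine
#' `U`, pyrrolysine `O`, the ambiguity codes `B` and `Z`, and `X`, which
#' doubles as the reserved unknown token.
#'
#' @param kind `"drug"` or `"target"`.
#' @return An object of class `token_vocabulary`: a list with elements
#'   `kind`, `tokens` (character vector in index order), `index` (named
#'   integer vector of 0-based token indices), `size`, and `unk` (the
#'   unknown-token string).
#' @examples
#' v <- token_vocabulary("drug")
#' v$size # 62
#' token_vocabulary("target")$size # 25
#' @export
token_vocabulary <- function(kind = c("drug", "target")) {
  kind <- match.arg(kind)
  if (kind == "drug") {
    elements <- c(
      "C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B",
      "Si", "Se", "As", "Te", "Al", "Zn", "Fe", "Cu", "Mn", "Co",
      "Ni", "Cr", "Mo", "V", "W", "Pt", "Pd", "Ru", "Rh", "Ag",
      "Au", "Hg", "Cd", "Pb", "Sn", "Sb", "Bi", "Ge", "Ga", "Li",
      "Na", "K", "Mg", "Ca", "Sr", "Ba", "Ti", "Zr", "Gd"
    )
    aromatic <- c("c", "n", "o", "s", "p", "se")
    charged <- c("N+", "N-", "O-", "O+", "S+", "S-")
    tokens <- c(elements, aromatic, charged, "UNK")
    unk <- "UNK"
  } else {
    tokens <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                "U", "O", "B", "Z", "X")
    unk <- "X"
  }
  index <- stats::setNames(seq_along(tokens) - 1L, tokens)
  structure(
    list(kind = kind, tokens = tokens, index = index,
         size = length(tokens), unk = unk),
    class = "token_vocabulary"
  )
}

#' @export
print.token_vocabulary <- function(x, ...) {
  cat(sprintf("<token_vocabulary> kind=%s size=%d unk=%s\n",
              x$kind, x$size, x$unk))
  invisible(x)
}

# Map atom descriptions to drug-vocabulary tokens.
# `element`: chemical symbols; `aromatic`: logical; `charge`: integer formal
# charge. Returns token strings (UNK where no rule applies).
drug_atom_token <- function(element, aromatic, charge, vocab) {
  stopifnot(vocab$kind == "drug")
  n <- length(element)
  out <- character(n)
  for (i in seq_len(n)) {
    el <- element[i]
    tok <- vocab$unk
    ar <- tolower(el)
    if (isTRUE(aromatic[i]) && ar %in% c("c", "n", "o", "s", "p", "se")) {
      tok <- ar
    } else if (charge[i] != 0 && el %in% c("N", "O", "S")) {
      cand <- paste0(el, if (charge[i] > 0) "+" else "-")
      if (cand %in% vocab$tokens) tok <- cand
    } else if (el %in% vocab$tokens) {
      tok <- el
    }
    out[i] <- tok
  }
  out
}

# Internal verbosity-gated logger (option gindta.verbose, default FALSE).
gindta_log <- function(fmt, ...) {
  if (isTRUE(getOption("gindta.verbose", FALSE))) {
    message(sprintf(fmt, ...))
  }
  invisible(NULL)
}
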