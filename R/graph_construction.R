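#' @importFrom ChemmineR smiles2sdf atomblock bondblock rings
NULL

new_molecular_graph <- function(node_tokens, node_labels, edges, origin,
                                source_id = "") {
  stopifnot(is.integer(node_tokens), is.matrix(edges), ncol(edges) == 2)
  structure(
    list(node_tokens = node_tokens, node_labels = node_labels,
         edges = edges, n_nodes = length(node_tokens),
         origin = origin, source_id = source_id),
    class = "molecular_graph"
  )
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> origin=%s id=%s nodes=%d edges=%d\n",
              x$origin, x$source_id, x$n_nodes, nrow(x$edges)))
  invisible(x)
}

gindta_parse_error <- function(smiles, why = "SMILES failed to parse") {
  stop(structure(
    class = c("gindta_parse_error", "error", "condition"),
    list(message = sprintf("%s: %s", why, smiles),
         call = sys.call(-1), smiles = smiles)
  ))
}

#' Canonicalize a SMILES string
#'
#' Uses Open Babel's canonical SMILES writer so that repeated spellings of the
#' same molecule ("CCO", "OCC") yield one canonical atom order. Drug graphs
#' are always built from the canonical form, which makes node order (and thus
#' the low-level feature matrix) independent of the input spelling.
#'
#' @param smiles A single SMILES string.
#' @return The canonical SMILES string.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", source = smiles),
    error = function(e) "")
  out <- sub("[\t\n ].*$", "", out)
  if (!nzchar(out)) gindta_parse_error(smiles)
  out
}

# Parse one SMILES into element / aromatic / charge / bond tables, in
# canonical atom order. Hydrogens are implicit: heavy atoms only.
parse_smiles_atoms <- function(smiles) {
  can <- canonical_smiles(smiles)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(can)),
    error = function(e) NULL)
  if (is.null(sdf) || length(sdf) < 1L) gindta_parse_error(smiles)
  sdf <- sdf[[1]]
  cl <- ChemmineR::header(sdf)[["Counts_Line"]]
  natoms <- suppressWarnings(as.integer(substr(cl, 1L, 3L)))
  ab <- ChemmineR::atomblock(sdf)
  if (is.na(natoms) || natoms < 1L) gindta_parse_error(smiles, "no atoms")
  if (nrow(ab) != natoms || !all(grepl("_", rownames(ab), fixed = TRUE))) {
    # single-atom (bond-free) molecules confuse the SDF reader; take the
    # element and charge straight from the V2000 atom line
    return(parse_smiles_single(smiles, can, natoms))
  }
  element <- sub("_.*$", "", rownames(ab))
  # V2000 atom-block charge codes: 1..3 => +3..+1, 5..7 => -1..-3
  code <- if ("C5" %in% colnames(ab)) ab[, "C5"] else rep(0, nrow(ab))
  charge <- integer(nrow(ab))
  charge[code == 1] <- 3L; charge[code == 2] <- 2L; charge[code == 3] <- 1L
  charge[code == 5] <- -1L; charge[code == 6] <- -2L; charge[code == 7] <- -3L
  bb <- ChemmineR::bondblock(sdf)
  edges <- if (is.null(bb) || nrow(bb) == 0L) {
    matrix(integer(0), 0, 2)
  } else {
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
  }
  aromatic <- logical(nrow(ab))
  if (nrow(edges) > 0L) {
    rg <- tryCatch(
      ChemmineR::rings(sdf, type = "all", arom = TRUE),
      error = function(e) NULL)
    if (!is.null(rg) && length(rg$RINGS) > 0L) {
      arom_atoms <- unique(unlist(rg$RINGS[unlist(rg$AROMATIC)]))
      if (length(arom_atoms) > 0L) {
        aromatic[as.integer(sub("^.*_", "", arom_atoms))] <- TRUE
      }
    }
  }
  list(canonical = can, element = element, aromatic = aromatic,
       charge = charge, edges = edges)
}

# Fallback for molecules whose SDF has no bond block (single heavy atom).
parse_smiles_single <- function(smiles, can, natoms) {
  txt <- tryCatch(ChemmineOB::convertFormat("SMI", "SDF", source = can),
                  error = function(e) "")
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L + natoms) gindta_parse_error(smiles, "bad SDF")
  atoml <- lines[5L:(4L + natoms)]
  element <- trimws(substr(atoml, 32L, 34L))
  code <- suppressWarnings(as.integer(trimws(substr(atoml, 37L, 39L))))
  code[is.na(code)] <- 0L
  charge <- integer(natoms)
  charge[code == 1] <- 3L; charge[code == 2] <- 2L; charge[code == 3] <- 1L
  charge[code == 5] <- -1L; charge[code == 6] <- -2L; charge[code == 7] <- -3L
  chg <- grep("^M  CHG", lines, value = TRUE)
  for (ln in chg) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    k <- f[1L]
    for (j in seq_len(k)) charge[f[2L * j]] <- f[2L * j + 1L]
  }
  list(canonical = can, element = element, aromatic = logical(natoms),
       charge = charge, edges = matrix(integer(0), 0, 2))
}

#' Build a drug atom graph from a SMILES string
#'
#' Parses the SMILES (via Open Babel), canonicalizes atom order, and returns
#' a graph with one node per heavy atom (hydrogens implicit) tokenized over
#' the 62-token drug vocabulary, and one undirected edge per bond. Atoms that
#' fall outside the vocabulary map to the reserved `UNK` token.
#'
#' @param smiles A single SMILES string.
#' @param vocab A drug [token_vocabulary()]; built on the fly if omitted.
#' @param source_id Identifier stored on the graph.
#' @return A `molecular_graph`: `node_tokens` (0-based vocabulary indices in
#'   canonical atom order), `node_labels`, `edges` (two-column matrix of
#'   1-based node indices, one row per undirected bond), `n_nodes`, `origin`.
#' @examples
#' \donttest{
#' g <- build_drug_graph("CCO")
#' g$n_nodes # 3
#' nrow(g$edges) # 2
#' }
#' @export
build_drug_graph <- function(smiles, vocab = token_vocabulary("drug"),
                             source_id = smiles) {
  stopifnot(inherits(vocab, "token_vocabulary"), vocab$kind == "drug")
  p <- parse_smiles_atoms(smiles)
  toks <- drug_atom_token(p$element, p$aromatic, p$charge, vocab)
  n_unk <- sum(toks == vocab$unk)
  if (n_unk > 0L) {
    gindta_log("drug %s: %d atom(s) mapped to UNK", source_id, n_unk)
  }
  edges <- p$edges
  if (nrow(edges) > 0L) {
    edges <- t(apply(edges, 1L, sort))
    edges <- unique(edges)
    if (any(edges[, 1] == edges[, 2])) {
      stop("self-loop in bond table for ", smiles)
    }
  }
  storage.mode(edges) <- "integer"
  new_molecular_graph(
    node_tokens = unname(vocab$index[toks]),
    node_labels = toks,
    edges = edges,
    origin = "drug",
    source_id = source_id
  )
}

#' Construct a residue fragment
#'
#' A window cut from a parent protein sequence. Offsets are 0-based,
#' half-open: `start` is the offset of the first residue, `end` is one past
#' the last, so `end - start == nchar(sequence)`.
#'
#' @param sequence Amino-acid string (possibly empty only for declared
#'   padding fragments).
#' @param parent_id Identifier of the parent sequence.
#' @param start,end 0-based half-open offsets into the parent.
#' @param is_padding Logical; `TRUE` for the empty placeholder fragments
#'   emitted when a sequence is shorter than the window length.
#' @return An object of class `residue_fragment`.
#' @export
residue_fragment <- function(sequence, parent_id = "", start = 0L,
                             end = start + nchar(sequence),
                             is_padding = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!is_padding && nchar(sequence) == 0L) {
    stop("empty fragment (only padding fragments may be empty)")
  }
  if (end - start != nchar(sequence)) {
    stop("end - start must equal the fragment length")
  }
  structure(
    list(sequence = toupper(sequence), parent_id = parent_id,
         start = as.integer(start), end = as.integer(end),
         is_padding = isTRUE(is_padding)),
    class = "residue_fragment"
  )
}

#' @export
print.residue_fragment <- function(x, ...) {
  cat(sprintf("<residue_fragment> %s[%d,%d)%s %s\n", x$parent_id, x$start,
              x$end, if (x$is_padding) " (padding)" else "", x$sequence))
  invisible(x)
}

#' Build a residue-level chain graph for a target fragment
#'
#' One node per residue, tokenized over the 25-token target vocabulary;
#' edges join sequence-adjacent residues, so a fragment of n residues is a
#' path graph with n-1 edges. Non-standard residue letters map to the
#' unknown token `X`. An atom-level alternative (`level = "atom"`) builds
#' the peptide molecule via Open Babel and tokenizes its atoms over the drug
#' vocabulary; residue level is the default and the representation the rest
#' of the pipeline assumes.
#'
#' @param fragment A [residue_fragment()] or a plain amino-acid string.
#' @param vocab A target [token_vocabulary()] (ignored at atom level).
#' @param level `"residue"` (default) or `"atom"`.
#' @return A `molecular_graph` with `origin = "target_fragment"`.
#' @examples
#' g <- build_fragment_graph("ACDE")
#' g$n_nodes # 4
#' nrow(g$edges) # 3
#' @export
build_fragment_graph <- function(fragment, vocab = token_vocabulary("target"),
                                 level = c("residue", "atom")) {
  level <- match.arg(level)
  if (is.character(fragment)) fragment <- residue_fragment(fragment)
  stopifnot(inherits(fragment, "residue_fragment"))
  if (fragment$is_padding || nchar(fragment$sequence) == 0L) {
    stop("cannot build a graph for an empty fragment")
  }
  if (level == "atom") {
    smi <- tryCatch(
      ChemmineOB::convertFormat("FASTA", "SMI",
                                source = paste0(">f\n", fragment$sequence)),
      error = function(e) "")
    smi <- sub("[\t\n ].*$", "", smi)
    if (!nzchar(smi)) gindta_parse_error(fragment$sequence, "peptide build failed")
    g <- build_drug_graph(smi, source_id = fragment$parent_id)
    g$origin <- "target_fragment"
    return(g)
  }
  stopifnot(inherits(vocab, "token_vocabulary"), vocab$kind == "target")
  chars <- strsplit(fragment$sequence, "")[[1]]
  toks <- ifelse(chars %in% vocab$tokens, chars, vocab$unk)
  n_unk <- sum(toks == vocab$unk & chars != vocab$unk)
  if (n_unk > 0L) {
    gindta_log("fragment %s[%d,%d): %d residue(s) mapped to %s",
               fragment$parent_id, fragment$start, fragment$end, n_unk,
               vocab$unk)
  }
  n <- length(toks)
  edges <- if (n > 1L) cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L) else
    matrix(integer(0), 0, 2)
  storage.mode(edges) <- "integer"
  new_molecular_graph(
    node_tokens = unname(vocab$index[toks]),
    node_labels = toks,
    edges = edges,
    origin = "target_fragment",
    source_id = fragment$parent_id
  )
}

# Dense symmetric adjacency matrix of a molecular_graph.
graph_adjacency <- function(graph) {
  n <- graph$n_nodes
  A <- matrix(0, n, n)
  if (nrow(graph$edges) > 0L) {
    A[graph$edges] <- 1
    A[graph$edges[, c(2, 1), drop = FALSE]] <- 1
  }
  A
}

# One-hot node feature matrix (n_nodes x vocab_size) from token indices.
graph_onehot <- function(graph, vocab_size) {
  n <- graph$n_nodes
  X <- matrix(0, n, vocab_size)
  X[cbind(seq_len(n), graph$node_tokens + 1L)] <- 1
  X
}
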