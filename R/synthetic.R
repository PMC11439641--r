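# Desk-scale synthetic data with a planted local-fragment interaction
# signal. The generator mirrors the modelling premise that affinity is
# driven by local substructures: targets carry short residue motifs, drugs
# carry pharmacophore substructures, and the affinity of a pair is a
# baseline plus the sum of interaction weights over (motif, pharmacophore)
# combinations present, plus Gaussian noise. Everything is seeded and the
# deterministic decomposition is recorded for recovery tests.

#' Specification of a synthetic drug-target affinity dataset
#'
#' @param n_drugs,n_targets Entity counts.
#' @param target_length_range Integer range of target sequence lengths.
#' @param motifs Character vector of residue motifs planted in targets.
#' @param pharmacophores Named character vector of SMILES fragments planted
#'   in drugs (names are used as pharmacophore ids). The defaults are a
#'   sulfonamide, a pyridine ring, and a trifluoromethyl group; the rest of
#'   the drug grammar avoids S, aromatic N and F so presence is
#'   unambiguous and checkable by substructure search.
#' @param weights Interaction weight matrix, motifs x pharmacophores.
#' @param baseline Baseline affinity (pKd-like scale).
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param n_pairs Number of labeled pairs to draw (capped at
#'   `n_drugs * n_targets`).
#' @param seed Integer master seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_drugs = 30L, n_targets = 20L,
                           target_length_range = c(120L, 300L),
                           motifs = c("HWKHY", "CDECW", "MFWFM"),
                           pharmacophores = c(sulfonamide = "S(=O)(=O)N",
                                              pyridine = "c1ccncc1",
                                              cf3 = "C(F)(F)F"),
                           weights = NULL, baseline = 5, noise_sd = 0.3,
                           n_pairs = 250L, seed = 1L) {
  if (is.null(weights)) {
    # rank-one positive interaction surface: affinity rises when a
    # motif-carrying pocket meets a pharmacophore-carrying ligand, with
    # per-motif / per-pharmacophore potencies
    weights <- outer(c(0.9, 0.7, 0.5), c(0.9, 0.7, 0.5))[
      seq_along(motifs), seq_along(pharmacophores), drop = FALSE]
  }
  stopifnot(n_drugs >= 1L, n_targets >= 1L, noise_sd >= 0,
            all(is.finite(weights)),
            nrow(weights) == length(motifs),
            ncol(weights) == length(pharmacophores))
  dimnames(weights) <- list(motifs, names(pharmacophores))
  structure(
    list(n_drugs = as.integer(n_drugs), n_targets = as.integer(n_targets),
         target_length_range = as.integer(target_length_range),
         motifs = motifs, pharmacophores = pharmacophores,
         weights = weights, baseline = baseline, noise_sd = noise_sd,
         n_pairs = as.integer(n_pairs), seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# SMILES fragment grammar. Infix units can sit anywhere in the backbone;
# terminal units close a branchless chain end (at most one per molecule).
.grammar_infix <- c("C", "CC", "CCC", "C(C)C", "O", "N", "CO", "CN",
                    "C1CCCCC1", "c1ccccc1")
.grammar_start <- c("CC", "CCC", "CCCC")

#' Generate synthetic drug SMILES
#'
#' Assembles valid SMILES from a curated fragment grammar (alkyl chains,
#' carbocycles, heteroatom links) and plants each pharmacophore of the spec
#' independently with probability 1/2 per drug. Presence is recorded and,
#' by construction of the grammar, coincides with substructure search.
#'
#' @param spec A [synthetic_spec()].
#' @return A data frame with columns `id` and `smiles`; attribute
#'   `pharmacophores` holds the logical presence matrix
#'   (drugs x pharmacophores).
#' @export
generate_drugs <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  np <- length(spec$pharmacophores)
  terminal_ph <- grepl("F", spec$pharmacophores, fixed = TRUE) # CF3-like
  present <- matrix(FALSE, spec$n_drugs, np,
                    dimnames = list(NULL, names(spec$pharmacophores)))
  smiles <- character(spec$n_drugs)
  for (i in seq_len(spec$n_drugs)) {
    present[i, ] <- stats::runif(np) < 0.5
    units <- sample(.grammar_infix, sample(2:4, 1L), replace = TRUE)
    ph_infix <- spec$pharmacophores[present[i, ] & !terminal_ph]
    for (u in ph_infix) {
      at <- sample.int(length(units) + 1L, 1L)
      units <- append(units, u, after = at - 1L)
    }
    tail_unit <- if (any(present[i, ] & terminal_ph)) {
      paste(spec$pharmacophores[present[i, ] & terminal_ph], collapse = "")
    } else if (stats::runif(1) < 0.3) "Cl" else ""
    smiles[i] <- paste0(sample(.grammar_start, 1L),
                        paste(units, collapse = ""), tail_unit)
  }
  out <- data.frame(id = sprintf("D%03d", seq_len(spec$n_drugs)),
                    smiles = smiles, stringsAsFactors = FALSE)
  attr(out, "pharmacophores") <- present
  out
}

#' Generate synthetic target sequences
#'
#' Uniform-random sequences over the 20 standard amino acids in the
#' configured length range; each motif of the spec is planted independently
#' with probability 1/2 at a recorded position (non-overlapping with other
#' planted motifs). Sequences with incidental occurrences of non-planted
#' motifs are resampled, so recorded presence coincides with string search.
#'
#' @param spec A [synthetic_spec()].
#' @return A data frame with columns `id` and `sequence`; attributes
#'   `motifs` (logical presence matrix, targets x motifs) and
#'   `motif_positions` (list of named integer vectors of 0-based offsets).
#' @export
generate_targets <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 2L)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  nm <- length(spec$motifs)
  present <- matrix(FALSE, spec$n_targets, nm,
                    dimnames = list(NULL, spec$motifs))
  positions <- vector("list", spec$n_targets)
  seqs <- character(spec$n_targets)
  rng <- spec$target_length_range
  for (i in seq_len(spec$n_targets)) {
    present[i, ] <- stats::runif(nm) < 0.5
    for (attempt in 1:20) {
      L <- sample(rng[1]:rng[2], 1L)
      s <- paste(sample(aa, L, replace = TRUE), collapse = "")
      pos <- integer(0)
      used <- integer(0)
      ok <- TRUE
      for (m in which(present[i, ])) {
        mot <- spec$motifs[m]
        ml <- nchar(mot)
        cand <- setdiff(seq_len(L - ml + 1L),
                        unlist(lapply(used, function(u) (u - ml + 1L):(u + ml - 1L))))
        cand <- cand[cand >= 1L]
        if (length(cand) == 0L) { ok <- FALSE; break }
        at <- if (length(cand) == 1L) cand else sample(cand, 1L)
        substr(s, at, at + ml - 1L) <- mot
        used <- c(used, at:(at + ml - 1L))
        pos <- c(pos, stats::setNames(at - 1L, mot))
      }
      if (!ok) next
      # reject incidental occurrences (absent motifs must stay absent and
      # planted motifs must occur exactly once)
      counts <- vapply(spec$motifs, function(m) {
        g <- gregexpr(m, s, fixed = TRUE)[[1]]
        if (g[1] == -1L) 0L else length(g)
      }, integer(1))
      if (all(counts == as.integer(present[i, ]))) break
      ok <- FALSE
    }
    if (!ok) stop("failed to plant motifs in target ", i)
    seqs[i] <- s
    positions[[i]] <- pos
  }
  out <- data.frame(id = sprintf("T%03d", seq_len(spec$n_targets)),
                    sequence = seqs, stringsAsFactors = FALSE)
  attr(out, "motifs") <- present
  attr(out, "motif_positions") <- positions
  out
}

#' Generate labeled affinity records from planted interactions
#'
#' For each sampled (drug, target) pair,
#' `y = baseline + sum over (motif m in target, pharmacophore p in drug)
#' weights[m, p] + Gaussian(0, noise_sd)`.
#'
#' @param drugs Output of [generate_drugs()].
#' @param targets Output of [generate_targets()].
#' @param spec The [synthetic_spec()] used to generate them.
#' @return A data frame (class `affinity_records`) with columns `drug_id`,
#'   `target_id`, `affinity`; attribute `ground_truth` is a data frame
#'   adding the deterministic `signal` component and the noise draw.
#' @export
generate_affinities <- function(drugs, targets, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 3L)
  ph <- attr(drugs, "pharmacophores")
  mo <- attr(targets, "motifs")
  stopifnot(!is.null(ph), !is.null(mo))
  all_pairs <- expand.grid(d = seq_len(nrow(drugs)),
                           t = seq_len(nrow(targets)))
  n <- min(spec$n_pairs, nrow(all_pairs))
  take <- sample.int(nrow(all_pairs), n)
  d <- all_pairs$d[take]; t <- all_pairs$t[take]
  # signal_it = 1(motifs of t) %*% W %*% 1(pharms of d)
  signal <- rowSums((mo[t, , drop = FALSE] %*% spec$weights) *
                      ph[d, , drop = FALSE])
  noise <- stats::rnorm(n, 0, spec$noise_sd)
  y <- spec$baseline + signal + noise
  out <- data.frame(drug_id = drugs$id[d], target_id = targets$id[t],
                    affinity = y, stringsAsFactors = FALSE)
  attr(out, "ground_truth") <- data.frame(
    drug_id = drugs$id[d], target_id = targets$id[t],
    baseline = spec$baseline, signal = signal, noise = noise,
    stringsAsFactors = FALSE)
  class(out) <- c("affinity_records", class(out))
  out
}

#' Write a complete synthetic fixture set to disk
#'
#' Emits `drugs.smi`, `drugs.csv`, `targets.fasta`, `affinities.csv` and
#' `ground_truth.json` under `dir`.
#'
#' @param dir Output directory (created if missing).
#' @param spec A [synthetic_spec()].
#' @return Invisibly, a list with the generated `drugs`, `targets` and
#'   `affinities`.
#' @export
make_fixtures <- function(dir, spec = synthetic_spec()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  drugs <- generate_drugs(spec)
  targets <- generate_targets(spec)
  aff <- generate_affinities(drugs, targets, spec)
  writeLines(paste(drugs$smiles, drugs$id, sep = "\t"),
             file.path(dir, "drugs.smi"))
  utils::write.csv(drugs, file.path(dir, "drugs.csv"), row.names = FALSE)
  write_fasta(targets, file.path(dir, "targets.fasta"))
  utils::write.csv(aff, file.path(dir, "affinities.csv"), row.names = FALSE)
  gt <- attr(aff, "ground_truth")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(baseline = spec$baseline, noise_sd = spec$noise_sd,
           weights = spec$weights,
           pharmacophores = as.data.frame(attr(drugs, "pharmacophores")),
           motifs = as.data.frame(attr(targets, "motifs")),
           records = gt),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(drugs = drugs, targets = targets, affinities = aff))
}
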