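test_that("recorded pharmacophore presence matches substructure search", {
  sp <- synthetic_spec(n_drugs = 15L, seed = 42L)
  drugs <- generate_drugs(sp)
  present <- attr(drugs, "pharmacophores")
  for (i in seq_len(nrow(drugs))) {
    sdf <- ChemmineR::smiles2sdf(drugs$smiles[i])
    for (p in seq_along(sp$pharmacophores)) {
      hits <- ChemmineR::smartsSearchOB(sdf, sp$pharmacophores[[p]],
                                        uniqueMatches = FALSE)
      expect_identical(unname(hits > 0), unname(present[i, p]),
                       info = sprintf("drug %s, pattern %s", drugs$smiles[i],
                                      sp$pharmacophores[[p]]))
    }
  }
})

test_that("recorded motif presence and positions match string search", {
  sp <- synthetic_spec(n_targets = 12L, seed = 7L)
  targets <- generate_targets(sp)
  present <- attr(targets, "motifs")
  positions <- attr(targets, "motif_positions")
  for (i in seq_len(nrow(targets))) {
    s <- targets$sequence[i]
    for (m in seq_along(sp$motifs)) {
      g <- gregexpr(sp$motifs[m], s, fixed = TRUE)[[1]]
      found <- g[1] != -1L
      expect_identical(found, unname(present[i, m]))
      if (found) {
        expect_length(g, 1L)  # planted motifs occur exactly once
        expect_identical(g[1] - 1L,
                         unname(positions[[i]][sp$motifs[m]]))
      }
    }
  }
})

test_that("target lengths respect the configured range", {
  sp <- synthetic_spec(n_targets = 10L, target_length_range = c(50L, 80L),
                       seed = 3L)
  targets <- generate_targets(sp)
  L <- nchar(targets$sequence)
  expect_true(all(L >= 50L & L <= 80L))
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", targets$sequence)))
})

test_that("noiseless affinities decompose exactly into planted signal", {
  sp <- synthetic_spec(noise_sd = 0, n_pairs = 100L, seed = 5L)
  drugs <- generate_drugs(sp)
  targets <- generate_targets(sp)
  aff <- generate_affinities(drugs, targets, sp)
  gt <- attr(aff, "ground_truth")
  expect_identical(aff$affinity, gt$baseline + gt$signal)
  expect_true(all(gt$noise == 0))
  # recompute the signal independently from the recorded presence masks
  ph <- attr(drugs, "pharmacophores")
  mo <- attr(targets, "motifs")
  for (r in sample(nrow(aff), 20L)) {
    d <- match(aff$drug_id[r], drugs$id)
    t <- match(aff$target_id[r], targets$id)
    sig <- 0
    for (m in seq_along(sp$motifs)) {
      for (p in seq_along(sp$pharmacophores)) {
        if (mo[t, m] && ph[d, p]) sig <- sig + sp$weights[m, p]
      }
    }
    expect_equal(gt$signal[r], sig, tolerance = 1e-12)
  }
})

test_that("noise has roughly the configured standard deviation", {
  sp <- synthetic_spec(n_pairs = 500L, n_drugs = 40L, n_targets = 30L,
                       noise_sd = 0.3, seed = 8L)
  aff <- generate_affinities(generate_drugs(sp), generate_targets(sp), sp)
  noise <- attr(aff, "ground_truth")$noise
  expect_lt(abs(mean(noise)), 3 * 0.3 / sqrt(500))
  se_sd <- 0.3 / sqrt(2 * (500 - 1))
  expect_lt(abs(sd(noise) - 0.3), 3 * se_sd)
})

test_that("generation is fully reproducible from the seed", {
  sp <- synthetic_spec(seed = 99L)
  a1 <- generate_affinities(generate_drugs(sp), generate_targets(sp), sp)
  a2 <- generate_affinities(generate_drugs(sp), generate_targets(sp), sp)
  expect_identical(a1, a2)
})

test_that("make_fixtures writes a readable, consistent dataset", {
  dir <- withr::local_tempdir()
  sp <- synthetic_spec(n_drugs = 8L, n_targets = 5L, n_pairs = 20L,
                       seed = 13L)
  res <- make_fixtures(dir, sp)
  expect_true(all(file.exists(file.path(
    dir, c("drugs.smi", "drugs.csv", "targets.fasta", "affinities.csv",
           "ground_truth.json")))))
  drugs <- read_drugs(file.path(dir, "drugs.smi"))
  targets <- read_targets(file.path(dir, "targets.fasta"))
  aff <- read_affinities(file.path(dir, "affinities.csv"))
  expect_identical(drugs$id, res$drugs$id)
  expect_identical(drugs$smiles, res$drugs$smiles)
  expect_identical(targets$sequence, res$targets$sequence)
  expect_equal(aff$affinity, res$affinities$affinity, tolerance = 1e-9)
  expect_silent(check_ids(aff, drugs, targets))
})

test_that("every generated drug SMILES parses into a graph", {
  sp <- synthetic_spec(n_drugs = 20L, seed = 21L)
  drugs <- generate_drugs(sp)
  for (s in drugs$smiles) {
    g <- build_drug_graph(s)
    expect_gt(g$n_nodes, 0L)
  }
})
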