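test_that("token vocabularies have the documented sizes and indices", {
  vd <- token_vocabulary("drug")
  vt <- token_vocabulary("target")
  expect_length(vd$tokens, 62L)
  expect_length(vt$tokens, 25L)
  expect_identical(unname(sort(vd$index)), 0:61)
  expect_identical(unname(sort(vt$index)), 0:24)
  expect_true(vd$unk %in% vd$tokens)
  expect_identical(vt$unk, "X")
  expect_true(all(c("c", "n", "o", "s") %in% vd$tokens))   # aromatic
  expect_true(all(c("N+", "O-") %in% vd$tokens))           # charged
})

test_that("ethanol parses into a 3-node, 2-edge graph", {
  g <- build_drug_graph("CCO")
  expect_s3_class(g, "molecular_graph")
  expect_identical(g$n_nodes, 3L)
  expect_identical(nrow(g$edges), 2L)
  expect_identical(sort(g$node_labels), c("C", "C", "O"))
  expect_true(all(g$edges[, 1] < g$edges[, 2]))
})

test_that("SMILES spelling variants share one canonical graph", {
  g1 <- build_drug_graph("CCO")
  g2 <- build_drug_graph("OCC")
  expect_identical(g1$node_tokens, g2$node_tokens)
  expect_identical(g1$edges, g2$edges)
})

test_that("aromatic atoms get lowercase tokens, ring edges are present", {
  g <- build_drug_graph("c1ccccc1")  # benzene
  expect_identical(g$n_nodes, 6L)
  expect_identical(nrow(g$edges), 6L)
  expect_identical(unique(g$node_labels), "c")
  # pyridine distinguishes the aromatic nitrogen
  gp <- build_drug_graph("c1ccncc1")
  expect_identical(sum(gp$node_labels == "c"), 5L)
  expect_identical(sum(gp$node_labels == "n"), 1L)
})

test_that("charge and single-atom molecules tokenize correctly", {
  g <- build_drug_graph("[NH4+]")
  expect_identical(g$n_nodes, 1L)
  expect_identical(g$node_labels, "N+")
  expect_identical(nrow(g$edges), 0L)
  g2 <- build_drug_graph("C")   # methane: one heavy atom, no bonds
  expect_identical(g2$n_nodes, 1L)
  expect_identical(g2$node_labels, "C")
})

test_that("malformed SMILES raise a typed parse error carrying the input", {
  err <- tryCatch(build_drug_graph("C1CC"), error = identity)
  expect_s3_class(err, "gindta_parse_error")
  expect_identical(err$smiles, "C1CC")
  expect_error(canonical_smiles("not a molecule ]["),
               class = "gindta_parse_error")
})

test_that("residue fragment graphs are path graphs over the AA vocabulary", {
  g <- build_fragment_graph("ACDE")
  expect_identical(g$n_nodes, 4L)
  expect_identical(g$node_labels, c("A", "C", "D", "E"))
  expect_identical(g$edges, cbind(1:3, 2:4))
  # non-standard letters map to the unknown token X
  g2 <- build_fragment_graph("AJA")
  expect_identical(g2$node_labels[2L], "X")
})

test_that("padding or empty fragments cannot become graphs", {
  pad <- residue_fragment("", parent_id = "p", start = 0L, end = 0L,
                          is_padding = TRUE)
  expect_error(build_fragment_graph(pad), "empty")
  expect_error(residue_fragment(""), "padding")
})

test_that("adjacency and one-hot helpers agree with the graph", {
  g <- build_fragment_graph("ACD")
  A <- gindta:::graph_adjacency(g)
  expect_identical(A, t(A))
  expect_identical(sum(A), 2 * nrow(g$edges))
  X <- gindta:::graph_onehot(g, 25L)
  expect_identical(dim(X), c(3L, 25L))
  expect_identical(rowSums(X), c(1, 1, 1))
  expect_identical(which(X[1, ] == 1) - 1L, g$node_tokens[1L])
})
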