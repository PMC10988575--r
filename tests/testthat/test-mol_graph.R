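test_that("parse_smiles handles single atoms, rings and valences", {
  g <- parse_smiles("O")
  expect_equal(nrow(g$atoms), 1L)
  expect_equal(g$atoms$element, "O")
  expect_equal(g$atoms$n_hydrogens, 2L)
  expect_equal(nrow(g$bonds), 0L)

  g <- parse_smiles("C1CC1")
  expect_equal(nrow(g$atoms), 3L)
  expect_equal(nrow(g$bonds), 3L)
  expect_true(all(g$atoms$degree == 2L))

  # counts cross-checked against an independent parser (RDKit 2024.09)
  cases <- list(
    list(smiles = "c1ccccc1", atoms = 6L, bonds = 6L, h = 6L),
    list(smiles = "c1ccc2ccccc2c1", atoms = 10L, bonds = 11L, h = 8L),
    list(smiles = "CC(=O)Oc1ccccc1C(=O)O", atoms = 13L, bonds = 13L, h = 8L),
    list(smiles = "C[C@H](N)O", atoms = 4L, bonds = 3L, h = 7L))
  for (cs in cases) {
    g <- parse_smiles(cs$smiles)
    expect_equal(nrow(g$atoms), cs$atoms, info = cs$smiles)
    expect_equal(nrow(g$bonds), cs$bonds, info = cs$smiles)
    expect_equal(sum(g$atoms$n_hydrogens), cs$h, info = cs$smiles)
  }

  expect_error(parse_smiles("C(C)(C)(C)(C)C"), "valence")
  expect_error(parse_smiles("C1CC"), "unclosed ring")
  expect_error(parse_smiles("C(("), "branch|unmatched|unexpected")
  expect_error(parse_smiles(""), "non-empty")
})

test_that("chirality parses to a single atom-level tag", {
  # alanine: RDKit finds exactly one chiral center on this string
  g <- parse_smiles("N[C@@H](C)C(=O)O")
  expect_equal(nrow(g$atoms), 6L)
  expect_equal(sum(g$atoms$chiral_tag != "none"), 1L)
  expect_equal(g$atoms$chiral_tag[g$atoms$chiral_tag != "none"], "clockwise")

  g_off <- parse_smiles("N[C@@H](C)C(=O)O", include_chirality = FALSE)
  expect_true(all(g_off$atoms$chiral_tag == "none"))
})

test_that("charges and bracket atoms are read", {
  expect_equal(sum(parse_smiles("CC(=O)[O-]")$atoms$formal_charge), -1L)
  expect_equal(sum(parse_smiles("C[N+](C)(C)C")$atoms$formal_charge), 1L)
  g <- parse_smiles("[nH]1cccc1")
  expect_equal(g$atoms$n_hydrogens[g$atoms$element == "N"], 1L)
})

test_that("featurization is pure, one-hot blocks sum to 1, OOV errors", {
  g <- parse_smiles("c1ccccc1")
  f <- featurize_atoms(g)
  expect_equal(nrow(f), 6L)
  # all benzene carbons identical
  expect_true(all(apply(f, 2, function(col) length(unique(col)) == 1L)))
  vocab <- default_element_vocabulary()
  elem_block <- f[, seq_along(vocab)]
  expect_true(all(rowSums(elem_block) == 1))
  chiral_block <- f[, ncol(f) - 2:0]
  expect_true(all(rowSums(chiral_block) == 1))
  expect_identical(f, featurize_atoms(parse_smiles("c1ccccc1")))
  expect_error(featurize_atoms(parse_smiles("C[Si](C)C"), vocab), "Si")
})

test_that("enantiomer features differ only in the chiral one-hot block", {
  f1 <- featurize_atoms(parse_smiles("C[C@H](N)O"))
  f2 <- featurize_atoms(parse_smiles("C[C@@H](N)O"))
  differing <- which(colSums(abs(f1 - f2)) > 0)
  names <- attr(f1, "feature_names")[differing]
  expect_true(length(differing) > 0)
  expect_true(all(grepl("^chiral_", names)))

  # chirality off: identical graphs, identical features
  f1_off <- featurize_atoms(parse_smiles("C[C@H](N)O", include_chirality = FALSE))
  f2_off <- featurize_atoms(parse_smiles("C[C@@H](N)O", include_chirality = FALSE))
  expect_identical(f1_off, f2_off)
})

test_that("JSON round-trip preserves atoms, bonds and chiral tags", {
  for (s in c("CC(=O)Oc1ccccc1C(=O)O", "N[C@@H](C)C(=O)O", "O",
              "C[N+](C)(C)C.[O-]C(=O)C")) {
    g <- parse_smiles(s)
    g2 <- graph_from_json(graph_to_json(g))
    expect_identical(g$atoms, g2$atoms, info = s)
    expect_identical(g$bonds, g2$bonds, info = s)
    expect_identical(graph_signature(g), graph_signature(g2), info = s)
  }
})

test_that("canonical signature is invariant to how the SMILES was written", {
  pairs <- list(c("OCC", "CCO"),
                c("c1ccccc1C", "Cc1ccccc1"),
                c("O=C(O)C", "CC(=O)O"),
                c("C1CCCCC1O", "OC1CCCCC1"))
  for (p in pairs)
    expect_identical(graph_signature(parse_smiles(p[1])),
                     graph_signature(parse_smiles(p[2])), info = p[1])
  # enantiomers: distinct with chirality, identical without
  e1 <- parse_smiles("C[C@H](N)O"); e2 <- parse_smiles("C[C@@H](N)O")
  expect_false(graph_signature(e1) == graph_signature(e2))
  expect_identical(graph_signature(e1, use_chirality = FALSE),
                   graph_signature(e2, use_chirality = FALSE))
})

test_that("SMILES writer round-trips graphs exactly", {
  for (s in c("CCO", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O", "N[C@@H](C)C(=O)O",
              "C1CCCCC1", "OB(O)c1ccc(OC)cc1", "CS(=O)C", "FC(F)(F)c1ccccc1",
              "C[N+](C)(C)C.[O-]C(=O)C")) {
    g <- parse_smiles(s)
    expect_identical(graph_signature(parse_smiles(write_smiles(g))),
                     graph_signature(g), info = s)
  }
})

test_that("Murcko scaffolds ignore side chains; acyclic molecules share ''", {
  expect_identical(murcko_scaffold(parse_smiles("CCCCO")), "")
  expect_identical(murcko_scaffold(parse_smiles("Cc1ccccc1")),
                   murcko_scaffold(parse_smiles("OCc1ccccc1N")))
  expect_false(murcko_scaffold(parse_smiles("C1CCCCC1")) ==
                 murcko_scaffold(parse_smiles("c1ccccc1")))
})
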