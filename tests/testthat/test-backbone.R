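test_that("benzene's six carbons get identical hidden states and predictions", {
  bb <- init_backbone(tiny_cfg(seed = 2))
  g <- parse_smiles("c1ccccc1")
  H <- encode_atoms(g, bb)
  expect_equal(nrow(H), 6L)
  for (i in 2:6) expect_equal(H[i, ], H[1, ], tolerance = 1e-5)
  pred <- predict_geometry(g, bb)
  for (i in 2:6) {
    expect_equal(pred$distances[i, ], pred$distances[1, ], tolerance = 1e-5)
    expect_equal(pred$angles[i, ], pred$angles[1, ], tolerance = 1e-5)
  }
})

test_that("message_steps = 0 makes states a function of own features only", {
  bb <- init_backbone(tiny_cfg(seed = 3, message_steps = 0L))
  # same atom environment-wise different neighbours: states must match anyway
  h_chain <- encode_atoms(parse_smiles("CCO"), bb)
  h_branched <- encode_atoms(parse_smiles("CC(C)O"), bb)
  # CH3 carbons in both molecules share (element, degree=1, H=3) features
  c1 <- which(parse_smiles("CCO")$atoms$n_hydrogens == 3)
  c2 <- which(parse_smiles("CC(C)O")$atoms$n_hydrogens == 3)
  expect_equal(h_chain[c1[1], ], h_branched[c2[1], ], tolerance = 1e-12)
})

test_that("atom states are permutation-equivariant, latent invariant", {
  bb <- init_backbone(tiny_cfg(seed = 4))
  recs <- make_structures(5, seed = 29)
  for (r in recs) {
    g <- r$graph
    n <- nrow(g$atoms)
    H <- encode_atoms(g, bb)
    z <- readout_latent(g, bb)
    set.seed(n)
    for (rep in 1:3) {
      perm <- sample.int(n)
      gp <- moltransfer:::permute_graph(g, perm)
      Hp <- encode_atoms(gp, bb)
      expect_equal(Hp[perm, , drop = FALSE], H, tolerance = 1e-5)
      expect_equal(readout_latent(gp, bb), z, tolerance = 1e-6)
    }
  }
})

test_that("sum pooling doubles for two disjoint copies of a molecule", {
  bb <- init_backbone(tiny_cfg(seed = 5))
  g1 <- parse_smiles("CCO")
  g2 <- parse_smiles("CCO.CCO")
  f1 <- moltransfer:::backbone_forward(g1, bb)
  f2 <- moltransfer:::backbone_forward(g2, bb)
  expect_equal(f2$pooled, 2 * f1$pooled, tolerance = 1e-9)
})

test_that("latent dimension is constant across molecule sizes", {
  bb <- init_backbone(tiny_cfg(seed = 6))
  for (s in c("O", "CCO", "CC(=O)Oc1ccccc1C(=O)O"))
    expect_length(readout_latent(parse_smiles(s), bb), 16L)
  expect_error(readout_latent(parse_smiles("[Si](C)(C)C"), bb), "Si")
})

test_that("enantiomers with chirality off give identical latents", {
  bb <- init_backbone(tiny_cfg(seed = 7))
  z1 <- readout_latent(parse_smiles("C[C@H](N)O", include_chirality = FALSE), bb)
  z2 <- readout_latent(parse_smiles("C[C@@H](N)O", include_chirality = FALSE), bb)
  expect_identical(z1, z2)
})

test_that("geometry head output matches the configured layout, bitwise stable", {
  cfg <- tiny_cfg(seed = 8)
  bb <- init_backbone(cfg)
  g <- parse_smiles("CC(C)CO")
  p1 <- predict_geometry(g, bb)
  p2 <- predict_geometry(g, bb)
  expect_identical(p1, p2)
  expect_equal(dim(p1$distances), c(5L, cfg$geometry$max_neighbors))
  expect_equal(dim(p1$angles), c(5L, cfg$geometry$max_angle_pairs))
  expect_true(all(p1$distances[p1$distance_mask == 1] > 0))
  expect_true(all(p1$angles[p1$angle_mask == 1] >= 0 &
                    p1$angles[p1$angle_mask == 1] <= 180))
})

test_that("fingerprint changes iff parameters change", {
  bb <- init_backbone(tiny_cfg(seed = 9))
  fp <- bb$fingerprint
  expect_identical(moltransfer::params_fingerprint(bb$params), fp)
  tweaked <- bb$params
  tweaked$W_r[1, 1] <- tweaked$W_r[1, 1] + 1e-12
  expect_false(moltransfer::params_fingerprint(tweaked) == fp)
  expect_false(init_backbone(tiny_cfg(seed = 10))$fingerprint == fp)
  expect_identical(init_backbone(tiny_cfg(seed = 9))$fingerprint, fp)
})

test_that("checkpoints round-trip exactly and reject corruption", {
  bb <- init_backbone(tiny_cfg(seed = 11))
  path <- tempfile(fileext = ".json")
  save_backbone(bb, path)
  bb2 <- load_backbone(path)
  expect_identical(bb2$params, bb$params)
  expect_identical(bb2$fingerprint, bb$fingerprint)
  txt <- readLines(path)
  writeLines(sub("\"fingerprint\":\"", "\"fingerprint\":\"00", txt), path)
  expect_error(load_backbone(path), "fingerprint mismatch")
})
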