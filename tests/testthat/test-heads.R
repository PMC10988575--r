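test_that("head parameter count matches the closed form and presets hit budgets", {
  expect_identical(head_param_count(head_spec("regression", 256, 120, 1)),
                   256L * 120L + 120L + 120L * 1L + 1L)  # 30 961
  expect_identical(head_param_count(head_spec("regression", 256, 120, 1)), 30961L)
  expect_identical(head_param_count(head_spec("regression", 1, 1, 1)), 4L)

  budgets <- c(toxicity = 32000, olfaction = 32000, yield = 260000,
               yield_large = 1e6)
  for (nm in names(budgets)) {
    count <- head_param_count(head_preset(nm))
    expect_lt(abs(count - budgets[[nm]]) / budgets[[nm]], 0.15)
  }
  expect_equal(head_preset("olfaction")$output_dim, 113L)
  expect_equal(head_preset("toxicity")$n_layers, 2L)
})

test_that("strip_and_attach: determinism, freeze, geometry removal", {
  bb <- init_backbone(tiny_cfg(seed = 12))
  fp <- bb$fingerprint
  spec <- head_spec("regression", 16, 8, 1)
  c1 <- strip_and_attach(bb, spec, seed = 3)
  c2 <- strip_and_attach(bb, spec, seed = 3)
  expect_identical(head_fingerprint(c1), head_fingerprint(c2))
  expect_false(head_fingerprint(strip_and_attach(bb, spec, seed = 4)) ==
                 head_fingerprint(c1))
  expect_identical(c1$backbone$fingerprint, fp)
  expect_error(predict_geometry(parse_smiles("CCO"), c1), "unavailable")
  expect_error(strip_and_attach(bb, head_spec("regression", 17, 8, 1)),
               "does not match")
})

test_that("finetuning changes only the head; fingerprint is bit-identical", {
  bb <- init_backbone(tiny_cfg(seed = 13))
  recs <- make_structures(20, seed = 63)
  lab <- generate_regression_labels(recs, fixture_config(20, seed = 63))
  comp <- strip_and_attach(bb, head_spec("regression", 16, 8, 1), seed = 1)
  hfp0 <- head_fingerprint(comp)
  ft <- finetune(comp, lab$data, epochs = 10, seed = 2)
  expect_identical(ft$composite$backbone$fingerprint, bb$fingerprint)
  expect_identical(ft$composite$backbone$params, bb$params)
  expect_false(head_fingerprint(ft$composite) == hfp0)
  expect_length(ft$loss_trace, 10L)
})

test_that("noiseless linear-on-latent labels are recovered (held-out R^2 > 0.9)", {
  cfg <- backbone_config(hidden_dim = 24, message_steps = 2, readout_dim = 48,
                         seed = 5)
  bb <- init_backbone(cfg)
  recs <- make_structures(300, seed = 21, size_range = c(4, 10))
  fc <- fixture_config(n_molecules = 300, seed = 21,
                       label_model = "linear_on_latent", noise_sd = 0)
  lab <- generate_regression_labels(recs, fc, backbone = bb)
  idx <- seq_len(240)
  comp <- strip_and_attach(bb, head_spec("regression", 48, 64, 1), seed = 2)
  ft <- finetune(comp, list(graphs = lapply(recs[idx], `[[`, "graph"),
                            y = lab$data$label[idx]),
                 epochs = 300, learning_rate = 5e-3, seed = 3)
  te_y <- lab$data$label[-idx]
  pred <- predict(ft$composite, list(graphs = lapply(recs[-idx], `[[`, "graph")))
  r2 <- 1 - sum((te_y - pred)^2) / sum((te_y - mean(te_y))^2)
  expect_gt(r2, 0.9)
})

test_that("reaction encoding: zero blocks, role-order canonicalization, block diffs", {
  bb <- init_backbone(tiny_cfg(seed = 14))
  roles <- c("nucleophile", "electrophile", "ligand", "base")
  comp <- strip_and_attach(bb, head_spec("regression", 4 * 16, 8, 1),
                           seed = 1, reaction_roles = roles)
  v <- encode_reaction(list(ligand = "CP(C)C"), comp)
  blocks <- split(seq_len(64), rep(1:4, each = 16))
  expect_true(all(v[blocks[[1]]] == 0) && all(v[blocks[[2]]] == 0) &&
                all(v[blocks[[4]]] == 0))
  expect_gt(sum(abs(v[blocks[[3]]])), 0)

  r1 <- list(nucleophile = "OB(O)c1ccccc1", electrophile = "Brc1ccccc1",
             ligand = "CP(C)C", base = "CCN(CC)CC")
  expect_identical(encode_reaction(r1, comp), encode_reaction(rev(r1), comp))

  r2 <- r1; r2$ligand <- "CCP(CC)CC"
  d <- encode_reaction(r1, comp) - encode_reaction(r2, comp)
  changed <- vapply(blocks, function(b) sum(abs(d[b])) > 0, logical(1))
  expect_identical(unname(changed), c(FALSE, FALSE, TRUE, FALSE))

  expect_error(encode_reaction(list(ligand = "not a smiles("), comp),
               "role 'ligand'")
})

test_that("freeze contract holds across all three task types", {
  bb <- init_backbone(tiny_cfg(seed = 15))
  recs <- make_structures(15, seed = 65)
  fp <- bb$fingerprint

  lab <- generate_regression_labels(recs, fixture_config(15, seed = 65))
  ft1 <- finetune(strip_and_attach(bb, head_spec("regression", 16, 8, 1), 1),
                  lab$data, epochs = 5)
  expect_identical(ft1$composite$backbone$fingerprint, fp)

  ml <- generate_multilabel_labels(recs, n_classes = 4, rule_seed = 2)
  ft2 <- finetune(strip_and_attach(bb, head_spec("multilabel", 16, 8, 4), 1),
                  list(graphs = lapply(recs, `[[`, "graph"), y = ml$labels),
                  epochs = 5)
  expect_identical(ft2$composite$backbone$fingerprint, fp)

  pal <- lapply(default_reaction_palettes()[c("electrophile", "ligand", "base")],
                utils::head, 2)
  rt <- generate_reaction_table(pal, seed = 3)
  roles <- names(pal)
  ft3 <- finetune(strip_and_attach(bb, head_spec("regression", 3 * 16, 8, 1),
                                   1, reaction_roles = roles),
                  rt$reactions, epochs = 5)
  expect_identical(ft3$composite$backbone$fingerprint, fp)
})

test_that("task/label mismatches error", {
  bb <- init_backbone(tiny_cfg(seed = 16))
  recs <- make_structures(6, seed = 67)
  graphs <- lapply(recs, `[[`, "graph")
  comp_r <- strip_and_attach(bb, head_spec("regression", 16, 8, 1), 1)
  expect_error(finetune(comp_r, list(graphs = graphs, y = matrix(0, 6, 2))),
               "label matrix")
  comp_m <- strip_and_attach(bb, head_spec("multilabel", 16, 8, 3), 1)
  expect_error(finetune(comp_m, list(graphs = graphs, y = matrix(0, 6, 2))),
               "does not match")
})

test_that("predict_topk orders by probability with index tie-breaks", {
  bb <- init_backbone(tiny_cfg(seed = 17))
  spec <- head_spec("multilabel", 16, 4, 3,
                    class_names = c("floral", "fruity", "musky"))
  comp <- strip_and_attach(bb, spec, seed = 1)
  # force logits to known values: zero first layer, bias-only output
  comp$head$W1[] <- 0; comp$head$b1[] <- 0; comp$head$W2[] <- 0
  comp$head$b2 <- c(0.1, 0.9, 0.5)
  expect_identical(predict_topk(comp, "CCO", k = 2), c("fruity", "musky"))
  expect_setequal(predict_topk(comp, "CCO", k = 3),
                  c("floral", "fruity", "musky"))
  comp$head$b2 <- c(0, 0, 0)  # uniform: tie-break by label index
  expect_identical(predict_topk(comp, "CCO", k = 2), c("floral", "fruity"))
  expect_error(predict_topk(comp, "CCO", k = 4), "between 1 and")
})

test_that("multi-seed replicates report distinct heads with mean and SE", {
  bb <- init_backbone(tiny_cfg(seed = 18))
  recs <- make_structures(30, seed = 69)
  lab <- generate_regression_labels(recs, fixture_config(30, seed = 69,
                                                         noise_sd = 0.1))
  df <- lab$data
  res <- finetune_replicates(bb, head_spec("regression", 16, 8, 1),
                             df[1:24, ], df[25:30, ], seeds = 1:5,
                             epochs = 30)
  expect_length(res$scores, 5L)
  expect_equal(length(unique(res$head_fingerprints)), 5L)
  expect_equal(res$summary[["mean"]], mean(res$scores))
  expect_equal(res$summary[["se"]], sd(res$scores) / sqrt(5))
})

test_that("enantiomer discrimination tracks the chirality flag", {
  bb <- init_backbone(tiny_cfg(seed = 19))
  recs <- make_structures(12, seed = 71)
  lab <- generate_regression_labels(recs, fixture_config(12, seed = 71))
  ft <- finetune(strip_and_attach(bb, head_spec("regression", 16, 8, 1), 1),
                 lab$data, epochs = 20)
  pair_on <- list(graphs = list(parse_smiles("C[C@H](N)O"),
                                parse_smiles("C[C@@H](N)O")))
  pair_off <- list(graphs = list(
    parse_smiles("C[C@H](N)O", include_chirality = FALSE),
    parse_smiles("C[C@@H](N)O", include_chirality = FALSE)))
  p_on <- predict(ft$composite, pair_on)
  p_off <- predict(ft$composite, pair_off)
  expect_identical(p_off[1], p_off[2])   # forced equal by identical graphs
  expect_false(isTRUE(all.equal(p_on[1], p_on[2], tolerance = 1e-12)))
})

test_that("composite models save and load exactly", {
  bb <- init_backbone(tiny_cfg(seed = 22))
  spec <- head_spec("multilabel", 16, 6, 3, class_names = c("a", "b", "c"))
  comp <- strip_and_attach(bb, spec, seed = 9)
  path <- tempfile(fileext = ".json")
  save_composite(comp, path)
  back <- load_composite(path)
  expect_identical(back$backbone$fingerprint, comp$backbone$fingerprint)
  expect_identical(head_fingerprint(back), head_fingerprint(comp))
  expect_identical(back$head_spec$class_names, spec$class_names)
})
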