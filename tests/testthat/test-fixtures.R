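test_that("molecule generation is reproducible and always target-extractable", {
  cfg <- fixture_config(n_molecules = 15, seed = 11)
  r1 <- suppressMessages(generate_molecule_set(cfg))
  r2 <- suppressMessages(generate_molecule_set(cfg))
  expect_identical(vapply(r1, `[[`, character(1), "smiles"),
                   vapply(r2, `[[`, character(1), "smiles"))
  for (i in seq_along(r1)) expect_identical(r1[[i]]$coords, r2[[i]]$coords)
  for (r in r1) {
    expect_no_error(tg <- extract_targets(r$graph, r$coords))
    expect_true(all(tg$distances[tg$distance_mask == 1] > 0.5))
    # generated SMILES parse back to the same graph
    expect_identical(graph_signature(parse_smiles(r$smiles)),
                     graph_signature(r$graph))
  }
  sizes <- vapply(r1, function(r) nrow(r$graph$atoms), integer(1))
  expect_true(all(sizes >= 4 & sizes <= 12))
})

test_that("corruption flag injects exactly one downstream reject", {
  recs <- suppressMessages(generate_molecule_set(
    fixture_config(n_molecules = 8, seed = 3, corrupt_overlap = TRUE)))
  fails <- vapply(recs, function(r)
    inherits(try(extract_targets(r$graph, r$coords), silent = TRUE),
             "try-error"), logical(1))
  expect_equal(sum(fails), 1L)
  expect_true(fails[1])
})

test_that("regression labels reconstruct exactly from the stored rule", {
  recs <- make_structures(20, seed = 31)
  cfg0 <- fixture_config(n_molecules = 20, seed = 31, noise_sd = 0)
  lab <- generate_regression_labels(recs, cfg0)
  rebuilt <- drop(lab$features %*% lab$coefficients) + lab$intercept
  expect_equal(lab$data$label, rebuilt, tolerance = 1e-12)

  # with noise, stored draws account for the difference
  cfg1 <- fixture_config(n_molecules = 20, seed = 31, noise_sd = 0.5)
  lab1 <- generate_regression_labels(recs, cfg1)
  expect_equal(lab1$data$label, rebuilt + lab1$noise, tolerance = 1e-12)
})

test_that("more label noise raises held-out error of a refit head", {
  bb <- init_backbone(tiny_cfg(seed = 30))
  recs <- make_structures(60, seed = 33)
  run <- function(noise_sd) {
    cfg <- fixture_config(n_molecules = 60, seed = 33, noise_sd = noise_sd,
                          label_model = "linear_on_latent")
    lab <- generate_regression_labels(recs, cfg, backbone = bb)
    comp <- strip_and_attach(bb, head_spec("regression", 16, 16, 1), seed = 1)
    ft <- finetune(comp, list(graphs = lapply(recs[1:45], `[[`, "graph"),
                              y = lab$data$label[1:45]),
                   epochs = 150, learning_rate = 5e-3, seed = 2)
    noiseless <- drop(lab$features %*% lab$coefficients) + lab$intercept
    pred <- predict(ft$composite,
                    list(graphs = lapply(recs[46:60], `[[`, "graph")))
    mae(noiseless[46:60], pred)
  }
  expect_lt(run(0), run(2))
})

test_that("multilabel rules reproduce the matrix and zero rows exactly", {
  recs <- make_structures(30, seed = 35)
  ml <- generate_multilabel_labels(recs, n_classes = 6, rule_seed = 7,
                                   zero_fraction = 0.2)
  expect_identical(ml$labels, apply_label_rules(recs, ml$rules))
  expect_equal(dim(ml$labels), c(30L, 6L))
  # all-zero rows: exactly the configured minority, floor(0.2 * 30) = 6
  expect_equal(which(rowSums(ml$labels) == 0), ml$rules$zero_rows)
  expect_length(ml$rules$zero_rows, 6L)
})

test_that("a finetuned head beats chance on held-out multilabel fixtures", {
  bb <- init_backbone(tiny_cfg(seed = 40))
  recs <- make_structures(100, seed = 37)
  ml <- generate_multilabel_labels(recs, n_classes = 5, rule_seed = 9,
                                   zero_fraction = 0.05)
  tr <- 1:80
  comp <- strip_and_attach(bb, head_spec("multilabel", 16, 24, 5), seed = 1)
  ft <- finetune(comp, list(graphs = lapply(recs[tr], `[[`, "graph"),
                            y = ml$labels[tr, ]),
                 epochs = 250, learning_rate = 5e-3, seed = 2)
  probs <- predict(ft$composite,
                   list(graphs = lapply(recs[-tr], `[[`, "graph")))
  pred <- threshold_probabilities(probs)
  truth <- ml$labels[-tr, ]
  f_model <- multilabel_fscore(truth, pred, "macro")
  # chance baseline: class-prevalence coin flips, best of a few draws
  set.seed(3)
  f_chance <- max(vapply(1:5, function(i) {
    flip <- matrix(rbinom(length(truth), 1, mean(truth)), nrow(truth))
    multilabel_fscore(truth, flip, "macro")
  }, numeric(1)))
  expect_gt(f_model, f_chance)
})

test_that("reaction tables: factorial counts, exact rule recomputation, negatives", {
  pal <- list(electrophile = c("Brc1ccccc1", "Ic1ccccc1"),
              base = c("CCN(CC)CC", "CN1CCCCC1"),
              ligand = c("CP(C)C", "CCP(CC)CC"))
  rt <- generate_reaction_table(pal, seed = 5, noise_sd = 0)
  expect_equal(nrow(rt$reactions), 8L)  # 2 x 2 x 2
  expect_true(all(rt$reactions$yield >= 0 & rt$reactions$yield <= 100))
  # zero noise: yields recompute exactly from per-component effects
  recomputed <- rt$rule$base_yield +
    rt$rule$component_effects$electrophile[rt$reactions$electrophile] +
    rt$rule$component_effects$base[rt$reactions$base] +
    rt$rule$component_effects$ligand[rt$reactions$ligand]
  expect_equal(rt$reactions$yield, unname(pmin(100, pmax(0, recomputed))),
               tolerance = 1e-12)

  rt2 <- generate_reaction_table(pal, seed = 5, negative_fraction = 0.25)
  expect_length(rt2$rule$negative_rows, 2L)
  expect_true(all(rt2$reactions$yield[rt2$rule$negative_rows] <= 5))

  rt3 <- generate_reaction_table(pal, n_reactions = 5, seed = 6)
  expect_equal(nrow(rt3$reactions), 5L)
  expect_error(generate_reaction_table(pal, n_reactions = 50), "factorial")
})

test_that("leave-one-ligand-out head beats a mean-only predictor on rule data", {
  bb <- init_backbone(tiny_cfg(seed = 44))
  pal <- default_reaction_palettes()[c("nucleophile", "electrophile",
                                       "ligand", "base")]
  pal <- lapply(pal, utils::head, 3)
  rt <- generate_reaction_table(pal, seed = 9, noise_sd = 0)
  plan <- leave_component_out_split(rt$reactions, "ligand")[[1]]
  audit_split(plan, rt$reactions)
  tr <- rt$reactions[as.integer(plan$train_ids), ]
  te <- rt$reactions[as.integer(plan$test_ids), ]
  comp <- strip_and_attach(bb, head_spec("regression", 4 * 16, 32, 1),
                           seed = 2, reaction_roles = names(pal))
  ft <- finetune(comp, tr, epochs = 200, learning_rate = 5e-3, seed = 3)
  m_model <- mae(te$yield, predict(ft$composite, te))
  m_mean <- mae(te$yield, rep(mean(tr$yield), nrow(te)))
  expect_lt(m_model, m_mean)
})
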