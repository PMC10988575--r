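test_that("geometry loss: perfect fit, single-term mean, loop oracle", {
  r <- make_structures(1, seed = 51)[[1]]
  tg <- extract_targets(r$graph, r$coords)
  expect_identical(geometry_loss(tg, tg), 0)

  # one atom, one masked distance 1.0 vs 1.5, no angles -> 0.5
  single <- structure(list(
    distances = matrix(c(1.0, 0, 0, 0), 1), angles = matrix(0, 1, 6),
    distance_mask = matrix(c(1, 0, 0, 0), 1), angle_mask = matrix(0, 1, 6)),
    class = "geometry_targets")
  truth <- single
  truth$distances[1, 1] <- 1.5
  expect_equal(geometry_loss(single, truth), 0.5)

  # random toy batch equals a scalar loop over masked entries
  set.seed(60)
  for (rep in 1:5) {
    n <- sample(2:6, 1)
    mk <- function() matrix(runif(n * 4, 0.5, 2), n, 4)
    mka <- function() matrix(runif(n * 6, 0, 180), n, 6)
    dm <- matrix(rbinom(n * 4, 1, 0.6), n, 4)
    am <- matrix(rbinom(n * 6, 1, 0.5), n, 6)
    if (sum(dm) == 0) dm[1, 1] <- 1
    pred <- structure(list(distances = mk(), angles = mka(),
                           distance_mask = dm, angle_mask = am),
                      class = "geometry_targets")
    tgt <- pred
    tgt$distances <- mk(); tgt$angles <- mka()
    w <- runif(1, 0.5, 2)
    acc_d <- 0; acc_a <- 0
    for (i in seq_len(n)) {
      for (k in 1:4) if (dm[i, k] == 1)
        acc_d <- acc_d + abs(pred$distances[i, k] - tgt$distances[i, k])
      for (k in 1:6) if (am[i, k] == 1)
        acc_a <- acc_a + abs(pred$angles[i, k] - tgt$angles[i, k])
    }
    expected <- acc_d / sum(dm) +
      if (sum(am) > 0) w * acc_a / (180 * sum(am)) else 0
    expect_equal(geometry_loss(pred, tgt, angle_weight = w), expected,
                 tolerance = 1e-10)
  }
  empty <- single
  empty$distance_mask[] <- 0
  expect_error(geometry_loss(empty, empty), "no masked-in entries")
})

test_that("zero learning rate leaves parameters untouched, trace constant", {
  recs <- make_structures(5, seed = 53)
  cfg <- tiny_cfg(seed = 1)
  fit <- train_foundational(recs, cfg, epochs = 4, learning_rate = 0, seed = 2)
  expect_identical(fit$backbone$fingerprint, init_backbone(
    backbone_config(hidden_dim = 16, message_steps = 2, readout_dim = 16,
                    seed = 2))$fingerprint)
  expect_equal(diff(range(fit$report$loss_trace)), 0, tolerance = 1e-12)
})

test_that("training is deterministic under a fixed seed", {
  recs <- make_structures(6, seed = 55)
  cfg <- tiny_cfg()
  f1 <- train_foundational(recs, cfg, epochs = 5, learning_rate = 1e-3, seed = 4)
  f2 <- train_foundational(recs, cfg, epochs = 5, learning_rate = 1e-3, seed = 4)
  expect_identical(f1$backbone$fingerprint, f2$backbone$fingerprint)
  f3 <- train_foundational(recs, cfg, epochs = 5, learning_rate = 1e-3, seed = 5)
  expect_false(f3$backbone$fingerprint == f1$backbone$fingerprint)
})

test_that("a short run already reduces the loss and evaluation is side-effect free", {
  recs <- make_structures(8, seed = 57)
  fit <- train_foundational(recs, tiny_cfg(), epochs = 25,
                            learning_rate = 5e-3, seed = 3, batch_size = 8)
  tr <- fit$report$loss_trace
  expect_lt(tr[length(tr)], tr[1])
  fp <- fit$backbone$fingerprint
  ev <- evaluate_geometry(fit$backbone, recs)
  expect_identical(fit$backbone$fingerprint, fp)
  expect_gte(ev$distance_mae, 0)
  expect_gte(ev$angle_mae, 0)
  expect_error(evaluate_geometry(fit$backbone, list()), "empty")
})

test_that("constant-zero distance predictor scores the mean masked distance", {
  recs <- make_structures(5, seed = 59)
  bb <- init_backbone(tiny_cfg(seed = 20))
  # force the distance head to emit ~0 (softplus of very negative raw)
  bb$params$W_d[] <- 0
  bb$params$b_d[] <- -40
  bb <- moltransfer:::new_backbone_params(bb$params, bb$config)
  all_d <- unlist(lapply(recs, function(r) {
    tg <- extract_targets(r$graph, r$coords)
    tg$distances[tg$distance_mask == 1]
  }))
  ev <- evaluate_geometry(bb, recs)
  expect_equal(ev$distance_mae, mean(all_d), tolerance = 1e-8)
})

test_that("early stopping halts when validation stalls", {
  recs <- make_structures(8, seed = 61)
  fit <- train_foundational(recs[1:6], tiny_cfg(), epochs = 60,
                            learning_rate = 5e-3, seed = 6,
                            validation = recs[7:8], patience = 3)
  expect_lte(fit$report$epochs_run, 60L)
  expect_false(is.na(fit$report$test_distance_mae))
})
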