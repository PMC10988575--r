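# Shared test helpers: tiny configs sized for CPU test runs, rigid-motion
# utilities, and independent oracles kept deliberately separate from the
# package's own code paths.

tiny_cfg <- function(seed = 1L, hidden_dim = 16L, message_steps = 2L,
                     readout_dim = 16L, ...) {
  backbone_config(hidden_dim = hidden_dim, message_steps = message_steps,
                  readout_dim = readout_dim, seed = seed, ...)
}

make_structures <- function(n, seed = 1L, ...) {
  suppressMessages(generate_molecule_set(
    fixture_config(n_molecules = n, seed = seed, ...)))
}

rigid_transform <- function(coords, seed) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(m))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  coords %*% Q + matrix(rnorm(3) * 4, nrow(coords), 3, byrow = TRUE)
}

# independent rigid-superposition RMSD: numerical optimization over the six
# rigid-motion parameters (no SVD, unlike the implementation's Kabsch path)
rmsd_by_optim <- function(a, b) {
  a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
  rot <- function(p) {
    cx <- cos(p[1]); sx <- sin(p[1])
    cy <- cos(p[2]); sy <- sin(p[2])
    cz <- cos(p[3]); sz <- sin(p[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Rx %*% Ry %*% Rz
  }
  obj <- function(p) {
    d <- a %*% rot(p[1:3]) - sweep(b, 2, -p[4:6])
    mean(rowSums(d^2))
  }
  best <- Inf
  for (s in 1:8) {
    set.seed(s)
    o <- optim(c(runif(3, -pi, pi), rnorm(3, sd = 0.1)), obj,
               method = "BFGS", control = list(maxit = 500))
    best <- min(best, o$value)
  }
  sqrt(best)
}

# mirror of the package's id assignment (incl. duplicate-name suffixing), so
# tests can state id expectations explicitly
dataset_ids_for_test <- function(dataset) {
  nms <- vapply(seq_along(dataset), function(i) {
    g <- if (inherits(dataset[[i]], "molecular_graph")) dataset[[i]]
         else dataset[[i]]$graph
    if (!is.null(g$name)) g$name else sprintf("record_%04d", i)
  }, character(1))
  if (anyDuplicated(nms)) nms <- sprintf("%s#%d", nms, seq_along(nms))
  nms
}

# brute-force scalar-loop MAE
mae_loop <- function(y, x) {
  s <- 0
  for (i in seq_along(y)) s <- s + abs(y[i] - x[i])
  s / length(y)
}

# brute-force per-class contingency F-score
fscore_loop <- function(truth, pred, average) {
  ncl <- ncol(truth)
  f1 <- numeric(ncl); support <- numeric(ncl)
  for (j in seq_len(ncl)) {
    tp <- fp <- fn <- 0
    for (i in seq_len(nrow(truth))) {
      if (truth[i, j] == 1 && pred[i, j] == 1) tp <- tp + 1
      if (truth[i, j] == 0 && pred[i, j] == 1) fp <- fp + 1
      if (truth[i, j] == 1 && pred[i, j] == 0) fn <- fn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[j] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    support[j] <- tp + fn
  }
  if (average == "macro") mean(f1)
  else if (sum(support) == 0) 0
  else sum(f1 * support) / sum(support)
}
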