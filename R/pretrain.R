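#' Masked geometry loss
#'
#' Mean absolute error over masked-in neighbour distances (Angstrom) plus
#' `angle_weight` times the mean absolute error over masked-in angles
#' normalized by 180 degrees. Only masked-in entries contribute; the data
#' model keeps angles physical (degrees) and normalizes inside the loss only.
#'
#' @param predicted,target `geometry_targets` objects with identical layouts
#'   and masks.
#' @param angle_weight weight on the normalized angle term (default 1).
#' @return Non-negative scalar; zero iff predictions equal targets on
#'   masked-in entries.
#' @export
geometry_loss <- function(predicted, target, angle_weight = 1) {
  check_same_layout(predicted, target)
  nd <- sum(target$distance_mask)
  na_ <- sum(target$angle_mask)
  if (nd + na_ == 0) stop("geometry_loss: no masked-in entries")
  dterm <- if (nd > 0)
    sum(abs(predicted$distances - target$distances) * target$distance_mask) / nd
  else 0
  aterm <- if (na_ > 0)
    sum(abs(predicted$angles - target$angles) * target$angle_mask) / (180 * na_)
  else 0
  dterm + angle_weight * aterm
}

check_same_layout <- function(a, b) {
  if (!identical(dim(a$distances), dim(b$distances)) ||
      !identical(dim(a$angles), dim(b$angles)))
    stop("geometry target layouts differ")
  if (any(a$distance_mask != b$distance_mask) ||
      any(a$angle_mask != b$angle_mask))
    stop("geometry target masks differ")
  invisible(TRUE)
}

# ---- Adam ------------------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- backprop --------------------------------------------------------------

zero_like <- function(params) lapply(params, function(x) x * 0)

# forward + gradient of the masked-L1 geometry loss for one molecule.
# Nd, Na are the batch-level masked-entry counts the means divide by.
backbone_mol_grad <- function(graph, target, backbone, angle_weight, Nd, Na) {
  p <- backbone$params
  cfg <- backbone$config
  fw <- backbone_forward(graph, backbone, with_cache = TRUE)
  gh <- geometry_head(fw, graph, backbone)
  pred <- gh$pred

  dm <- target$distance_mask; am <- target$angle_mask
  loss_num <- sum(abs(pred$distances - target$distances) * dm) +
    angle_weight * sum(abs(pred$angles - target$angles) * am) * (Nd / (180 * Na))
  # upstream grads on the (masked) outputs
  dDist <- sign(pred$distances - target$distances) * dm / Nd
  dAng <- sign(pred$angles - target$angles) * am * angle_weight / (180 * Na)

  # through softplus and scaled sigmoid
  dD_raw <- dDist * (1 / (1 + exp(-gh$D_raw)))
  dA_raw <- dAng * 180 * gh$sA * (1 - gh$sA)

  g <- list()
  Din <- gh$Din
  g$W_d <- crossprod(Din, dD_raw); g$b_d <- colSums(dD_raw)
  g$W_a <- crossprod(Din, dA_raw); g$b_a <- colSums(dA_raw)
  dDin <- tcrossprod(dD_raw, p$W_d) + tcrossprod(dA_raw, p$W_a)

  h <- cfg$hidden_dim; r <- cfg$readout_dim
  n <- nrow(Din)
  dH <- dDin[, seq_len(h), drop = FALSE]
  dz <- colSums(dDin[, h + seq_len(r), drop = FALSE])

  # latent: z = tanh(pooled %*% W_r + b_r)
  z <- fw$latent
  dpz <- dz * (1 - z^2)
  g$W_r <- outer(fw$pooled, dpz); g$b_r <- dpz
  dpool <- drop(p$W_r %*% dpz)
  scale <- if (cfg$aggregation == "sum") 1 else 1 / n
  dH <- dH + matrix(dpool * scale, n, h, byrow = TRUE)

  # message steps, backwards (shared weights accumulate)
  Hs <- fw$cache$Hs; A <- fw$cache$A
  g$U <- matrix(0, h, h); g$b_u <- numeric(h)
  for (o in .BOND_ORDERS) g[[paste0("W_", o)]] <- matrix(0, h, h)
  W_o <- list(single = p$W_single, double = p$W_double,
              triple = p$W_triple, aromatic = p$W_aromatic)
  for (t in rev(seq_len(cfg$message_steps))) {
    Ht <- Hs[[t + 1L]]; Hprev <- Hs[[t]]
    dS <- dH * (1 - Ht^2)
    g$U <- g$U + crossprod(Hprev, dS)
    g$b_u <- g$b_u + colSums(dS)
    dH <- dS %*% t(p$U)
    for (o in .BOND_ORDERS) {
      AH <- A[[o]] %*% Hprev
      g[[paste0("W_", o)]] <- g[[paste0("W_", o)]] + crossprod(AH, dS)
      dH <- dH + A[[o]] %*% (dS %*% t(W_o[[o]]))
    }
  }

  # input layer: H0 = tanh(X %*% W_in + b_in)
  H0 <- Hs[[1L]]
  dS0 <- dH * (1 - H0^2)
  g$W_in <- crossprod(fw$cache$X, dS0)
  g$b_in <- colSums(dS0)

  list(grads = g, loss_num = loss_num, pred = pred)
}

accumulate_grads <- function(total, g) {
  if (is.null(total)) return(g)
  for (nm in names(g)) total[[nm]] <- total[[nm]] + g[[nm]]
  total
}

# ---- training --------------------------------------------------------------

#' Pretrain the foundational model on geometry targets
#'
#' Optimizes the masked-L1 [geometry_loss] with Adam over full passes through
#' the structure set (order reshuffled each epoch). Structures are assumed to
#' be already curated ([filter_rare_elements],
#' [filter_ambiguous_and_polymorphs]) and split upstream. Deterministic given
#' `seed`; training aborts with a diagnostic if the loss goes non-finite. If
#' `validation` structures are supplied, the held-out loss is traced and
#' early stopping applies after `patience` epochs without improvement.
#'
#' @param structures list of `list(graph, coords)` pairs (training set).
#' @param config a [backbone_config].
#' @param epochs number of passes (default 100).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed RNG seed for init and shuffling.
#' @param angle_weight weight on the angle loss term (default 1).
#' @param batch_size molecules per gradient step (default 8).
#' @param validation optional held-out structures for early stopping.
#' @param patience early-stopping patience in epochs (default Inf: off).
#' @param verbose print the loss every 10 epochs.
#' @return A list with `backbone` (trained `backbone_params`) and `report`
#'   (class `pretrain_report`): per-epoch loss trace, final train/test
#'   distance MAE (Angstrom) and angle MAE (degrees), config and seed.
#' @export
train_foundational <- function(structures, config = backbone_config(),
                               epochs = 100L, learning_rate = 1e-3,
                               seed = 1L, angle_weight = 1,
                               batch_size = 8L, validation = NULL,
                               patience = Inf, verbose = FALSE) {
  if (!length(structures)) stop("no training structures")
  config$seed <- as.integer(seed)
  backbone <- init_backbone(config)
  targets <- lapply(structures, function(s)
    extract_targets(s$graph, s$coords, config$geometry))
  val_targets <- if (!is.null(validation))
    lapply(validation, function(s)
      extract_targets(s$graph, s$coords, config$geometry))

  st <- adam_state(backbone$params)
  trace <- numeric(0)
  val_trace <- numeric(0)
  best_val <- Inf; best_params <- backbone$params; since_best <- 0L
  set.seed(seed)
  n <- length(structures)

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_terms <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      Nd <- sum(vapply(idx, function(i) sum(targets[[i]]$distance_mask), 0))
      Na <- sum(vapply(idx, function(i) sum(targets[[i]]$angle_mask), 0))
      if (Nd == 0 && Na == 0) next
      Nd <- max(Nd, 1); Na <- max(Na, 1)
      total <- NULL; batch_loss <- 0
      for (i in idx) {
        mg <- backbone_mol_grad(structures[[i]]$graph, targets[[i]], backbone,
                                angle_weight, Nd, Na)
        total <- accumulate_grads(total, mg$grads)
        batch_loss <- batch_loss + mg$loss_num / Nd
      }
      if (!is.finite(batch_loss))
        stop(sprintf("non-finite loss at epoch %d; try a lower learning rate", ep))
      if (learning_rate > 0) {
        upd <- adam_step(backbone$params, total, st, learning_rate)
        backbone$params <- upd$params
        st <- upd$state
      }
      ep_loss <- ep_loss + batch_loss; ep_terms <- ep_terms + 1L
    }
    trace[ep] <- ep_loss / max(ep_terms, 1L)
    if (!is.null(validation)) {
      vm <- evaluate_geometry_internal(backbone, validation, val_targets)
      val_loss <- vm$distance_mae + angle_weight * vm$angle_mae / 180
      val_trace[ep] <- val_loss
      if (val_loss < best_val - 1e-9) {
        best_val <- val_loss; best_params <- backbone$params; since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= patience) break
      }
    }
    if (verbose && ep %% 10L == 0L)
      message(sprintf("epoch %d: loss %.5f", ep, trace[ep]))
  }
  if (!is.null(validation) && is.finite(best_val))
    backbone$params <- best_params
  backbone <- new_backbone_params(backbone$params, backbone$config)

  train_mae <- evaluate_geometry_internal(backbone, structures, targets)
  test_mae <- if (!is.null(validation))
    evaluate_geometry_internal(backbone, validation, val_targets)
  else list(distance_mae = NA_real_, angle_mae = NA_real_)
  report <- structure(list(
    loss_trace = trace, validation_trace = val_trace,
    train_distance_mae = train_mae$distance_mae,
    train_angle_mae = train_mae$angle_mae,
    test_distance_mae = test_mae$distance_mae,
    test_angle_mae = test_mae$angle_mae,
    epochs_run = length(trace), seed = seed,
    config = unclass(config)[c("hidden_dim", "message_steps", "readout_dim",
                               "aggregation")],
    learning_rate = learning_rate, angle_weight = angle_weight
  ), class = "pretrain_report")
  list(backbone = backbone, report = report)
}

#' @export
print.pretrain_report <- function(x, ...) {
  cat(sprintf("<pretrain_report: %d epochs, train MAE %.4f A / %.2f deg%s>\n",
              x$epochs_run, x$train_distance_mae, x$train_angle_mae,
              if (!is.na(x$test_distance_mae))
                sprintf(", test MAE %.4f A / %.2f deg",
                        x$test_distance_mae, x$test_angle_mae) else ""))
  invisible(x)
}

#' Evaluate geometry prediction error
#'
#' Masked mean absolute errors of the geometry head per quantity: distances
#' in Angstrom, angles in degrees. No gradient updates; the backbone
#' fingerprint is untouched.
#'
#' @param backbone a `backbone_params` object.
#' @param structures list of `list(graph, coords)` pairs.
#' @return A list with `distance_mae` and `angle_mae`.
#' @export
evaluate_geometry <- function(backbone, structures) {
  if (!length(structures)) stop("cannot evaluate on an empty structure set")
  targets <- lapply(structures, function(s)
    extract_targets(s$graph, s$coords, backbone$config$geometry))
  evaluate_geometry_internal(backbone, structures, targets)
}

evaluate_geometry_internal <- function(backbone, structures, targets) {
  dnum <- 0; dden <- 0; anum <- 0; aden <- 0
  for (i in seq_along(structures)) {
    pred <- predict_geometry(structures[[i]]$graph, backbone)
    tg <- targets[[i]]
    dnum <- dnum + sum(abs(pred$distances - tg$distances) * tg$distance_mask)
    dden <- dden + sum(tg$distance_mask)
    anum <- anum + sum(abs(pred$angles - tg$angles) * tg$angle_mask)
    aden <- aden + sum(tg$angle_mask)
  }
  list(distance_mae = dnum / max(dden, 1), angle_mae = anum / max(aden, 1))
}
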