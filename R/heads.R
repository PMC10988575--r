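# Transfer learning: discard the geometry output layer, freeze the backbone,
# stack a shallow 2-linear-layer head on the latent space and train only the
# head.

#' Task head specification
#'
#' A shallow feedforward head: exactly two linear layers with one rectifier
#' between, consuming the frozen backbone's latent vector (or, for reaction
#' tasks, the concatenation of per-role latents).
#'
#' @param task `"regression"` or `"multilabel"`.
#' @param input_dim latent width (or roles x latent width for reactions).
#' @param hidden_dim hidden layer width.
#' @param output_dim 1 for regression; the class count for multilabel.
#' @param class_names optional label names for multilabel heads.
#' @return A list of class `head_spec`.
#' @export
head_spec <- function(task = c("regression", "multilabel"), input_dim,
                      hidden_dim, output_dim = 1L, class_names = NULL) {
  task <- match.arg(task)
  stopifnot(input_dim >= 1L, hidden_dim >= 1L, output_dim >= 1L)
  if (task == "regression" && output_dim != 1L)
    stop("regression heads have output_dim 1")
  if (!is.null(class_names) && length(class_names) != output_dim)
    stop("class_names length must equal output_dim")
  structure(list(task = task, input_dim = as.integer(input_dim),
                 hidden_dim = as.integer(hidden_dim),
                 output_dim = as.integer(output_dim),
                 n_layers = 2L, class_names = class_names),
            class = "head_spec")
}

#' Exact parameter count of a head
#'
#' Closed form for the 2-linear-layer head:
#' `input_dim x hidden_dim + hidden_dim + hidden_dim x output_dim + output_dim`.
#'
#' @param spec a [head_spec].
#' @return Integer parameter count.
#' @export
head_param_count <- function(spec) {
  with(spec, input_dim * hidden_dim + hidden_dim +
         hidden_dim * output_dim + output_dim)
}

#' Preset head geometries
#'
#' Ready-made head widths sized to the three published head budgets:
#' `"toxicity"` (~32k parameters on a 256-wide latent), `"olfaction"` (~32k,
#' 113 classes), `"yield"` (~260k on 7 concatenated role latents) and
#' `"yield_large"` (~1M, the boosted head that recovers unseen-ligand
#' accuracy). Widths scale with `readout_dim` so the counts stay on target
#' for the default latent width of 256.
#'
#' @param name preset name.
#' @param readout_dim backbone latent width (default 256).
#' @param n_roles reaction role count for yield heads (default 7).
#' @param n_classes class count for the olfaction preset (default 113).
#' @return A [head_spec].
#' @export
head_preset <- function(name = c("toxicity", "olfaction", "yield",
                                 "yield_large"),
                        readout_dim = 256L, n_roles = 7L, n_classes = 113L) {
  name <- switch(match.arg(name),
    toxicity = head_spec("regression", readout_dim, 124L, 1L),
    olfaction = head_spec("multilabel", readout_dim, 86L, n_classes,
                          class_names = sprintf("odor_%03d", seq_len(n_classes))),
    yield = head_spec("regression", n_roles * readout_dim, 145L, 1L),
    yield_large = head_spec("regression", n_roles * readout_dim, 557L, 1L))
  name
}

.init_head <- function(spec, seed) {
  set.seed(seed)
  list(W1 = matrix(stats::rnorm(spec$input_dim * spec$hidden_dim,
                                sd = 1 / sqrt(spec$input_dim)),
                   spec$input_dim, spec$hidden_dim),
       b1 = numeric(spec$hidden_dim),
       W2 = matrix(stats::rnorm(spec$hidden_dim * spec$output_dim,
                                sd = 1 / sqrt(spec$hidden_dim)),
                   spec$hidden_dim, spec$output_dim),
       b2 = numeric(spec$output_dim))
}

#' Freeze the backbone and attach a fresh task head
#'
#' Builds a composite model: the pretrained backbone with its geometry output
#' layer discarded and all remaining parameters frozen (witnessed by the
#' stored fingerprint, which finetuning never changes), plus a freshly
#' initialized 2-layer head.
#'
#' @param backbone a `backbone_params` object.
#' @param spec a [head_spec]; `input_dim` must equal the backbone's
#'   `readout_dim` (times the role count for reaction heads).
#' @param seed head initialization seed.
#' @param reaction_roles ordered role names for reaction-yield tasks (NULL
#'   for plain molecular tasks).
#' @return A `composite_model`.
#' @export
strip_and_attach <- function(backbone, spec, seed = 1L,
                             reaction_roles = NULL) {
  expected <- backbone$config$readout_dim *
    if (is.null(reaction_roles)) 1L else length(reaction_roles)
  if (spec$input_dim != expected)
    stop("head input_dim ", spec$input_dim, " does not match expected ",
         expected, " (readout_dim x roles)")
  structure(list(backbone = backbone, head = .init_head(spec, seed),
                 head_spec = spec, reaction_roles = reaction_roles,
                 head_seed = as.integer(seed)),
            class = "composite_model")
}

#' @export
print.composite_model <- function(x, ...) {
  cat(sprintf("<composite_model: %s head (%d params) on frozen backbone %s%s>\n",
              x$head_spec$task, head_param_count(x$head_spec),
              x$backbone$fingerprint,
              if (!is.null(x$reaction_roles))
                paste0(", roles: ", paste(x$reaction_roles, collapse = "/"))
              else ""))
  invisible(x)
}

#' Fingerprint of a composite's head parameters
#' @param composite a `composite_model`.
#' @return Character scalar.
#' @export
head_fingerprint <- function(composite) params_fingerprint(composite$head)

# latent lookup with memoisation by SMILES (reaction tables repeat components)
latent_cache <- function(backbone) {
  env <- new.env(parent = emptyenv())
  function(smiles, role = NULL) {
    if (is.null(env[[smiles]])) {
      g <- tryCatch(parse_smiles(smiles), error = function(e)
        stop("unparseable component", if (!is.null(role)) paste0(" in role '", role, "'"),
             ": ", conditionMessage(e), call. = FALSE))
      env[[smiles]] <- readout_latent(g, backbone)
    }
    env[[smiles]]
  }
}

#' Encode a reaction as a fixed-role feature vector
#'
#' Frozen-backbone latent per component, concatenated in the composite's
#' fixed role order; absent roles contribute a zero block. The input key
#' order never matters, and two reactions differing in one component differ
#' only in that component's block.
#'
#' @param record named list / one-row data.frame mapping roles to SMILES.
#' @param composite a `composite_model` with `reaction_roles`.
#' @param cache optional memoised latent lookup (internal use).
#' @return Numeric vector of length `roles x readout_dim`.
#' @export
encode_reaction <- function(record, composite, cache = NULL) {
  roles <- composite$reaction_roles
  if (is.null(roles)) stop("composite has no reaction_roles")
  if (is.data.frame(record)) record <- as.list(record[1, , drop = FALSE])
  r <- composite$backbone$config$readout_dim
  if (is.null(cache)) cache <- latent_cache(composite$backbone)
  out <- numeric(length(roles) * r)
  for (i in seq_along(roles)) {
    smi <- record[[roles[i]]]
    if (is.null(smi) || is.na(smi) || !nzchar(smi)) next
    out[(i - 1L) * r + seq_len(r)] <- cache(as.character(smi), roles[i])
  }
  out
}

# dataset -> (feature matrix, labels). Accepts:
#  * regression: data.frame(smiles, label) or list(graphs=, y=)
#  * multilabel: list(graphs= or smiles=, y=binary matrix)
#  * reaction:   data.frame with role columns + yield
prepare_task_data <- function(composite, dataset) {
  spec <- composite$head_spec
  if (!is.null(composite$reaction_roles)) {
    if (!is.data.frame(dataset) || !"yield" %in% names(dataset))
      stop("reaction tasks need a data.frame with role columns and a yield column")
    if (any(dataset$yield < 0 | dataset$yield > 100, na.rm = TRUE))
      stop("yields must lie in [0, 100]")
    cache <- latent_cache(composite$backbone)
    X <- t(vapply(seq_len(nrow(dataset)), function(i)
      encode_reaction(dataset[i, , drop = FALSE], composite, cache),
      numeric(spec$input_dim)))
    return(list(X = X, y = dataset$yield))
  }
  graphs <- if (is.data.frame(dataset)) {
    lapply(dataset$smiles, parse_smiles)
  } else if (!is.null(dataset$graphs)) {
    dataset$graphs
  } else if (!is.null(dataset$smiles)) {
    lapply(dataset$smiles, parse_smiles)
  } else stop("cannot interpret dataset")
  Z <- t(vapply(graphs, readout_latent,
                numeric(composite$backbone$config$readout_dim),
                backbone = composite$backbone))
  y <- if (spec$task == "multilabel") {
    ym <- if (is.data.frame(dataset)) parse_label_column(dataset, spec)
          else as.matrix(dataset$y)
    if (ncol(ym) != spec$output_dim)
      stop("label matrix width ", ncol(ym), " does not match head output ",
           spec$output_dim)
    ym
  } else {
    lv <- if (is.data.frame(dataset)) dataset$label else dataset$y
    if (is.null(lv)) stop("regression dataset must carry a 'label' column")
    if (!is.null(dim(lv)) && ncol(lv) > 1L)
      stop("regression task got a label matrix")
    as.numeric(lv)
  }
  list(X = Z, y = y)
}

# "label1;label2" strings -> binary matrix over spec$class_names
parse_label_column <- function(dataset, spec) {
  if (is.null(spec$class_names))
    stop("multilabel head needs class_names to parse a label column")
  y <- matrix(0, nrow(dataset), spec$output_dim,
              dimnames = list(NULL, spec$class_names))
  for (i in seq_len(nrow(dataset))) {
    labs <- strsplit(as.character(dataset$labels[i]), ";", fixed = TRUE)[[1]]
    labs <- trimws(labs[nzchar(trimws(labs))])
    unknown <- setdiff(labs, spec$class_names)
    if (length(unknown)) stop("unknown label(s): ", paste(unknown, collapse = ", "))
    y[i, labs] <- 1
  }
  y
}

head_forward <- function(head, X) {
  A1 <- sweep(X %*% head$W1, 2, head$b1, "+")
  R <- pmax(A1, 0)
  list(out = sweep(R %*% head$W2, 2, head$b2, "+"), R = R, A1 = A1)
}

#' Finetune a composite model (head only)
#'
#' Trains the head with Adam while the backbone stays frozen — its
#' fingerprint is asserted bit-identical before and after. Regression heads
#' train on absolute-error loss; multilabel heads on per-class binary
#' cross-entropy. Latents are computed once through the frozen backbone and
#' reused, which is what makes finetuning cheap.
#'
#' @param composite a `composite_model` from [strip_and_attach].
#' @param dataset task data (see Details in [prepare_task_data] formats:
#'   `(smiles, label)` data.frame, `list(graphs, y)`, or a role-columned
#'   reaction data.frame with `yield`).
#' @param epochs training epochs (default 200).
#' @param learning_rate Adam step size (default 1e-2).
#' @param seed shuffling seed.
#' @param batch_size minibatch size (default 64).
#' @param verbose print loss every 50 epochs.
#' @return A list with `composite` (trained head), `loss_trace`, and the
#'   frozen `backbone_fingerprint`.
#' @export
finetune <- function(composite, dataset, epochs = 200L, learning_rate = 1e-2,
                     seed = 1L, batch_size = 64L, verbose = FALSE) {
  fp_before <- composite$backbone$fingerprint
  td <- prepare_task_data(composite, dataset)
  spec <- composite$head_spec
  if (spec$task == "multilabel" && is.null(dim(td$y)))
    stop("multilabel task needs a label matrix")
  if (spec$task == "regression" && !is.null(dim(td$y)))
    stop("regression task got a label matrix")

  head <- composite$head
  st <- adam_state(head)
  n <- nrow(td$X)
  trace <- numeric(epochs)
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      X <- td$X[idx, , drop = FALSE]
      fw <- head_forward(head, X)
      if (spec$task == "regression") {
        yhat <- drop(fw$out)
        y <- td$y[idx]
        loss <- mean(abs(yhat - y))
        dout <- matrix(sign(yhat - y) / length(idx), ncol = 1)
      } else {
        p <- 1 / (1 + exp(-fw$out))
        y <- td$y[idx, , drop = FALSE]
        eps <- 1e-12
        loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
        dout <- (p - y) / length(p)
      }
      if (!is.finite(loss)) stop("non-finite head loss at epoch ", ep)
      g <- list(
        W2 = crossprod(fw$R, dout), b2 = colSums(dout),
        W1 = NULL, b1 = NULL)
      dR <- tcrossprod(dout, head$W2) * (fw$A1 > 0)
      g$W1 <- crossprod(X, dR); g$b1 <- colSums(dR)
      upd <- adam_step(head, g, st, learning_rate)
      head <- upd$params; st <- upd$state
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    trace[ep] <- ep_loss / nb
    if (verbose && ep %% 50L == 0L)
      message(sprintf("epoch %d: loss %.5f", ep, trace[ep]))
  }
  composite$head <- head
  stopifnot(identical(composite$backbone$fingerprint, fp_before))
  list(composite = composite, loss_trace = trace,
       backbone_fingerprint = fp_before)
}

#' Predict with a composite model
#'
#' Regression heads return a numeric vector (reaction-yield predictions are
#' clipped to [0, 100] at inference only); multilabel heads return a matrix
#' of per-class probabilities.
#'
#' @param object a `composite_model`.
#' @param newdata task data in the same formats as [finetune].
#' @param ... unused.
#' @return Numeric vector or probability matrix.
#' @export
predict.composite_model <- function(object, newdata, ...) {
  td <- prepare_task_data_for_predict(object, newdata)
  fw <- head_forward(object$head, td$X)
  if (object$head_spec$task == "regression") {
    yhat <- drop(fw$out)
    if (!is.null(object$reaction_roles)) yhat <- pmin(100, pmax(0, yhat))
    yhat
  } else {
    p <- 1 / (1 + exp(-fw$out))
    colnames(p) <- object$head_spec$class_names
    p
  }
}

# prediction tolerates missing labels
prepare_task_data_for_predict <- function(composite, newdata) {
  if (!is.null(composite$reaction_roles) && is.data.frame(newdata) &&
      !"yield" %in% names(newdata))
    newdata$yield <- 0
  if (is.data.frame(newdata) && is.null(newdata$label) &&
      is.null(newdata$labels) && is.null(composite$reaction_roles))
    newdata$label <- 0
  if (is.list(newdata) && !is.data.frame(newdata) && is.null(newdata$y))
    newdata$y <- if (composite$head_spec$task == "multilabel")
      matrix(0, length(newdata$graphs), composite$head_spec$output_dim)
    else numeric(length(newdata$graphs))
  prepare_task_data(composite, newdata)
}

#' Top-k label prediction
#'
#' The `k` most probable labels for one molecule, descending; ties broken by
#' label index.
#'
#' @param composite a multilabel `composite_model`.
#' @param molecule a [molecular_graph] or SMILES string.
#' @param k how many labels (1 <= k <= class count).
#' @return Character vector of `k` label names (indices as strings when the
#'   head has no class names).
#' @export
predict_topk <- function(composite, molecule, k = 5L) {
  spec <- composite$head_spec
  if (spec$task != "multilabel") stop("predict_topk needs a multilabel head")
  if (k < 1L || k > spec$output_dim)
    stop("k must be between 1 and the class count (", spec$output_dim, ")")
  g <- if (is.character(molecule)) parse_smiles(molecule) else molecule
  z <- readout_latent(g, composite$backbone)
  p <- drop(head_forward(composite$head, matrix(z, 1))$out)
  ord <- order(-p, seq_along(p))[seq_len(k)]
  if (!is.null(spec$class_names)) spec$class_names[ord] else as.character(ord)
}

#' Finetune across several head seeds and summarize
#'
#' The multi-seed protocol: one finetuning run per seed (fresh head
#' initialization each time, same frozen backbone), scored on the test set,
#' reported as mean and standard error.
#'
#' @param backbone a `backbone_params`.
#' @param spec a [head_spec].
#' @param train,test task datasets.
#' @param seeds head seeds (default 1:5).
#' @param metric scoring function `(y_true, y_pred) -> scalar`
#'   (default [mae]).
#' @param reaction_roles passed to [strip_and_attach].
#' @param ... passed to [finetune].
#' @return A list with `scores`, `summary` (`mean`, `se`),
#'   `head_fingerprints` and `composites`.
#' @export
finetune_replicates <- function(backbone, spec, train, test, seeds = 1:5,
                                metric = mae, reaction_roles = NULL, ...) {
  runs <- lapply(seeds, function(s) {
    comp <- strip_and_attach(backbone, spec, seed = s,
                             reaction_roles = reaction_roles)
    ft <- finetune(comp, train, seed = s, ...)
    pred <- predict(ft$composite, test)
    truth <- if (!is.null(reaction_roles)) test$yield
             else if (is.data.frame(test)) test$label else test$y
    list(score = metric(truth, pred), composite = ft$composite)
  })
  scores <- vapply(runs, `[[`, numeric(1), "score")
  smry <- if (length(scores) >= 2L) summarize_runs(scores)
          else c(mean = scores, se = NA_real_)
  list(scores = scores, summary = smry,
       head_fingerprints = vapply(runs, function(r) head_fingerprint(r$composite),
                                  character(1)),
       composites = lapply(runs, `[[`, "composite"))
}
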