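#' Backbone configuration
#'
#' Architecture hyperparameters for the message passing neural network that
#' underlies the foundational model. Messages are conditioned on the bond
#' order category (single/double/triple/aromatic), update and message weights
#' are shared across message-passing rounds, and the molecule-level latent is
#' the post-pooling penultimate activation — the vector transfer learning
#' reuses. Defaults are sized for CPU work and are fully config-exposed.
#'
#' @param hidden_dim per-atom hidden state width (default 128).
#' @param message_steps number of message-passing rounds (default 3; 0 means
#'   hidden states are functions of each atom's own features only).
#' @param readout_dim latent vector width (default 256).
#' @param aggregation atom-state pooling, `"sum"` (default) or `"mean"`.
#' @param seed parameter initialization seed.
#' @param vocabulary element vocabulary for featurization.
#' @param geometry a [geometry_config] fixing the geometry-head widths.
#' @return A list of class `backbone_config`.
#' @export
backbone_config <- function(hidden_dim = 128L, message_steps = 3L,
                            readout_dim = 256L,
                            aggregation = c("sum", "mean"), seed = 1L,
                            vocabulary = default_element_vocabulary(),
                            geometry = geometry_config()) {
  stopifnot(hidden_dim >= 1L, readout_dim >= 1L, message_steps >= 0L)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 message_steps = as.integer(message_steps),
                 readout_dim = as.integer(readout_dim),
                 aggregation = match.arg(aggregation),
                 seed = as.integer(seed),
                 vocabulary = vocabulary,
                 geometry = geometry),
            class = "backbone_config")
}

.BOND_ORDERS <- c("single", "double", "triple", "aromatic")

#' Initialize backbone parameters
#'
#' Gaussian initialization scaled by 1/sqrt(fan-in), deterministic in
#' `config$seed`.
#'
#' @param config a [backbone_config].
#' @return A list of class `backbone_params` with named parameter matrices,
#'   the config, and a content `fingerprint`.
#' @export
init_backbone <- function(config = backbone_config()) {
  f <- atom_feature_width(config$vocabulary)
  h <- config$hidden_dim; r <- config$readout_dim
  K <- config$geometry$max_neighbors; P <- config$geometry$max_angle_pairs
  set.seed(config$seed)
  mk <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)
  params <- list(
    W_in = mk(f, h), b_in = numeric(h),
    U = mk(h, h), b_u = numeric(h),
    W_single = mk(h, h), W_double = mk(h, h), W_triple = mk(h, h),
    W_aromatic = mk(h, h),
    W_r = mk(h, r), b_r = numeric(r),
    W_d = mk(h + r, K), b_d = numeric(K),
    W_a = mk(h + r, P), b_a = numeric(P)
  )
  new_backbone_params(params, config)
}

new_backbone_params <- function(params, config) {
  structure(list(params = params, config = config,
                 fingerprint = params_fingerprint(params)),
            class = "backbone_params")
}

#' @export
print.backbone_params <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<backbone_params: hidden %d, steps %d, latent %d, %s pooling, %d parameters, fingerprint %s>\n",
              x$config$hidden_dim, x$config$message_steps,
              x$config$readout_dim, x$config$aggregation, np, x$fingerprint))
  invisible(x)
}

#' Content fingerprint of a parameter set
#'
#' A deterministic hash over every parameter tensor (shape and values at full
#' double precision). Any change to any parameter changes the fingerprint;
#' it is the freeze-contract witness for transfer learning.
#'
#' @param params named list of numeric arrays.
#' @return Character scalar (8 hex digits).
#' @export
params_fingerprint <- function(params) {
  acc <- character()
  for (nm in sort(names(params))) {
    x <- params[[nm]]
    acc <- c(acc, nm, paste(dim(x), collapse = "x"),
             sprintf("%.17g", c(length(x), sum(x), sum(x * x),
                                sum(x * seq_along(x)))))
  }
  fnv1a32(paste(acc, collapse = "|"))
}

# 32-bit FNV-1a over the UTF-8 bytes of a string. Exact in double arithmetic:
# the XOR only touches the low byte, and the 32-bit modular multiply is split
# into 16-bit halves to stay below 2^53.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- h - h %% 256 + bitwXor(as.integer(h %% 256), as.integer(b))
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  # h < 2^32 exceeds integer range; format the two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# adjacency matrices per bond order (dense; molecules are small)
order_adjacency <- function(graph) {
  n <- n_atoms(graph)
  out <- lapply(.BOND_ORDERS, function(o) matrix(0, n, n))
  names(out) <- .BOND_ORDERS
  b <- graph$bonds
  for (k in seq_len(nrow(b))) {
    o <- b$order[k]
    out[[o]][b$a1[k], b$a2[k]] <- 1
    out[[o]][b$a2[k], b$a1[k]] <- 1
  }
  out
}

# forward pass for one molecule; returns atom states (+ cache for backprop)
backbone_forward <- function(graph, backbone, with_cache = FALSE) {
  cfg <- backbone$config
  p <- backbone$params
  X <- featurize_atoms(graph, cfg$vocabulary)
  if (ncol(X) != nrow(p$W_in))
    stop("feature width ", ncol(X), " does not match W_in rows ", nrow(p$W_in))
  A <- order_adjacency(graph)
  H <- tanh(sweep(X %*% p$W_in, 2, p$b_in, "+"))
  Hs <- list(H)
  W_o <- list(single = p$W_single, double = p$W_double,
              triple = p$W_triple, aromatic = p$W_aromatic)
  for (t in seq_len(cfg$message_steps)) {
    M <- matrix(0, nrow(H), ncol(H))
    for (o in .BOND_ORDERS) M <- M + A[[o]] %*% (H %*% W_o[[o]])
    H <- tanh(sweep(H %*% p$U + M, 2, p$b_u, "+"))
    Hs[[t + 1L]] <- H
  }
  pooled <- if (cfg$aggregation == "sum") colSums(H) else colMeans(H)
  z <- tanh(drop(pooled %*% p$W_r) + p$b_r)
  out <- list(atom_states = H, pooled = pooled, latent = z)
  if (with_cache) out$cache <- list(X = X, A = A, Hs = Hs)
  out
}

#' Per-atom hidden states from the MPNN
#'
#' Runs `message_steps` rounds of bond-order-conditioned neighbour
#' aggregation and update from the initial atom features. Deterministic given
#' parameters; equivariant under atom relabelling, so chemically identical
#' atoms (e.g. the six carbons of benzene) receive identical states.
#'
#' @param graph_batch a [molecular_graph] or list of them.
#' @param backbone a `backbone_params` object.
#' @return A matrix (atoms x hidden_dim) for a single graph, else a list of
#'   such matrices.
#' @export
encode_atoms <- function(graph_batch, backbone) {
  if (inherits(graph_batch, "molecular_graph"))
    return(backbone_forward(graph_batch, backbone)$atom_states)
  lapply(graph_batch, function(g) backbone_forward(g, backbone)$atom_states)
}

#' Molecule-level latent vector
#'
#' Permutation-invariant pooling of the atom states followed by the
#' penultimate transform. This is "the latent space": the fixed-length
#' molecular embedding that every transfer head consumes.
#'
#' @param graph a [molecular_graph].
#' @param backbone a `backbone_params` object.
#' @return Numeric vector of length `readout_dim`.
#' @export
readout_latent <- function(graph, backbone) {
  if (n_atoms(graph) == 0L) stop("cannot read out an empty graph")
  backbone_forward(graph, backbone)$latent
}

#' Predict geometry targets from the 2D graph
#'
#' The pretraining output layer: per-atom heads fed with the atom state
#' concatenated with the molecule latent emit padded neighbour-distance
#' (softplus, Angstrom) and angle (scaled sigmoid, degrees) predictions in
#' the [extract_targets] layout. Masks are derived from the graph's bonded
#' degrees. This is the layer that transfer learning discards and replaces.
#'
#' @param graph a [molecular_graph].
#' @param backbone a `backbone_params` object.
#' @return A `geometry_targets` object with predicted values.
#' @export
predict_geometry <- function(graph, backbone) {
  if (inherits(backbone, "composite_model"))
    stop("geometry prediction is unavailable on a composite model: ",
         "the geometry output layer was discarded at head attachment")
  fw <- backbone_forward(graph, backbone)
  geometry_head(fw, graph, backbone)$pred
}

geometry_head <- function(fw, graph, backbone) {
  p <- backbone$params
  cfg <- backbone$config$geometry
  n <- nrow(fw$atom_states)
  Din <- cbind(fw$atom_states, matrix(fw$latent, n, length(fw$latent),
                                      byrow = TRUE))
  D_raw <- sweep(Din %*% p$W_d, 2, p$b_d, "+")
  A_raw <- sweep(Din %*% p$W_a, 2, p$b_a, "+")
  dist <- log1p(exp(D_raw))            # softplus > 0
  sA <- 1 / (1 + exp(-A_raw))
  ang <- 180 * sA
  masks <- graph_target_masks(graph, cfg)
  pred <- structure(list(distances = dist * masks$distance_mask,
                         angles = ang * masks$angle_mask,
                         distance_mask = masks$distance_mask,
                         angle_mask = masks$angle_mask,
                         neighbor_order = masks$neighbor_order,
                         config = cfg),
                    class = "geometry_targets")
  list(pred = pred, Din = Din, D_raw = D_raw, A_raw = A_raw, sA = sA)
}

# masks implied by the bonded graph (degree-capped)
graph_target_masks <- function(graph, cfg) {
  n <- n_atoms(graph)
  K <- cfg$max_neighbors; P <- cfg$max_angle_pairs
  nb <- neighbor_list(graph)
  dm <- matrix(0, n, K); am <- matrix(0, n, P)
  nb_used <- vector("list", n)
  for (i in seq_len(n)) {
    k <- min(length(nb[[i]]), K)
    nb_used[[i]] <- nb[[i]][seq_len(k)]
    if (k > 0) dm[i, seq_len(k)] <- 1
    if (k >= 2) am[i, seq_len(min(choose(k, 2), P))] <- 1
  }
  list(distance_mask = dm, angle_mask = am, neighbor_order = nb_used)
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load a backbone checkpoint
#'
#' JSON named-tensor archive with the config and content fingerprint; loading
#' re-derives the fingerprint and refuses a corrupted file.
#'
#' @param backbone a `backbone_params` object.
#' @param path file path.
#' @return `save_backbone()` returns `path` invisibly; `load_backbone()` the
#'   restored `backbone_params`.
#' @export
save_backbone <- function(backbone, path) {
  cfg <- backbone$config
  payload <- list(
    config = list(hidden_dim = cfg$hidden_dim,
                  message_steps = cfg$message_steps,
                  readout_dim = cfg$readout_dim,
                  aggregation = cfg$aggregation, seed = cfg$seed,
                  vocabulary = cfg$vocabulary,
                  geometry = list(max_neighbors = cfg$geometry$max_neighbors,
                                  max_angle_pairs = cfg$geometry$max_angle_pairs,
                                  neighbor_mode = cfg$geometry$neighbor_mode)),
    params = lapply(backbone$params, function(x)
      list(dim = dim_or_length(x), values = as.numeric(x))),
    fingerprint = backbone$fingerprint
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17)), path)
  invisible(path)
}

dim_or_length <- function(x) if (is.matrix(x)) dim(x) else length(x)

#' @rdname save_backbone
#' @export
load_backbone <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- backbone_config(
    hidden_dim = x$config$hidden_dim, message_steps = x$config$message_steps,
    readout_dim = x$config$readout_dim, aggregation = x$config$aggregation,
    seed = x$config$seed, vocabulary = x$config$vocabulary,
    geometry = geometry_config(x$config$geometry$max_neighbors,
                               x$config$geometry$max_angle_pairs,
                               x$config$geometry$neighbor_mode))
  params <- lapply(x$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$values, p$dim[1], p$dim[2])
    else as.numeric(p$values)
  })
  bb <- new_backbone_params(params, cfg)
  if (!identical(bb$fingerprint, x$fingerprint))
    stop("checkpoint fingerprint mismatch: file is corrupted or was edited")
  bb
}
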