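#' Geometry target configuration
#'
#' Width settings for the rotation/translation-invariant geometry proxies the
#' foundational model learns: for each atom, the through-space distances to
#' its neighbours and the angles each neighbour pair forms at that atom.
#' Defaults cover standard organic valences: up to 4 neighbours and
#' choose(4, 2) = 6 angle pairs.
#'
#' @param max_neighbors maximum neighbours per atom (default 4).
#' @param max_angle_pairs maximum angle pairs per atom (default 6).
#' @param neighbor_mode `"bonded"` (1-hop bonded neighbours, the default — it
#'   makes "the corresponding bond angles" well-defined) or `"spatial_knn"`
#'   (nearest atoms in space, bonded or not).
#' @return A list of class `geometry_config`.
#' @export
geometry_config <- function(max_neighbors = 4L, max_angle_pairs = 6L,
                            neighbor_mode = c("bonded", "spatial_knn")) {
  stopifnot(max_neighbors >= 1L, max_angle_pairs >= 1L)
  structure(list(max_neighbors = as.integer(max_neighbors),
                 max_angle_pairs = as.integer(max_angle_pairs),
                 neighbor_mode = match.arg(neighbor_mode)),
            class = "geometry_config")
}

#' Extract per-atom geometry targets from 3D coordinates
#'
#' Computes, for every atom, the Euclidean distances to its neighbours
#' (bonded 1-hop by default, or spatial k-nearest) and the angle at the atom
#' for every pair of those neighbours, padded and masked to fixed widths.
#' Distances and angles are invariant to rigid rotation, translation and
#' reflection of the coordinates, which is the entire point: they are a
#' conformation proxy a 2D model can be trained against.
#'
#' Neighbours are taken in canonical atom order (ties in spatial mode broken
#' by index) and truncated at `max_neighbors`; angle pairs are enumerated in
#' lexicographic neighbour order and truncated at `max_angle_pairs`.
#'
#' @param graph a [molecular_graph].
#' @param coords numeric matrix (n_atoms x 3), Angstrom, row i = atom i.
#' @param config a [geometry_config].
#' @return A list of class `geometry_targets` with `distances`, `angles`
#'   (matrices n_atoms x width, padded with 0), `distance_mask`, `angle_mask`
#'   (0/1 matrices), and `neighbor_order` (list of neighbour index vectors).
#' @export
extract_targets <- function(graph, coords, config = geometry_config()) {
  coords <- as.matrix(coords)
  n <- n_atoms(graph)
  if (nrow(coords) != n || ncol(coords) != 3)
    stop("coords must be an n_atoms x 3 matrix aligned with the graph")
  if (any(!is.finite(coords))) stop("coords contain non-finite values")

  K <- config$max_neighbors
  P <- config$max_angle_pairs
  nb <- if (config$neighbor_mode == "bonded") {
    neighbor_list(graph)
  } else {
    lapply(seq_len(n), function(i) {
      d <- sqrt(colSums((t(coords) - coords[i, ])^2))
      d[i] <- Inf
      ord <- order(d, seq_len(n))
      ord[seq_len(min(K, n - 1L))]
    })
  }

  dist_m <- matrix(0, n, K)
  dist_mask <- matrix(0, n, K)
  ang_m <- matrix(0, n, P)
  ang_mask <- matrix(0, n, P)
  nb_used <- vector("list", n)

  for (i in seq_len(n)) {
    nbr <- nb[[i]]
    if (length(nbr) > K) nbr <- nbr[seq_len(K)]  # canonical-rank truncation
    nb_used[[i]] <- nbr
    k <- length(nbr)
    if (k == 0L) next
    vecs <- coords[nbr, , drop = FALSE] - matrix(coords[i, ], k, 3, byrow = TRUE)
    d <- sqrt(rowSums(vecs^2))
    if (any(d < 1e-8)) {
      j <- nbr[which(d < 1e-8)[1]]
      stop(sprintf("degenerate geometry: atoms %d and %d coincide", i, j))
    }
    dist_m[i, seq_len(k)] <- d
    dist_mask[i, seq_len(k)] <- 1
    if (k >= 2L) {
      pairs <- utils::combn(k, 2)
      np <- min(ncol(pairs), P)
      for (p in seq_len(np)) {
        u <- vecs[pairs[1, p], ] / d[pairs[1, p]]
        v <- vecs[pairs[2, p], ] / d[pairs[2, p]]
        cosang <- max(-1, min(1, sum(u * v)))
        ang_m[i, p] <- acos(cosang) * 180 / pi
        ang_mask[i, p] <- 1
      }
    }
  }
  structure(list(distances = dist_m, angles = ang_m,
                 distance_mask = dist_mask, angle_mask = ang_mask,
                 neighbor_order = nb_used, config = config),
            class = "geometry_targets")
}

#' Verify SE(3) invariance of geometry targets
#'
#' Applies `n_transforms` random rigid rotations + translations to the
#' coordinates, re-extracts targets, and returns the largest element-wise
#' absolute deviation from the untransformed targets over masked-in entries.
#' By construction this should be at numerical noise level (<= 1e-6).
#'
#' @param graph a [molecular_graph].
#' @param coords n x 3 coordinate matrix.
#' @param n_transforms number of random rigid transforms (>= 0).
#' @param seed RNG seed for the transforms.
#' @param config a [geometry_config].
#' @return Maximum absolute deviation (0 when `n_transforms` is 0).
#' @export
targets_invariance_check <- function(graph, coords, n_transforms = 10L,
                                     seed = 1L, config = geometry_config()) {
  if (n_transforms < 0L) stop("n_transforms must be >= 0")
  base <- extract_targets(graph, coords, config)
  if (n_transforms == 0L) return(0)
  rng <- local({ set.seed(seed); function(n) stats::rnorm(n) })
  dev <- 0
  for (t in seq_len(n_transforms)) {
    R <- random_rotation(rng)
    shift <- rng(3) * 5
    tc <- coords %*% R + matrix(shift, nrow(coords), 3, byrow = TRUE)
    dev <- max(dev, target_deviation(base, extract_targets(graph, tc, config)))
  }
  dev
}

random_rotation <- function(rng) {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  m <- matrix(rng(9), 3, 3)
  qr_ <- qr(m)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

target_deviation <- function(a, b) {
  max(abs(a$distances - b$distances) * a$distance_mask,
      abs(a$angles - b$angles) * a$angle_mask,
      abs(a$distance_mask - b$distance_mask),
      abs(a$angle_mask - b$angle_mask))
}

#' Flatten geometry targets to a per-atom table
#'
#' One row per atom (molecule id, atom index, padded distances, padded
#' angles, masks), suitable for writing to CSV for inspection.
#'
#' @param targets a `geometry_targets` object.
#' @param molecule_id identifier recycled over rows.
#' @return A data.frame.
#' @export
targets_as_table <- function(targets, molecule_id = NA_character_) {
  n <- nrow(targets$distances)
  K <- ncol(targets$distances); P <- ncol(targets$angles)
  out <- data.frame(molecule_id = rep(molecule_id, n), atom = seq_len(n))
  for (k in seq_len(K)) out[[paste0("dist_", k)]] <- targets$distances[, k]
  for (p in seq_len(P)) out[[paste0("angle_", p)]] <- targets$angles[, p]
  for (k in seq_len(K)) out[[paste0("dist_mask_", k)]] <- targets$distance_mask[, k]
  for (p in seq_len(P)) out[[paste0("angle_mask_", p)]] <- targets$angle_mask[, p]
  out
}
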