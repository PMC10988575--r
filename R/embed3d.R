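# Constructive 3D embedding for synthetic fixtures.
#
# The pretraining corpus this package emulates is experimental crystal
# geometry, which is not redistributable; fixtures instead get conformers
# built constructively: ring atoms from rigid templates (regular hexagon /
# chair / pentagon at ideal bond lengths), acyclic atoms placed one at a time
# at the ideal bond length in the direction that best avoids the parent's
# existing substituents, with seeded randomization and a collision check.
# The result is a deliberate, documented surrogate: locally realistic bond
# lengths and angles, no claim of global conformational realism.

embed_coordinates <- function(graph, seed = 1L, jitter_sd = 0.01,
                              ring_template = NULL, max_tries = 30L) {
  set.seed(seed)
  n <- n_atoms(graph)
  nb <- neighbor_list(graph)
  border <- bond_order_lookup(graph)
  blen <- function(i, j)
    ideal_bond_length(graph$atoms$element[i], graph$atoms$element[j],
                      border[[paste(min(i, j), max(i, j))]])
  coords <- matrix(NA_real_, n, 3)

  # rigid template for ring atoms, if declared by the generator
  if (!is.null(ring_template)) {
    idx <- ring_template$atoms
    m <- length(idx)
    L <- blen(idx[1], idx[2])
    radius <- L / (2 * sin(pi / m))
    theta <- 2 * pi * (seq_len(m) - 1) / m
    zs <- if (ring_template$kind == "chair") 0.25 * (-1)^(seq_len(m)) else 0
    coords[idx, ] <- cbind(radius * cos(theta), radius * sin(theta), zs)
  }

  placed <- !is.na(coords[, 1])
  if (!any(placed)) {
    coords[1, ] <- 0
    placed[1] <- TRUE
  }

  # BFS placement from placed seeds
  queue <- which(placed)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in nb[[v]]) {
      if (placed[w]) next
      L <- blen(v, w)
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        dirs <- coords[nb[[v]][placed[nb[[v]]]], , drop = FALSE]
        repel <- if (nrow(dirs)) {
          u <- sweep(dirs, 2, coords[v, ])
          -colSums(u / sqrt(rowSums(u^2)))
        } else c(0, 0, 0)
        noise <- stats::rnorm(3)
        dir <- repel + (0.55 + 0.25 * (try - 1) / max_tries) *
          noise / sqrt(sum(noise^2)) * max(1, sqrt(sum(repel^2)))
        dir <- dir / sqrt(sum(dir^2))
        cand <- coords[v, ] + L * dir
        others <- which(placed); others <- setdiff(others, c(v, nb[[w]]))
        mind <- if (length(others))
          min(sqrt(rowSums(sweep(coords[others, , drop = FALSE], 2, cand)^2)))
        else Inf
        if (mind > 1.2) { ok <- TRUE; break }
      }
      if (!ok) stop("embedding failure: could not place atom ", w)
      coords[w, ] <- cand
      placed[w] <- TRUE
      queue <- c(queue, w)
    }
  }
  if (any(!placed)) stop("embedding failure: disconnected atoms left unplaced")
  if (jitter_sd > 0) coords <- coords + stats::rnorm(3 * n, sd = jitter_sd)
  unname(coords)
}
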