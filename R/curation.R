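# Dataset curation filters applied before pretraining: rare-element removal,
# and removal of ambiguous-bonding records and conformational polymorphs.

#' Filter molecules containing rare elements
#'
#' Counts every occurrence of every element across the dataset (before any
#' dropping), then drops each molecule that contains any element whose total
#' occurrence count is below `min_count`. The default threshold of 100
#' matches the curation used for crystal-structure pretraining at corpus
#' scale. Idempotent: re-filtering the kept set changes nothing.
#'
#' @param dataset list of [molecular_graph]s, or of records with a `$graph`.
#' @param min_count minimum total occurrences for an element to be common
#'   (default 100).
#' @return A list with `kept`, `dropped` (same record types as the input) and
#'   `dropped_elements` (the rare element(s) in each dropped molecule).
#' @export
filter_rare_elements <- function(dataset, min_count = 100L) {
  stopifnot(min_count >= 0L)
  graphs <- lapply(dataset, as_graph)
  counts <- table(unlist(lapply(graphs, function(g) g$atoms$element)))
  rare <- names(counts)[counts < min_count]
  has_rare <- lapply(graphs, function(g) intersect(unique(g$atoms$element), rare))
  drop <- lengths(has_rare) > 0L
  list(kept = dataset[!drop], dropped = dataset[drop],
       dropped_elements = vapply(has_rare[drop], paste, character(1),
                                 collapse = ","),
       element_counts = counts)
}

as_graph <- function(x) {
  if (inherits(x, "molecular_graph")) x
  else if (is.list(x) && inherits(x$graph, "molecular_graph")) x$graph
  else stop("expected a molecular_graph or a record containing one")
}

#' Best-fit RMSD after Kabsch superposition
#'
#' Centers both coordinate sets, finds the optimal proper rotation by SVD and
#' returns the root-mean-square deviation. Rows must correspond atom-for-atom
#' (canonical order gives this for conformers of the same molecule).
#'
#' @param a,b n x 3 coordinate matrices.
#' @return RMSD in the coordinate units.
#' @export
kabsch_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(identical(dim(a), dim(b)), ncol(a) == 3)
  a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(a, b))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((a %*% t(R) - b)^2)))
}

#' Filter ambiguous-bonding records and conformational polymorphs
#'
#' Two curation rules applied to a structure set: records whose bond
#' perception failed or was flagged ambiguous are dropped (pass
#' `load_structures()`'s rejects through the `rejects` argument, or mark a
#' record with `$ambiguous = TRUE`); and for groups of records sharing one
#' canonical graph, the whole group is dropped if any pair of conformers
#' differs by more than `rmsd_threshold` after Kabsch superposition — the
#' operational definition of "conformational polymorphs with a significant
#' difference in their conformations".
#'
#' @param structures list of `list(graph, coords)` records.
#' @param rmsd_threshold heavy-atom RMSD above which a conformer pair is a
#'   significant polymorph (Angstrom; default 1.0, config-exposed because no
#'   canonical value exists).
#' @param rejects optional data.frame of upstream parse rejects (reported in
#'   the dropped reasons, for bookkeeping).
#' @return A list with `kept`, `dropped` and `dropped_reasons`.
#' @export
filter_ambiguous_and_polymorphs <- function(structures, rmsd_threshold = 1.0,
                                            rejects = NULL) {
  stopifnot(rmsd_threshold > 0)
  n <- length(structures)
  reason <- rep(NA_character_, n)

  flagged <- vapply(structures, function(s) isTRUE(s$ambiguous), logical(1))
  reason[flagged] <- "ambiguous bonding"

  sigs <- vapply(structures, function(s) graph_signature(s$graph), character(1))
  for (sig in unique(sigs)) {
    idx <- which(sigs == sig & !flagged)
    if (length(idx) < 2L) next
    polymorph <- FALSE
    for (i in seq_along(idx)[-1]) for (j in seq_len(i - 1L)) {
      r <- kabsch_rmsd(structures[[idx[i]]]$coords, structures[[idx[j]]]$coords)
      if (r > rmsd_threshold) { polymorph <- TRUE; break }
    }
    if (polymorph)
      reason[idx] <- sprintf("conformational polymorph (RMSD > %.2f A)",
                             rmsd_threshold)
  }

  drop <- !is.na(reason)
  dropped_reasons <- reason[drop]
  if (!is.null(rejects) && nrow(rejects))
    dropped_reasons <- c(dropped_reasons,
                         paste0("ambiguous bonding: ", rejects$reason))
  list(kept = structures[!drop], dropped = structures[drop],
       dropped_reasons = dropped_reasons)
}
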