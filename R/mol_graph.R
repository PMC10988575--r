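#' Molecular graph objects
#'
#' A `molecular_graph` is the 2D input to every model in this package: a
#' heavy-atom graph with per-atom chemical attributes and typed bonds.
#' Hydrogens are folded into an `n_hydrogens` count per heavy atom (explicit-H
#' graphs balloon geometry-target widths for no modelling gain); readers can
#' optionally retain explicit hydrogens.
#'
#' Fields:
#' \describe{
#'   \item{atoms}{data.frame with columns `element`, `formal_charge`,
#'     `degree` (heavy-atom bonds), `aromatic`, `n_hydrogens`, `chiral_tag`
#'     (one of `"none"`, `"clockwise"`, `"counterclockwise"`).}
#'   \item{bonds}{data.frame with columns `a1`, `a2` (atom indices, `a1 < a2`)
#'     and `order` (one of `"single"`, `"double"`, `"triple"`, `"aromatic"`).}
#'   \item{name}{optional identifier.}
#'   \item{source_smiles}{the SMILES the graph was parsed from, if any.}
#' }
#'
#' Atoms are stored in a canonical order (iterative neighbourhood refinement
#' with deterministic tie-breaking) so that serialization is stable and
#' enantiomer pairs align row-for-row; model outputs never depend on the
#' ordering (tested as a permutation-invariance property).
#'
#' @param atoms,bonds see above.
#' @param name,source_smiles optional identifiers.
#' @param canonicalize reorder atoms canonically (default TRUE).
#' @return A `molecular_graph` object.
#' @export
molecular_graph <- function(atoms, bonds, name = NULL, source_smiles = NULL,
                            canonicalize = TRUE) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms) == 0L) stop("molecular_graph needs at least one atom")
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- 0L
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  if (is.null(atoms$n_hydrogens)) atoms$n_hydrogens <- 0L
  if (is.null(atoms$chiral_tag)) atoms$chiral_tag <- "none"
  bad_tag <- !atoms$chiral_tag %in% c("none", "clockwise", "counterclockwise")
  if (any(bad_tag)) stop("invalid chiral_tag: ", atoms$chiral_tag[bad_tag][1])

  if (is.null(bonds) || (is.data.frame(bonds) && nrow(bonds) == 0L) ||
      (!is.data.frame(bonds) && length(bonds) == 0L)) {
    bonds <- data.frame(a1 = integer(), a2 = integer(),
                        order = character(), stringsAsFactors = FALSE)
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  }
  if (nrow(bonds)) {
    if (any(bonds$a1 == bonds$a2)) stop("bond with identical endpoints")
    rng <- range(c(bonds$a1, bonds$a2))
    if (rng[1] < 1L || rng[2] > nrow(atoms)) stop("bond endpoint out of range")
    if (any(!bonds$order %in% c("single", "double", "triple", "aromatic")))
      stop("invalid bond order")
    swap <- bonds$a1 > bonds$a2
    tmp <- bonds$a1[swap]; bonds$a1[swap] <- bonds$a2[swap]; bonds$a2[swap] <- tmp
    key <- paste(bonds$a1, bonds$a2)
    if (anyDuplicated(key)) stop("duplicate bond between atoms ",
                                 key[duplicated(key)][1])
  }
  atoms$degree <- tabulate_degree(bonds, nrow(atoms))

  g <- structure(
    list(atoms = atoms, bonds = bonds, name = name,
         source_smiles = source_smiles),
    class = "molecular_graph"
  )
  if (canonicalize) g <- canonicalize_graph(g)
  g
}

tabulate_degree <- function(bonds, n) {
  if (!nrow(bonds)) return(integer(n))
  tabulate(c(bonds$a1, bonds$a2), nbins = n)
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph%s: %d atoms, %d bonds%s>\n",
              if (!is.null(x$name)) paste0(" ", x$name) else "",
              nrow(x$atoms), nrow(x$bonds),
              if (!is.null(x$source_smiles))
                paste0(", from ", x$source_smiles) else ""))
  invisible(x)
}

n_atoms <- function(graph) nrow(graph$atoms)
n_bonds <- function(graph) nrow(graph$bonds)

# Adjacency as a list of integer vectors (1-hop neighbours, canonical order).
neighbor_list <- function(graph) {
  n <- n_atoms(graph)
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer()
  b <- graph$bonds
  for (k in seq_len(nrow(b))) {
    nb[[b$a1[k]]] <- c(nb[[b$a1[k]]], b$a2[k])
    nb[[b$a2[k]]] <- c(nb[[b$a2[k]]], b$a1[k])
  }
  lapply(nb, sort)
}

# ---- canonical ranking -----------------------------------------------------

# Iterative neighbourhood (Weisfeiler-Lehman style) refinement over
# (element, degree, charge, H-count, aromatic) seeds, with deterministic
# tie-breaking: the lowest-indexed atom of the first non-singleton class is
# individualized and refinement re-run. Chiral tags are excluded so enantiomer
# pairs receive identical orderings.
canonical_ranks <- function(graph) {
  a <- graph$atoms
  n <- nrow(a)
  if (n == 1L) return(1L)
  nb <- neighbor_list(graph)
  b <- graph$bonds
  ord_code <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)
  bond_code <- matrix(0L, n, n)
  for (k in seq_len(nrow(b)))
    bond_code[b$a1[k], b$a2[k]] <- bond_code[b$a2[k], b$a1[k]] <-
      ord_code[[b$order[k]]]

  seed <- paste(a$element, a$degree, a$formal_charge, a$n_hydrogens,
                as.integer(a$aromatic))
  codes <- match(seed, sort(unique(seed)))

  refine <- function(codes) {
    repeat {
      sig <- vapply(seq_len(n), function(i) {
        nbr <- nb[[i]]
        if (!length(nbr)) return(paste0(codes[i], "|"))
        pairs <- sort(paste0(bond_code[i, nbr], ":", codes[nbr]))
        paste0(codes[i], "|", paste(pairs, collapse = ","))
      }, character(1))
      new_codes <- match(sig, sort(unique(sig)))
      # sig embeds the old code, so the new partition refines the old one;
      # equal class counts therefore means the partition is stable
      if (length(unique(new_codes)) == length(unique(codes)))
        return(new_codes)
      codes <- new_codes
    }
  }

  codes <- refine(codes)
  while (length(unique(codes)) < n) {
    tab <- table(codes)
    cls <- as.integer(names(tab)[tab > 1L])[1]
    pick <- which(codes == cls)[1]
    # individualize: give the picked atom a strictly smaller fractional code
    frac <- codes - 0.5 * (seq_len(n) == pick)
    codes <- match(frac, sort(unique(frac)))
    codes <- refine(codes)
  }
  codes
}

canonicalize_graph <- function(graph) {
  ranks <- canonical_ranks(graph)
  if (all(ranks == seq_along(ranks))) {
    graph$atoms <- graph$atoms[order(ranks), , drop = FALSE]
    rownames(graph$atoms) <- NULL
    graph$bonds <- sort_bonds(graph$bonds)
    return(graph)
  }
  permute_graph(graph, ranks)
}

# new_index[i] gives the position atom i moves to.
permute_graph <- function(graph, new_index) {
  inv <- order(new_index)
  graph$atoms <- graph$atoms[inv, , drop = FALSE]
  rownames(graph$atoms) <- NULL
  if (nrow(graph$bonds)) {
    graph$bonds$a1 <- new_index[graph$bonds$a1]
    graph$bonds$a2 <- new_index[graph$bonds$a2]
    swap <- graph$bonds$a1 > graph$bonds$a2
    tmp <- graph$bonds$a1[swap]
    graph$bonds$a1[swap] <- graph$bonds$a2[swap]
    graph$bonds$a2[swap] <- tmp
  }
  graph$bonds <- sort_bonds(graph$bonds)
  graph
}

sort_bonds <- function(bonds) {
  if (!nrow(bonds)) return(bonds)
  bonds <- bonds[order(bonds$a1, bonds$a2), , drop = FALSE]
  rownames(bonds) <- NULL
  bonds
}

# ---- signatures ------------------------------------------------------------

#' Canonical graph signature
#'
#' A canonical string identifying a molecular graph up to atom relabelling,
#' used for duplicate detection (k-fold co-assignment), conformer grouping in
#' the polymorph filter, and scaffold keys. Two enantiomers differ only when
#' `use_chirality = TRUE`.
#'
#' @param graph a [molecular_graph].
#' @param use_chirality include chiral tags in the signature.
#' @return A character scalar.
#' @export
graph_signature <- function(graph, use_chirality = TRUE) {
  g <- canonicalize_graph(graph)
  a <- g$atoms
  atom_part <- paste(a$element, a$formal_charge, a$n_hydrogens,
                     as.integer(a$aromatic),
                     if (use_chirality) a$chiral_tag else "x",
                     sep = ":", collapse = ";")
  b <- g$bonds
  bond_part <- if (nrow(b)) paste(b$a1, b$a2, b$order, sep = ":", collapse = ";") else ""
  paste(atom_part, bond_part, sep = "|")
}

# ---- scaffolds -------------------------------------------------------------

#' Bemis-Murcko scaffold key
#'
#' Iteratively removes terminal (degree-1) heavy atoms until only ring systems
#' and their linkers remain — the Bemis-Murcko framework. Acyclic molecules
#' have an empty framework and share the scaffold key `""`. The key is a
#' canonical signature over elements, aromaticity and bond orders only
#' (charges, H-counts and chirality are not part of a framework).
#'
#' @param graph a [molecular_graph].
#' @return A character scalar scaffold key.
#' @export
murcko_scaffold <- function(graph) {
  keep <- rep(TRUE, n_atoms(graph))
  bonds <- graph$bonds
  repeat {
    deg <- tabulate(c(bonds$a1[keep[bonds$a1] & keep[bonds$a2]],
                      bonds$a2[keep[bonds$a1] & keep[bonds$a2]]),
                    nbins = n_atoms(graph))
    drop <- keep & deg <= 1L
    if (!any(drop) || sum(keep & !drop) == 0L) {
      if (all(drop[keep])) return("")  # fully acyclic
      break
    }
    keep[drop] <- FALSE
  }
  idx <- which(keep)
  remap <- integer(n_atoms(graph)); remap[idx] <- seq_along(idx)
  sel <- keep[bonds$a1] & keep[bonds$a2]
  sub_atoms <- data.frame(
    element = graph$atoms$element[idx],
    formal_charge = 0L,
    aromatic = graph$atoms$aromatic[idx],
    n_hydrogens = 0L,
    chiral_tag = "none",
    stringsAsFactors = FALSE
  )
  sub_bonds <- data.frame(a1 = remap[bonds$a1[sel]], a2 = remap[bonds$a2[sel]],
                          order = bonds$order[sel], stringsAsFactors = FALSE)
  sub <- molecular_graph(sub_atoms, sub_bonds, canonicalize = TRUE)
  graph_signature(sub, use_chirality = FALSE)
}

# Ring membership: an atom/bond is in a ring iff it survives iterative
# pruning of degree-1 atoms AND (for bonds) removing the bond keeps its
# endpoints connected. Used by descriptors and the fixture generator.
ring_atoms <- function(graph) {
  n <- n_atoms(graph)
  keep <- rep(TRUE, n)
  bonds <- graph$bonds
  repeat {
    sel <- keep[bonds$a1] & keep[bonds$a2]
    deg <- tabulate(c(bonds$a1[sel], bonds$a2[sel]), nbins = n)
    drop <- keep & deg <= 1L
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  which(keep & tabulate(c(bonds$a1, bonds$a2), nbins = n) >= 2L)
}

count_rings <- function(graph) {
  # cyclomatic number: bonds - atoms + components
  n <- n_atoms(graph)
  comp <- connected_components(graph)
  n_bonds(graph) - n + length(unique(comp))
}

connected_components <- function(graph) {
  n <- n_atoms(graph)
  nb <- neighbor_list(graph)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in nb[[v]]) if (!comp[w]) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

# ---- serialization ---------------------------------------------------------

#' Serialize / deserialize a molecular graph as JSON
#'
#' Round-trips atom count, bond multiset and chiral tags exactly; atoms are
#' stored in their canonical order so indices are stable.
#'
#' @param graph a [molecular_graph].
#' @param json a JSON string produced by `graph_to_json()`.
#' @return `graph_to_json()` a JSON string; `graph_from_json()` a
#'   [molecular_graph].
#' @export
graph_to_json <- function(graph) {
  jsonlite::toJSON(list(
    atoms = graph$atoms,
    bonds = graph$bonds,
    name = graph$name,
    source_smiles = graph$source_smiles
  ), dataframe = "columns", auto_unbox = TRUE, null = "null", digits = I(17))
}

#' @rdname graph_to_json
#' @export
graph_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  atoms <- as.data.frame(x$atoms, stringsAsFactors = FALSE)
  bonds <- if (length(x$bonds$a1)) as.data.frame(x$bonds) else NULL
  molecular_graph(atoms, bonds,
                  name = x$name, source_smiles = x$source_smiles,
                  canonicalize = FALSE)
}

# ---- featurization ---------------------------------------------------------

#' Atom feature matrix
#'
#' Builds the fixed-width per-atom feature rows consumed by the MPNN: one-hot
#' element over `vocabulary`, formal charge, heavy-atom degree, aromaticity
#' flag, hydrogen count, and a 3-slot one-hot chiral tag
#' (none / clockwise / counterclockwise). Featurization is a pure function of
#' the graph: identical graphs give identical matrices.
#'
#' @param graph a [molecular_graph].
#' @param vocabulary element vocabulary; out-of-vocabulary elements are an
#'   error naming the element (this is the hook the rare-element curation
#'   filter relies on).
#' @return A numeric matrix with `attr(, "feature_names")`; one row per atom.
#' @export
featurize_atoms <- function(graph, vocabulary = default_element_vocabulary()) {
  a <- graph$atoms
  oov <- setdiff(unique(a$element), vocabulary)
  if (length(oov))
    stop("element not in vocabulary: ", paste(oov, collapse = ", "))
  n <- nrow(a)
  elem_block <- matrix(0, n, length(vocabulary))
  elem_block[cbind(seq_len(n), match(a$element, vocabulary))] <- 1
  chiral_levels <- c("none", "clockwise", "counterclockwise")
  chiral_block <- matrix(0, n, 3)
  chiral_block[cbind(seq_len(n), match(a$chiral_tag, chiral_levels))] <- 1
  m <- cbind(elem_block, a$formal_charge, a$degree, as.integer(a$aromatic),
             a$n_hydrogens, chiral_block)
  colnames(m) <- NULL
  attr(m, "feature_names") <- c(paste0("element_", vocabulary),
                                "formal_charge", "degree", "aromatic",
                                "n_hydrogens", paste0("chiral_", chiral_levels))
  m
}

#' Width of the atom feature vector for a vocabulary
#' @param vocabulary element vocabulary.
#' @return Integer feature count.
#' @export
atom_feature_width <- function(vocabulary = default_element_vocabulary()) {
  length(vocabulary) + 4L + 3L
}
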