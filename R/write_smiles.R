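#' Write a molecular graph as a SMILES string
#'
#' Depth-first traversal from atom 1 with ring-closure digits for non-tree
#' bonds. Organic-subset atoms are written bare when their hydrogen count
#' matches the implicit-valence rules; anything else (charges, chiral tags,
#' unusual H counts, exotic elements) is written in brackets. The output
#' parses back to an identical graph with [parse_smiles].
#'
#' @param graph a [molecular_graph].
#' @return A SMILES string.
#' @export
write_smiles <- function(graph) {
  n <- n_atoms(graph)
  a <- graph$atoms
  nb <- neighbor_list(graph)
  border <- bond_order_lookup(graph)

  # ring-closure bonds = non-tree edges of a DFS forest
  visited <- rep(FALSE, n)
  tree_parent <- rep(NA_integer_, n)
  ring_bonds <- list()
  for (root in seq_len(n)) {
    if (visited[root]) next
    stack <- root; visited[root] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (w in nb[[v]]) {
        if (!visited[w]) {
          visited[w] <- TRUE; tree_parent[w] <- v
          stack <- c(stack, w)
        } else if (w != tree_parent[v] && v < w) {
          # non-tree edge; dedupe by orientation
          already <- any(vapply(ring_bonds, function(rb)
            identical(sort(c(rb[1], rb[2])), c(v, w)), logical(1)))
          if (!is_tree_edge(v, w, tree_parent) && !already)
            ring_bonds[[length(ring_bonds) + 1L]] <- c(v, w)
        }
      }
    }
  }
  ring_digit <- new.env(parent = emptyenv())
  for (k in seq_along(ring_bonds)) {
    key <- paste(ring_bonds[[k]], collapse = "-")
    assign(key, k, envir = ring_digit)
  }
  ring_at <- vector("list", n)
  for (k in seq_along(ring_bonds)) {
    rb <- ring_bonds[[k]]
    ring_at[[rb[1]]] <- c(ring_at[[rb[1]]], k)
    ring_at[[rb[2]]] <- c(ring_at[[rb[2]]], k)
  }
  ring_other <- lapply(seq_len(n), function(v)
    vapply(ring_at[[v]], function(k) setdiff(ring_bonds[[k]], v), integer(1)))

  bond_sym <- function(v, w) {
    o <- border[[paste(min(v, w), max(v, w))]]
    both_arom <- a$aromatic[v] && a$aromatic[w]
    switch(o,
           single = if (both_arom) "-" else "",
           double = "=", triple = "#",
           aromatic = if (both_arom) "" else ":")
  }

  emitted <- rep(FALSE, n)
  emit <- function(v, parent) {
    emitted[v] <<- TRUE
    s <- atom_token(a[v, ], border, v, nb)
    for (k in ring_at[[v]]) {
      other <- setdiff(ring_bonds[[k]], v)
      dig <- if (k <= 9) as.character(k) else sprintf("%%%02d", k)
      # bond symbol written at the first endpoint only
      sym <- if (!emitted[other]) bond_sym(v, other) else ""
      s <- paste0(s, sym, dig)
    }
    kids <- setdiff(nb[[v]], c(parent, ring_other[[v]]))
    kids <- kids[!emitted[kids]]
    if (length(kids)) {
      parts <- vapply(kids, function(w) paste0(bond_sym(v, w), emit(w, v)),
                      character(1))
      if (length(parts) > 1L)
        s <- paste0(s, paste0("(", parts[-length(parts)], ")", collapse = ""),
                    parts[length(parts)])
      else s <- paste0(s, parts)
    }
    s
  }

  comps <- connected_components(graph)
  pieces <- character()
  for (cmp in unique(comps)) {
    root <- which(comps == cmp)[1]
    pieces <- c(pieces, emit(root, NA_integer_))
  }
  paste(pieces, collapse = ".")
}

is_tree_edge <- function(v, w, parent) {
  (!is.na(parent[v]) && parent[v] == w) || (!is.na(parent[w]) && parent[w] == v)
}

bond_order_lookup <- function(graph) {
  b <- graph$bonds
  out <- list()
  for (k in seq_len(nrow(b))) out[[paste(b$a1[k], b$a2[k])]] <- b$order[k]
  out
}

atom_token <- function(atom, border, v, nb) {
  el <- atom$element
  sym <- if (atom$aromatic) tolower(el) else el
  # would the bare symbol imply the right H count?
  bsum <- 0
  for (w in nb[[v]]) bsum <- bsum + bond_order_value(border[[paste(min(v, w), max(v, w))]])
  used <- floor(bsum)
  vals <- .STANDARD_VALENCES[[el]]
  implied <- if (!is.null(vals) && length(vals[vals >= used]))
    vals[vals >= used][1] - used else -1L
  bare_ok <- el %in% .ORGANIC_SUBSET && atom$formal_charge == 0L &&
    atom$chiral_tag == "none" && implied == atom$n_hydrogens &&
    (!atom$aromatic || tolower(el) %in% .AROMATIC_SYMBOLS)
  if (bare_ok) return(sym)
  chir <- switch(atom$chiral_tag, none = "", clockwise = "@@",
                 counterclockwise = "@")
  hpart <- if (atom$n_hydrogens == 0L) ""
           else if (atom$n_hydrogens == 1L) "H"
           else paste0("H", atom$n_hydrogens)
  ch <- atom$formal_charge
  cpart <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
           else if (ch > 0L) paste0("+", ch) else paste0("-", abs(ch))
  paste0("[", sym, chir, hpart, cpart, "]")
}
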