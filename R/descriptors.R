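#' Simple graph descriptors
#'
#' A small fixed descriptor vector used by the synthetic label generators:
#' heavy-atom count, ring count (cyclomatic), heteroatom count, aromatic-atom
#' count, double-bond count, total hydrogen count and halogen count. These
#' are the "known generative structure" behind fixture labels, so recovery
#' tests have an exact ground truth.
#'
#' @param graph a [molecular_graph].
#' @return Named numeric vector of length 7.
#' @export
graph_descriptors <- function(graph) {
  a <- graph$atoms
  c(n_atoms = nrow(a),
    n_rings = count_rings(graph),
    n_hetero = sum(a$element != "C"),
    n_aromatic = sum(a$aromatic),
    n_double = sum(graph$bonds$order == "double"),
    n_hydrogens = sum(a$n_hydrogens),
    n_halogen = sum(a$element %in% c("F", "Cl", "Br", "I")))
}

descriptor_matrix <- function(graphs) {
  t(vapply(graphs, graph_descriptors, numeric(7)))
}
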