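# Element tables used across parsing, bond perception and fixture embedding.

# Covalent radii (Angstrom), Cordero-style consensus values.
.COVALENT_RADII <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Se = 1.20, Br = 1.20, I = 1.39
)

# Standard valence sets for implicit-hydrogen assignment (Daylight organic
# subset semantics: smallest listed valence >= current bond order sum).
.STANDARD_VALENCES <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1, Si = 4, Se = c(2, 4, 6), H = 1
)

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_SYMBOLS <- c("b", "c", "n", "o", "p", "s")

#' Default element vocabulary
#'
#' The fixed element vocabulary used for one-hot atom featurization. Elements
#' outside this list are legal in a [molecular_graph] but trigger an error at
#' featurization time, which is how the rare-element curation pathway surfaces
#' exotic chemistry before it reaches a model.
#'
#' @return Character vector of element symbols.
#' @export
default_element_vocabulary <- function() {
  c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B")
}

covalent_radius <- function(element) {
  r <- .COVALENT_RADII[element]
  r[is.na(r)] <- 1.2  # permissive fallback for exotic elements
  unname(r)
}

bond_order_value <- function(order) {
  c(single = 1, double = 2, triple = 3, aromatic = 1.5)[order]
}

# Ideal bond length (Angstrom) between two elements at a given order; used by
# the synthetic conformer builder.
ideal_bond_length <- function(el1, el2, order) {
  base <- covalent_radius(el1) + covalent_radius(el2)
  scale <- c(single = 1, double = 0.87, triple = 0.78, aromatic = 0.93)[order]
  unname(base * scale)
}
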