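#' Fixture configuration
#'
#' Settings for the synthetic data generator that stands in for downloadable
#' corpora: random small organic molecules with constructively embedded 3D
#' conformers, and task labels with stored generative structure so recovery
#' tests have exact ground truth. Everything is reproducible from
#' `(config, seed)`.
#'
#' @param n_molecules number of molecules to generate.
#' @param seed RNG seed.
#' @param element_palette elements sampled while growing molecules; repeats
#'   act as weights (default is carbon-rich organic chemistry).
#' @param size_range heavy-atom count bounds, inclusive.
#' @param ring_prob probability a molecule is grown from a ring template.
#' @param label_model `"linear_on_descriptors"` or `"linear_on_latent"`.
#' @param noise_sd Gaussian label noise standard deviation (>= 0).
#' @param jitter_sd coordinate jitter applied to embedded conformers, in
#'   Angstrom (default 0.01 — crystallographic-refinement-scale noise).
#' @param corrupt_overlap inject one overlapping-atom record (for testing the
#'   rejection path downstream).
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_molecules = 20L, seed = 1L,
                           element_palette = c("C", "C", "C", "C", "N", "O",
                                               "O", "S", "F", "Cl"),
                           size_range = c(4L, 12L), ring_prob = 0.5,
                           label_model = c("linear_on_descriptors",
                                           "linear_on_latent"),
                           noise_sd = 0, jitter_sd = 0.01,
                           corrupt_overlap = FALSE) {
  stopifnot(n_molecules >= 1L, size_range[1] >= 2L,
            size_range[2] >= size_range[1], noise_sd >= 0)
  structure(list(n_molecules = as.integer(n_molecules), seed = as.integer(seed),
                 element_palette = element_palette,
                 size_range = as.integer(size_range), ring_prob = ring_prob,
                 label_model = match.arg(label_model), noise_sd = noise_sd,
                 jitter_sd = jitter_sd, corrupt_overlap = corrupt_overlap),
            class = "fixture_config")
}

.MAX_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, B = 3,
                  F = 1, Cl = 1, Br = 1, I = 1)

# grow one random molecular graph; returns list(graph, ring_template) with
# atoms in build order (not yet canonicalized)
grow_molecule <- function(n_heavy, palette, ring_prob) {
  ring_template <- NULL
  el <- character(); used <- numeric(); aromatic <- logical()
  bonds <- data.frame(a1 = integer(), a2 = integer(), order = character(),
                      stringsAsFactors = FALSE)
  add_bond <- function(i, j, order) {
    bonds <<- rbind(bonds, data.frame(a1 = i, a2 = j, order = order,
                                      stringsAsFactors = FALSE))
    used[i] <<- used[i] + bond_order_value(order)
    used[j] <<- used[j] + bond_order_value(order)
  }

  if (stats::runif(1) < ring_prob && n_heavy >= 6L) {
    kind <- sample(c("benzene", "chair", "pentagon"), 1L)
    m <- if (kind == "pentagon") 5L else 6L
    arom <- kind == "benzene"
    el <- rep("C", m); used <- numeric(m); aromatic <- rep(arom, m)
    for (i in seq_len(m))
      add_bond(i, if (i == m) 1L else i + 1L,
               if (arom) "aromatic" else "single")
    ring_template <- list(atoms = seq_len(m), kind = kind)
  } else {
    el <- sample(c("C", "C", "N"), 1L)  # start on a growable atom
    used <- 0; aromatic <- FALSE
  }

  while (length(el) < n_heavy) {
    free <- which(.MAX_VALENCE[el] - floor(used) >= 1)
    if (!length(free)) break
    parent <- if (length(free) == 1L) free else sample(free, 1L)
    new_el <- sample(palette, 1L)
    order <- "single"
    if (!aromatic[parent] &&
        .MAX_VALENCE[el[parent]] - floor(used[parent]) >= 2 &&
        .MAX_VALENCE[new_el] >= 2 && stats::runif(1) < 0.15)
      order <- "double"
    el <- c(el, new_el); used <- c(used, 0); aromatic <- c(aromatic, FALSE)
    add_bond(parent, length(el), order)
  }

  n_h <- pmax(0L, as.integer(.MAX_VALENCE[el] - floor(used)))
  atoms <- data.frame(element = el, formal_charge = 0L, aromatic = aromatic,
                      n_hydrogens = n_h, chiral_tag = "none",
                      stringsAsFactors = FALSE)
  g <- molecular_graph(atoms, bonds, canonicalize = FALSE)
  list(graph = g, ring_template = ring_template)
}

#' Generate a synthetic molecule set with 3D conformers
#'
#' Randomly assembles valid small organic molecules (valence-respecting
#' growth from a weighted element palette, optionally seeded on an aromatic,
#' chair or pentagon ring template) and embeds one constructive conformer
#' each (see the package vignette for what this surrogate does and does not
#' emulate). Molecules whose embedding fails are resampled and logged via a
#' message. Deterministic given the config.
#'
#' @param config a [fixture_config].
#' @return A list of `list(graph, coords, smiles)` records; graphs are
#'   canonical and `coords` row-aligned. With `corrupt_overlap = TRUE` the
#'   first record's second atom is moved onto its first (one downstream
#'   reject, by construction).
#' @export
generate_molecule_set <- function(config = fixture_config()) {
  set.seed(config$seed)
  records <- vector("list", config$n_molecules)
  i <- 1L
  guard <- 0L
  while (i <= config$n_molecules) {
    guard <- guard + 1L
    if (guard > 50L * config$n_molecules)
      stop("molecule generation failed to converge")
    n_heavy <- sample(seq(config$size_range[1], config$size_range[2]), 1L)
    gm <- grow_molecule(n_heavy, config$element_palette, config$ring_prob)
    emb_seed <- sample.int(2^30, 1L)
    coords <- tryCatch(
      embed_coordinates(gm$graph, seed = emb_seed,
                        jitter_sd = config$jitter_sd,
                        ring_template = gm$ring_template),
      error = function(e) e)
    if (inherits(coords, "error")) {
      message("resampling molecule ", i, ": ", conditionMessage(coords))
      next
    }
    # canonicalize graph and permute coordinates identically
    ranks <- canonical_ranks(gm$graph)
    g <- permute_graph(gm$graph, ranks)
    g$name <- sprintf("mol_%03d", i)
    coords <- coords[order(ranks), , drop = FALSE]
    g$source_smiles <- write_smiles(g)
    records[[i]] <- list(graph = g, coords = coords, smiles = g$source_smiles)
    i <- i + 1L
  }
  if (config$corrupt_overlap && config$n_molecules >= 1L)
    records[[1]]$coords[2, ] <- records[[1]]$coords[1, ]
  records
}

#' Generate regression labels with known linear structure
#'
#' Labels are a stored linear function of either simple graph descriptors
#' ([graph_descriptors]) or a frozen backbone's latent vectors, plus Gaussian
#' noise of sd `config$noise_sd`. The full generative record (coefficients,
#' intercept, noise draws) is returned so tests can reconstruct the labels
#' exactly and benchmark recovery.
#'
#' @param molecules records from [generate_molecule_set] (or a list of
#'   `list(graph = ...)`).
#' @param config a [fixture_config] (`label_model`, `noise_sd`, `seed`).
#' @param backbone required when `label_model = "linear_on_latent"`.
#' @return A list with `data` (data.frame: `id`, `smiles`, `label`),
#'   `coefficients`, `intercept`, `noise`, and `features`.
#' @export
generate_regression_labels <- function(molecules, config, backbone = NULL) {
  set.seed(config$seed + 1L)
  graphs <- lapply(molecules, `[[`, "graph")
  X <- if (config$label_model == "linear_on_latent") {
    if (is.null(backbone))
      stop("label_model 'linear_on_latent' needs a backbone")
    t(vapply(graphs, readout_latent, numeric(backbone$config$readout_dim),
             backbone = backbone))
  } else {
    descriptor_matrix(graphs)
  }
  beta <- stats::rnorm(ncol(X)) * if (config$label_model == "linear_on_latent")
    3 / sqrt(ncol(X)) else 0.5
  intercept <- stats::rnorm(1)
  noise <- stats::rnorm(nrow(X), sd = config$noise_sd)
  label <- drop(X %*% beta) + intercept + noise
  data <- data.frame(
    id = vapply(graphs, function(g) if (is.null(g$name)) NA_character_ else g$name,
                character(1)),
    smiles = vapply(graphs, function(g)
      if (is.null(g$source_smiles)) write_smiles(g) else g$source_smiles,
      character(1)),
    label = label, stringsAsFactors = FALSE)
  list(data = data, coefficients = beta, intercept = intercept, noise = noise,
       features = X, label_model = config$label_model)
}

# ---- multilabel ------------------------------------------------------------

.RULE_TYPES <- c("has_ring", "has_aromatic", "contains_element", "min_atoms",
                 "has_double", "min_hetero", "min_hydrogens")

rule_applies <- function(rule, graph) {
  d <- graph_descriptors(graph)
  switch(rule$type,
         has_ring = d[["n_rings"]] > 0,
         has_aromatic = d[["n_aromatic"]] > 0,
         contains_element = rule$element %in% graph$atoms$element,
         min_atoms = d[["n_atoms"]] >= rule$threshold,
         has_double = d[["n_double"]] > 0,
         min_hetero = d[["n_hetero"]] >= rule$threshold,
         min_hydrogens = d[["n_hydrogens"]] >= rule$threshold,
         stop("unknown rule type: ", rule$type))
}

#' Apply stored multilabel rules to molecules
#'
#' Reapplies a rule record from [generate_multilabel_labels]; reproduces its
#' label matrix exactly (including the forced all-zero rows).
#'
#' @param molecules fixture records (or `list(graph = ...)` lists).
#' @param rule_record the `rules` element returned by
#'   [generate_multilabel_labels].
#' @return Binary label matrix.
#' @export
apply_label_rules <- function(molecules, rule_record) {
  graphs <- lapply(molecules, `[[`, "graph")
  L <- vapply(rule_record$rules, function(rule)
    vapply(graphs, function(g) as.numeric(rule_applies(rule, g)), numeric(1)),
    numeric(length(graphs)))
  L <- matrix(L, nrow = length(graphs))
  if (length(rule_record$fallback_rows))
    L[rule_record$fallback_rows, 1] <- 1
  L[rule_record$zero_rows, ] <- 0
  colnames(L) <- rule_record$class_names
  L
}

#' Generate multilabel odor-style labels
#'
#' Each class is assigned by a stored substructure/descriptor rule (has a
#' ring, contains sulfur, at least k heteroatoms, ...), so the Bayes-optimal
#' label for every molecule is known. A configured minority of rows is forced
#' all-zero, mimicking molecules with no detectable fragrance; rows whose
#' rules fire for no class but that are not part of that minority receive a
#' recorded fallback label in class 1, so the all-zero count is exactly
#' `floor(zero_fraction * n)`.
#'
#' @param molecules fixture records.
#' @param n_classes number of label classes (>= 2).
#' @param rule_seed seed for rule sampling and zero-row choice.
#' @param zero_fraction fraction of molecules forced to all-zero labels
#'   (default 0.1).
#' @return A list with `labels` (binary matrix, molecules x classes) and
#'   `rules` (rule record: `rules`, `class_names`, `zero_rows`).
#' @export
generate_multilabel_labels <- function(molecules, n_classes, rule_seed = 1L,
                                       zero_fraction = 0.1) {
  if (n_classes < 2L) stop("n_classes must be >= 2")
  set.seed(rule_seed)
  rules <- lapply(seq_len(n_classes), function(j) {
    type <- sample(.RULE_TYPES, 1L)
    switch(type,
           contains_element = list(type = type,
                                   element = sample(c("N", "O", "S", "F", "Cl"), 1L)),
           min_atoms = list(type = type, threshold = sample(5:10, 1L)),
           min_hetero = list(type = type, threshold = sample(1:3, 1L)),
           min_hydrogens = list(type = type, threshold = sample(8:16, 1L)),
           list(type = type))
  })
  n <- length(molecules)
  zero_rows <- sort(sample.int(n, floor(zero_fraction * n)))
  record <- list(rules = rules,
                 class_names = sprintf("class_%02d", seq_len(n_classes)),
                 zero_rows = zero_rows, fallback_rows = integer())
  L0 <- apply_label_rules(molecules, record)
  record$fallback_rows <- setdiff(which(rowSums(L0) == 0), zero_rows)
  list(labels = apply_label_rules(molecules, record), rules = record)
}

# ---- reactions -------------------------------------------------------------

.REACTION_ROLES <- c("nucleophile", "electrophile", "catalyst", "ligand",
                     "base", "additive", "solvent")

#' Built-in reaction component palettes
#'
#' Small fixed SMILES palettes per role, emulating the shape of HTE
#' cross-coupling plates (aryl nucleophiles and halide electrophiles varied
#' widely, few ligands and bases). All strings parse with [parse_smiles].
#'
#' @return Named list of SMILES character vectors.
#' @export
default_reaction_palettes <- function() {
  list(
    nucleophile = c("OB(O)c1ccccc1", "OB(O)c1ccc(C)cc1", "OB(O)c1ccc(F)cc1",
                    "OB(O)c1ccc(OC)cc1", "OB(O)c1ccc(Cl)cc1", "OB(O)C1CCCCC1"),
    electrophile = c("Brc1ccccc1", "Brc1ccc(C)cc1", "Ic1ccccc1",
                     "Brc1ccc(C(=O)C)cc1", "Clc1ccc(OC)cc1", "BrC1CCCCC1"),
    ligand = c("CP(C)C", "CCP(CC)CC", "CP(C1CCCCC1)C1CCCCC1",
               "CC(C)P(C(C)C)C(C)C"),
    base = c("CCN(CC)CC", "CN1CCCCC1", "OC(=O)C"),
    additive = c("Cc1ccccc1", "COc1ccccc1", "CC(C)O", "CS(=O)C")
  )
}

#' Generate a synthetic reaction-yield table
#'
#' Builds a factorial (or sampled) combination table over role palettes.
#' Yield is a stored additive function of each component's descriptors with
#' role-specific effect scales — substrates (nucleophile/electrophile) carry
#' the largest effects, ligands deliberately small ones, so that
#' leave-one-ligand-out extrapolation is possible for a model that has learnt
#' the other roles — plus optional Gaussian noise, clipped to [0, 100]. A
#' configurable fraction of reactions is turned into near-zero "negative
#' reactions".
#'
#' @param role_palettes named list of SMILES vectors
#'   (default [default_reaction_palettes]).
#' @param n_reactions number of sampled combinations; `NULL` (default) for
#'   the full factorial.
#' @param seed RNG seed for the yield rule, sampling and noise.
#' @param noise_sd Gaussian yield noise sd (percentage points; default 0).
#' @param negative_fraction fraction of reactions forced to yields in
#'   [0, 5] (default 0).
#' @return A list with `reactions` (data.frame: one role column each plus
#'   `yield`) and `rule` (role coefficient vectors, base yield, noise draws,
#'   negative-reaction rows).
#' @export
generate_reaction_table <- function(role_palettes = default_reaction_palettes(),
                                    n_reactions = NULL, seed = 1L,
                                    noise_sd = 0, negative_fraction = 0) {
  stopifnot(length(role_palettes) >= 1L,
            all(lengths(role_palettes) >= 1L),
            all(names(role_palettes) %in% .REACTION_ROLES))
  set.seed(seed)
  grid <- expand.grid(role_palettes, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  if (!is.null(n_reactions)) {
    if (n_reactions > nrow(grid))
      stop("n_reactions exceeds the factorial size ", nrow(grid))
    grid <- grid[sample.int(nrow(grid), n_reactions), , drop = FALSE]
    rownames(grid) <- NULL
  }

  role_scale <- c(nucleophile = 4, electrophile = 4, catalyst = 2, ligand = 1,
                  base = 2, additive = 2, solvent = 1)
  rule <- list(base_yield = 50, gamma = list(), role_scale = role_scale)
  contrib <- matrix(0, nrow(grid), length(role_palettes),
                    dimnames = list(NULL, names(role_palettes)))
  for (role in names(role_palettes)) {
    gamma <- stats::rnorm(7) * role_scale[[role]]
    rule$gamma[[role]] <- gamma
    comp_desc <- descriptor_matrix(lapply(role_palettes[[role]], parse_smiles))
    comp_desc <- scale(comp_desc)
    comp_desc[is.nan(comp_desc)] <- 0  # constant descriptor within a palette
    effect <- drop(comp_desc %*% gamma)
    contrib[, role] <- effect[match(grid[[role]], role_palettes[[role]])]
    rule$component_effects[[role]] <- stats::setNames(effect,
                                                      role_palettes[[role]])
  }
  noise <- stats::rnorm(nrow(grid), sd = noise_sd)
  yield <- pmin(100, pmax(0, rule$base_yield + rowSums(contrib) + noise))
  negative_rows <- integer()
  if (negative_fraction > 0) {
    negative_rows <- sort(sample.int(nrow(grid),
                                     floor(negative_fraction * nrow(grid))))
    yield[negative_rows] <- stats::runif(length(negative_rows), 0, 5)
  }
  grid$yield <- yield
  rule$noise <- noise
  rule$negative_rows <- negative_rows
  list(reactions = grid, rule = rule)
}
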