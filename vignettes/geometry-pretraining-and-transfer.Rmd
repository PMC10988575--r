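---
title: "Geometry pretraining and frozen-backbone transfer: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry pretraining and frozen-backbone transfer: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moltransfer)
```

## The model

`moltransfer` trains a message passing neural network (MPNN) to predict a
molecule's 3D geometry from its 2D graph, then reuses the trained network's
penultimate layer — the *latent space* — as a fixed molecular featurizer for
small downstream datasets.

**Inputs.** A molecule is a heavy-atom graph. Each atom carries a one-hot
element over a fixed vocabulary (default `C N O S P F Cl Br I B`), formal
charge, heavy-atom degree, an aromaticity flag, an implicit-hydrogen count,
and a 3-slot one-hot chiral tag (`none` / `clockwise` /
`counterclockwise`). The chiral tag is the only thing that distinguishes
enantiomers; placing it at the atom level is the one placement that lets
message passing propagate it. Hydrogens are folded into the H-count rather
than kept as atoms: explicit-H graphs would roughly double every graph and
widen every geometry-target row while adding no information the count does
not carry. Readers can keep explicit hydrogens (`keep_hydrogens = TRUE`)
when the application needs them.

**Architecture.** With per-atom states $h_i \in \mathbb{R}^{d}$
initialised as $h_i^{(0)} = \tanh(W_{in} x_i + b)$ from the feature rows
$x_i$, each of $T$ message-passing rounds computes

$$ h_i^{(t+1)} = \tanh\Big(U h_i^{(t)} + \textstyle\sum_{o}\sum_{j \in N_o(i)}
   W_o\, h_j^{(t)} + b_u\Big), $$

where $N_o(i)$ are the neighbours of $i$ connected by a bond of order $o$
(single, double, triple, aromatic) — the simplest faithful bond-conditioned
MPNN, with weights shared across rounds. Atom states are pooled
(sum by default; mean available) and passed through one further nonlinear
layer to give the molecule latent $z \in \mathbb{R}^{r}$. The geometry
output layer predicts, for every atom, `max_neighbors` distances (softplus,
so strictly positive, in Å) and `max_angle_pairs` angles (scaled sigmoid,
degrees in $[0, 180]$) from the concatenation $[h_i, z]$. Feeding $z$ into
the geometry head is a deliberate design choice: it puts the latent on the
gradient path of pretraining, so the vector that transfer later consumes is
actually shaped by the pretraining signal rather than remaining at its
random initialisation.

**Geometry targets.** Raw coordinates are not a function of the molecule —
any rigid motion changes them — so the model predicts an invariant proxy
instead: for each atom, the Euclidean distances to its neighbours and the
angle at the atom for every neighbour pair, padded and masked to fixed
widths. "Neighbours" defaults to bonded 1-hop atoms, which is what makes
"the angles formed" well-defined chemistry (bond angles); a spatial
k-nearest-neighbour mode is available for users who prefer the purely
geometric reading. Angles are stored in degrees and only normalised by 180
inside the loss, keeping the data model physical. Invariance of the targets
under rotation, translation and reflection is tested to $10^{-6}$
(`targets_invariance_check()`); reflections are included because unsigned
distances and angles are achiral — 2D chirality enters through the atom
tags, not the targets.

**Loss and training.** Pretraining minimises masked L1 error — distance MAE
(Å) plus `angle_weight` × angle MAE / 180 — matching the MAE evaluation
criterion; `angle_weight` defaults to 1 after normalisation, which puts a
1° angle error on the same footing as a ~5.6 mÅ distance error. The
optimiser is Adam (rate $10^{-3}$ by default for large runs; the test and
example configurations use $5 \times 10^{-3}$, which is stable at their
scale), batching by molecule count, with optional early stopping on a
held-out scaffold set (`patience`). The loss form, schedule and stopping
criterion are this package's choices; nothing in the transferred interface
depends on them.

## Transfer

`strip_and_attach()` removes the geometry output layer and attaches a fresh
head: exactly two linear layers with one rectifier between, the published
head shape. The backbone is frozen — `finetune()` touches only head
parameters and asserts, bitwise, that the backbone's content fingerprint is
unchanged. Three task types share this mechanic:

* **Regression** (e.g. log-LD50): head on $z$, trained with absolute-error
  loss to match the MAE metric.
* **Reaction yields**: each reaction component is embedded separately
  through the frozen backbone and the latents are concatenated in a fixed
  role order (nucleophile, electrophile, catalyst, ligand, base, additive,
  solvent), absent roles contributing zero blocks. Concatenation rather
  than pooling preserves role identity, which is what makes unseen-ligand
  and unseen-base splits distinguishable tasks. How the original work
  combined components is not documented; this is our design decision.
  Yield predictions are clipped to $[0, 100]$ at inference only, so
  training gradients are never zeroed by the clamp.
* **Multilabel classification** (e.g. odor): independent per-class binary
  cross-entropy, probabilities thresholded at 0.5 (config-exposed) for
  F-scores, `predict_topk()` for top-k label lists with ties broken by
  label index.

Preset head widths (`head_preset()`) land within 15% of the published
budgets: ~32k parameters for scalar and 113-class heads on a 256-wide
latent, ~260k for the base reaction head on seven concatenated latents, and
~1M for the enlarged reaction head.

Multi-seed protocol: `finetune_replicates()` re-initialises the head per
seed and reports mean ± standard error (sample sd / √n), the reporting
convention used for the published numbers.

## Curation and splits

* **Rare elements**: occurrence counts are computed over the whole dataset
  *before* any dropping; a molecule is dropped iff it contains an element
  seen fewer than `min_count` times (default 100, the published threshold).
  The filter is idempotent.
* **Ambiguous bonding**: operationalised as parser/valence/perception
  failure flags — overlapping atoms, impossible valences, unparseable
  records. (Curated databases carry their own ambiguity annotations; those
  are not available offline, so the parser's own failures stand in.)
* **Conformational polymorphs**: records sharing a canonical graph are
  compared pairwise by best-fit heavy-atom RMSD (Kabsch superposition); if
  any pair exceeds `rmsd_threshold` the whole group is dropped. No
  canonical threshold exists for "significant difference", so the default
  (1.0 Å) is config-exposed.
* **Scaffold split**: Bemis–Murcko frameworks (iterative pruning of
  terminal atoms; acyclic molecules share the empty framework), whole
  groups assigned greedily largest-first to the training budget, ties
  shuffled by seed. The realised test fraction is within one scaffold group
  of the request, and no framework ever straddles the split.
* **Unseen-molecule k-fold**: duplicate structures (identical canonical
  signature, chirality included) are always co-assigned, so test molecules
  are genuinely unseen.
* **Leave-component-out**: one plan per held-out component; every test
  reaction contains it, no training reaction does.
  `most_common_component()` supports the "most common reactant as test
  split" protocol.

`audit_split()` re-verifies all of these properties on any plan and is run
by the command layer before scoring; the test suite fuzzes it over random
datasets.

## Synthetic fixtures: what they emulate, what they do not

The pretraining corpus this design targets (≈10⁶ experimental organic
crystal structures) is proprietary, and the downstream benchmarks are
external downloads. The fixture module therefore generates everything:

* **Molecules** grown atom-by-atom from a weighted organic element palette
  under valence constraints, optionally seeded on an aromatic ring, chair
  or pentagon template (4–12 heavy atoms by default — small-molecule scale
  chosen so a CPU test run trains in seconds).
* **Conformers** built constructively: template ring geometry, ideal bond
  lengths from covalent radii (order-scaled), substituents placed at the
  bond length in the direction repelling the parent's existing neighbours,
  with collision checks and resampling on failure, plus 0.01 Å Gaussian
  coordinate jitter (the scale of crystallographic refinement noise). This
  surrogate has locally realistic bond lengths and plausible angles — the
  quantities the model predicts — but makes **no claim** of realistic
  torsional ensembles, crystal packing, or intermolecular contacts. A green
  pretraining test therefore establishes that the pipeline learns
  learnable geometry, not that it reproduces crystallographic accuracy.
* **Labels** with stored generative structure: regression labels linear in
  either simple graph descriptors or the frozen latent (so a head that can
  represent a linear map must recover them — the parameter-recovery
  acceptance check); multilabel classes assigned by stored
  substructure/descriptor rules with a configured minority of all-zero
  rows (the "no detectable fragrance" pattern; rows that would be
  accidentally all-zero outside that minority get a recorded fallback
  label so the count is exact); reaction yields as a stored additive
  function of per-component descriptors, clipped to $[0, 100]$, with a
  configurable negative-reaction fraction. Role effect scales are fixed a
  priori with substrates largest and ligands smallest — the chemically
  sensible regime in which leave-one-ligand-out extrapolation is possible
  at all; with ligand effects dominating, no model could beat the mean on
  an unseen ligand.

Odor semantics, real structure–activity relationships and assay noise
structure are *not* emulated; fixture results demonstrate mechanics and
recoverability, never chemistry.

## Numerical choices

* **Canonical atom ordering**: iterative neighbourhood refinement from
  (element, degree, charge, H-count, aromaticity) seeds with deterministic
  lowest-index tie-breaking, applied at parse time. Chiral tags are
  excluded from the refinement so enantiomers order identically and their
  feature matrices differ only in the chiral one-hot block. Model outputs
  are independent of ordering (permutation equivariance/invariance tested
  at $10^{-5}$/$10^{-6}$).
* **Implicit hydrogens**: smallest standard valence ≥ the bond-order sum;
  aromatic bonds count 1.5 with the sum floored, which reproduces the
  expected counts on aromatic and fused-ring systems. Valence violations
  on organic-subset atoms are parse errors; charged bracket atoms are not
  second-guessed.
* **Fingerprints**: per-tensor moments formatted at 17 significant digits,
  hashed with 32-bit FNV-1a implemented exactly in double arithmetic. Any
  single-parameter change flips the fingerprint; checkpoints refuse to
  load if it does not match.
* **Serialization**: all numeric JSON uses 17 significant digits, which
  round-trips IEEE doubles exactly — checkpoints reload bit-identically.
* **Degenerate inputs**: coincident atoms are an error naming the pair
  (geometry targets) or an ambiguity rejection (bond perception); empty
  graphs cannot be read out; zero masked-in entries make the loss an
  error rather than 0/0.
* **Initialisation**: Gaussian, sd = 1/√fan-in, fully determined by the
  config seed; two runs with one seed produce identical fingerprints.

## Known limitations

* The SMILES dialect covers the Daylight organic subset, brackets,
  chirality tags, ring closures and dot-components; tautomer or
  protonation standardisation, cis/trans bond stereo and polymer/disorder
  CIF records are out of scope. Chiral tags are recorded as written, not
  re-canonicalised against neighbour order.
* Bond perception from coordinates is radius-based and deliberately
  conservative: crowded geometries are rejected as ambiguous rather than
  guessed at.
* The MPNN is plain and CPU-sized; attention variants, 3D-input networks,
  uncertainty estimation and backbone unfreezing are non-goals here.
* Canonical ranking is Weisfeiler–Lehman refinement with
  individualisation; for the small organic graphs in scope it separates
  all non-equivalent atoms, but it is not a general graph-isomorphism
  certificate.
* Published benchmark numbers (toxicity MAE on TDC, Suzuki/HTE yield MAEs,
  odor F-scores) require the external corpora and full-scale pretraining;
  nothing in this package claims to reproduce them, and no test asserts
  them.
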