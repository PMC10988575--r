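Package: moltransfer
Title: Geometry-Pretrained Message Passing Networks with Frozen-Backbone
    Transfer for Molecular Property Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A foundational-model workflow for cheminformatics: a message
    passing neural network (MPNN) is pretrained on 2D molecular graphs to
    predict rotation- and translation-invariant 3D geometry proxies
    (per-atom neighbour distances and the bond angles they form), and the
    frozen backbone's penultimate-layer latent space is then reused by
    shallow two-layer task heads for toxicity-style regression,
    reaction-yield regression over role-encoded reaction components, and
    multilabel odor classification. Includes SMILES/SDF/CIF molecular
    graph handling, dataset curation filters (rare-element removal,
    ambiguous bonding and conformational-polymorph screening), scaffold,
    unseen-molecule k-fold and leave-component-out split protocols with
    leakage audits, MAE and macro/weighted multilabel F-score metrics,
    and a fully synthetic fixture generator (molecules, conformers,
    labelled tasks) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
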