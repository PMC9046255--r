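Package: geoprot
Title: Sequence- and Structure-Informed Protein Property Prediction with
    Geometric Graph Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein properties from backbone structure and amino-acid
    sequence. Parses PDB backbones, builds attributed k-nearest-neighbour
    residue graphs with scalar and vector features (dihedral angles, radial
    basis distance encodings, backbone direction vectors), and trains geometric
    vector perceptron (GVP) or graph attention (GAT) networks on them, either
    structure-only or as a hybrid with per-residue embeddings from a
    transformer protein language model (two-stage with a frozen language model,
    or end-to-end with gradual unfreezing). Includes integrated-gradients
    residue saliency against binding-site annotations, zero-shot mutational
    effect scoring via masked marginal probabilities, a sparse logistic probe
    predicting residue contacts from attention maps, and deterministic
    synthetic-structure generators so every component is testable offline. All
    model gradients come from a small built-in reverse-mode automatic
    differentiation engine.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    glmnet
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
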