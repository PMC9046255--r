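# geoprot

Sequence- and structure-informed protein property prediction with geometric
graph networks, in pure R.

## The problem

Protein function, stability and other assayable properties depend on both
the amino-acid sequence and the folded 3D structure. Transformer protein
language models (LMs) capture evolutionary signal from sequence alone; graph
neural networks over residue graphs capture geometry. `geoprot` implements
both views and their combination for researchers who want to train,
interrogate and compare such models on protein-level tasks:

* **structure-only** models: the backbone is turned into a k-nearest-neighbour
  residue graph (k = 30 by default) whose nodes carry scalar features
  (sin/cos of the dihedrals φ, ψ, ω and a 21-way residue one-hot) and unit
  vector features (directions to the adjacent Cα atoms and to Cβ), and whose
  edges carry 16 Gaussian radial-basis encodings of the Cα distance, a
  16-dim sinusoidal encoding of the sequence offset, and the inter-residue
  unit vector. The graph is processed either by **geometric vector
  perceptron (GVP)** convolutions — which keep scalar channels
  rotation-invariant and vector channels rotation-equivariant by
  construction — or by **graph attention (GAT)** convolutions, message
  passing of the form *M*(h_i, h_j, e_{j→i}) aggregated over incoming edges
  and updated as LayerNorm(h + (1/m)·Dropout(Σ messages));
* **sequence-only** models: a head on the pooled `[CLS]` token of a
  transformer LM (a deterministic stub LM ships with the package; a
  pretrained adapter only has to honour the same interface);
* **hybrids**: per-residue LM embeddings T = LM(a) ∈ R^{L×h} join the node
  scalar channel, either **two-stage** (LM frozen) or **end-to-end** with
  gradual unfreezing (train the GVP head until the validation loss stops
  improving, then unfreeze the LM transformer layers).

Training uses Adam (β₁ = 0.9, β₂ = 0.999), MSE for regression and
label-weighted binary cross-entropy for multi-label tasks with
w_j = max(1, min(10, Σᵢ Nᵢ⁺ / (l·N_j⁺))), early stopping with patience 10,
and a learning-rate × batch-size grid selected on validation loss.
Evaluation provides micro-AUPR, per-label AUPR, protein-centric Fmax and
Spearman ρ.

Three analysis procedures accompany the models:

* **integrated-gradients saliency**: per-residue attributions
  ig(i) = Σ_j ig(i, j) of a model output against an all-`[SEP]` baseline
  embedding, compared to binding-site annotations by rank AUROC;
* **zero-shot variant scoring**: the masked-marginal score
  Σ_{i∈M} log p(x_i = x_i^mt | x_\M) − log p(x_i = x_i^wt | x_\M), all
  mutated positions masked jointly, correlated with assay values by
  Spearman ρ;
* **contact probing**: an L1-penalized logistic regression (glmnet) from
  symmetrized per-pair attention values to true contacts (Cα ≤ 10 Å,
  ≥ 6 residues apart), evaluated as precision over the top-L pairs.

All gradients come from a small reverse-mode autodiff engine built into the
package (no external deep-learning framework), verified against finite
differences. Deterministic generators (idealized backbones from internal
coordinates, labelled toy tasks, planted mutational scans) make every module
testable offline.

## Worked example

```r
library(geoprot)

# a labelled synthetic task: helix-rich vs strand/coil-rich chains
task <- make_structure_task(60, rule = "helix_fraction_threshold", seed = 1)

# train a small structure-only GVP network
fit <- geoprot_fit(task$structures, task$labels, "multilabel", family = "gvp",
                   dims = model_dims(s_h = 16, v_h = 4, penultimate = 32, k = 10),
                   config = train_config(lr_grid = 1e-3, batch_grid = 8,
                                         patience = 5, max_epochs = 15, seed = 1))
fit
#> <geoprot_fit> gvp (none), multilabel task
#>   selected lr=0.001 batch=8; best validation loss 0.028251
#>   15 epoch(s) over 1 phase(s)

val <- fit$val_idx
evaluate(predict(fit, task$structures[val]),
         task$labels[val, , drop = FALSE], "multilabel")$micro_aupr
#> [1] 1

# zero-shot mutational scoring with the stub language model
lm <- stub_lm()
masked_marginal_score(lm, "MKTAYIAKQR", "T3W;Y5F")
#> [1] 3.511908

# residue saliency of the fitted model for protein 1
prof <- residue_saliency(fit$model, task$structures[[1]], steps = 64)
prof
#> <saliency_profile> L=33, target 1, 64 steps, completeness gap 2.12e-05
```

The validation micro-AUPR of 1 says the small GVP separates helix-rich from
non-helix chains perfectly on this toy task (its dihedral features expose the
label directly); the positive masked-marginal score of 3.51 means the stub LM
assigns the double mutant a higher joint likelihood than the wildtype at
those masked positions (the stub's preferences are arbitrary — the machinery,
not the biology, is the point); the saliency profile attributes the
prediction across the 33 residues with a completeness gap of ~2·10⁻⁵, i.e.
the attributions account for the model output change essentially exactly.

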