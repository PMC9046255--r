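---
title: "Methods: geometric sequence-structure models for protein properties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric sequence-structure models for protein properties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geoprot)
```

## The modelling problem

`geoprot` predicts protein-level properties (multi-label function classes or a
real-valued assay score) from two complementary views of a protein: its
amino-acid sequence and its backbone structure. The package implements four
model families over a shared representation:

* **sequence-only** — a linear head on the pooled `[CLS]` representation of a
  transformer protein language model (LM);
* **structure-only** — a graph neural network (GVP or GAT) over a residue
  graph built from backbone coordinates, with one-hot residue identities as
  node scalars;
* **two-stage hybrid** — per-residue LM embeddings are computed once with the
  LM frozen and concatenated into the node scalar channel (GVP) or used in
  place of the one-hot features (GAT); only the graph network trains;
* **end-to-end hybrid** — the same architecture, but gradients flow back into
  the LM transformer layers under a gradual-unfreezing schedule.

## The residue graph

A protein of length $L$ becomes a directed graph whose nodes are residues.
Each node receives edges from its $k = 30$ nearest residues by C$\alpha$
Euclidean distance (ties broken by the smaller residue index; distances are
rounded at $10^{-9}$ Å before sorting so that the ordering is stable under
rigid motions of the coordinates).

Node features are a (scalar, vector) pair:

* scalars: $\sin$ and $\cos$ of the backbone dihedrals $\phi, \psi, \omega$
  (6 values; an undefined terminal angle is encoded as $(0, 0)$ so that $L$
  always matches the sequence), plus the 21-way one-hot residue identity
  (20 standard amino acids + X) and/or the LM embedding row, depending on the
  feature mode;
* vectors (3 per node): unit vectors toward the next and previous C$\alpha$
  (zero and flagged at chain termini) and the unit direction from C$\alpha$
  to C$\beta$. Missing C$\beta$ atoms (always, for glycine) are imputed from
  the local N–CA–C frame with ideal geometry (bond 1.522 Å, angle
  N–CA–CB 110.4°, dihedral C–N–CA–CB $-122.5$°); the construction uses a
  cross product and therefore preserves chirality — mirroring the backbone
  does not mirror the imputed atom.

Edge scalars are 16 Gaussian radial basis responses to the C$\alpha$ distance
(centers evenly spaced on $[0, 20]$ Å; width equal to the 20/15 Å spacing)
concatenated with a 16-dimensional sinusoidal encoding of the signed sequence
offset $j - i$ (the Transformer recipe; 16 dimensions is this package's
choice, which separates every offset in $[-30, 30]$). The edge vector is the
unit vector between the two C$\alpha$ atoms.

## The geometric vector perceptron

A GVP maps a (scalar, vector) pair to another such pair so that scalar
outputs are invariant and vector outputs equivariant under rotations (and any
orthogonal transform) of the vector channel. This implementation uses the
row-norm formulation: vectors pass through a learned linear map over the
vector-count axis; the row norms of the mapped vectors join the scalar
channel; the scalar output is an affine map with a pointwise nonlinearity;
the vector output is a second linear map gated elementwise by a sigmoid
factor computed from the scalar output. Assembled models use tanh as the
scalar nonlinearity (and for the penultimate dense layer): a smooth
activation makes the integrated-gradients quadrature converge cleanly with
step count, which piecewise-linear activations do not guarantee. The
standalone `gvp_transform()` primitive defaults to ReLU, the common choice
in the geometric-learning literature, and accepts either. On the autodiff tape the vector channel is stored as three
aligned $n \times \nu$ component matrices, so no operation ever mixes spatial
coordinates — equivariance holds by construction and is asserted numerically
in the tests to $10^{-10}$.

One graph-convolution layer computes a message per directed edge by applying
a single GVP to the concatenation (channel-wise) of the source-node state and
the edge features, averages messages over each node's incoming edges, applies
dropout (default rate 0.1, training only), and updates residually:
LayerNorm on the scalar channel; the vector channel is scaled by the
reciprocal of its mean row norm (the standard LayerNorm update is defined on
scalars; scaling vectors by their mean norm is this package's choice and
keeps the update equivariant). Three such layers run in
sequence after an input-projection GVP that lifts the raw features to the
hidden widths. The readout concatenates the per-layer states, average-pools
over residues, flattens the pooled vectors through their norms, and feeds a
dense penultimate layer (400 wide at full scale) before the task head.

The GAT alternative follows the original graph-attention recipe: a shared
linear map, LeakyReLU pairwise logits, softmax over each node's
in-neighbourhood *including itself* (the self term is exactly the
$\alpha_{ii} W h_i$ update term), ELU nonlinearity, single head by default,
scalar features only, and a sum-pooled concatenation of the three layers.

## Losses, weights and the training protocol

Regression tasks use mean squared error. Multi-label tasks use binary
cross-entropy on logits with per-label weights
$w_j = \max(1, \min(10, \sum_i N_i^+ / (l\,N_j^+)))$ — the inverse positive
frequency relative to the average, clamped to $[1, 10]$; a label with no
positives takes the clamp limit 10 with a warning. The weight multiplies both
the positive and negative terms of its label.

Training uses Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$), early stopping on
validation loss with patience 10 (a run stops once the number of epochs since
the best validation loss reaches the patience; the best weights are
restored), at most 200 epochs, and a grid search over learning rates
$\{10^{-4}, 10^{-5}, 10^{-6}\}$ and batch sizes $\{16, 32\}$ selected by
validation loss. All of these are defaults of `train_config()` and every test
and example states the (smaller) values it actually uses.

End-to-end hybrids train with gradual unfreezing. Phase 1 trains the graph
network and head with the LM frozen; "until convergence" is operationalized
as the same early-stopping criterion. Phase 2 unfreezes the LM transformer
layers (never the token-embedding table), re-initializes the Adam state (a
design choice, recorded in the fit history via the phase column), and
continues with early stopping. Because every phase restores its
best-validation weights, the end-to-end fit can never finish with a worse
validation loss than the two-stage fit at the same seed — the directional
ordering between the two schedules is a property of the protocol, and the
package asserts it empirically over multiple seeds rather than assuming it.
Two-stage training is bit-for-bit identical to end-to-end training with phase
2 disabled (`phase2_max_epochs = 0`), which the tests check on identical
histories.

Determinism: given a seed, shuffling, dropout and initialization all draw
from R's RNG, so two runs of `geoprot_fit()` with the same inputs produce
bitwise-identical histories on a single-threaded BLAS.

## The stub language model

No pretrained protein LM ships with the package (such models are gigabytes
of weights); instead a deterministic 2-layer, 2-head, width-16
transformer over single amino-acid tokens (`[CLS]` seq `[SEP]`) serves as the
embedder. It is seed-reproducible, CPU-cheap (a length-200 forward pass takes
~10 ms), exposes the exact interface a pretrained adapter must honour
(embeddings, pooled `[CLS]`, masked-token distributions, attention maps), and
its masked-LM head is initialized at a scale (Gaussian, sd 0.6) that makes
token distributions far from uniform — chosen once so that zero-shot scores
have non-degenerate spread (their standard deviation across random single
mutants is about 4 on the log-probability scale, an order of magnitude above
the synthetic scan's default assay noise of $\sigma = 0.1$). Special-token
rows are stripped from embeddings; attention maps are stripped and
row-renormalized.

What the stub does *not* emulate: evolutionary knowledge. Its distributions
are arbitrary functions of context, so passing tests demonstrate the
correctness of the scoring and probing *machinery* (masking semantics, joint
versus marginal distributions, rank correlations), not biological validity of
any particular score.

## Interpretation, variant scoring, contact probing

**Integrated gradients.** Attributions are the midpoint-rule approximation of
the path integral $(x - x')\odot \int_0^1 \nabla F(x' + \alpha(x - x'))\,
d\alpha$ with 64 steps by default. The attribution surface is the $L \times h$
per-residue embedding matrix (the LM output) for hybrid models; for the
sequence-only model it is the embedding-layer output (token + position); for
structure-only models it is the residue-identity block of the scalar channel
with a zero baseline — coordinates are never interpolated. The baseline is
the embedding of an all-`[SEP]` sequence of the same length. Per-residue
saliency sums attributions over the embedding width, and the completeness gap
$|\sum \text{attr} - (F(x) - F(x'))| / |F(x) - F(x')|$ is reported with every
profile. The explained output is the target logit (not the probability).
Saliency is compared against binding-site annotations by rank-based AUROC
with average ranks on ties; a helper derives annotations from ligand
proximity (any sidechain atom within 5 Å of a non-water HETATM) when no
curated table is available.

**Masked-marginal variant scoring.** For a mutation set $M$, all mutated
positions are masked in one forward pass and the score is
$\sum_{i \in M} \log p(x_i = x_i^{mt} \mid x_{\setminus M}) - \log p(x_i =
x_i^{wt} \mid x_{\setminus M})$. Wildtype records score exactly zero;
multi-mutants use the joint-mask distribution (which the tests distinguish
from summed single-mask scores); insertions and deletions are rejected.

**Contact probe.** Ground-truth contacts are C$\alpha$ pairs within 10 Å at
sequence separation $\geq 6$. Pair features are the symmetrized attention
values $(A_{ij} + A_{ji})/2$, one per (layer, head); no average-product
correction is applied (none is part of this package's procedure). Pairs
pool across proteins into a single L1-penalized logistic regression (glmnet,
per-sample-averaged loss so duplicated rows cannot change the fit, solver
tolerance $10^{-6}$), with the penalty chosen on a held-out split by
log-loss. Evaluation reports precision over the top-$L$ ranked pairs
($L$ = protein length); when fewer than $L$ eligible pairs exist all pairs
are used and the result is flagged.

## Synthetic data: what it emulates and what it does not

`build_chain()` places backbone atoms sequentially (NeRF) with ideal bond
lengths (N–CA 1.458, CA–C 1.525, C–N 1.329 Å) and angles, honouring
per-residue $\phi/\psi/\omega$; `compute_dihedrals()` recovers the input
torsions to $10^{-3}$ degrees, making the pair a round-trip oracle. The
constants only need internal consistency, not crystallographic fidelity.

`make_structure_task()` emits chains of random helix/strand/coil segments
(helix $\phi=-57^\circ$, $\psi=-47^\circ$; strand $-139^\circ$, $135^\circ$;
3° jitter) with a per-protein helix propensity drawn uniformly so that the
binary helix-fraction label stays balanced. The label is a deterministic
function of structure that the dihedral features expose directly — by design,
so that a correctly wired structure model can learn it quickly at desk scale.
Real function prediction is much harder; success here validates wiring and
optimization, not benchmark-level accuracy. Idealized extended chains are
nearly contact-free above the 6-residue separation band, so the contact-probe
tests instead use compact random-walk C$\alpha$ traces with realistic step
lengths.

`make_mutscan()` plants a known effect: assay = stub masked-marginal score +
$\mathcal{N}(0, \sigma^2)$ with $\sigma = 0.1$ by default, so the attainable
Spearman correlation is known (1.0 at $\sigma = 0$, above 0.9 at the default
noise with 200 records).

## Numerical choices and degenerate inputs

* Gradients come from the package's own reverse-mode tape; every primitive is
  verified against central finite differences to $10^{-6}$.
* Vector norms are computed exactly (no epsilon in the value) with a clamped
  denominator in the backward pass, so zero vectors stay exactly zero forward
  and have zero subgradient.
* Softmax rows are stabilized by a detached per-row maximum (shift-invariant,
  so gradients stay exact).
* Model-level activations are smooth (tanh); with ReLU networks the
  midpoint-rule completeness gap of integrated gradients oscillates with the
  step count instead of decreasing.
* Collinear atom quadruples make a dihedral undefined (warning, $(0,0)$
  encoding); collinear N–CA–C frames make C$\beta$ imputation an error.
* Duplicate C$\alpha$ coordinates are allowed in the k-NN search (distance 0
  sorts first).
* Missing O atoms are tolerated and imputed from the local frame (O is not
  used by any feature); residues missing N, CA or C are dropped with a
  warning because every feature needs the full frame.
* Alternate locations resolve by highest occupancy then file order; only the
  first model of multi-model files is read; `MSE` and a few other modified
  residues map to their parent amino acid, anything else to X.

## Scale of the shipped experiments

The package's tests and the acceptance script run entirely on synthetic data
at desk scale: hidden widths 8–16 scalars and 2–4 vectors, chains of 10–35
residues, tasks of 8–200 proteins, and single-point learning-rate grids
(10^-3^, batch 16) — stated here as the package's chosen study sizes. The
full-scale defaults (scalar width 100, vector count 16, penultimate 400,
the full learning-rate × batch grid) remain the documented defaults of
`model_dims()` and `train_config()`.

## Known limitations

* Single chains only; no multi-chain complexes, no mmCIF, no hydrogens,
  no sidechain torsions or solvent accessibility.
* The stub LM cannot stand in for a pretrained model scientifically; adapters
  for real LMs must satisfy the same conformance tests but are not shipped.
* The featurization is chirality-aware (dihedral signs, C$\beta$
  construction), so end-to-end outputs are invariant under proper rigid
  motions but *not* under reflections of the input coordinates; the network
  itself is O(3)-invariant in its scalar channel, which is the level at which
  the reflection claim holds and is tested.
* Training is plain single-device, full-precision; no mixed precision or
  distributed support.
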