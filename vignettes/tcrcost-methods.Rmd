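---
title: "Correcting predicted TCR-peptide structures and classifying binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting predicted TCR-peptide structures and classifying binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

T-cell receptors (TCRs) recognise antigenic peptides through their third
complementarity-determining regions (CDR3α and CDR3β), short hypervariable
loops of roughly 11–18 residues. Predicting whether a TCR binds a given
peptide is a central problem in systems immunology, and structure-based
predictors promise more than sequence-based ones — if enough reliable 3D
structures of CDR3A:CDR3B:peptide complexes are available. Structure
predictors can generate complexes at scale, but their output for short,
hypervariable loops is of low confidence, with side chains modelled worse
than backbones. `tcrcost` implements a two-stage pipeline for this setting:

1. a **structure-correction network** that refines low-quality predicted
   coordinates, treating main-chain and side-chain atoms separately, and
2. a **binding classifier**, a residual 3D convolutional network over a
   voxelized representation of per-atom chemical features.

A deterministic synthetic-complex generator stands in for curated
experimental structures so that every stage is testable offline.

## Structure representation

A structure is a tibble of heavy atoms (hydrogens are ignored throughout)
in a canonical order: segments CDR3A, CDR3B, peptide; residues by index;
backbone atoms N, CA, C, O first within each residue, then side-chain
atoms. "Main chain" means the backbone set {N, CA, C, O}; local residue
frames use N, CA, C only. Coordinates are always in Ångström.

For the correction network, coordinates are padded to a fixed 400-atom
input (longer structures are truncated), and two binary membership
matrices — `Mm` (400×150) for main-chain atoms and `Ms` (400×400) for
side-chain atoms — encode the split: `t(Mm) %*% X` extracts main-chain
coordinates in order and `Mm %*% Xm + Ms %*% Xs` re-interleaves the
chains. The 150-slot main-chain capacity caps complexes at 37 residues
(4 backbone atoms each); the generator's default lengths (13 + 14 + 9 = 36
residues) are chosen inside the stated CDR3/peptide ranges to respect it.

## The three geometric losses

**Main-chain loss (frame-aligned point error).** Each residue `i` defines
a rigid frame from its N, CA, C atoms by Gram–Schmidt (e1 along CA→C,
origin at CA). Every residue `j` is represented by its three frame atoms;
their positions are expressed in frame `i` of the corrected and of the
reference structure, and the loss is the average Euclidean deviation over
all frame/residue pairs and the three atoms:

$$ L_{main} = \frac{1}{N^2}\sum_{i,j}\; \tfrac{1}{3}\sum_{a \in \{N,CA,C\}}
\lVert T_{o,i}^{-1}(x_{j,a}) - T_{r,i}^{-1}(\tilde x_{j,a}) \rVert $$

Because frames co-move with the coordinates, the loss is invariant to
rigid transforms of either structure. Deviations are not clamped by
default (a config flag adds a clamp); the residue-to-point reduction via
the three frame atoms is a design choice — the loss is stated per residue
pair, and the frame atoms are the natural representatives.

**Side-chain loss (distance-difference).** With `Dr`, `Dc` the pairwise
distance matrices of reference and corrected side-chain atoms and
thresholds $t_k = 0.5, 1, 2, 4$ Å (weights $p_k = 1/4$):

$$ L_{side} = \sum_k p_k \cdot
\frac{\sum_{i<j} \mathrm{ReLU}(|Dr_{ij}-Dc_{ij}| - t_k)}
     {\sum_{i<j} |Dr_{ij}-Dc_{ij}|} \in [0, 1] $$

Identical matrices give the 0/0 limit, defined as 0 (the limit of the
expression as the structures converge). The loss sees only internal
distances, so it is rigid-invariant and captures interactions between
side-chain atoms of non-adjacent residues.

**Whole-structure loss.** $L_{all}$ applies the frame-aligned error to the
full structure's backbone and adds L1 penalties on peptide-bond geometry:
the C(i)–N(i+1) bond length and the CA(i)–C(i)–N(i+1) angle of every
consecutive residue pair, corrected minus reference.

*Angle units.* The public `bond_geometry()`/`l_all()` report degrees, the
conventional unit. For **training**, the package defaults to radians
(`angle_unit` in `correction_config()`): in degrees the angle sum is two
orders of magnitude larger than the frame-aligned term (~1400 vs ~10 on
freshly perturbed synthetic complexes), and because L1 gradients have
constant magnitude, the angle term then dominates every update and
measurably degrades the corrected shape. In radians the three terms are
commensurate. We observed exactly this failure mode when training with
degree-scaled angles, which is why radians are the default.

## The correction network

Pipeline per structure: a 1D convolution along the atom axis (3 coordinate
channels, kernel 5, residual) provides local context; atoms are split into
main/side chains via the membership matrices; each chain is corrected by a
two-layer LSTM (bidirectional by default) whose hidden state is projected
to a per-atom 3-vector; the chains are recombined in the original atom
order; a final two-layer LSTM corrects the whole structure. All heads are
additive-residual — corrected = input + displacement — so a zero-weight
model is the identity, which both stabilises training and makes the
untrained model testable.

Numerical choices worth recording:

* **Input normalisation.** The recurrent correctors see centred
  coordinates divided by `input_scale` (default 10 Å) and displacement
  outputs are scaled back. Raw coordinates (±15 Å) saturate LSTM gates;
  normalisation keeps pre-activations in the sensitive range. Outputs are
  unchanged at initialisation because heads start at zero.
* **Rigid gauge handling.** All three training losses are invariant to a
  global rigid motion of the output, so the network determines the
  corrected structure only up to rotation/translation — six flat
  directions along which stochastic optimisation would drift. Two
  measures fix the gauge. First, every displacement field is projected
  onto the orthogonal complement of the rigid subspace (translations plus
  infinitesimal rotations about the input configuration); the projector
  is built from the constant input coordinates, so it is linear and
  self-adjoint, and the backward pass applies the same projection.
  Second, `correct_structure()` re-anchors the final output onto the
  *input* pose by least-squares rigid alignment (Kabsch). No reference
  structure is involved in either step — both are pure gauge fixing —
  and RMSD against the reference is still computed on paired atoms
  without any superposition onto the reference.
* **Loss smoothing.** The absolute values and norms in the training
  losses are smoothed as `|x| -> sqrt(x^2 + eps^2)` with `eps = 0.01`
  (Å or radians; `loss_smooth_eps`). The exact kinks leave
  constant-magnitude, sign-flipping gradients once a term is satisfied,
  which oscillate at the optimizer's step-size floor and — through
  Adam's second-moment normalisation — drown the smaller frame-aligned
  signal on shared weights. The smoothed gradients decay with the
  residual instead; the value change is bounded by `eps` per term. The
  public loss functions stay exact.
* **Gradient routing.** The chain losses train their branches with full
  backpropagation through the shared 1D convolution. The whole-structure
  loss trains only the final corrector by default
  (`staged_gradients = TRUE`): letting it flow back into the chain
  branches measurably stalls their own objectives (the main-chain loss
  freezes near its initial value and the side-chain loss increases),
  whereas the staged routing lets all three terms descend together. This
  mirrors the staged design: chains are pre-corrected first, then the
  assembled structure receives final adjustments. Full backpropagation
  is available as a switch and is what the gradient-check tests
  exercise.
* **Padding.** Padded rows are zeroed after every stage and excluded from
  every loss; the recurrent branches only run up to the longest real
  sequence in a batch.
* **Training.** Adam (default learning rate 1e-3; the desk-scale runs in
  this package use 1e-2) with cosine learning-rate decay, global-norm
  gradient clipping at 5, one unweighted sum of the active loss terms
  (per-term weights are exposed but default to 1). Seeded shuffling makes
  runs bit-reproducible. Gradients pass through both the points and the
  predicted-side frames of the frame-aligned loss, verified against
  central differences.

The ablation variants mirror the architecture study: `LSTM_MAIN` corrects
only the main chain (trained with the main-chain and whole-structure
losses), `LSTM_SIDE` only the side chain (side + whole-structure), and
`LSTM_ALL` only the recombined structure (whole-structure loss alone).
`loss_mode = "MSE"` swaps all geometric terms for mean squared coordinate
error on the final output.

## Featurization and voxelization

Each atom carries eight chemical features: atomic number, formal charge,
aromaticity, ring membership, hybridization code (SP/SP2/SP3 → 1/2/3,
other 0), and explicit/implicit/total valence. They come from a fixed
plain-text lookup table keyed by (residue, atom name), generated once for
mid-chain residues of G-X-G tripeptides with a cheminformatics toolkit;
featurization is therefore deterministic with no runtime chemistry
dependency.

The voxel grid is 48×48×48×8 at 1 Å per voxel, centred on the heavy-atom
centroid (which makes voxelization exactly translation invariant). An atom
contributes its raw feature values — one channel per feature, no one-hot
encoding, which would change the channel count — to the voxel containing
it; collisions accumulate by summation, so per-channel grid sums equal
per-feature atom sums whenever nothing falls outside the cube
(out-of-bounds atoms are dropped and counted). No rotation augmentation is
applied by default. Channels are z-scored with training-set statistics
stored in the checkpoint.

## The binding classifier

Four 3×3×3 convolution layers with batch normalization and ReLU; one
residual block spans layers 2–3 (stride 1 inside the block; the shortcut
is the identity when channel counts match and a 1×1×1 projection
otherwise — the default channel schedule [8, 32, 64, 128, 128] needs the
projection); strided convolutions (2, 1, 1, 2) provide the spatial
down-sampling, followed by a two-layer fully connected head and a sigmoid.
Training minimises binary cross-entropy with Adam; the decision threshold
for accuracy-type metrics is 0.5, and AUC is threshold-free. An optional
`input_pool` factor average-pools the grid before the first convolution;
the desk-scale runs use factor 2 (24³ input) with a reduced channel
schedule so that the full training loop stays inside a few CPU-minutes.

Negative samples are generated by peptide swap: each positive's peptide
segment is replaced by the peptide of another positive (uniformly drawn
among complexes with a different peptide identity, seeded), rigidly
translated so its centroid matches the original peptide's centroid. This
in-place substitution is a modelling choice — re-predicting the swapped
complex from sequence is out of reach without a structure predictor — and
is the largest approximation in this module. Train/test splits can be
grouped by TCR so the same receptor never appears on both sides.

## The synthetic generator

`synth_config()` defines the study conditions: idealized backbones with
canonical bond lengths (N–CA 1.46, CA–C 1.52, C–N 1.33 Å) laid along
seeded, jittered helical curves; side chains grown from residue-template
connectivity with element-typed bond lengths; three segments placed so the
two CDR3 centroids sit 11 Å apart. The binding label is planted
geometrically: label 1 iff the peptide centroid lies within
`binding_rule_radius` (6 Å) of the inter-CDR3 midpoint; binders are placed
within 3 Å of that midpoint and non-binders 11–14 Å away, so the rule is
exactly recoverable from noiseless geometry and all fixtures fit the 48 Å
cube. "Predicted" structures add zero-mean Gaussian noise with a larger
standard deviation on side chains (default 2 Å) than on main chains
(default 1 Å), emulating the main/side quality gap of structure
predictors, plus a small global rigid jitter.

What the generator does *not* emulate: real rotamer distributions, ring
closure of aromatic side chains, physically relaxed packing, the smooth
spatially-correlated error fields of real structure predictors (the noise
here is independent per atom), or sequence–structure dependence beyond the
planted rule. Passing tests therefore demonstrate that the implementation
learns and evaluates as specified on a controlled signal — not that the
trained weights transfer to experimental TCR complexes.

## Problem sizes used by the tests and the acceptance script

The shipped demonstration runs use deliberately reduced problem sizes so
that the whole suite remains a desk-scale computation; the sizes are the
package's own choices and are recorded here:

* Correction efficacy: 50 training pairs at noise levels 1 Å (main) and
  2 Å (side), hidden size 16, bidirectional, 300 epochs of minibatch-10
  Adam; mean paired-atom RMSD is compared before and after correction on
  those pairs. Held-out improvement requires substantially longer
  training and is not claimed at this scale — see the optimisation
  discussion above: raw RMSD only drops after the invariant shape terms
  are driven low.
* Ablation ordering: each architecture variant is trained to depth
  (350 epochs) on a small fixed set of five short complexes and the
  variants are compared on that same distribution, across five training
  seeds. In the under-trained regime the ordering is systematically
  inverted — variants that correct less damage less — so a deep run on a
  small set is the scaled-down setting in which the architecture
  comparison is meaningful.
* Binding recovery: 200 complexes, TCR-grouped 80/20 split, the pooled
  24³ input, channel schedule [8, 16, 16, 32, 32], 10 epochs.

The defaults in the configuration objects (hidden 128, channels
[8, 32, 64, 128, 128]) remain the reference settings for full-scale use.

## Known limitations

* Backbone O atoms participate in no geometric loss term (frames and the
  frame-aligned error use N/CA/C; bond penalties use C/N/CA; the
  side-chain loss uses side-chain atoms), so the correction network leaves
  them essentially at their input positions unless trained with MSE.
* The side-chain loss constrains only internal distances; the absolute
  placement of the side-chain cloud is held near the input by the residual
  parametrisation and the whole-structure stage, not by the loss itself.
* The geometric losses create an optimisation path on which raw RMSD can
  transiently rise before the shape terms are driven low; short training
  runs can end inside that regime. The loss traces returned by
  `train_correction()` make this visible.
* Peptide-swap negatives keep the donor peptide's internal conformation;
  no repacking is attempted.
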