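---
title: "Geometric graph learning for drug-target binding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric graph learning for drug-target binding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tribind)
```

## The problem

Molecular recognition between a small molecule and a protein target spans
three nested questions: does the pair bind at all (occurrence), which
residues form the interface (site), and how strong is the interaction
(affinity, expressed as p-affinity, the negative decadic logarithm of a
molar Ki/Kd/IC50). tribind treats the three as one hierarchy over shared
representations: a residue-level protein graph carrying geometric and
surface determinants of recognition, an atom-level drug graph carrying
physicochemical determinants, one protein encoder and one drug encoder,
and three task heads that consume the encodings at the granularity each
question needs.

## Protein representation

A protein (or pocket) of $N_p$ residues becomes a directed graph whose
nodes are residues and whose edges connect residue pairs with alpha-carbon
separation up to 12 Å. Node features are 1024-dimensional per-residue
sequence embeddings. The package defines an embedder interface so a
pretrained protein language model can be plugged in; the bundled default is
a deterministic position-aware hash embedder that maps (residue letter,
position) to values in $[-1, 1]$ with the letter component dominating
(weight 0.8). This keeps every pipeline stage runnable and testable
offline; it carries residue identity and position but none of the
evolutionary signal a real language model would add, which bounds what the
synthetic experiments below can show about real proteins.

Each residue carries a right-handed orthonormal local frame: origin at the
alpha-carbon, $\hat{x}$ along C$\alpha\to$C, $\hat{y}$ the Gram-Schmidt
complement of C$\alpha\to$N, $\hat{z}$ their cross product. Residues with
missing or collinear backbone atoms fall back to a chain-direction frame
(x toward the next residue's alpha-carbon, Gram-Schmidt against a global
axis), so a frame always exists. For a directed edge $(i, j)$ the 8-d edge
feature is

$$e_{ij} = [\, x_{ij}, y_{ij}, z_{ij},\; \phi(d_{ij}),\; q_{ij} \,]$$

where $(x_{ij}, y_{ij}, z_{ij})$ are residue $j$'s alpha-carbon
coordinates expressed in frame $i$, $\phi(d) = \exp(-d^2 / 2\sigma^2)$
with $\sigma = 1$ Å is a radial-basis distance encoding, and $q_{ij}$ is
the unit quaternion of the relative rotation between the two frames
(columns of frame $j$'s basis expressed in frame $i$; canonical sign
$w \ge 0$ to remove the quaternion double cover). Everything is built from
relative geometry, so the features are invariant under global rigid
motions — the test suite verifies this to $10^{-5}$ over batches of random
rotations and translations, and the heads inherit the invariance.

### Surface descriptors

Each residue additionally carries a 10-d surface vector: mean curvature,
Gaussian curvature, shape index and curvedness of the solvent-accessible
surface averaged over the surface points assigned to the residue, followed
by the mean atom-type one-hot composition (C, H, O, N, S, other) over the
residue's atoms. The surface is sampled as a dot surface: each atom's
probe-expanded sphere (probe 1.4 Å, van der Waals radii by element) is
covered with a Fibonacci point lattice and points buried inside any other
expanded sphere are discarded. Principal curvatures come from a local
quadric fit (with the outward sphere normal as the height axis) over a
3 Å neighbourhood; shape index is
$(2/\pi)\arctan\!\big((\kappa_1 + \kappa_2)/(\kappa_1 - \kappa_2)\big)$
with $\kappa_1 \ge \kappa_2$, curvedness
$\sqrt{(\kappa_1^2 + \kappa_2^2)/2}$. We chose the dot-surface + quadric
route over a volumetric mesh because it needs no voxelization, gives
direct control of sampling density, and recovers the analytic sphere to a
few percent (tested). Two details matter numerically: sampling directions
are drawn in a body frame (principal axes of the heavy-atom cloud, signs
fixed by the third moment along each axis) so the dot surface co-rotates
exactly with the structure and surface descriptors are rigid-motion
invariant to float precision; and each surface point is assigned to the
residue of its generating atom, which for an accessible-surface point is
its nearest heavy atom. Residues with no surface points (fully buried)
get a zero geometric block; hydrogens are simply absent from most
structure files, in which case the H slot of the composition stays zero.

## Drug representation

Molecules parse from SMILES (through OpenBabel) or SDF (coordinates
retained). The graph is undirected; atoms carry an 82-d concatenation of
one-hot blocks — element over 44 common elements plus other (45), degree
0-10 (11), explicit valence 0-10 (11), implicit valence 0-10 (11),
aromaticity (2) and a reserved formal-charge-sign pad (2) — and bonds a
6-d vector: bond-type one-hot over single/double/triple/aromatic plus
conjugation and ring-membership flags. Only the total width is canonical;
the partition is declared in one place (`tribind:::ATOM_ELEMENTS` and
`featurize_atoms`) so it can be swapped without touching the encoders.
Valence semantics follow the reference cheminformatics toolkit: explicit
valence is the sum of kekulized bond orders, implicit valence the standard
element valence minus the explicit part, conjugation requires pi density
on both endpoints; the test suite freezes toolkit-verified values for
ethane, benzene and butadiene.

## Encoders

The protein encoder runs $T = 3$ layers of attention-based message
passing with weights shared across layers (the update and attention
operators are layer-free in the model definition). Per layer, the message
into residue $i$ from neighbour $j$ is
$m_{ij} = \alpha_{ij} (W_v h_j + W_e e_{ij})$, with

$$\alpha_{ij} = \lambda\,\mathrm{softmax}_j\!\left(\tfrac{(W_Q^v h_j)^\top
(W_K^v h_i)}{\sqrt{d_h}}\right) + (1 - \lambda)\,
\mathrm{softmax}_j\!\left(\tfrac{(W_Q^e e_{ij})^\top (W_K^e e_{ij})}
{\sqrt{d_e}}\right), \qquad \lambda = 0.5,$$

both softmaxes normalized over the in-neighbourhood of $i$ (the only
normalization domain under which the attention weights of a node sum to
one). Setting $\lambda$ to 1 or 0 recovers pure node- or edge-similarity
attention, which the tests assert against a dense re-implementation. The
residual update is $h_i \leftarrow \sigma(W_{out}(h_i + \sum_j m_{ij})) +
h_i$ with LeakyReLU $\sigma$. After the last layer the node state is
concatenated with the projected surface vector (width $h_2 = 32$) and
fused by a two-layer MLP back to width $h_1$.

The drug encoder is a three-layer message-passing network: messages
$\sigma(W_u [h_j \,\|\, e_{ij}])$ flow along both directions of every
bond and the update concatenates the current state with the message sum,
$h_i \leftarrow W_C [h_i \,\|\, \textstyle\sum_j m_{ij}]$.

## Task heads

**Occurrence.** Both encodings are projected to width $h_4$, refined by a
dual-pathway multi-head cross-attention (protein queries against drug
keys/values and vice versa, 4 heads, residual + layer normalization), and
gated per modality: $g = \mathrm{sigmoid}([H' \| H] W)$,
$H^f = g \odot H' + (1 - g) \odot H$. Mean plus max pooling gives one
vector per modality, each refined by a residual MLP; the joint vector
$z = [z_p \| z_d \| z_p \odot z_d \| z_p - z_d]$ feeds a four-layer
classifier ($4h_4 \to 2h_4 \to h_4 \to h_4/2 \to 1$, LeakyReLU + layer
norm + dropout between layers). The final squashing is a sigmoid on the
single logit — the two-class softmax of the model definition collapses to
exactly this once one logit is fixed at zero. Pooling makes the output
invariant to residue and atom order.

**Site.** Projections to $h_5$, one cross-attention (protein queried
against the drug) with a residual, then residue self-attention; the two
streams fuse through a gate, and the per-residue probability is
$\mathrm{sigmoid}(W_r z_i + \mathrm{MLP}(z_i))$ with MLP widths
$h_5 \to 2h_5 \to 1$. The fused embedding $z_i$ is the only per-residue
tensor in scope, so it is the argument of both terms. Every stage is
permutation-equivariant.

**Affinity.** The pocket-centred heterogeneous graph has residue and atom
nodes; each residue connects to its $k = 6$ nearest drug atoms and each
atom to its 6 nearest residues (Euclidean alpha-carbon-to-atom distances;
squared distances are rounded to $10^{-6}$ before ranking so exact
geometric ties break by index regardless of global orientation). Interface
frames differ from the encoder frames: a residue's z axis points at its
nearest drug atom with the xz plane spanned toward the preceding residue;
an atom's z axis points at its nearest residue with the xz plane toward
its nearest bonded neighbour. Edge features mirror the 8-d geometric
layout. $T$ typed attention-convolution layers (per-layer weights, as the
model definition indexes them by layer) update both node sets; attention
scores are $\langle W_Q h_i,\; W_K [h_j \| e_{ij}] \rangle / \sqrt{h_6}$
normalized per neighbourhood. The printed update adds an $h_6$ vector to a
$2h_6$ message sum, which cannot type-check; we interpose a value
projection $W_V \in \mathbb{R}^{2h_6 \times h_6}$ on $[h_j \| e_{ij}]$ —
the standard attention-value form and the minimal dimensionally consistent
reading. Sum pooling over pocket residues and over atoms gives $u_p$ and
$u_d$ (sum, not mean: the output is deliberately sensitive to molecular
size, which a test asserts by duplicating the drug). A pairwise term
aggregates $[h_{p,i} \| h_{d,j}]$ over residue-atom pairs with
softmax-normalized scalar weights — normalization is implied by
"adaptively weighted aggregation", and without it the aggregate scales
with pair count; the pair set defaults to hetero-graph edges
(`pairwise = "edges"`) for tractability, with `"all"` available. The final
regressor maps $[g \| u_d \| u_p]$ through $3h_6 \to 2h_6 \to 1$.

## Losses, metrics, and training

Occurrence trains with binary cross-entropy, affinity with mean-squared
error on p-affinity (Ki, Kd and IC50 values are pooled after the
$-\log_{10}$ transform), and site with focal loss
$-\,\bar\alpha\,(1 - p_t)^\gamma \log p_t$ with $\bar\alpha = \alpha$ on
positives and $1 - \alpha$ on negatives ($\gamma = 2$), which down-weights
easy, abundant non-binding residues. We default $\alpha = 0.75$: at the
~1:48 site imbalance the positive class is the rare one, so the class
weight must favour it for the loss to improve minority sensitivity — its
stated purpose. The $\alpha = 0.25$ convention of the detection literature
belongs to a regime of overwhelmingly many *easy* negatives where the
focusing term alone suppresses them; on our fixtures it down-weights the
minority threefold and measurably hurts held-out ranking of binding
residues, which is why we rejected it;
at $\gamma = 0$, $\alpha = 0.5$ it is exactly half the cross-entropy, a
closed form the tests pin to $10^{-9}$. Metrics are the standard panel —
MCC, F1, accuracy, specificity at a 0.5 threshold, rank-based AUROC
(average-tie handling) and step-integrated AUPRC for classification;
RMSE, MAE, Pearson and Spearman for regression — with AUROC cross-checked
against brute-force pairwise counting and AUPRC against frozen reference
values. Splits are random 7:1:2 within one of exact proportions and
reproducible by seed.

All learnable tensors live in a flat named list; forward passes are
written once against a small reverse-mode autodiff tape (matrix
primitives plus segment softmax/sum for variable-size neighbourhoods) and
serve both prediction and Adam training. Gradients of the tape are
verified against central differences, encoder outputs against dense
hand-rolled re-implementations with shared weights.

## Synthetic fixtures and what they show

The fixture generator plants recoverable statistical structure, not
physics. Toy proteins are ideal alpha-helices (rise 1.5 Å, 100° per
residue, radius 2.3 Å — consecutive alpha-carbons 3.8 Å apart) with
N/C$\alpha$/C backbones; toy molecules are 5-20-atom trees of C/N/O with
1.5 Å bonds, occasional double bonds and clash-free 3D poses. A complex
poses the molecule 4-6 Å off a random face of the helix; the planted site
is every residue with an atom within 5 Å of the ligand (checked against a
brute-force scan), and the planted affinity is
$4.0 + 0.02 \times (\text{contact pairs}) + \mathcal{N}(0, 0.1)$, all
constants recorded in the fixture manifest. Site residues draw
hydrophobic-biased letters (probability 0.8 from {L, I, V, F, W, M}),
emulating the compositional bias of real pockets so sequence features
carry site signal; for controlled imbalance experiments the site can
instead be planted as the exact $m$ residues nearest the ligand (98
residues with 2 site residues gives exactly the 1:48 positive:negative
ratio of curated site-annotation corpora).

The verification experiments run at desk scale: hidden widths 32 (surface
projection 16), 2 attention heads — `desk_config()` — with Adam at
learning rate $10^{-3}$, the standard small-data regime for the
eight-complex overfitting runs (300 epochs) and the focal-vs-cross-entropy
comparison (8 training and 6 held-out complexes per seed, 60 epochs, 5
seeds). Passing them shows the architecture is wired correctly, respects
its symmetries, and can extract planted signal; it says nothing about
accuracy on real proteins, which would require real structures, a
pretrained embedder, and benchmark-scale training.

## Numerical choices and limitations

Degenerate inputs are handled explicitly: missing backbone atoms fall to
chain-direction frames (with a warning), structures with fewer than four
heavy atoms get zero surface geometry, probabilities are clipped at
$10^{-7}$ inside losses, single-class label vectors report AUROC as
missing, and layer normalization uses $\epsilon = 10^{-5}$. Altloc
records keep the highest-occupancy conformer ('A' on ties); only the
first model of multi-model files is read by default; nonstandard residues
with an alpha-carbon are kept and typed "X". Known limitations: the stub
embedder is not a language model; the dot surface under-samples deep
crevices at low point densities; training is single-threaded CPU and
meant for small corpora; and uncertainty quantification is out of scope.
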