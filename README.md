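# tribind

Geometric graph learning for the three levels of drug–target molecular
recognition: **does** a small molecule bind a protein (occurrence), **where**
does it bind (residue-level site localization), and **how strongly**
(binding affinity regression).

## Who this is for

Computational chemists and structural bioinformaticians who want a fully
inspectable, pure-R implementation of a mechanism-aware drug–target
architecture — every featurization step, attention block, and gradient is
ordinary R code that can be read, tested and modified — together with a
synthetic-fixture harness that lets every stage run and be verified
offline, with no downloads, GPUs or pretrained weights.

## The model

Proteins are residue-level directed graphs: nodes carry 1024-d sequence
embeddings (pluggable embedder; a deterministic position-aware hash stub is
bundled), edges connect residues with Cα–Cα distance ≤ 12 Å and carry 8-d
rotation-invariant geometric features

&nbsp;&nbsp;&nbsp;&nbsp;*e*<sub>ij</sub> = [ x<sub>ij</sub>, y<sub>ij</sub>, z<sub>ij</sub>, φ(d<sub>ij</sub>), q<sub>ij</sub> ]

— the neighbour's Cα in the residue's local backbone frame, a Gaussian
radial basis φ(d) = exp(−d²/2σ²) (σ = 1 Å), and the unit quaternion of the
relative frame rotation. Each residue also carries a 10-d surface vector
(mean/Gaussian curvature, shape index, curvedness of the solvent-accessible
surface, plus atom-type composition). Drugs are atom-level graphs with 82-d
atom and 6-d bond one-hot features.

A shared graph-attention encoder (λ-blended node/edge similarity attention,
λ = 0.5, T = 3 layers, residual updates, surface fusion) and a drug
message-passing encoder feed three heads:

- **occurrence** — dual-pathway gated multi-head cross-attention, mean+max
  pooling, joint vector [z<sub>p</sub> ∥ z<sub>d</sub> ∥ z<sub>p</sub>⊙z<sub>d</sub> ∥ z<sub>p</sub>−z<sub>d</sub>], 4-layer classifier → probability;
- **site** — cross-attention + residue self-attention with gated fusion →
  per-residue probabilities, trained with focal loss (α = 0.75 on the rare positive class, γ = 2) for
  the ~1:48 binding:non-binding residue imbalance;
- **affinity** — pocket-centred heterogeneous residue↔atom graph (k = 6
  nearest neighbours each way, frame-based 8-d edge features), typed
  attention convolutions, sum pooling + pairwise aggregation → p-affinity
  (−log₁₀ molar).

Training runs on a small built-in reverse-mode autodiff engine with Adam;
gradients are test-verified against central differences, and forward passes
against independent dense re-implementations.

## Worked example

Train the site head on four synthetic complexes and probe an unseen one:

```r
library(tribind)

cx <- make_toy_complex(seed = 7)           # helix + posed toy ligand
which(cx$site == 1)                        # planted binding residues
#> 18 19 21 22 23 25
round(cx$affinity, 3)                      # planted p-affinity
#> 4.52

cfg <- desk_config(epochs = 120, seed = 1) # desk-scale widths (h = 32)
ds  <- make_task_dataset("site", 4, seed = 0, config = cfg)
model <- train_task("site", ds, cfg)
model$metrics
#> metrics (site, n = 202):
#>   MCC          1.0000
#>   F1           1.0000
#>   Accuracy     1.0000
#>   AUROC        1.0000
#>   AUPRC        1.0000

s  <- featurize_complex(cx, "site", cfg)
Hp <- encode_protein(s$pgraph, model$params, cfg)
Hd <- encode_drug(s$dgraph, model$params, cfg)
probs <- predict_sites(Hp, Hd, model$params, cfg)
round(auprc(probs, cx$site), 3)
#> 0.399
```

The training metrics show the model memorizes its four training complexes
perfectly (202 residues, all correctly classified) — the architecture can
fit residue-level labels. The held-out AUPRC of 0.399 against a 13% base
rate shows modest transfer of the planted compositional signal: four toy
complexes and a hash-stub embedder carry only weak transferable
information. Real-data performance requires real structures, a
pretrained protein-language-model embedder, and benchmark-scale training.

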