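---
title: "poseMIL: attention-based multi-instance learning over docking-pose bags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{poseMIL: attention-based multi-instance learning over docking-pose bags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Structure-based affinity models are usually trained and evaluated on
co-crystal complexes, but in a live discovery campaign one rarely has a
crystal structure for each ligand — what one has is a set of docking poses,
most of which may be wrong. poseMIL treats each protein–ligand entity as a
*bag* in the multi-instance-learning (MIL) sense: the bag
$X = \{x_1, \dots, x_K\}$ contains $K$ pose instances (typically up to 10
docking poses, optionally plus the crystal pose) and carries a single
real-valued label $y$, the experimental affinity in pK units
($-\log K_i$ or $-\log K_d$). Individual poses are unlabeled; the working
assumption is only that at least one pose is close to the binding mode that
generated the measurement.

Each pose-with-receptor is embedded by a graph-network backbone
$h_k = G_\psi(x_k)$, and the bag is pooled by a learned attention layer:

$$ z = \sum_{k=1}^{K} a_k h_k, \qquad
   a_k = \operatorname{softmax}_k\!\big(\tanh(W h_k^\top)\big), $$

followed by three fully-connected layers mapping $z$ to the predicted
affinity. The weights $a_k$ are nonnegative and sum to one, so the pooled
embedding is a convex combination of the instance embeddings and the whole
predictor is invariant to the order of poses in the bag — docking rank is
deliberately not an input. $W$ is a single row (one logit per instance);
the softmax is applied directly to the tanh
output, and the gated two-projection variant of attention-MIL is
intentionally not used. A multi-head variant (each head attending over its own slice of
the embedding, outputs concatenated) is provided for comparison; it changes
little in practice.

## Featurization and graphs

Atoms become nodes with a 19-dimensional feature vector in the Pafnucy
lineage: a 9-slot element one-hot (B, C, N, O, P, S, Se, halogen, metal),
a hybridization code (1/2/3 for sp/sp²/sp³, 0 when undefined), heavy- and
hetero-neighbor counts, five binary property bits (hydrophobic, aromatic,
acceptor, donor, ring), the partial charge, and the van der Waals radius.
The slot allocation (9+1+1+1+5+1+1) is the unique layout consistent with
that feature list at width 19. Perception is rule-based from elements and
the file bond table (aromaticity from aromatic bond records, ring
membership from cycle-containing biconnected components, donors as N/O with
an explicit hydrogen, acceptors as O or trivalent-or-less N, hydrophobic
carbons/halogens without hetero heavy neighbors); partial charges are read
from Mol2 input and otherwise computed with OpenBabel's Gasteiger model,
the same tool family the feature set originates from. Hydrogens never
become nodes but still inform the donor bit. Coordinates are centered on
the ligand heavy-atom centroid, and the receptor is truncated to a pocket
within 8 Å of any ligand heavy atom — comfortably beyond every graph
cutoff, so graph construction is unaffected by the truncation; the radius
is exposed for users who want the full receptor.

Two graph flavors feed the two backbones:

* **Spatial two-edge-type graph** — covalent edges for pairs within 1.5 Å,
  noncovalent edges for pairs in (1.5, 4.5] Å, both carrying the Euclidean
  distance. Cutoffs are inclusive (the boundary convention is frozen in
  tests). Classification is purely distance-based; unusually long covalent
  bonds (S–S ≈ 2.05 Å) therefore land in the noncovalent set, which is
  documented rather than special-cased. Intra- and intermolecular pairs are
  both kept.
* **Radius graph** — all pairs within 5 Å, the distance being the single
  scalar edge feature.

## Backbones

The **spatial graph convolutional backbone** (PotentialNet lineage) runs a
gated message-passing stage over covalent edges and then one over
noncovalent edges, two GRU propagation steps each; each stage closes with a
gated attention-sum readout ("gather") of width 16 (covalent) and 12
(noncovalent). The embedding is the concatenation [covalent ‖ noncovalent],
hence 28-dimensional at the default widths — the gather widths *are* the
embedding size, so no separate embedding-dimension knob exists for this
backbone. Internals the lineage leaves open (the linear input embedding,
GRU gating, the gather form, the concatenation order) are reconstructions
in its style and are marked as such in the code.

The **E(n)-invariant backbone** runs 6 message-passing layers over the
radius graph with residual connections and a per-edge sigmoid attention
gate; the squared distance is the only edge feature. Because the target is
a scalar, only invariant quantities are needed, so the coordinate-update
channel of the E(n)-equivariant family is omitted: distances are fixed
across layers and the embedding (a mean-pooled node state after an output
MLP, default width 128, 32 in desk-scale runs) is exactly invariant to
rotations, translations and reflections, which the tests assert against
random rigid motions including reflections.

In both cases the "embedding" is the activation immediately before the
backbone's scalar head, and a small scalar head on top of it provides the
per-pose predictions used in stage-1 training and by the Top/Avg baselines.

## Two-stage training

Training follows the separate ("two-stage") protocol. Stage 1 trains a
backbone on individual pose instances, each inheriting its entity's label —
the only label available, and the same supervision the Top/Avg baselines
see. Stage 2 freezes the backbone, extracts one embedding per pose into a
store, and trains the attention head on bags of embeddings. Both stages use
RMSprop (alpha 0.99, eps 1e-8) at an initial learning rate of 0.001 decayed
by 0.9 at epochs 5, 10, 20, 30, 50, 70 and 90, mini-batches of 20
(instances, then bags), mean-squared-error loss — the natural choice for an
RMSE-centric evaluation — and last-epoch checkpointing with no
validation-based selection. An end-to-end simultaneous option (batch of one
bag, gradients flowing through the pooling into the backbone) exists behind
the same interface and is smoke-tested.

One numerical choice deserves note: the attention head standardizes
incoming embeddings with per-dimension training-set statistics frozen into
the head. Without this, untrained embedding scales can push every logit
into tanh saturation, where softmax weights are frozen at uniform and the
attention gradient vanishes. The standardization affects the logits and the
fully-connected input; the pooled `z` returned to callers remains a convex
combination of the raw embeddings, so the pooling contracts (K = 1 gives
z = h, identical instances give uniform weights) hold exactly.

Both networks are trained by an in-package reverse-mode automatic
differentiation engine over dense matrices; the spatial backbone's batched
forward/backward pass also exists as a compiled (RcppArmadillo) kernel used
by the training loop, cross-checked in the tests against the reference
engine to 1e-9 and against finite differences.

## The synthetic benchmark

No deposited structures are required anywhere: a generator emits complete
synthetic entities — a ligand (random spatial walk, optionally seeded with
an aromatic six-ring, with elements, bonds, explicit polar hydrogens and
charges), a pocket of protein atoms in a shell around it, a *true* pose,
and K docking-style decoys. Decoys are produced by a rotation-plus-
translation perturbation rescaled to hit a prescribed heavy-atom RMSD
exactly; "good" poses draw their target RMSD from [0.3, 2.0] Å, "bad" ones
from [4, 10] Å. Ligands come from template families (a scaffold-family
analog) so a group split can hold entire families out.

The label is a deterministic function of the true pose only:
$y = 0.6\,c/n_\ell + 1 + \varepsilon$, where $c$ counts protein–ligand
heavy-atom pairs within 4.5 Å of the *true* pose, $n_\ell$ is the ligand
heavy-atom count and $\varepsilon$ is Gaussian (default sd 0.1 pK). The
constants place labels in a realistic pK range (roughly 2–12, sd ≈ 2, close
to the spread of public affinity sets). Two generator details exist
specifically to keep the MIL premise honest:

* the *contact fraction* of the true placement is sampled per entity and
  the pocket is built to achieve it (a near-shell/far-shell mixture), so
  the label is a property of how snugly the true pose sits — not of pocket
  size — and a decoy displaced out of the site cannot simply read it off
  the receptor;
* docking scores are a noisy decreasing function of pose contacts with
  noise on the order of the signal, so pose ranks are only weakly
  informative, mirroring the observation that the top-ranked pose is often
  not the best one.

What the generator does *not* emulate is real chemistry: atoms are points
with plausible element labels, bonds are distance-plausible, there are no
torsions, no force field, no docking search. Passing tests therefore
demonstrate the *mechanism* — that attention pooling recovers bag labels
from pose sets when only some poses are informative — not performance on
PDBbind-scale data.

## Evaluation protocols

`compute_metrics` reports RMSE, MAE, $r^2$, Pearson $r$ and Spearman $\rho$
(average ranks on ties; correlation metrics are flagged undefined on
zero-variance inputs). `compare_methods` evaluates three predictors over
the same entities: **Top** (stage-1 prediction of the rank-1 docking pose),
**Avg** (unweighted mean of stage-1 predictions across the bag) and **MIL**
(the attention head). Good poses are those with reference RMSD strictly
below 2.5 Å; entities stratify into "none", "1–4" and ">4" good-pose
groups. Pairwise pose-RMSD histograms (0.5 Å bins, density-normalized) give
a crystal-free consistency read-out. The bag-size ablation re-evaluates the
trained MIL head on k poses subsampled per bag (k = 1, 3, 5, 7, 9; 10
draws), reporting mean/min/max.

## Problem sizes and reproducibility

The desk-scale study conditions used by the test suite and the acceptance
script are: 700 entities split 500/200, 10 poses per bag with 1–3
informative, label noise 0.1 pK, the spatial backbone, 5 stage-1 and 40
stage-2 epochs, over seeds 0–9 (reduced epochs relative to the 100–200 of a
full-scale run; the loss traces show the backbone loss is well past its
fast-decay phase by then). The stratification analog uses the
all-good/all-bad/mixed mixture (0.3/0.3/0.4) at 250 entities, and the
noiseless-recovery check uses one informative pose, zero label noise and
longer training (10/50 epochs). Every random quantity — data, splits,
initialization, batch order, subsampling — derives from explicit seeds, and
fixed seeds reproduce results exactly.

## What bounded attention can and cannot recover

Because the attention logits pass through `tanh` before the softmax, they
live in $[-1, 1]$, and the weight on a single informative pose among $K$
can never exceed $e / (e + (K-1)e^{-1})$ — about 0.45 at $K = 10$. The
pooled embedding of a bag with one good pose is therefore always a mixture
carrying a majority of uninformative-pose signal, and the fully-connected
stack must decode the label through that mixture. This keeps the weights
well-conditioned and interpretable, but it places a ceiling on how exactly
a bag label can be recovered when informative poses are rare: in the
noiseless single-good-pose setting the trained model approaches the
mixture bound rather than the perfect-selection bound. With several good
poses per bag (the common docking regime) the informative mass grows
accordingly and the distinction fades.

## Known limitations

* Pose RMSD is plain matched-order heavy-atom RMSD without graph-symmetry
  correction; synthetic ligands avoid the symmetric topologies where this
  differs from a symmetry-corrected RMSD. Real symmetric ligands would need
  one.
* Covalent edges come from the 1.5 Å distance rule, not the file bond
  table; long covalent bonds are classified noncovalent.
* The embedding store is an RDS-backed single-file store (one group per
  entity, one record per pose rank, bit-exact round trip), suitable for the
  package's scale.
* Bag-level confounding is reduced, not eliminated: a receptor shared
  across instances always leaks some label-relevant signal into every pose,
  which is equally true of real docking data.
* The crystal instance, when included, is an ordinary rank-0 instance; the
  model is not told which instance it is.
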