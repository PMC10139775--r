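---
title: "Structure-aware protein self-supervised learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-aware protein self-supervised learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steps)
```

## The problem

Protein representation learning aims to compress a protein into a vector
useful for downstream prediction (function annotation, localization, enzyme
class). Sequence-only language models capture evolutionary statistics but no
explicit geometry; labels for supervised structural learning are scarce. The
approach implemented here pretrains a graph neural network (GNN) on protein
*backbone structures* with two self-supervised tasks that force the learned
representation to encode geometry, and couples the GNN to a pluggable
sequence encoder through a mutual-information objective so that sequence
knowledge flows into the structural model without ever modifying the sequence
encoder itself.

## Protein model

A protein of $L$ residues is a graph $G(V, E)$: one node per residue, an edge
between residues $i$ and $j$ whenever the C$\alpha$--C$\alpha$ distance
$d_{ij}$ is strictly below a threshold (default 7 Å, a standard contact
cutoff). Each edge carries the weight $e_{ij} = 1 / d_{ij}^2$, so spatially
closer residues exchange stronger messages. Each node carries

$$X_v = [\,h^{raw}_v \,\|\, \mathrm{RBF}(\phi_v/\pi) \,\|\,
\mathrm{RBF}(\psi_v/\pi) \,\|\, m_v\,],$$

where $h^{raw}_v$ is the residue's sequence embedding, $\phi_v, \psi_v$ are
the backbone dihedrals (normalized from $(-\pi, \pi]$ to $(-1, 1]$), RBF is a
bank of Gaussian kernels $\exp(-\gamma (x - u_k)^2)$ with centers $u_k$
evenly spaced on $[-1, 1]$ (16 centers, $\gamma = 10$ by default), and $m_v$
is a mask flag. Angles that are geometrically undefined (chain termini,
chain breaks) are encoded as all-zero RBF blocks with $m_v = 0$; *masked*
angles are all-zero blocks with $m_v = 1$. The flag channel is an addition of
this implementation: without it, a masked residue would be indistinguishable
from a terminus.

The GNN uses sum aggregation weighted by $e_{ij}$ and a purely linear COMBINE
per layer:

$$a_i^{(k)} = \sum_{v \in N(i)} e_{iv} h_v^{(k-1)}, \qquad
h_i^{(k)} = W_k\,(h_i^{(k-1)} + a_i^{(k)}) + b_k,$$

with $K = 2$ layers and hidden width 1280 by default. At the first layer the
sum $h^{(0)}_i + a^{(1)}_i$ is formed in the raw feature space and $W_1$ maps
it to the hidden width; this is the most literal reading of the combine rule,
which adds the two terms *before* the linear map. No nonlinearity is applied
between layers (an optional ReLU flag exists but defaults off). The graph
representation $h_G$ is the mean over final-layer node representations, and
the fused per-residue representation is $h_i = h_i^s + h_i^{(K)}$, where
$h_i^s$ is the sequence representation projected to the hidden width.

## Self-supervised objectives

**Distance-bin classification.** Because raw distances span very different
numerical scales within one protein, distance prediction is cast as
classification over $T = 30$ uniform bins. The bin range $[2, 20]$ Å is a
design choice of this package (2 Å is below any physical C$\alpha$ spacing;
20 Å separates medium- from long-range contacts); values outside the range
clamp into the first and last bin, so the top bin absorbs all distal pairs. A
two-layer ReLU head maps the difference $h_i - h_j$ to $T$ logits, and the
loss is the mean cross-entropy over all *ordered* pairs $i \ne j$. The
diagonal is excluded (normalizer $L^2 - L$): $h_i - h_i$ is identically zero
and $d_{ii} = 0$, so including it would hand the model a free constant class.
With zero head weights the prediction is uniform and the loss is exactly
$\ln 30 \approx 3.4012$ — a closed form the test suite pins to $10^{-9}$.

**Masked dihedral regression.** For each protein,
$\max(1, \mathrm{round}(0.15\,L))$ residues are drawn uniformly from those
whose $\phi$ *and* $\psi$ are both defined; their angle features are zeroed
and flagged, and a two-layer ReLU head reconstructs the normalized pair from
the fused representation. The loss is the *sum* (not mean) over masked
residues of both squared errors. One masked forward pass per protein feeds
both objectives — the distance task sees the angle-masked features — and the
joint loss is $\mathcal{L} = \ell_{dis} + \ell_{angle}$, each term averaged
over the proteins of a batch (batch pooling is unspecified in the original
formulation; a per-protein mean keeps the two terms on stable scales across
batch sizes).

## Sequence encoder and mutual information

The sequence encoder is deliberately pluggable. The built-in stand-in is a
learned per-amino-acid embedding table followed by a fixed symmetric
5-residue sliding-window average and a linear projection to the hidden width
— the minimal differentiable stand-in for a protein language model, adequate
because the bi-level machinery only requires that the encoder's parameters
$\theta$ exist and carry gradients. Precomputed per-residue embeddings from
any external protein language model can be supplied instead (TSV keyed by
protein id), in which case $\theta$ reduces to the projection.

The coupling between sequence and structure is the Jensen–Shannon
mutual-information lower bound

$$I(\theta, \omega) = \mathbb{E}_P[-\mathrm{sp}(-T_\beta(s_x, g_x))]
 - \mathbb{E}_{P \times \tilde P}[\mathrm{sp}(T_\beta(s_x, g_{\tilde x}))],$$

where $s_x$ is the mean projected sequence representation of protein $x$,
$g_x$ is its GNN readout, $\mathrm{sp}(z) = \log(1 + e^z)$, and the
discriminator $T_\beta$ applies a three-layer fully connected tower with skip
connections and ReLU to each side and scores the pair by dot product.
Negatives pair each protein's sequence vector with a *different* protein's
structure vector through a seeded within-batch derangement. Pooling to the
protein level is a design decision of this package (the residue level would
need a residue-pairing scheme for negatives); the zero-discriminator value
$-2\ln 2$ gives another exact closed form used in testing.

Two further decisions were genuinely open. The discriminator $\beta$ is
trained persistently by gradient ascent on $I$ at every outer step: an
untrained discriminator would make the inner maximization vacuous, and
$\beta$ — unlike $\theta$ — is not a pretrained asset, so updating it cannot
distort anything. And the MI estimate is computed on the unmasked forward
pass, since it relates representations of the *intact* protein.

## Pseudo bi-level optimization

The inner level nudges the sequence encoder toward higher MI with one
gradient-ascent step,

$$\theta(\omega) = \theta + \eta\, \partial I(\theta, \omega) / \partial \theta,
\qquad \eta = 5 \times 10^{-5},$$

and the outer level descends $\mathcal{L}(\theta(\omega), \omega, \alpha)$ in
$\omega$ (GNN) and $\alpha$ (heads) with learning rate $10^{-3}$ under cosine
decay. The scheme is *pseudo* because $\theta(\omega)$ is discarded after the
gradient computation: $\theta$ is byte-identical before and after every
epoch, which the test suite checks with `identical()`. This protects the
pretrained sequence encoder from the collapse that joint or alternating
optimization risks, while still letting its knowledge shape $\omega$.

Differentiating through the inner step requires the mixed second derivative:

$$\frac{d\mathcal{L}}{d\omega} = \frac{\partial \mathcal{L}}{\partial \omega}
 + \eta\, \frac{\partial^2 I}{\partial \omega\, \partial \theta}\, v,
 \qquad v = \frac{\partial \mathcal{L}}{\partial \theta}\Big|_{\theta(\omega)}.$$

The package's reverse-mode tape is first-order, so the Hessian-vector product
is computed by the standard central-difference trick
$[\nabla_\omega I(\theta + \epsilon v) - \nabla_\omega I(\theta - \epsilon v)]
/ (2\epsilon)$ with $\epsilon = 10^{-3} / \max(1, \|v\|)$. The step size was
chosen for numerical accuracy: the truncation error scales as $\epsilon^2$
while roundoff scales as $10^{-16}/\epsilon$, and at $\epsilon = 10^{-3}$ the
assembled outer gradient matches a full central-difference oracle of
$\omega \mapsto \mathcal{L}(\theta + \eta \nabla_\theta I, \omega, \alpha)$
to better than $10^{-9}$ relative on the small-toy checks in the test suite.
Three modes are exposed: `second_order` (default), `first_order` (treats
$\theta(\omega)$ as constant in $\omega$; cheaper, and a hedge against the
instabilities that motivate freezing $\theta$ in the first place), and `off`
(plain SSL training, which the tests verify agrees with a hand-rolled
training loop to $10^{-12}$ per step).

## Why a hand-written autodiff tape

No automatic-differentiation or deep-learning framework is part of this
package's R dependency set, and the bi-level scheme needs exact gradients of
a composite objective in which $\theta$ enters through three paths (node
features, fused representations, and the MI sequence side). The package
therefore includes a small reverse-mode tape over matrices
(`R/autodiff.R`): each operation accepts either plain numerics or tape nodes,
so a single implementation of the forward model serves both inference and
training. Every gradient path is validated against central finite differences
in the test suite, and the numeric forward pass is by construction identical
to the differentiated one.

## The synthetic-structure generator

All training and testing runs on synthetic backbones with analytically known
geometry, built by natural-extension-of-reference-frame (NeRF) chain
extension from ideal internal coordinates: bond lengths N–C$\alpha$ 1.458 Å,
C$\alpha$–C 1.525 Å, C–N 1.329 Å; bond angles 121.7°/111.2°/116.2°; peptide
bond fixed trans ($\omega = \pi$). These standard values give the canonical
~3.8 Å consecutive C$\alpha$ spacing. Three generators cover the
conformational extremes: ideal $\alpha$-helix ($\phi, \psi = -57°, -47°$),
ideal $\beta$-strand ($-120°, +120°$), and random coil ($\phi, \psi$ uniform
on $(-\pi, \pi]$). Sequences are uniform over the 20 amino acids, so sequence
and structure are statistically independent *except* through the generator
class — exactly the coupling the MI objective is meant to detect. Labelled
toy datasets assign each protein its generator type as the class.

What the generator does *not* emulate: side chains, self-avoidance (random
coils may clash sterically), loop/turn structure between secondary-structure
elements, multi-domain architecture, and any realistic sequence–structure
statistics. Passing tests therefore demonstrate that the machinery is
mathematically correct and that the objectives extract recoverable geometric
signal — not that the defaults are tuned for real proteomes.

## Degenerate inputs and numerical choices

* Torsions follow the standard convention (trans $= \pi$, cis $= 0$, sign by
  right-hand rule); the implementation is cross-checked against an
  independent torsion routine (bio3d) in the tests. Collinear atom triples
  raise an undefined-dihedral error, which the dihedral table converts to an
  invalid flag rather than an exception.
* A 2-residue chain has exactly one valid $\phi$ and one valid $\psi$ but no
  residue with both, so such proteins contribute to the distance loss and are
  skipped by the angle task (a typed condition, not a crash).
* Coincident C$\alpha$ positions ($d_{ij} = 0$, $i \ne j$) are rejected when
  building a graph because the edge weight $1/d^2$ is undefined.
* Distances below/above the bin range clamp to the extreme bins rather than
  being discarded.
* PDB output is the minimal single-model, single-chain, N/CA/C dialect at the
  format's $10^{-3}$ Å precision; reading drops residues missing any backbone
  atom and records a chain break there and at residue-number gaps.
* The finetune head is a single linear map initialized at zero: a zero-init
  linear probe is deterministic and lets the learned gradient direction,
  rather than a random initial projection, decide early argmax predictions.
* Internal indexing is 1-based (R convention); user-facing class labels and
  distance-bin indices are 0-based counts in $[0, C)$ and $[0, T)$.

## Problem sizes in the shipped experiments

The test suite and the acceptance script run the full pipeline at reduced
width so everything completes in seconds to a couple of minutes on one CPU:
hidden width 8–32 (vs the 1280 default), stand-in embedding width 5–16,
200-protein pretraining sets of length 20–40 for the recovery experiment,
and 60/20 train/test splits for helix-vs-strand finetuning. These sizes are
the package's chosen desk-scale study conditions; the defaults in
`steps_config()` remain the full-scale values. The headline benchmark
accuracies of structure-aware pretraining at scale require a pretrained
protein language model, a large predicted-structure corpus and GPU training,
and are out of scope here; nothing in this vignette states an empirical
result that the tests or `scripts/acceptance.R` do not themselves compute.

## Known limitations

* The stand-in sequence encoder carries no evolutionary information; MI
  coupling can only exploit within-dataset statistics.
* The FD Hessian-vector product costs two extra MI gradient evaluations per
  outer step and is approximate near ReLU kinks (measure-zero in practice).
* Cross-entropy over all ordered pairs is $O(L^2)$ per protein; for long
  chains a pair-subsampling strategy would be needed.
* `mi_estimate` requires batches of at least two proteins; singleton batches
  fall back to plain SSL gradients.
* Random-coil fixtures are not self-avoiding, so their contact graphs are
  denser than real disordered regions.
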