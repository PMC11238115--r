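---
title: "Gram-matrix conformation encoding and geometric pretraining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gram-matrix conformation encoding and geometric pretraining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gramconf)
```

## The representation

A conformer is an `N x 3` coordinate matrix `X` in Angstrom. After
translating the centroid of *all* atoms (hydrogens included) to the origin,
the Gram matrix

\[ G = X X^\top, \qquad G_{ij} = x_i \cdot x_j \]

captures the full geometry up to rigid motion and reflection. Three facts
make it attractive as a learning target:

1. **E(3)-invariance.** Rotations, reflections and (after centering)
   translations leave `G` unchanged, so a network predicting `G` never has
   to learn pose.
2. **Exact interconvertibility.** With the atom-to-origin distances
   `D_{0i} = \lVert x_i\rVert`, `G` and the interatomic distance matrix `D`
   convert exactly both ways; bond lengths are distances of bonded pairs,
   and any angle cosine is a closed-form ratio of Gram entries. `G` carries
   strictly more information than `D` alone (it fixes the origin frame).
3. **Invertibility to coordinates.** The symmetric eigendecomposition
   `G = Q \Lambda Q^\top` with the three largest eigenvalues gives
   `x_{ik} = \lambda_k^{1/2} Q_{ik}` — classical multidimensional scaling.
   For an exact `G` the remaining eigenvalues vanish; for a noisy predicted
   `G` the top-3 truncation is the best rank-3 least-squares fit.

The corresponding functions are `gram_from_coords()`, `gram_to_distance()`,
`distance_to_gram()`, `angle_cosine_from_gram()` and `mds_reconstruct()`.
Chirality is the one thing `G` cannot see: a structure and its mirror image
share a Gram matrix. Reconstructions are therefore scored with
reflection-tolerant alignment by default (`aligned_rmsd(allow_reflection =
TRUE)`); set the flag to `FALSE` when comparing against bioactive reference
geometries where handedness matters.

## Numerical choices

All tolerances live in one place (`gram_tolerances()`):

* symmetry acceptance, relative: `1e-9`;
* radicand clamp in `G -> D`: negative squared distances above
  `-1e-6 * max|G|` are treated as roundoff and clamped to zero, anything
  more negative raises an error (the matrix is then not a Gram matrix of
  real points);
* rank threshold: eigenvalues below `1e-9` times the leading eigenvalue
  count as zero. `mds_reconstruct()` also zeroes such eigenvalues so planar
  (rank-2) and collinear (rank-1) inputs reconstruct exactly flat.

The eigensolver is LAPACK's symmetric solver on `(G + G^T)/2`; eigenvalues
come back sorted, ties are broken by solver order, which is harmless because
reconstruction is defined only up to E(3) and every comparison aligns
first. Negative eigenvalues among the selected three (possible for
predicted matrices) are clamped to zero before the square root.

`angle_cosine_from_gram()` refuses triples with a zero-length arm
(degenerate geometry) rather than returning `NaN`; `derive_geometry_from_gram()`
clamps and flags degenerate radicands instead, because a training loop must
survive a bad predicted matrix.

## The encoder

`pregtm()` trains a Graphormer-style encoder: atoms are nodes, and structure
enters through three learned biases rather than message passing —

* a **centrality** embedding added to each atom's initial state, indexed by
  degree (capped at `max_degree_cap`, default 8);
* a per-head **spatial** bias on every attention logit, indexed by
  shortest-path hop count (capped at `max_hop_cap`, default 8, with one
  sentinel bucket for disconnected pairs and one for the super node);
* an **edge encoding** shared across heads: the mean over the shortest
  path's edges of the bond-feature vector projected by a per-position
  weight. Shortest paths are computed by BFS with lexicographically
  smallest-neighbor expansion, so the chosen path — and hence the encoding —
  is reproducible.

A super node attends bidirectionally to all atoms through its own hop
bucket; it is excluded from the Gram head and anchors the origin-distance
head. Blocks are pre-norm (LayerNorm, multi-head attention, residual,
LayerNorm, GELU feed-forward, residual), followed by a final linear layer.
Input features are the 17-dimensional atom and 7-dimensional bond schema
documented in `featurize()`.

The Gram head is the plain inner product `Ĝ_uv = h_u · h_v`, which makes
`Ĝ` symmetric and positive semidefinite for *any* parameter values — a
structural guarantee, not a learned property. Distances derived from
embeddings are `‖h_u − h_v‖`, so predicted radicands can never go negative.
Origin distances and bond lengths map through softplus (non-negative),
angles through a sigmoid scaled to `(0, π)`; the angle head canonicalizes
`(i, j, k)` with the smaller terminal index first so both orientations give
one value.

Everything — forward pass, backpropagation, Adam, gradient-norm clipping —
is base R matrix algebra. The test suite checks the analytic gradients of
all four loss variants against central finite differences.

### Supervision variants and losses

| variant | supervised quantities |
|---|---|
| a | distance matrix |
| b | distance matrix + origin distances |
| c | Gram matrix |
| d | Gram matrix + bond lengths + bond angles (MLP heads) |

Per-molecule losses are means over all `N²` ordered pairs (diagonal
included — it carries `‖x_i‖²` information in the Gram case), over atoms for
origin distances, and over the bond and angle sets for the auxiliary terms;
molecules in a batch are averaged unweighted. Term weights default to 1 and
are configurable. The angle term is squared error in radians by default;
`angle_squared = FALSE` restores a literal linear form for comparison.

### Initial-state noise

Atoms in identical chemical environments (e.g. the three hydrogens of a
methyl group) receive identical features and identical attention biases, so
a deterministic encoder must give them identical embeddings — yet their true
coordinates differ. Gaussian noise added to the initial states breaks these
ties. `N(noise_mu, noise_sigma^2)` is interpreted with sigma as a *standard
deviation*. The package default is `noise_sigma = 0.02` (a gentle
perturbation appropriate when generalization matters); for memorization-type
experiments, where each training molecule's noise draw is fixed and
replayed every step and at prediction time, a sigma near the unit scale of
the initial states (`noise_sigma = 1.0`) is used — at that scale the draw
acts as an effective atom identifier and the symmetric-atom error floor
disappears. Each training molecule's draw comes from the run seed; unseen
molecules are embedded with noise off (`sigma = 0` at inference), which is
also the default for frozen-embedding extraction.

### Optimizer settings

Adam with `beta1 = 0.9`, `beta2 = 0.99`, global gradient-norm clipping at 5
(attention logits occasionally spike on near-converged objectives; clipping
removed the instability in our training curves), and an optional cosine
decay from `lr` to `lr_final`. Training histories, early stopping on a
validation set (patience in evaluations) and a `stop_loss` floor are built
into `pregtm()`.

## Two-stage pipeline

Stage 1 (`pregtm()`) needs conformers; stage 2 (`pregtm_property()`)
deliberately does not. A fresh encoder of the same family produces `h'_u`;
the frozen stage-1 embeddings `h_u` are concatenated per atom, pooled by a
readout (mean over real atoms by default; sum and super-node readouts are
selectable), and passed to a fully connected head — squared error for
regression, logistic cross-entropy for binary classification, with `NA`
labels masked. The frozen parameters are checksummed before and after stage
2 and asserted unchanged. `pregtm_end_to_end()` chains data, split,
pretraining, embedding, property training and evaluation, and writes a
manifest (seed, config, parameter checksums) so a run can be reproduced
exactly; with noise off, reruns are bit-identical.

## Synthetic fixtures

`generate_point_clouds()` draws uniform points in a box with a minimum
separation (default 0.8 Å) — the right input for purely geometric claims,
where chemistry is irrelevant. `generate_toy_molecules()` emulates
small-molecule inputs: up to 9 heavy atoms over C/N/O/F with explicit
hydrogens (at most 29 atoms total), as random single-bonded trees plus
carbonyl-, nitrile- and aromatic-ring-bearing variants, with coordinates
from idealized internal geometry — standard bond lengths per element pair
and order, tetrahedral/trigonal/linear angles by hybridization, randomized
torsions, exact planar hexagons for rings.

What these fixtures do **not** emulate: conformational strain, ring pucker,
non-ideal angles, intramolecular clashes beyond a separation floor,
electrostatics, and the size/flexibility of drug-like molecules. Passing
tests therefore demonstrate the *mathematics* (conversions, invariances,
spectra), the *implementability* of the learning objective (overfit
recovery), and the *mechanics* of the pipeline — not chemical accuracy on
real data, which requires pretraining on real conformer sets at scale.

Featurization chemistry (hybridization from incident bond orders,
aromaticity of alternating six-rings, a conjugation rule) is heuristic and
documented in `featurize()`; it is exact on the fixture chemistry this
package generates, which is what the tests rely on.

## Problem sizes used by the checks

The package's own validation runs at deliberately small scale: 1000 random
conformers (4–29 atoms) for reconstruction precision; 500 conformers times
10 rigid motions for invariance; 500 round-trip instances; overfit recovery
with `layers = 3, hidden = 64, heads = 4` on 6 toy molecules for up to 2000
steps and three seeds; 200 conformers per noise level on the tolerance
curve; and a 28-molecule two-stage run for the frozen-embedding sanity
tasks. These sizes were chosen so every claim re-verifies in minutes on one
CPU while still exercising each code path at full fidelity.

## Known limitations

* No conformer-ensemble generation: one Gram matrix, one reconstruction.
  COV/MAT default to ensemble size 1 accordingly.
* Chirality is invisible to `G`; handedness must come from elsewhere.
* The scaffold split's greedy rule (groups sorted by size then string,
  assigned to the first split still below capacity, training first) can
  overshoot capacities by design — groups are never divided.
* Open Babel performs SMILES parsing and canonicalization; molecules
  outside the H/C/N/O/F valence model of the sanitizer are rejected rather
  than silently accepted.
* Training is single-threaded base R: perfectly adequate for the fixture
  scale this package targets, not for pretraining on hundreds of thousands
  of conformers.
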