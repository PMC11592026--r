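---
title: "Rebuilding protein backbones from CA traces: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rebuilding protein backbones from CA traces: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Coarse-grained simulations and some experimental maps yield only the
alpha-carbon positions of a protein chain. Most downstream tools need the
full heavy backbone (N, C, O). `replate` rebuilds those atoms from the CA
trace alone, exploiting the planarity of the peptide bond: because of its
partial double-bond character, the atoms C(i), O(i), N(i+1) and the two
flanking alpha carbons lie in one plane (the *peptide plate*). Treating the
plate as a rigid body of ideal geometry, its only remaining degree of
freedom — once both CA anchors are known — is a single rotation $\lambda$
about the CA(i)–CA(i+1) virtual bond. Backbone reconstruction therefore
reduces from nine unknown coordinates per residue to one angle per plate.

## The $\lambda$ parameterization

For plate $p$ (between CA$_p$ and CA$_{p+1}$), $\lambda_p$ is the dihedral
between the plate plane and a reference plane through three consecutive
alpha carbons. Conventions the package fixes once and uses identically in
extraction and placement (so the two are exact inverses regardless of the
choice):

* **Reference CA.** CA$_{p+2}$ for $p \le K-2$; the final plate, which has
  no following CA, falls back to CA$_{p-1}$. No sign adjustment is needed
  because extraction and placement share the frame.
* **Zero and sign.** $\lambda_p = 0$ orients the plate in the plane spanned
  by the virtual-bond axis and the reference CA, with the plate's +y side
  towards the reference; increasing $\lambda$ rotates by the right-hand
  rule about CA$_p \to$ CA$_{p+1}$.
* **Extraction from real backbones.** Observed plates are never perfectly
  ideal, so $\lambda$ is defined as the angle whose rigid plate placement
  best fits the observed C, O and N atoms in the least-squares sense. This
  has the closed form $\lambda^\* = \operatorname{atan2}\!\big(\sum_k y_k
  (d_k\!\cdot\! e_z),\ \sum_k y_k (d_k\!\cdot\! e_y)\big)$, where $y_k$ are
  the template's off-axis coordinates, $d_k$ the observed positions relative
  to CA$_p$, and $(e_y, e_z)$ the frame's transverse axes. For a backbone
  that was itself built from ideal plates the fit is exact, which gives the
  package its machine-precision round-trip identity.
* **Plate indexing.** Plate $p$ contributes C and O to residue $p$ and N to
  residue $p+1$; the network's per-residue output row $i$ predicts plate
  $i-1$. The first residue's N and the last residue's C and O have no
  defining plate and are not reconstructed (nor is OXT).

Templates come in four variants — generic/proline crossed with trans/cis —
built from a single table of ideal bond lengths and planar angles in the
Engh–Huber style (`ideal_geometry()`, all values overridable from a
key-value config file). Cis plates are diagnosed from the CA–CA pseudo-bond
(< 3.5 Å, strict). The template is anchored at CA$_p$ with its axis along
the observed virtual bond; the far CA is *not* forced onto the template's
CA2, so plate-internal bonds (CA–C, C=O, C–N) stay exactly ideal while the
N–CA bond of the next residue absorbs the (small) difference between the
observed CA–CA distance and the template's. The trans template's own CA–CA
distance is 3.804 Å.

## Input features (K × 37)

Per residue, computed from the CA trace only: a 21-slot one-hot of residue
type (20 canonical + X); six local distances $|CA_i - CA_{i\pm j}|$,
$j \in \{3,4,5\}$ (0.0 sentinel outside the chain); four neighbor counts at
4, 4.5, 5, 6 Å (strict <, self excluded); a 3-slot secondary-structure
one-hot; a cis flag for bond $(i, i+1)$; and counts of helix- and
strand-type hydrogen-bond partners. Features are fed to the network
unnormalized (raw Å and counts); a standardization switch exists for
experimentation.

The secondary-structure assigner and the H-bond detector stand in for
external coarse-grained methods whose algorithms are not published in a
reimplementable form. Both are deliberately simple geometric rules with
config-exposed thresholds, validated against the ideal helix and hairpin
generators: helix requires $d(i,i+3) \in [4.5, 6.0]$ and
$d(i,i+4) \in [5.5, 6.9]$ Å over runs of ≥ 3; strand requires extended
local geometry ($d(i,i+2) > 6.3$ Å, runs of ≥ 2) plus a spatial partner at
sequence separation ≥ 3 within [4.2, 5.6] Å; H-bond counts are gated so
they are nonzero only inside regular elements. These rules will not
reproduce any particular reference assigner's labels on real proteins;
they exist to give the network a consistent, trace-derived signal.

## The network

Five sequential 1-D convolutional layers (kernel widths 11, 9, 5, 3, 1;
zero-padded to preserve length) map the K × 37 features to K × 2 outputs.
The reference configuration uses 1024 kernels per hidden layer; the width is
config-exposed and the CPU-scale experiments in this package use 32.
Because a dihedral is periodic, the network regresses $(\sin\lambda,
\cos\lambda)$ under a masked mean-squared-error loss and the angle is
recovered with a quadrant-aware arctangent, which is invariant to positive
rescaling of the pair, so no output normalization is needed.

Implementation choices fixed here: ReLU hidden
activations with a linear head; He-style initialization; Adam at learning
rate $10^{-3}$; one chain per optimization step (the natural batch for
variable-length chains); a 10 % chain-level validation split with early
stopping; forward/backward passes implemented directly in R via im2col and
BLAS matrix products. Training is bitwise reproducible for a fixed seed.

## Synthetic data

All tests run without downloads on generated structures whose ground truth
is exact by construction:

* `make_ideal_helix()` / `make_ideal_sheet()` build regular geometries from
  constants frozen out of backbones constructed with standard dihedrals
  (helix $\phi=-57^\circ$, $\psi=-47^\circ$, giving $\lambda = -1.9045$ rad;
  antiparallel strand $\phi=-119^\circ$, $\psi=113^\circ$, $\lambda =
  -1.5791$ rad; see `data-raw/derive_constants.R`).
* `make_synthetic_chain()` draws a hidden three-state Markov chain — helix,
  extended, and a short-lived left-handed (alpha-L-like) state at the
  mirrored $\lambda = +1.9045$ rad — and samples both the CA pseudo-geometry
  and the plate $\lambda$ from state-conditional distributions (spreads
  0.08, 0.35 and 0.25 rad). The states' stationary shares (roughly 50/45/5)
  and the resulting bimodal $\lambda$ histogram, with modes near $-1.8$ and
  $+1.9$ rad, mirror what the same extraction measures on experimental
  X-ray structures (lysozyme: helix $\lambda = -1.82 \pm 0.13$ rad, plus a
  minor mode near $+1.8$). Mean run lengths (8 residues helix, 6 extended)
  and a 1 % cis rate are realistic defaults. Chains with any non-bonded CA
  pair closer than 3 Å are resampled.

What the generator does *not* emulate: real side-chain packing, the exact
deterministic coupling between trace geometry and $\lambda$ (here they are
conditionally independent given the hidden state, so the state-conditional
spread is an irreducible error floor), amino-acid composition statistics,
and long-range contact order. Passing the learnability tests therefore
shows the pipeline and optimizer work end to end, not that the small test
network matches full-scale accuracy on real proteins — the latter needs
the full-width network and a PISCES-scale training set.

## Evaluation

Reconstruction error is the coordinate RMSD over atoms matched by residue
and atom name, with no superposition: reconstruction reuses the input CA
coordinates, so the frames coincide (a Kabsch option exists for comparison
studies). Reports split the per-atom displacement distribution by atom
type and by secondary structure; the mode is estimated as the midpoint of
the peak bin of a 0.003 Å histogram. Multi-chain summaries are
chain-weighted. $\lambda$ prediction error is $|\mathrm{wrap}(\Delta)|
\in [0, \pi]$.

Because the carbonyl O sits farthest from the rotation axis (off-axis
distances: O 1.75 Å, C 0.53 Å, N 0.38 Å in the trans template), angular
error in $\lambda$ maps to Cartesian error in the order O > C ≥ N — the
package asserts this ordering under $\sigma = 0.14$ rad angular noise.

On experimental X-ray structures shipped with bio3d, rebuilding from
*extracted* (true) $\lambda$ leaves only the ideal-geometry error:
crmsd 0.065 Å (lysozyme 1HEL) and 0.053 Å (1DPX), the same order as
reconstruction with ideal plates can ever achieve and consistent with the
known split between angle-prediction error and geometry error.

## Quality filters

Training chains must have every backbone atom present, no chain break
(consecutive CA–CA outside [2.6, 4.3] Å — the lower bound admits cis
bonds, the upper rejects gaps), no alternate locations, at least 6 residues
(the feature window needs offsets to ±5), and backbone bond lengths within
±0.2 Å of ideal. The break window and the bond-length screen are this
package's operationalization of removing "incomplete or incorrect"
chains; files with alternate locations are parsed by keeping the
highest-occupancy conformer and flagging the chain so dataset builders can
drop it. Insertion codes count as distinct residues in file order; only
the first model of multi-model files is read.

## Numerical notes and limitations

* Problem sizes in the tests (chains of 10–60 residues, 220 training
  chains, 32-kernel network) were chosen so the whole suite runs on a
  single CPU in well under an hour; they are stated here as the package's
  own experimental conditions.
* Undefined $\lambda$ entries (termini, masked plates) are filled by
  copying the nearest defined plate before reconstruction.
* Degenerate geometry (reference CA collinear with the virtual bond,
  coincident anchors) raises an error in placement and yields an undefined
  mask entry in extraction.
* The torsion routine returns angles in $[-\pi, \pi)$; dihedrals are
  invariant under end-for-end point reversal and flip sign under
  mirroring.
* The stereochemistry of the rebuilt N–CA bond is only as good as the
  CA–CA spacing of the input trace (see the template-anchoring decision
  above); with ideal spacing it is exact.
* No energy minimization, no side chains, no amide H by default (a
  template with H exists), no OXT.
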