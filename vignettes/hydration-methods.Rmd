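---
title: "Predicting binding-site hydration thermodynamics from static structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting binding-site hydration thermodynamics from static structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Water molecules in protein binding sites are not passive filler: their
occupancy pattern and the free-energy cost of displacing them are major
contributors to ligand binding.  The reference way to obtain this
information is explicit-solvent molecular dynamics followed by
hydration-site analysis, which yields, on a 3D grid over the binding site,
a time-averaged water *occupancy* (≈ 0.02 in bulk solvent, rising to
0.045–0.07 in hydration-site cores, zero inside protein atoms) and a
*desolvation free energy* ΔG per grid point (positive where displacing
water is favourable for a ligand).  That calculation takes hours to days
per structure.  `hydronet` implements learned surrogates that produce both
grids directly from a static, protonated structure, plus the
post-processing a medicinal chemist needs: hydration-site extraction,
comparison with crystallographic waters, and desolvation scoring of ligand
series.

## Input featurization

**Structure model.**  PDB input is reduced to protein ATOM records
(waters, ions and heteroatoms removed, alternate locations restricted to
A).  Each atom is assigned a partial charge, vdW radius σᵢ and well depth
εᵢ from a packaged Amber-type parameter table: generic backbone charges,
residue-specific polar side-chain charges, element-based radii/depths, and
an element fallback for anything unlisted.  The table is a documented
approximation bundled with the package, not a force-field export — the
networks only need a physically sensible, *consistent* parameterization.
Hydrogen-bond donors and acceptors come from a fixed residue template
(e.g. serine OG is both), and a donor keeps its flag only if it has a
bonded hydrogen.  Covalent bonds are inferred when two atoms lie within
the sum of their covalent radii plus 0.45 Å; a cutoff of the form
0.6·(rᵢ+rⱼ)+0.6 Å was considered and rejected because it sits at 1.51 Å
for C–C and misses real 1.53 Å bonds.

**Interaction fields.**  Five physics-based fields are evaluated at grid
points r_k for a water-like probe (σ_p = 1.6 Å, ε_p = 0.012 kcal/mol):

* electrostatics Σᵢ Qᵢ/|Rᵢ−r_k| (distances clamped at 0.5 Å to avoid the
  singularity);
* soft van der Waals Σᵢ √(εᵢε_p)((σᵢp/d)⁴ − (σᵢp/d)²), σᵢp = σᵢ+σ_p, which
  vanishes at d = σᵢp and has its minimum −√(εᵢε_p)/4 at d = σᵢp√2;
* a hydrophobic contact cubic in s = 2(d − σᵢp − 2)/3 over apolar atoms
  (carbons, sulfurs and their hydrogens — configurable);
* hydrogen-bond acceptor strength Σ exp(−(d − R⁰)²), R⁰ = 1.94 Å;
* a directional donor term −exp(−(d − R⁰)²)·cos α, active only when
  cos α < 0, where α is the angle at the donor hydrogen between the
  donor→H and H→point directions.  The convention is fixed so that a
  linear D–H···point arrangement gives cos α = −1: it is the only reading
  under which the sign test rewards ideal geometry, making the field +1 at
  a perfect hydrogen-bond position.

Fields are squashed with tanh to [0,1] (electrostatics to [−1,1]; the
attractive part of the vdW term is clipped at zero first, so that channel
measures steric conflict only).

**Probe channels for the segmentation network.**  Twelve probes spanning
water-like, charged, hydrogen-bonding, hydrophobic and halogen-like
characters (a packaged table of per-probe σ_p, ε_p, charge and field
weights) each produce one input channel: the weighted field sum clipped at
±20 kcal/mol and scaled linearly to [−1,1].  The probe names follow common
MIF naming purely for reporting; a correlation-based selector
(`select_probes`, k-medoids under the distance 1 − Pearson r) is provided
for reducing larger custom libraries, with k-medoids chosen over k-means
because medoids keep representatives interpretable and the procedure
deterministic for a fixed input order.

**Point descriptors.**  The classification descriptor concatenates four
25-bin blocks (all atoms, donors, acceptors, flexibility).  Distances are
surface-corrected (r̃ = d − σᵢ, kept up to 6 Å), accumulated into Gaussian
bins of width 7/25 Å, and each bin is squashed as tanh(·/5); the squash is
applied after accumulation, matching the reading that the bins first
collect per-atom Gaussians and are "finally scaled".  The flexibility
block weights side-chain atoms by fᵢ = 2·tanh(tᵢ/4), where tᵢ is the
bond-count distance to the residue Cα (backbone rigid), and subtracts the
weighted accumulation from the unweighted one *before* the squash, so
entries lie in (−1, 1) and an environment of highly flexible atoms flips
the sign of its bins.  The donor/acceptor blocks use the same tanh(·/5)
divisor as the all-atom block; nothing suggests a different constant.

The regression descriptor adds the environment: around each point, seven
shells ([0,1], [0.5,1.5], …, [3,4] Å, widened by ε = 0.01 Å) collect
neighbouring lattice nodes; each field's values on a shell are expanded in
real orthonormal spherical harmonics by quadrature
a_lm = (4π/N)·Σ E·Y_lm, and the degree norms ã_l = ‖a_l‖₂ are kept.  The
L2 norm is used because the coefficients of degree l transform among
themselves by an orthogonal (Wigner) matrix under rotation, making ã_l
exactly rotation invariant — an L1 sum of |a_lm| is not, and descriptor
invariance under pose is the entire point of the construction.  Each
tanh(ã_l) is Gaussian-binned into 5 bins.  The final descriptor is the
100-entry direct block (5 fields × 20 bins) followed by the environment
block ordered degree-major (all l = 0 entries, then all l = 1): with this
ordering, raising `l_max` strictly appends entries without renumbering
existing ones, so descriptors of different depths remain
prefix-compatible.  Default `l_max = 1`; on the synthetic corpus the step
from l = 0 to l = 1 changes held-out correlation only marginally, matching
the saturation seen when the descriptor family was introduced.
Quadrature (rather than least squares) keeps the expansion deterministic
on the few, non-uniform nodes of a lattice shell; degrees with fewer
samples than coefficients are zeroed with a warning.

## Networks and training

**Segmentation.**  Occupancy grids become six cumulative binary labels
(occupancy > τ for τ = 0, 0.02, 0.03, 0.045, 0.06, 0.07).  Two U-Net
variants operate on the probe channels: a baseline (stride-2 kernel-2
down-sampling convolutions; default filter plan 32, 64, 128, 256, 512, 512
and mirrored decoder) and an Inception+Residual variant (each stage an
Inception block with parallel effective kernels 1/3/5, skip connections
passed through a residual block).  The kernel-5 branch is factorized into
two stacked kernel-3 convolutions — the same receptive field at a quarter
of the im2col traffic.  Every block is followed by per-channel
normalization over the sample's voxels, leaky-ReLU (slope 0.1) and
dropout.  The normalization layer is essential, not cosmetic: without it,
Adam updates compound multiplicatively through the depth, activations
explode within tens of steps, the sigmoids saturate and all gradients
vanish.  Leaky activations are used in both variants for the same reason
at this data scale — hard ReLUs die irreversibly.  The final layer is a
kernel-1 convolution to six channels with *sigmoid* (not softmax) output:
the labels are cumulative, so the channels are six correlated binary
problems rather than one exclusive classification; label monotonicity is
checked on predictions and reported, never silently enforced.  The final
bias starts at the logit of each class's training frequency.

Training minimizes the generalized Dice loss with class weights
w_l = 1/((Σ r)²+1).  Two numerical amendments matter at desk scale:
classes entirely absent from a reference (toy pockets rarely exceed
occupancy 0.06) are dropped from the loss — the +1 guard alone hands an
empty class a weight of 1 against ~10⁻⁸ for populated ones, freezing
training — and the weights are normalized to sum to one, which leaves the
loss value mathematically unchanged while keeping gradient magnitudes
independent of class populations.  Augmentation applies one of the 24
axis-aligned proper rotations jointly to channels and labels (lattice
exactness; arbitrary-angle rotations would resample the grid).  A
configurable boundary margin (default 4 nodes) is masked at evaluation,
since voxels near the box face lack spatial context.  Optimization is
Adam; all gradients — convolutions (im2col/col2im in RcppArmadillo),
normalization, inception routing, skip concatenations — are hand-written
and verified against numerical differentiation in the test suite.

**Point-wise networks.**  The classifier (hidden 1024/512, leaky-ReLU,
dropout 0.5, sigmoid, binary cross-entropy) separates occupied
(occupancy > 10⁻⁵) from dry points on the 100-dim classification
descriptor.  The regressor (hidden 2048/1024, two linear outputs) predicts
(occupancy, ΔG) for occupied points from the full descriptor; targets are
standardized per output during training because occupancy (~0.02–0.08)
and ΔG (−3 to +8 kcal/mol) differ by two orders of magnitude and an
unweighted MSE would otherwise ignore occupancy entirely.  Desk-scale
runs use reduced hidden sizes (256/128) and epochs; the architecture
constants remain the defaults.

## Synthetic study conditions

The generator emulates the statistical signatures of MD-derived hydration
grids without claiming physical realism.  A toy "protein" is a two-shell
Fibonacci arrangement of parameterized pseudo-atoms around an empty pocket
(wall at pocket radius + 1.7 Å, backing layer 2.2 Å further, minimum
separation 2 Å, seeded rotation/jitter), its wall lined with donor
nitrogens (explicit inward hydrogen), acceptor oxygens and ±0.8 e charged
atoms; a carbon pseudo-ligand marks the pocket center.  The oracle
occupancy is 0 inside atoms, bulk (0.02) in open space, and enhanced where
a soft-thresholded combination of the hydrogen-bond and electrostatic
fields is favourable; the enhancement is smoothed with a 0.6 Å-σ Gaussian
(≈1.4 Å full width) before seeded noise (σ = 0.0015) is added.  The
smoothing stands in for water–water network coupling: it makes a point's
occupancy depend on its *neighbourhood's* fields, which is precisely the
information the environment descriptors capture and the direct block
cannot — the mechanism the point-wise architecture exists to exploit.
ΔG = 2.5 − 3.8·log(occ/0.02) + noise, clamped to [−3, 8] kcal/mol: a
monotone decreasing map whose constants were fixed once so that the
strongest cores sit near −3 and sterically excluded or strongly sub-bulk
regions near +8, matching the isolevel ranges used for display and SAR
work on real systems.  Under these conditions the grids reproduce the
target statistics: ≥ 90 % of voxels below occupancy 0.03 (the class
imbalance that motivates the GDL) and pocket maxima in the 0.045–0.07
hydration-site band.

What passing tests on this corpus demonstrate: that the implementation
learns the intended mapping when the signal is present, that environment
descriptors add real information over point fields, and that every
pipeline stage composes.  What they cannot demonstrate: accuracy on real
proteins — toy pockets have no backbone topology, no conformational
strain, idealized charge patterns, and an oracle far smoother than MD
water statistics.

## Problem sizes and reference results

The shipped studies use sizes chosen to exercise the full pipeline on a
single CPU core in minutes: the point-wise study trains on 30 of 40
pockets (150 points each, 6 000 descriptors) and evaluates on the held-out
10; the segmentation study trains the Inception+Residual variant (filters
8/16/24) on 20 pockets at 24³ voxels for 22 epochs and evaluates on 4
held-out pockets within 5 Å of the pseudo-ligand.  Under these conditions
the held-out point-wise correlation for occupancy is ≈ 0.97 with full
descriptors against ≈ 0.76 with the direct block only — the qualitative
analogue of the published direct-vs-environment gap — and the held-out
masked Dice at the bulk threshold is ≈ 0.8.  `scripts/acceptance.R`
recomputes all of these from scratch for any seed.

## Numerical choices and degenerate inputs

* Grid convention: isotropic, axis-aligned lattices; origin at the minimum
  corner; node = origin + index·spacing; x varies fastest.  OpenDX is the
  interchange format (z-fastest on disk, converted on read/write);
  non-isotropic or sheared DX files are rejected rather than resampled.
* Default spacing 0.5 Å; segmentation boxes pad their node count to a
  multiple of 2^(encoder stages − 1).
* Distance clamp 0.5 Å in 1/d terms; shell membership ε = 0.01 Å;
  Dice smoothing constant ε_s = 1; GDL guard +1 (amended as above).
* QT clustering breaks ties by summed occupancy then lowest node index,
  making site extraction deterministic and enumeration-order invariant;
  the printed protocol's parameters (diameter 1.9 Å, ≥ 5 points) are
  asserted exactly in the tests.  The density-based alternative is an
  occupancy-weighted DBSCAN (a core point needs bulk-equivalent
  neighbourhood weight ≥ min_samples); it is a documented variant, not a
  reproduction of any specific published pseudo-code.
* Degenerate inputs fail loudly: empty structures, single-class training
  labels, all-zero label grids, all-outside ligands and zero-variance
  scores raise errors; empty shells, donors without hydrogens and empty
  ligand masks warn and continue.

## Known limitations

Histidine tautomers and terminal residues are parameterized by the
template's single convention (HIE-like histidine; OXT acceptor), not
predicted.  The convolution engine trades memory for BLAS speed
(im2col) and is sized for ≤ 48³ grids on a desktop.  Training at the
published scale (thousands of structures, 100+ epochs, full filter plans)
is out of desk-scale reach; the defaults encode the published
architecture, the tests encode reduced, seeded study conditions.  The
X-ray comparison utilities implement the retention (within 5 Å of ligand
and protein) and distance-binning protocol but ship no crystallographic
data.
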