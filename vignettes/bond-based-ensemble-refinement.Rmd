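---
title: "Bond-based ensemble parametrization and torsion-space refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bond-based ensemble parametrization and torsion-space refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bondflex)
```

## The model

Conventional macromolecular refinement treats every atom as an
independent position plus a B factor: at least four parameters per atom,
restrained by prior chemical knowledge.  `bondflex` instead expresses a
protein chain as a *tree of bonds* rooted at a single **anchor atom**
(by default the backbone N of the residue closest to the chain's centre
of mass).  Bond lengths and bond angles are held at canonical values;
the refinable parameters are

* the mean torsion angle of every rotatable bond (backbone phi/psi and
  side-chain chi angles; the peptide bond omega and ring torsions are
  fixed),
* a *kick* per rotatable bond and a reverse kick per C-alpha
  (dimensionless magnitudes of per-conformer torsion deviation),
* bond angles at C-beta and aromatic C-gamma atoms only,
* two axis-tilt angles (alpha, beta) per side-chain bond, and
* whole-molecule motions: a symmetric translation tensor **T** (6
  parameters) and screw motions (5 parameters each, 3 screws by
  default), plus the cloud radius omega per chain.

On a 50-residue mixed-sequence chain this inventory is roughly 60%
smaller than atomistic counting (`count_refinable_parameters()`).

Flexibility is represented *explicitly* rather than by Gaussian B
factors: the anchor atom carries a cloud of J atom points (default 120)
arranged on ten concentric shells of outer radius omega (initially
0.356 Å), each shell populated proportionally to its surface area on a
golden-angle Fibonacci lattice.  Every other atom-point cloud is placed
recursively from the previous three clouds through the bond internal
coordinates (natural-extension placement, exact to machine precision).
With no flexibility this *flexless structure* is a rigid duplication of
the anchor cloud at every atom average position; the J-th point of every
cloud, linked together, is one deterministic conformer.  Sampling
density J changes only how finely the distribution is sampled — never
the parameter count.

Whole-molecule motions act on the anchor cloud alone: **T** maps each
point displacement through `U W^(1/2) U'` of its eigendecomposition (so
**T** acts as a covariance), then each screw rotates the per-conformer
frame by the angle `d_j = delta_j . r` about the axis of `r` and adds a
translation `d_j S w` perpendicular to the displacement.  Kicks add
per-conformer torsion deviations `k * s_j` (radians), where `s_j` is the
dot product between the unit point displacement and the (optionally
alpha/beta-tilted) normal of the local bond plane, computed once from
the flexless structure.  Reverse kicks rotate the anchor seed about the
flexless C-alpha bond with a cancelling torsion correction, so
flexibility propagates toward the anchor side only; the cancellation is
exact to < 1e-8 Å and both kick directions preserve every bond length
and angle to < 1e-9.

## Density, solvent and structure factors

Atom points deposit unit weight over the eight surrounding voxel corners
(opposite-fractional-volume weights), which conserves the deposited
density exactly; per-element maps are multiplied by the element's
four-Gaussian reciprocal form factor and summed.  The voxel rule is
d/4, capped at 0.8 Å.  HETATM records keep their own isotropic B-factor
Gaussians, added analytically in reciprocal space, and are never
remodelled.

Numerical choices made here, where the published description leaves the
mechanism open, and their rationale:

* **Deposition deconvolution.**  Trilinear deposition convolves the
  density with a triangle kernel.  The structure-factor path deposits on
  an internally 2x-oversampled grid, divides by the kernel's transform
  `sinc^2` in reciprocal space, and band-limits back to the d/4 grid.
  This brings amplitude agreement with a direct structure-factor
  summation on point-atom toys above 0.999 (the uncorrected two-grid
  remap saturates near 0.997).
* **Direct cell-grid rasterization.**  For F_calc the asymmetric unit is
  deposited directly in cell-fractional coordinates, making the
  remapping an exact index wrap.  The cubic-segment machinery plus
  mass-conserving push remap remains available for real-space segment
  work and is tested against the same contracts.
* **Interpolation.**  Wherever a grid is interpolated the package uses
  trilinear weights with reciprocal-space kernel compensation rather
  than a bespoke higher-order stencil; the conservation and oracle
  contracts, not the stencil identity, are what the tests assert.

The bulk solvent is a multi-conformer flat mask: each conformer's non-H
atom points mask voxels within per-element radii (Jiang & Bruenger-type
values), the mask is shrunk by switching model voxels within 0.4 Å of
solvent to solvent, internal solvent strips shorter than 2.0 Å along
every crystallographic axis are filled, and the J binary masks —
carried bit-packed, 16 per 32-bit word — are averaged.  Space-group
symmetry is applied by adding symmetry-transformed complex coefficients
in reciprocal space (operators for P 1, P 21, P 21 21 21 are built in).
`F_calc = F_explicit + k exp(-B/(4 d^2)) F_solvent`, with (k, B) fitted
by 100 simplex cycles from start values (0, 40 Å²) and steps (0.4,
40 Å²), then amplitude-matched to F_obs in 20 equal-volume resolution
bins.

## Phase-spread weighted maps

Downweighting a noisy amplitude is treated as phase uncertainty: each
reflection gets `d_k = exp(-(sigmaF/F)^2)`, converted through a lookup
table into an equivalent Gaussian phase spread sigma_phi, and the
2Fo-Fc synthesis sums 25 phase-shifted transforms spanning +-2
sigma_phi at normalized Gaussian weights (free reflections are omitted;
with all sigma_phi = 0 the result is exactly the plain map).

The tabulated relation is the centroid radius of the unit circle
weighted by `exp(-phi^2 / (2 sigma^2))`.  The angular range of this
weighted arc is not fully determined by the published description; we
scanned the candidate conventions (full circle, +-sigma, +-2 sigma,
+-2 pi, and discrete 25-step variants) and adopted the **full circle**
(`phi` in `[-pi, pi]`, fine numerical integration): it is the only
candidate that is strictly monotone over the tabulated range and
matches the natural reading of "the radial point at each phase angle".
Its endpoint is d(6.27) = 0.0250, which does not reproduce the
published endpoint of 0.0308 (that value would correspond to a spread
of 5.67 rad under this convention); none of the scanned conventions
reproduces it.  The discrepancy is documented here and the package
reports its own computed value.

## The refinement engine

All four modes minimize with Nelder-Mead simplex descent
(`simplex_minimize()`, initial simplex from per-parameter step sizes,
standard coefficients).

* **Mode 1** fits torsions to the *original positions*: windows of four
  sequential backbone torsions (max 60 steps, convergence 0.005 deg),
  advancing one bond at a time from the anchor to the N terminus and
  then to the C terminus, side chains after their supporting backbone;
  five passes (two torsion-only at 2 deg steps, three adding
  C-beta/aromatic C-gamma bond angles at 0.2 deg).
* **Mode 2a** refines whole-molecule motions against the weighted map
  using a Pearson-weighted correlation over the backbone + C-beta
  density (weights: the active-atom density itself).  New screws scan 31
  Fibonacci directions before continuous refinement; the first
  macrocycle ends with three screws; **T** is refined through a
  Cholesky-like factor so candidates stay positive semi-definite.
* **Mode 2b** groups backbone bonds by the similarity of their rotation
  effects on every C-alpha atom point (cosine times smaller magnitude
  ratio times both s factors, summed; antisymmetrized; SVD).  The top
  ten singular vectors, or as many as cover 50% of the singular-value
  sum, become clusters, each refining independent k and k' multipliers
  (at least 20 parameters).
* **Mode 3** refines each side chain against the monomer segment
  (torsions and refinable angles at 0.1 deg steps, kicks at 0.5,
  alpha/beta at 30 deg).

The protocol applies the acceptance rules: any whole-molecule stage that
raises R_work is reverted; after three rising intramolecular cycles
omega contracts by 10% for as long as R_work keeps falling
(`contract_omega()`); before mode 3 the state reverts to the best cycle,
and a mode 3 that raises R_work is reverted too.  R_free is reported
every cycle and never drives a decision.

For the correlation targets the active-atom structure factors are
evaluated by exact direct summation over the data's Miller indices and
synthesized on the unit-cell grid restricted to exactly those
coefficients, so the compared densities carry identical Fourier content.
This removes a smoothing bias: with gridded approximate densities the
correlation optimum rewards inflating the translation tensor to mimic
interpolation blur.

## The synthetic generators, and what passing tests show

`make_ideal_peptide()` builds ideal-geometry chains (helix -57/-47,
strand -120/+120, loop -70/+150, omega 180, extended side chains) with a
full truth record; `make_two_domain_toy()` joins two helices by a loop
linker; `simulate_reflections()` computes structure factors from the
model's own ensemble, applies multiplicative Gaussian amplitude noise
(`sigmaF = noise * |F|`, default 2%, the scale of good diffraction
data), and assigns a seeded free set (5%).  Default toy cells are P1
boxes of 20-30 Å; a P 21 variant exercises the symmetry code.  The
planted whole-molecule tensor used in recovery experiments,
diag(9, 4, 2), corresponds to translational B contributions of roughly
6/2.7/1.3 Å² — the realistic scale for lattice disorder.  All
randomness flows from one seed.

These fixtures emulate idealized crystals: exact ensemble-generated
amplitudes plus uncorrelated Gaussian noise, no lattice-packing
contacts, no measurement-dependent sigmas, no alternate conformations,
no model incompleteness.  Passing the recovery tests therefore shows
the machinery is self-consistent and identifiable at fixture scale; it
does not show that real crystals are described this well, where the
published benchmark behaviour (R factors a few percent above atomistic
refinement but with a smaller work/free gap) is the relevant evidence.

Problem sizes used by the test-suite are deliberately small — 5-20
residue chains, J of 8-24, 1.8-3 Å data in 20-26 Å cells — which keeps
every property at the same mathematical contracts while the suite runs
in minutes.

## Known limitations

* One polypeptide chain per bond graph; disulfides and other cross-links
  are not bonded (the tree keeps the recursion well defined); nucleic
  acids and ligand bond models are out of scope (HETATM atoms stay
  atomistic).
* The built-in space-group table covers the primitive groups the
  fixtures use; other symbols are an error.
* Reflections travel as plain text (h k l F SIGF FREE); binary MTZ is
  not parsed.
* Chirality is enforced through template branch offsets; there is no
  explicit chiral-volume check.
* The anchor cloud is generated in the anchor frame, so the whole
  construction is equivariant under rigid motions of the input; the
  translation tensor and alpha/beta angles are expressed in global
  axes, as whole-molecule parameters should be.
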