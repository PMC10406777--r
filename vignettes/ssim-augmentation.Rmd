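---
title: "Shape and intensity model based augmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape and intensity model based augmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ssimaug` generates synthetic training images for segmentation models by
sampling a statistical shape and intensity model (SSIM) of a segmented
structure and compositing each sampled instance into a real training image.
This vignette documents the method, its assumptions, the tunable
parameters, and the design decisions taken where more than one faithful
implementation was possible.

## Pipeline overview

Given training samples — each a volume, a binary mask of one structure and
a corresponded tetrahedral mesh of that structure — one augmented image is
produced by:

1. constrained random sampling of a mesh-plus-intensities instance from the
   SSIM;
2. selection of the closest training image by an affine-registration
   distance between corresponded meshes;
3. "cleaning" of the structure out of the closest image by mirrored
   exterior intensities;
4. thin-plate-spline (TPS) warping of the cleaned image with painting of
   the instance's encoded intensities, followed by rigid realignment.

`generate_augmented_set()` orchestrates all four; every stage is exported
and individually testable.

## Shape model

Corresponded vertex sets are aligned by generalized Procrustes analysis
with rotation and translation only — no scaling, so size variation remains
part of the learned shape statistics, and reflections are excluded by
forcing determinant +1 in every Kabsch solve. The mean is re-estimated
until it moves less than 1e-7 mm RMS (at most 100 rounds). PCA of the
flattened aligned coordinates uses the eigendecomposition of the n-by-n
Gram matrix of the centered data, numerically equivalent to an SVD, with
eigenvalue = squared singular value / (n − 1); this fixes the scale of the
`λ_i` used by every sampling bound. The retained mode count `k` is the
smallest whose cumulative eigenvalue sum reaches the configured variance
fraction (default 0.95), and never exceeds n − 1.

## Intensity encoding

Within one tetrahedron the intensity is the barycentric Bernstein density

$$D(p) = \sum_{i+j+k+l=d} C_{ijkl}\, B^d_{ijkl}(p), \qquad
B^d_{ijkl}(p) = \tfrac{d!}{i!j!k!l!} p_x^i p_y^j p_z^k p_w^l,$$

with $m = \binom{d+3}{3}$ coefficients per tet (20 at the default d = 3).
Coefficients are stored in a frozen lexicographically descending
multi-index order; model containers depend on it.

Fitting is an independent per-tetrahedron least squares over the voxel
centers located inside that tet — no continuity constraints across faces,
which is the simplest faithful reading of a per-tet density model;
inter-tet discontinuities are accepted and in practice small. Membership
is by voxel center only (no partial-volume weighting), matching the
rasterization convention used everywhere else. Two documented fallbacks
handle thin geometry:

- *under-determined tets* (fewer interior voxel centers than m, or a
  rank-deficient design): ridge-regularized solve with penalty
  `1e-6 · trace(XᵀX)/m`;
- *empty tets* (no interior voxel center): constant coefficients equal to
  the mean of the image sampled trilinearly at the four vertices.

Both are counted in a single warning. Because fields that are global
polynomials of total degree ≤ d restrict to degree-≤ d barycentric
polynomials on every tet, well-populated fits reproduce such fields exactly
at the sampled voxel centers (the suite checks ≤ 1e-6 relative).
Intensities are encoded in native units; no rescaling is applied.

The encoding error metric is the mean over interior voxels of
`|I − D| / max(|I|, ε) · 100` with ε = 1 intensity unit; the floor makes
the "relative" error well-defined at near-zero intensities and is a
package decision.

## Constrained sampling

Mode weights are drawn independently as `b_i ~ N(0, λ_i)`, then clipped to
`[−2.5√λ_i, 2.5√λ_i]`, then — in that order — rescaled by
`√(M / Σ b_i²/λ_i)` whenever the Mahalanobis bound `Σ b_i²/λ_i ≤ M` is
violated. `M` defaults to the 0.95 quantile of the chi-squared distribution
with `k` degrees of freedom (`chi2_quantile` is configurable, as is
`clip_sigma`). Shape and intensity parameters are sampled independently:
the two PCAs are separate models with separate mode counts, and
independence is the simplest consistent way to unify them; a joint
shape-intensity PCA is deliberately out of scope. Sampled meshes with any
non-positive tet volume are rejected and redrawn (at most 100 attempts);
geometric validity is the testable proxy for "no extreme instances", and
at the packaged phantom amplitudes no rejection is ever observed.

## Creating the augmented image

**Closest image.** Each candidate's mesh is affine-registered (12-parameter
least squares) to the instance mesh and scored by the RMS corresponded
vertex distance; the argmin wins, ties to the lowest index. RMS after
affine is scale-free enough for ranking and is documented as the package's
distance; during set generation the score of candidate j is multiplied by
`1 + balance_strength · usage_j` (default 0.2), which de-prioritizes
heavily used patients without enforcing exact balance; 0 recovers the pure
criterion.

**Cleaning.** A signed Euclidean distance map of the mask gives every
interior voxel v its closest boundary point w; v's intensity is replaced by
the trilinear sample at the mirror point `v + 2(w − v)`. The distance
transform is the exact separable lower-envelope algorithm with feature
tracking, correct under anisotropic spacing; the boundary is discretized as
opposite-class voxel centers (an interior voxel's w is the nearest exterior
voxel center), which matches the brute-force oracle the tests use. If the
mirror point falls outside the image or back inside the mask, the mirror
factor steps down through 2, 1.5, 1.25, 1.125, 1.0625 before falling back
to the value at w itself — deterministic, local, and hole-free. Exterior
voxels are returned bit-identical.

**Warping and painting.** A TPS is fitted from farthest-point-sampled
surface landmarks of the instance mesh (default `min(300, surface count)`,
deterministic start at the lowest-index surface vertex) to the
corresponding vertices of the closest sample's mesh. The 3D biharmonic
kernel `U(r) = r` is used — the correct 3D analogue of the planar
`r² log r`. The system is solved in centered unit-scale coordinates (an
exact reparameterization, since the kernel is scale-equivariant) with one
step of iterative refinement; at λ = 0 landmarks interpolate to ≤ 1e-6 mm
and affine target configurations yield zero warping energy. Each output
voxel center is mapped through the TPS and the cleaned image sampled
trilinearly; out-of-field voxels receive the cleaned image's minimum
intensity (CT-air-like padding without hardcoding a value). Voxels inside
the instance mesh are then hard-overwritten with the instance density —
no boundary feathering, keeping mask and intensities exactly consistent.
The output grid is the closest image's grid: composing the resampling with
the final rigid realignment, a single interpolation target avoids a second
resampling pass.

**Rigid realignment.** A corresponded rigid fit from the instance mesh to
the closest sample's mesh removes the bulk motion the TPS may introduce.
The image is pulled back trilinearly; the output mask is re-rasterized from
the rigidly moved mesh rather than resampled, so the invariant
*mask = rasterization of the carried mesh* holds exactly for every
augmented sample (nearest-neighbour mask resampling agrees with it to
Dice ≥ 0.98, which the suite also checks).

## The phantom generator

`phantom_spec()`/`generate_population()` emulate the statistical structure
the method assumes, with known ground truth: a reference ellipsoid tet mesh
(a spherified-cube tet grid, so surface vertices lie exactly on the
analytic ellipsoid), deformed per sample by a known linear combination of
smooth displacement fields (latent shape modes, truncated-normal weights)
plus a small random rigid pose; interior intensities follow a low-order
polynomial field evaluated at corresponded reference positions — so
intensity latents are exactly linear in the stored ground truth — plus an
optional bright "cortical" shell; the background is a smooth ramp; Gaussian
noise is added everywhere. Defaults: 64³ voxels at 1.5 mm, semi-axes
(30, 22, 18) mm, 2 shape modes of RMS amplitude (3, 2.5) mm, 2 intensity
modes of amplitude (60, 40) units, noise σ = 16 (about 2% of the ~800-unit
dynamic range). `worked_example()` is the frozen fixture: seed 0, 8
samples, 2 + 2 latent modes, 32³ by default with a `size` argument that
scales the ellipsoid and mesh resolution.

What the phantoms deliberately do **not** emulate: CT physics (beam
hardening, metal artifacts), multi-structure anatomy (one structure per
image; multiple structures are independent runs), non-identity acquisition
orientations, and non-smooth pathology. Passing tests therefore demonstrate
correctness of the statistical and geometric machinery under the model's
own assumptions — not clinical segmentation performance, which requires
training on real data and is outside this package.

Two phantom regimes matter for tests. Latent *shape* recovery is clean at
any resolution (vertices carry no noise). Latent *intensity* recovery via
fitted coefficients requires well-populated tets: on under-determined tets
the ridge fallback's minimum-norm completion varies with the voxel sample
set and raises the effective noise floor, and the non-polynomial shell
contributes a shape-dependent fit residual. The recovery tests therefore
use a shell-free, noise-free population at 48³ with a coarse mesh
(divisions 2), where coefficients are exactly linear in the latents; this
is the "amplitude well above the noise floor" regime the recovery property
presumes.

## Numerical conventions

- Identity orientation only; world = `origin + index · spacing` with
  0-based indices at voxel centers. Files with other direction matrices are
  rejected loudly rather than silently reinterpreted.
- Point-in-tet containment tolerance: barycentric components ≥ −1e-9;
  points on shared faces resolve to the lowest incident tet index. The
  binned spatial search is behaviorally identical to exhaustive scanning
  (tested).
- Degenerate tets (volume ≤ 1e-9 mm³) are construction errors; tets are
  reoriented to positive volume on construction.
- Trilinear sampling clamps coordinates within 1e-6 voxel of the grid
  boundary so that boundary voxel centers are in-field under identity
  transforms.
- Model containers are a single JSON file of named arrays plus a manifest
  (degree, mode counts, variance fraction, topology sizes); doubles are
  written with 17 significant digits, so round-trips are bit-exact, and
  every load cross-checks array shapes against the manifest.
- Test problem sizes are chosen so the default suite completes in well
  under a minute of compute: 32³ fixtures for module tests, 48³ for
  intensity-latent recovery, 64³ for pipeline near-identity and encoding
  fidelity checks.

## Known limitations

- Mesh correspondence quality is assumed, not established:
  `fit_reference_to_mask()` is a simplified similarity-ICP + projection +
  TPS stand-in sufficient for phantoms, not a replacement for a full
  groupwise non-rigid registration pipeline.
- General tetrahedralization of arbitrary surfaces is out of scope; the
  package builds structured tet grids and phantom meshes and reads
  externally produced VTK tet meshes.
- Per-tet independent fitting admits intensity discontinuities across tet
  faces; smoothness-constrained fitting is a possible extension.
- The balancing penalty is one multiplicative knob; it reproduces
  "balanced but not enforced" behavior but is not a claim about any
  particular empirical usage distribution.
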