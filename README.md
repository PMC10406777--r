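# ssimaug

Statistical shape and intensity model (SSIM) based augmentation of 3D
medical images.

Deep segmentation models for CT are starved for annotated training data.
`ssimaug` synthesizes new, anatomically plausible training images from a
small set of segmented volumes: it learns a statistical model of both the
*shape* of a segmented structure and the *intensities* inside it, samples
new constrained instances from that model, and paints each instance into a
real training image whose structure has first been "cleaned" away. The
package is aimed at medical-image-analysis researchers who have co-registered
volumes, masks and corresponded meshes (or want to prototype on the bundled
phantom generator, which requires no data at all).

## The model

For a training population with corresponded tetrahedral meshes:

- **Shape.** After generalized Procrustes alignment (rotation + translation
  only), the flattened vertex coordinates are modeled by PCA as a point
  distribution model: `x = x̄ + P b`, with eigenvalues `λ_i` and modes
  retained up to 95% of total variance.
- **Intensity.** Inside every tetrahedron the image is encoded as a
  degree-`d` barycentric Bernstein density

  `D(p) = Σ_{i+j+k+l=d} C_{ijkl} · B^d_{ijkl}(p)`,

  with `m = (d+3)!/(3! d!)` coefficients per tetrahedron (`m = 20` at the
  default `d = 3`), fitted per tet by least squares over interior voxel
  centers. The flattened coefficient matrices get their own PCA.
- **Constrained sampling.** Mode weights are drawn as
  `b_i ~ N(0, λ_i)`, clipped to `[−2.5√λ_i, 2.5√λ_i]`, and rescaled so that
  `Σ b_i²/λ_i ≤ M`, where `M` is a chi-squared quantile (0.95 by default)
  with `k` degrees of freedom.
- **Image creation.** Each sampled instance picks its closest training
  image (RMS vertex distance after affine registration, with an optional
  patient-balancing penalty), the structure is erased by mirroring exterior
  intensities through the closest boundary point (`v + 2(w − v)` from a
  signed Euclidean distance map), the cleaned image is warped by a
  thin-plate spline (3D kernel `U(r) = r`) fitted on farthest-point surface
  landmarks, the instance's encoded intensities are painted inside its
  mesh, and the result is rigidly realigned to the closest image.

## Worked example

Everything below runs in a few seconds on one CPU with no input data:

```r
library(ssimaug)

# 8 synthetic phantoms: 64^3 voxels at 1.5 mm, ellipsoid-like structure,
# 2 latent shape + 2 latent intensity modes, bright shell, noisy background
pop  <- worked_example(size = 64, n_samples = 8)
ssim <- build_ssim(pop$samples, d = 3, variance_fraction = 0.95)
ssim
#> <ssim_model> 125 vertices, 320 tets, degree 3; 2 shape + 7 intensity modes

# fidelity of the Bernstein intensity encoding on one phantom
s1  <- pop$samples[[1]]
enc <- fit_encoding(s1$image, s1$mesh, d = 3)
encoding_error(s1$image, enc, s1$mesh)
#> [1] 2.85

# ten augmented image/mask pairs, patient-balanced, reproducible
res <- generate_augmented_set(pop$samples, ssim, n = 10,
                              balance_strength = 0.2, seed = 7)
res$usage
#> phantom01 phantom02 phantom03 phantom04 phantom05 phantom06 phantom07 phantom08
#>         1         0         4         2         2         1         0         0
res$samples[[1]]
#> <augmented_sample> from phantom03: 64x64x64 voxels, 12686 mask voxels
```

The model reports 2 shape modes — the phantom generator really has 2 latent
shape modes, and PCA at the 95% variance rule recovers exactly that. The
encoding error of 2.85% says the 20-coefficient-per-tet cubic Bernstein
encoding reproduces each interior voxel to within a few percent despite the
added image noise. The usage histogram shows the balanced-but-not-uniform
patient selection. Each augmented sample carries provenance (source patient,
sampled mode weights, closest-image distance, seed).

A command-line interface over the same functions ships at
`inst/cli/ssimaug.R` (`make-phantoms`, `encode`, `encode-error`,
`reconstruct`, `build-model`, `sample`, `augment`), reading and writing
NIfTI/MetaImage volumes, VTK tetrahedral meshes, PLY surfaces, YAML sample
manifests and JSON model containers.

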