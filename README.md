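# FlexField

Deformation-field analysis of continuous conformational heterogeneity in
cryo-EM, for structural biologists and methods developers who need to move
flexibility information between representations: 3D Zernike polynomial
deformation fields, elastic-network normal modes, and structural-ensemble
principal components.

## What it does

A molecule's departure from a reference conformation is modelled as a
smooth displacement field expanded in a 3D Zernike basis on a support ball
of radius *R*:

    u(r) = Σ_{l,n,m} α_{l,n,m} Z_{l,n,m}(r),
    Z_{l,n,m}(r) = R_{n,l}(|r − c|/R) · y_{l,m}(θ, φ)

with Canterakis radial polynomials `R_{n,l}` and real spherical harmonics
`y_{l,m}`. The same motion sampled at P atoms can be written as a linear
combination of elastic-network normal modes `u_k` with amplitudes `g_k`.
The package provides:

- **Zernike fields** — basis construction at atoms or voxels, least-squares
  coefficient fitting, application of fields to structures (`coords + u`)
  and to density maps (mass-conserving forward-splat warping).
- **Elastic network models** — anisotropic (ANM, uniform springs, 3P × 3P
  Hessian) and Gaussian (GNM, P × P Kirchhoff) network models, mode
  slicing/extension, pseudo-inverse covariances, mean-square fluctuations
  and cross-correlations.
- **Conversion** — least-squares interconversion between Zernike
  coefficient space and mode-amplitude space: `g = argmin ‖U g − d‖²` and
  its inverse via per-component basis fits.
- **Reference reassignment** — re-express all per-particle deformation
  fields relative to a different reference conformation by field
  subtraction and re-fitting (exact coefficient difference when both
  references share a mask), without losing any particle.
- **Focused analysis** — re-fit coefficient landscapes using only points
  inside a region mask, so local motions are not drowned out by global ones.
- **Landscape toolbox** — ensemble building with iterative (Kabsch)
  superposition, PCA and projections, deformation vectors, overlap and
  cumulative-overlap analysis, per-point motion statistics, greedy
  RMSD-threshold clustering, best-view selection by projection Pearson
  correlation, PCA landscape reduction and k-means representatives.
- **Synthetic generators** — seeded toy structures, Gaussian-splat maps,
  random coefficient sets, landscape tables and mode-displaced ensembles,
  so everything runs without external data.

## Worked example

```r
library(FlexField)

# toy globular structure and a Zernike basis over it
atoms <- makeToyStructure(60, "blob", seed = 1, sigma = 8)
xyz   <- atomCoords(atoms)
ctr   <- colMeans(xyz)
rad   <- max(sqrt(rowSums(sweep(xyz, 2, ctr)^2))) * 1.2
basis <- buildBasis(xyz, ctr, rad, lMax = 4, nMax = 4)
basis
#> ZernikeBasis: 60 points, B = 35 (lMax = 4, nMax = 4), R = 28.24 A

# ANM modes and a mode-built deformation, converted to Zernike space
modes <- computeModes(anmHessian(atoms, cutoff = 20), k = 5, "ANM")
modes
#> ANM NormalModeSet: 5 modes x 60 atoms (6 zero modes excluded)
g      <- c(1.5, -0.5, 0, 0.25, 0)
coeffs <- nmaToZernike(g, modes, basis)

# ... and back: amplitudes are recovered by least squares
round(amplitudes(zernikeToNma(coeffs, basis, modes)), 3)
#> [1]  1.499 -0.499  0.001  0.249  0.000
```

The six near-zero Hessian eigenvalues (rigid-body motions of the connected
contact graph) are detected and excluded automatically. The recovered
amplitudes differ from the inputs only by the part of the mode shapes a
degree-4 basis cannot represent; with a degree-2 basis the same round trip
returns visibly distorted amplitudes (`1.026, -0.524, 0.329, ...`), which
is the expected basis-truncation effect.

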