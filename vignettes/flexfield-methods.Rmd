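---
title: "Deformation-field models and their interconversion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformation-field models and their interconversion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FlexField)
```

## The deformation-field picture

Continuous conformational heterogeneity in cryo-EM is naturally described
by a *deformation field*: a vector field $u(\mathbf r)$ assigning to every
point of a reference conformation (atom or voxel) the displacement that
carries it into another conformation. FlexField implements two standard
parametrizations of such fields and the least-squares machinery to move
between them.

**Zernike expansion.** The field is expanded in products of radial
polynomials and real spherical harmonics on a support ball of radius $R$
about a center $c$:

$$u(\mathbf r) \;=\; \sum_{l,n,m} \alpha_{l,n,m}\, Z_{l,n,m}(\mathbf r),
\qquad
Z_{l,n,m}(\mathbf r) = R_{n,l}\!\left(\frac{|\mathbf r - c|}{R}\right)
y_{l,m}(\theta, \varphi),$$

with one coefficient vector $\alpha_{l,n,m} \in \mathbb R^3$ per basis
function, stored as a $3 \times B$ array $A$ (rows $x, y, z$). The index
set contains all $(l, n, m)$ with $0 \le l \le l_\max$,
$l \le n \le n_\max$, $n - l$ even and $-l \le m \le l$, ordered by $l$,
then $n$, then $m$; the order is part of every on-disk header so files are
self-describing.

**Normal-mode expansion.** The same field sampled at $P$ atoms is
approximated by a linear combination $d = U g$ of elastic-network normal
modes, where $U$ is the $3P \times K$ mode matrix (atom-major stacking:
atom $i$ owns rows $3i-2 \ldots 3i$) and $g$ the amplitude vector.

### Conventions that matter

* **Radial polynomials** are the Canterakis 3D Zernike polynomials in
  Jacobi form, $R_{n,l}(\rho) \propto \rho^l\,
  P^{(0,\,l+1/2)}_{(n-l)/2}(2\rho^2 - 1)$, normalized so that
  $\max_{[0,1]} |R_{n,l}| = 1$. The normalization is a declared convention:
  coefficients are only ever used self-consistently inside the toolkit, and
  the max-normalization keeps all basis columns on a comparable scale.
  The Jacobi values are generated by the standard three-term recurrence.
* **Spherical harmonics** are real, orthonormal, without the
  Condon–Shortley phase, ordered $m = -l \ldots l$ with $\sin$ terms on
  negative $m$ and $\cos$ terms on positive $m$.
* **Support.** Points with $|\mathbf r - c| > R$ receive all-zero basis
  rows rather than raising an error. This matches masked-map practice,
  where a mask defines the "valid positions" and everything outside simply
  does not move.
* **Stacking order** (atom-major $xyz$) is shared by the ANM Hessian
  block layout, mode matrices and field stacking, so conversions never
  materialize a Kronecker-product matrix; tests verify the equivalence to
  the explicit Kronecker construction on small instances.

## Least-squares fitting

Coefficient fitting solves, per Cartesian component,
$\min_a \|Z a - d\|^2 (+ \lambda \|a\|^2)$. The solver is SVD-based
(rank-revealing): with $\lambda = 0$ and full column rank it equals the
normal-equations solution $(Z^\top Z)^{-1} Z^\top d$, which serves as the
*test oracle only*; rank-deficient systems return the minimum-norm solution
with a warning; $\lambda > 0$ applies Tikhonov filter factors
$d_i/(d_i^2+\lambda)$. The same solver converts fields to mode amplitudes,
$g = \operatorname{argmin} \|U g - d\|^2$, reporting the residual norm
$\|d - Ug\|$ as a diagnostic of how much of the field the modes span.

Because both directions are orthogonal projections, the composed maps are
idempotent (`z2nma ∘ nma2z ∘ z2nma = z2nma`) and linear; both properties
are enforced by tests at 1e-8/1e-10.

## Elastic network models

The ANM Hessian uses uniform springs ($\gamma = 1$; the value only scales
eigenvalues, not mode shapes) and super-element blocks
$-\gamma\,\Delta r \Delta r^\top / |\Delta r|^2$ for pairs within the
cutoff. Defaults: 15 Å for ANM (the community standard for C$^\alpha$
networks) and 10 Å for GNM (the common choice for Kirchhoff contact
graphs); both are arguments. Zero modes are detected with a *relative*
tolerance ($\lambda < 10^{-6} \lambda_\max$), because absolute thresholds
break across structure scales; a connected non-collinear structure yields
exactly 6 (ANM) or 1 (GNM) of them. Degenerate eigenvalues carry no
canonical ordering, so tests compare subspaces and residuals
($\|Mv - \lambda v\|$), never individual vectors.

GNM covariances are built from the $P-1$ nonzero modes,
$\Sigma = \sum_{k \ge 2} \lambda_k^{-1} v_k v_k^\top$ — the Moore–Penrose
pseudo-inverse of the Kirchhoff matrix. A disconnected contact graph (two
or more zero modes) is an error naming the component count, since the
pseudo-inverse then mixes disconnected rigid pieces.

Mode editing supports *slice* (keep selected atoms' rows, re-normalize
columns to unit norm) and *extend* (zero-pad to a larger atom set). Model
reduction in the vibrational-subsystem sense is deliberately not
implemented; slicing and extension cover the selection workflows the rest
of the toolkit needs.

## Reference reassignment and focused analysis

Reassigning a landscape from reference $R$ to a new reference $R'$ uses
the additivity of deformation fields evaluated at a common point set: the
field $R' \to X$ is the difference of the fields $R \to X$ and
$R \to R'$, evaluated at the *original* reference's valid positions and
re-fitted onto the new reference's basis. When both references share the
same mask (identical basis matrices) the re-fit is exact and the result
collapses to the coefficient difference $A_{R\to X} - A_{R \to R'}$ — the
implementation short-circuits to that exact path. Composition of
reassignments under a shared mask is therefore an exact group action,
and the whole map is affine in $A_{R\to X}$; both are tested at 1e-10.
Fields are composed additively at the common evaluation set, not warped
through displaced positions; this is the regime in which the shared-mask
simplification above is exact, and it keeps reassignment linear.

Focused analysis re-fits each particle's field using only the points
inside a region mask. By default the basis is *recentered and rescaled* to
the masked region's bounding sphere: a small region expanded about the
global center uses only a thin shell of each radial polynomial, whereas
recentering devotes the full degree budget to the region, which is what
lets small-region motion stand out. `recenter = FALSE` keeps the original
support and only restricts the evaluation points, for cases where focused
coefficients must remain comparable with the full-model ones. Masks may be
boolean vectors over the basis points or density masks (inside = value
> 0.5, sampled trilinearly at the points). A mask selecting fewer points
than basis functions is rejected with a hint to lower the degrees.

## Landscape toolbox

* **Motion statistics**: per point, the mean displacement over all
  particles and the total standard deviation
  $\sqrt{\tfrac1M \sum_m \|u_m - \bar u\|^2}$ (a scalar, in Å). Two passes
  keep the variance exact, so identical rows give exactly zero spread.
* **RMSD clustering** is greedy and sequential: each conformer joins the
  first cluster whose representative (aligned member mean) is within the
  cutoff RMSD after Kabsch superposition, else seeds a new cluster;
  assignment passes repeat until stable (max 10), so every member ends
  within the cutoff of its representative. Greedy assignment is
  order-dependent by construction; input order is preserved and documented
  rather than hidden.
* **Best-view heatmaps** rotate both maps by ZYZ Euler angles
  (rot, tilt, 0) with trilinear interpolation, project along $z$ and record
  the Pearson correlation of the projections; in-plane rotation (psi) is
  fixed at 0 because it rotates both projections identically and leaves the
  correlation unchanged. Low-correlation cells mark views that discriminate
  the conformations. Rotation uses *clamp-to-edge* sampling: out-of-cube
  positions take the nearest edge value, which makes constant maps exactly
  rotation-invariant and hence the correlation exactly invariant under
  affine rescaling of either map — zero-fill sampling would break both at
  the box boundary. Zero-variance projections yield `NA` cells (an explicit
  undefined marker) rather than propagating NaNs; the default grid is rot
  0–355°, tilt 0–180°, step 5°.
* **Landscape reduction** is PCA of the centered coefficient rows (SVD,
  deterministic up to sign). The dimension bound is the rank bound
  $\min(M-1, 3B)$: collinear landscapes are allowed and simply produce
  trailing embedding coordinates that are numerically zero, which is more
  useful than rejecting them.
* **k-means representatives** use `stats::kmeans` with 10 restarts under a
  caller-fixed seed; `k = M` short-circuits to the exact answer (every row
  its own center) since iterative refinement adds nothing there.

## Synthetic generators and what they do (not) show

All tests and the acceptance script consume only seeded generators:
helical/blob/two-domain toy structures, Gaussian-splat density maps,
random per-degree-damped coefficient sets (magnitude × decay$^n$, default
decay 0.7 — smooth motions dominated by low orders), landscape tables
(cluster centers + isotropic coefficient noise, uniform-on-sphere
orientations) and mode-displaced ensembles. Ground truth (labels,
amplitudes) travels in a separate return slot from the data objects, so
pipeline code cannot peek.

The mode-ensemble generator has a `decorrelate` option that centers and
orthogonalizes the drawn amplitude columns while preserving their sample
variances. With only a handful of members, raw Gaussian draws have
noticeably correlated sample amplitudes, and principal components then
legitimately rotate within the planted-mode plane; decorrelated draws make
the sample covariance exactly diagonal, which is the right substrate for
testing *component recovery* rather than sampling noise.

These fixtures emulate geometry, smooth fields and noise — not CTF
effects, image formation, non-uniform orientation distributions, map
anisotropy or model/map mismatch. Passing tests therefore demonstrate the
correctness of the numerics and the declared conventions, not performance
on experimental data.

## Problem sizes and numerical choices

The shipped tests and acceptance script use 20–200-point structures,
$l_\max = n_\max \le 5$ bases ($B \le 56$), 24³–32³ voxel maps and
landscape tables of 50–100 rows — sizes at which every oracle
(normal equations, explicit pseudo-inverse, Kronecker stacking, brute-force
splatting) can be computed densely alongside the implementation.
Amplitude-recovery checks that require the basis to carry a mode-built
field exactly use an interpolating basis ($B \ge P$), accepting the
documented minimum-norm warning. Further fixed tolerances: relative
zero-eigenvalue threshold $10^{-6}$, SVD rank tolerance
$\max(\dim) \cdot \epsilon \cdot d_1$, focused-basis bounding spheres
padded by 5% so boundary points stay strictly inside the support.

## Known limitations

* Coefficient estimation from particle *images* is out of scope; the
  toolkit starts from coefficient tables, structures and maps.
* PDB is the only structure dialect (mmCIF is not parsed); MRC maps are
  restricted to mode-2 float32 with isotropic voxels.
* Bit-compatibility of coefficient files with other software is not
  claimed: radial normalization and $m$-ordering are declared in this
  package's headers, and conversions are only guaranteed self-consistent.
* Forward-splat map warping conserves density only up to boundary loss;
  fields that push mass outside the box lose it by design.
* Greedy RMSD clustering is input-order dependent, as any sequential
  threshold scheme is; k-means on coefficients is the order-free
  alternative provided alongside.
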