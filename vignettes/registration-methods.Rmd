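---
title: "One-step 2D–3D registration for biplanar videoradiography: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-step 2D-3D registration: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bvreg)
```

## The estimation problem

A biplanar videoradiography system captures synchronised image pairs of a
moving joint with two X-ray imaging chains. Each chain is modelled as a
lumped pinhole camera: the perspective centre `C`, an object-to-image
rotation `M(κ, φ, ω)`, a principal point `(x_p, y_p)` and a principal
distance `c` (all from an external photogrammetric calibration, which this
package consumes but never estimates), plus a per-point distortion
correction `(Δx, Δy)`. The collinearity condition — perspective centre,
image point and object point on one line — gives the projection

$$x = x_p - c\,\frac{U}{W} + \Delta x,\qquad
  y = y_p - c\,\frac{V}{W} + \Delta y,\qquad
  (U,V,W)^\top = M\,(X - C).$$

The unknown is the pose of a bone model point cloud: translation
`(X_t, Y_t, Z_t)` in mm and rotation, built as
`R3(κ_t) R2(φ_t) R1(ω_t)` from Euler angles about Z, Y, X (column-vector,
right-handed; degrees at the interface, radians inside). An optional single
non-rigid parameter, the scale `λ`, acts about the model centroid,
`p ↦ X̄ + λ(p − X̄)`, so scaling never moves the model (the printed operand
order of the composite scale-plus-shift expression is dimensionally
inconsistent in the source description; the centroid-invariant form is the
one consistent with its own text and figure, and is what is implemented).

Both registration flavours minimise the same objective — the sum of squared
2D distances between measured *master* points and projected *slave* model
points over both cameras with equal unit weight — differing only in what
the master data are:

* **marker-based**: extracted centres of implanted beads, matched
  one-to-one to the projected bead positions by a greedy global
  assignment on the distance matrix (every bead pairs up; discarding
  claims at poor poses would reward degenerate matchings during
  initialisation);
* **model-based**: bone edges from a bank of Canny detectors, matched to
  the outline of the projected cloud by the two-pass rule (each edge point
  claims its nearest outline point; an outline point keeps only its
  closest claimant), injective in outline points.

## Solving: quaternion-constrained Gauss–Newton

Euler parameterisations of the design matrix suffer from trigonometric
complexity and gimbal lock, so the solver works in the unit quaternion
`q = (q0, q1, q2, q3)`. The rotation matrix is the standard quadratic
9-term expansion of an *unnormalised* `q`; the constraint `g(q) = Σq² = 1`
enters the linearised system as an extra row (the gradient `2q`), appended
as a pseudo-observation with weight 1e6 relative to unit-weight pixel
residuals, and the quaternion is renormalised after every accepted step.
Residuals and the analytic Jacobian (`build_jacobian()`) differentiate the
same polynomial form, so the Jacobian is verifiable against central finite
differences to 1e-5 — one of the package's standing tests. The derivative
of the distortion correction with respect to the image point is neglected
in the Jacobian; for the identity provider it is exactly zero, and for
calibrated systems the correction varies slowly at the sub-pixel step
scale of an iteration.

Gauss–Newton steps are accepted only if the objective does not increase;
otherwise Levenberg–Marquardt damping is raised until it does (the
objective is therefore non-increasing by construction, asserted in tests).
Iteration stops when the largest parameter update falls below 1e-8 (mm or
quaternion units; configurable) or after 100 iterations. The outer loop
alternates matching and solving — match, solve to convergence, re-match —
and terminates when the matching is stable and the pose no longer moves.

**Outlier rejection.** Matches whose residual distance is unusually large
are mismatches. The batch rule deactivates pairs with
`d > mean(d) + 3·sd(d)`, recomputed once per solve round (not after each
removal). The centred form matters: a rule comparing `d` against `3·sd(d)`
alone is not idempotent — after removing true outliers the spread
collapses and every clean pair would exceed it — whereas the centred rule
is idempotent and rejects nothing when all distances are equal.

**Precision.** Parameter standard deviations come from the inverse of the
constrained normal matrix scaled by the a-posteriori variance factor with
redundancy `2·n_active − n_params` (`n_params` = 6 rigid, 7 scaled: the
constraint removes one of the quaternion's four degrees of freedom).
Quaternion covariance is propagated to Euler-angle sigmas numerically. A
Monte-Carlo test checks the predicted sigmas against the empirical spread
of 100 noisy replicates (agreement within 1.5×).

## The two-step baseline

Classical RSA first triangulates each bead from its stereo measurements
(midpoint of the common perpendicular between the two viewing rays — the
intersection rule is not specified by the source system, and the midpoint
is the classical choice), then fits the rigid transform from model beads to
triangulated beads with Horn's closed-form quaternion method (unweighted;
whether the original weighted beads is unknown). Errors of the first step
propagate unmodelled into the second, which is why the one-step fit attains
a lower reprojection residual; on noise-free data both are exact and agree
to 1e-9.

## Marker extraction

Bead centres are found by Canny edge detection (Gaussian smoothing, Sobel
gradients, non-maximum suppression, hysteresis with thresholds relative to
the maximum gradient magnitude), 8-connected component grouping, sub-pixel
edge refinement (parabolic interpolation of the gradient magnitude along
the quantised gradient direction), and a direct least-squares ellipse fit
(Fitzgibbon-type conic fit with the ellipse constraint, computed on
centred/scaled coordinates; exact on noise-free samples). Fits whose
semi-axes fall outside the expected bead size range are discarded — the
default gate assumes ~3 mm beads at the nominal rig magnification. Beads
in low-intensity image regions lose contrast below the edge detector's
relative thresholds; a linear intensity enhancement (`gain·I + offset`,
clipped) restores their contrast, and the extractor retries once on the
enhanced image when fewer targets than expected are found, deduplicating
centres closer than the largest accepted semi-major axis.

## Model-based front end

Radiograph contrast is low and no single Canny parameterisation recovers
the whole bone edge, so a bank of detectors (default 5 sigmas × 5
hysteresis pairs = 25 filters; the threshold grid is spaced geometrically
between loose and strict defaults since only the count and sigma span are
prescribed) is overlaid and the union thinned to one-pixel chains
(Zhang–Suen). Edges are pose-independent, so the bank runs once per image.
The projected-outline extraction rasterises the projected cloud on an
occupancy grid (cell ≈ 1.5× the median nearest-neighbour spacing of the
projected points), closes single-cell gaps and fills enclosed holes so
sampling sparsity cannot masquerade as boundary, and keeps one projected
point per boundary cell — the most outward one, which best approximates
the physical silhouette boundary where image edges lie (the nearest-to-
cell-centre choice sits systematically inside it by about half the point
spacing and biases the scale factor upward). Each outline point carries
its 3D model index into the least-squares solve.

In scaled mode the driver first runs a rigid registration and starts the
8-parameter problem from its solution: the scale and depth directions are
strongly correlated and shallow, and a distant start can otherwise settle
in a slightly biased basin.

## Initialisation

Iterative registration has a limited rotational capture range, so
registration starts from 64 poses on an even `4×4×4` Euler grid (each
angle in {−135°, −45°, 45°, 135°}; the exact construction used by the
source system's reference is not public, and the grid generator is
swappable), all sharing a translation guess (default: the rig's
convergence point). Each start runs a capped registration (10 inner
iterations, 3 matching rounds); the best few candidates (default 5) then
run to full convergence and the smallest final RMSE wins, ties broken by
the lowest index. The refinement stage guards against a wrong basin
narrowly out-scoring the right one under the iteration cap.
Whether the original 64 starts also varied translation is unstated;
rotation-only variation is implemented. For image sequences, the previous
epoch's pose is the natural warm start and the CLI uses it.

## Accuracy and precision metrics

`accuracy_report()` gives parameter differences and the per-axis /
Euclidean RMS of bead position differences between two registrations of
the same cloud — the standard accuracy table when a marker-based solution
serves as ground truth for a model-based one. `precision_rms_3d()` lifts
each matched edge point into 3D along its viewing ray at the image-space
depth of its matched model point and reports the RMS distance to those
model points; it is exactly zero for a perfect noiseless registration and
needs no ground truth, which is what makes it usable in vivo.

## The synthetic study conditions

Real phantom and in vivo data are unavailable, so validation runs on
synthetic fixtures built by the package itself:

* **Phantom**: surface points on an elongated tri-axial ellipsoid
  (semi-axes 22, 18, 55 mm) with two unequal spherical condyles (radii 14
  and 11 mm) — bone-like, and asymmetric so no 180° flip maps the cloud
  onto itself; beads (default 7, mirroring six/seven implanted beads with
  redundancy beyond the three of older practice) are placed by
  farthest-point sampling with a 15 mm separation floor.
* **Rig**: two cameras in the Y–Z plane converging on the origin at 60°,
  source–object distance 1000 mm, principal distance 2800 px at
  1008×1008 px (half the real detector resolution, keeping the ~2.8 px/mm
  magnification while halving render cost); X is vertical and Y the mean
  viewing (depth) direction.
* **Renders**: 4× supersampled, box down-sampled. Beads are fixed-level
  dark disks (steel absorbs nearly all radiation), so a low-intensity
  band collapses their contrast — the situation the enhancement retry
  exists for; the band's edge is a raised-cosine ramp so the band boundary
  itself produces no spurious edge. Silhouettes are filled projected
  clouds with Gaussian-blurred boundaries and an optional uniform inward
  edge offset emulating the systematic inward displacement of
  heavily-smoothed edge detections.
* **Noise**: two distinct injection points — i.i.d. Gaussian noise on
  extracted 2D coordinates (default 0.5 px; the real system's noise level
  is unknown) for estimator studies, and i.i.d. Gaussian intensity noise
  for image-pipeline studies.

Problem sizes in the test-suite and acceptance runs — 600-point phantoms
for bead studies, 2000–4000 points and 256 px images for silhouette
studies, 50–100 Monte-Carlo replicates — were chosen as the smallest at
which the Monte-Carlo checks are statistically meaningful.

What passing these tests shows — and what it does not: the synthetic
fixtures exercise the full geometry and estimation chain under controlled,
correctly-modelled noise, but real radiographs add structured background,
scatter, overlapping anatomy, calibration error and edge-detection biases
far richer than a uniform inward offset. Results on synthetic data bound
the method's behaviour from the favourable side.

## Numerical choices and degenerate inputs

* Projection refuses points in a camera's principal plane (|W| < 1e-12),
  naming the offending indices; triangulation refuses near-parallel rays.
* `fit_ellipse()` requires ≥ 5 points and rejects collinear sets; the
  eigenvector with `4AC − B² > 0` is selected.
* `horn_absolute_orientation()` requires ≥ 3 non-collinear pairs (checked
  by the second singular value of the centred set).
* A scale estimate drifting outside [0.5, 2] raises an implausible-scale
  warning; `λ = 1` reproduces the rigid path bitwise.
* Rank deficiency in the normal system is reported with the null
  direction rather than silently regularised.
* Image-space ↔ raster convention: matrix element `[r, c]` is the pixel
  with 0-based image coordinates `x = c − 1`, `y = r − 1`; y grows with
  the row index. The exact mapping is not prescribed by the source
  system, so it is fixed here and used consistently by renderers,
  extractors and file I/O.

## Known limitations

* The 3σ rejection is batch-per-round; a sequential re-estimate after each
  removal would be marginally more robust at small n.
* The outline extractor's occupancy grid quantises the silhouette at
  ~1.5× point spacing; on rendered (as opposed to outline-derived) edges,
  rotations about the least-constrained axis (κ in the default rig)
  converge to the sub-half-degree level, not machine precision.
* No temporal model: each epoch is solved independently (warm-started in
  sequences); dynamic filtering across frames is out of scope.
* Intensity/DRR-based registration and deformable models beyond the single
  scale factor are out of scope by design.
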