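# bvreg — one-step 2D–3D registration for biplanar videoradiography

High-speed biplanar videoradiography (dual fluoroscopy) images a joint with
two synchronised X-ray chains while the subject moves. Recovering the
six-degree-of-freedom pose of a 3D bone model (segmented from MRI or CT) in
every synchronised image pair is what turns those image series into 3D
kinematics — and, downstream, into cartilage contact estimates that demand
sub-millimetre registration accuracy. `bvreg` implements that registration
for R users: biomechanics and medical-imaging researchers who need a
transparent, testable reference implementation rather than a black box.

## The method

Each imaging chain (source, intensifier, camera) is a lumped pinhole camera
with exterior orientation `(X_C, Y_C, Z_C, ω, φ, κ)` and interior
orientation `(x_p, y_p, c)`. An object point `X` maps to image coordinates
through the collinearity condition

    (U, V, W)' = M(κ, φ, ω) (X − C)
    x = x_p − c·U/W + Δx,   y = y_p − c·V/W + Δy

with `Δx, Δy` supplied by the system's distortion calibration. The bone
model is a point cloud transformed rigidly, `X_i = M(κ_t, φ_t, ω_t) p_i + t`,
optionally augmented by a single scale factor `λ` applied about the model
centroid, `p_i ↦ X̄ + λ(p_i − X̄)`, which absorbs a systematic offset between
detected radiograph edges and the true bone boundary.

Registration is **one-step projection**: the model points (fiducial bead
centres, or the outline of the projected cloud) are projected into both
images and the summed squared 2D distances to the measured master points —
extracted bead centres, or bank-of-Canny bone edges — are minimised directly
over `(t, q, [λ])`, where the rotation is a unit quaternion `q` kept on the
sphere by the constraint `Σq² = 1` appended to the Gauss–Newton system.
Matching (one-to-one, by point-to-point distance) and estimation alternate
until the pose is stable; matches beyond three standard deviations of the
residual distances are rejected as mismatches. This avoids the two-step
error propagation of classical Roentgen stereophotogrammetry (RSA:
triangulate beads, then Horn's absolute orientation), which the package also
implements as the comparison baseline.

Because the real study data (phantom and in vivo knee) are not public, the
package ships a synthetic module — a bone-like phantom with surface beads, a
convergent two-camera rig, and marker/silhouette radiograph renderers with
controlled noise and edge offsets — so every claim is testable end to end.

## Worked example

```r
library(bvreg)

phantom <- make_phantom(n_surface_points = 2000, n_beads = 7, seed = 42)
rig     <- make_rig(rig_spec(angle_deg = 60, distance_mm = 1000,
                             c_px = 2800, image_size = c(1008, 1008)))
trial   <- simulate_trial(trial_spec(n_epochs = 1, noise_px = 0.5, seed = 42,
                                     base_pose = pose(5, -10, 8, 20, -15, 30)),
                          phantom, rig)

beads <- bead_cloud(phantom)
init  <- coarse_search(beads, rig, trial$tracks[[1]])$pose   # 64-pose search
fit   <- register(beads, rig, trial$tracks[[1]], init = init)
fit
#> rigid-mode registration (converged, 2 iterations)
#> pose: t = (4.97141, -10.2079, 7.99565) mm;  (omega, phi, kappa) = (19.9618, -14.9811, 29.6546) deg
#>   rms 2D residual = 0.5621 px over 14 pairs (0 rejected)
#>   parameter sigmas: X=0.0611  Y=0.123  Z=0.0703  omega=0.176  phi=0.126  kappa=0.276

rsa_register(beads, rig, trial$tracks[[1]])$rms_2d
#> [1] 0.5679      # two-step baseline: higher residual than 0.5621 px

accuracy_report(fit, trial$poses[[1]], beads)$rms
#>        X        Y        Z distance
#>   0.1049   0.2183   0.0120   0.2425   # mm, vs the simulated ground truth
```

The true pose was `(5, −10, 8)` mm and `(20, −15, 30)`°; with 0.5 px of
image noise the fit lands within ~0.2 mm, the per-parameter standard
deviations (from the a-posteriori covariance) are 0.06–0.12 mm and
0.13–0.28°, and the one-step fit attains a lower reprojection residual than
the RSA baseline on the same measurements.

Model-based (bead-free) registration works from the images alone:

```r
imgs <- lapply(rig, function(cam)
  render_silhouette_image(cam, phantom, trial$poses[[1]])$image)
fit_mb <- register_model_based(imgs, phantom, rig, init = fit$pose,
                               mode = "scaled")
precision_rms_3d(fit_mb)     # back-projection precision, mm
```

A thin command-line front end (`inst/cli/bvreg.R`) chains the same
functions: `simulate`, `register-markers`, `register-model`, `rsa`,
`init-search`, `evaluate`.

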