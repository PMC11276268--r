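Package: bvreg
Title: Rigorous One-Step 2D-3D Registration for Biplanar Videoradiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Registers a 3D bone model point cloud to pairs of biplanar
    radiographs by a one-step projection strategy: reprojection distances of
    matched 2D features are minimised directly by quaternion-constrained
    Gauss-Newton least squares, for both marker-based (implanted fiducial
    beads) and model-based (bone silhouette edge) registration, with rigid
    and scale-augmented transformation models. Includes the classical
    two-step Roentgen stereophotogrammetry (RSA) baseline (ray triangulation
    followed by Horn's absolute orientation), fiducial target extraction
    from radiographs (Canny edges, direct ellipse fitting, semi-axis
    gating, intensity enhancement), a multi-threshold Canny edge bank with
    thinning for bone edges, automatic 64-pose initialisation, accuracy and
    back-projection precision metrics, and a synthetic phantom/camera-rig
    generator for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
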