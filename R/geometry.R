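# Coordinate systems, transformation models and the collinearity projection.
#
# Conventions used throughout the package:
#  * object space in mm, image measurements and the principal distance in px;
#  * rotations are right-handed, column-vector convention;
#  * the pose rotation is the Euler factorisation R3(kappa) %*% R2(phi) %*% R1(omega)
#    (elementary rotations about Z, Y, X respectively);
#  * angles are radians internally; user-facing helpers accept/report degrees.

#' Elementary rotation about the X axis
#' @param a angle, radians
#' @return 3x3 rotation matrix
#' @keywords internal
rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}

#' @rdname rot_x
#' @keywords internal
rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

#' @rdname rot_x
#' @keywords internal
rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

#' Rotation matrix from Euler angles
#'
#' Builds the rotation matrix `R3(kappa) %*% R2(phi) %*% R1(omega)`:
#' a rotation by `omega` about X, then `phi` about Y, then `kappa` about Z,
#' in the column-vector convention.
#'
#' @param omega,phi,kappa rotation angles about the X, Y and Z axes, radians.
#' @return orthonormal 3x3 matrix with determinant +1.
#' @export
#' @examples
#' euler_to_matrix(0, 0, pi / 2) %*% c(1, 0, 0)  # -> (0, 1, 0)
euler_to_matrix <- function(omega, phi, kappa) {
  if (!all(is.finite(c(omega, phi, kappa))))
    stop("euler_to_matrix: angles must be finite")
  rot_z(kappa) %*% rot_y(phi) %*% rot_x(omega)
}

#' Euler angles from a rotation matrix
#'
#' Inverts [euler_to_matrix()]. Returns the branch with `phi` in
#' `[-pi/2, pi/2]`; at gimbal lock (`|phi| = pi/2`) `omega` is set to 0 and
#' the full rotation is absorbed into `kappa`.
#'
#' @param R 3x3 rotation matrix.
#' @return named numeric vector `c(omega, phi, kappa)`, radians.
#' @export
matrix_to_euler <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  sphi <- -R[3, 1]
  sphi <- max(-1, min(1, sphi))
  phi <- asin(sphi)
  if (abs(sphi) > 1 - 1e-12) {
    omega <- 0
    kappa <- atan2(-R[1, 2], R[2, 2])
  } else {
    omega <- atan2(R[3, 2], R[3, 3])
    kappa <- atan2(R[2, 1], R[1, 1])
  }
  c(omega = omega, phi = phi, kappa = kappa)
}

#' Six-parameter rigid pose
#'
#' A rigid-body transform of object space: translation `(Xt, Yt, Zt)` in mm
#' and Euler rotations `(omega, phi, kappa)` about the X, Y, Z axes.
#'
#' @param Xt,Yt,Zt translation, mm.
#' @param omega,phi,kappa rotation angles; degrees when `degrees = TRUE`
#'   (the default for this constructor), stored in radians.
#' @param degrees logical; interpret the angles as degrees.
#' @return object of class `bv_pose` with fields `t` (length-3 translation)
#'   and `angles` (radians).
#' @export
pose <- function(Xt = 0, Yt = 0, Zt = 0, omega = 0, phi = 0, kappa = 0,
                 degrees = TRUE) {
  a <- c(omega = unname(omega), phi = unname(phi), kappa = unname(kappa))
  if (degrees) a <- a * pi / 180
  if (!all(is.finite(c(Xt, Yt, Zt, a)))) stop("pose: non-finite parameters")
  structure(list(t = unname(c(Xt, Yt, Zt)), angles = a), class = "bv_pose")
}

#' @export
print.bv_pose <- function(x, ...) {
  cat("pose: t = (", paste(signif(x$t, 6), collapse = ", "), ") mm;  ",
      "(omega, phi, kappa) = (",
      paste(signif(x$angles * 180 / pi, 6), collapse = ", "), ") deg\n",
      sep = "")
  invisible(x)
}

#' Rotation matrix of a pose
#' @param p a `bv_pose`.
#' @return 3x3 rotation matrix.
#' @export
pose_matrix <- function(p) {
  euler_to_matrix(p$angles[["omega"]], p$angles[["phi"]], p$angles[["kappa"]])
}

#' Invert a pose
#' @param p a `bv_pose`.
#' @return the inverse pose: composing the two gives the identity.
#' @export
pose_inverse <- function(p) {
  R <- pose_matrix(p)
  Rt <- t(R)
  a <- matrix_to_euler(Rt)
  ti <- -as.vector(Rt %*% p$t)
  pose(ti[1], ti[2], ti[3], a[1], a[2], a[3], degrees = FALSE)
}

#' Pose with a unit-quaternion rotation
#'
#' Alternate parameterisation of [pose()] used by the estimator: translation
#' plus a unit quaternion `(q0, q1, q2, q3)` (scalar first, Hamilton
#' convention). The quaternion is renormalised on construction.
#'
#' @param Xt,Yt,Zt translation, mm.
#' @param q length-4 quaternion, non-zero.
#' @return object of class `bv_quat_pose`.
#' @export
quat_pose <- function(Xt = 0, Yt = 0, Zt = 0, q = c(1, 0, 0, 0)) {
  stopifnot(length(q) == 4)
  n <- sqrt(sum(q^2))
  if (!is.finite(n) || n < 1e-12) stop("quat_pose: zero or non-finite quaternion")
  structure(list(t = c(Xt, Yt, Zt), q = q / n), class = "bv_quat_pose")
}

#' Rotation matrix from a unit quaternion
#'
#' Standard 9-term expansion, scalar-first Hamilton convention. `q` and `-q`
#' map to the same matrix.
#'
#' @param q length-4 quaternion with norm within 1e-6 of 1 (renormalised
#'   internally).
#' @return orthonormal 3x3 matrix.
#' @export
quat_to_matrix <- function(q) {
  stopifnot(length(q) == 4)
  n <- sqrt(sum(q^2))
  if (!is.finite(n) || n < 1e-12) stop("quat_to_matrix: zero quaternion")
  q <- q / n
  q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
  matrix(c(
    q0^2 + q1^2 - q2^2 - q3^2, 2 * (q1 * q2 + q0 * q3),   2 * (q1 * q3 - q0 * q2),
    2 * (q1 * q2 - q0 * q3),   q0^2 - q1^2 + q2^2 - q3^2, 2 * (q2 * q3 + q0 * q1),
    2 * (q1 * q3 + q0 * q2),   2 * (q2 * q3 - q0 * q1),   q0^2 - q1^2 - q2^2 + q3^2
  ), 3, 3)
}

#' Unit quaternion from a rotation matrix
#'
#' Shepperd's method: picks the numerically largest component first.
#' The sign is fixed so that `q0 >= 0`.
#'
#' @param R 3x3 rotation matrix.
#' @return length-4 unit quaternion, scalar first.
#' @export
matrix_to_quat <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 - R[1, 1] + R[2, 2] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 - R[1, 1] - R[2, 2] + R[3, 3]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, s / 4)
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

#' Convert between Euler and quaternion pose forms
#' @param p a `bv_pose` or `bv_quat_pose`.
#' @return the other representation of the same rigid motion.
#' @export
as_quat_pose <- function(p) {
  if (inherits(p, "bv_quat_pose")) return(p)
  stopifnot(inherits(p, "bv_pose"))
  quat_pose(p$t[1], p$t[2], p$t[3], matrix_to_quat(pose_matrix(p)))
}

#' @rdname as_quat_pose
#' @export
as_euler_pose <- function(p) {
  if (inherits(p, "bv_pose")) return(p)
  stopifnot(inherits(p, "bv_quat_pose"))
  a <- matrix_to_euler(quat_to_matrix(p$q))
  pose(p$t[1], p$t[2], p$t[3], a[1], a[2], a[3], degrees = FALSE)
}

#' Point cloud of a 3D bone model
#'
#' An N x 3 matrix of object-space coordinates (mm) with an optional subset
#' of rows marking implanted fiducial beads.
#'
#' @param points N x 3 numeric matrix (columns X, Y, Z, mm).
#' @param bead_indices optional integer vector of rows that are fiducial
#'   beads.
#' @return object of class `bv_cloud` with fields `points`, `centroid`,
#'   `bead_indices`.
#' @export
point_cloud <- function(points, bead_indices = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3 || nrow(points) < 1)
    stop("point_cloud: need an N x 3 matrix with N >= 1")
  if (!all(is.finite(points))) stop("point_cloud: non-finite coordinates")
  storage.mode(points) <- "double"
  colnames(points) <- c("X", "Y", "Z")
  if (!is.null(bead_indices)) {
    bead_indices <- as.integer(bead_indices)
    if (any(bead_indices < 1L | bead_indices > nrow(points)))
      stop("point_cloud: bead indices out of range")
  }
  structure(list(points = points, centroid = colMeans(points),
                 bead_indices = bead_indices),
            class = "bv_cloud")
}

#' @export
print.bv_cloud <- function(x, ...) {
  cat("point cloud:", nrow(x$points), "points",
      if (!is.null(x$bead_indices)) sprintf("(%d beads)", length(x$bead_indices)) else "",
      "\n  centroid:", paste(signif(x$centroid, 6), collapse = ", "), "mm\n")
  invisible(x)
}

#' Bead subset of a cloud as a cloud
#' @param cloud a `bv_cloud` with bead indices.
#' @return a `bv_cloud` of the bead points only.
#' @export
bead_cloud <- function(cloud) {
  if (is.null(cloud$bead_indices)) stop("bead_cloud: cloud has no bead subset")
  point_cloud(cloud$points[cloud$bead_indices, , drop = FALSE])
}

#' Apply a rigid-body transform to a point cloud
#'
#' Maps each point p to `M %*% p + t` where `M` is the pose rotation matrix.
#'
#' @param p a `bv_pose` or `bv_quat_pose`.
#' @param cloud a `bv_cloud` or N x 3 matrix.
#' @return transformed object of the same kind as `cloud`.
#' @export
apply_rigid <- function(p, cloud) {
  apply_scaled(p, 1, cloud)
}

#' Apply a scale-augmented (non-rigid) transform
#'
#' The single non-rigid parameter is a scale `lam` applied about the cloud
#' centroid before the rigid motion: points map to
#' `M %*% (cbar + lam * (p - cbar)) + t`, so the pre-rotation cloud keeps its
#' centroid. `lam = 1` reduces exactly to [apply_rigid()].
#'
#' @param p a `bv_pose` or `bv_quat_pose`.
#' @param lam positive scale factor.
#' @param cloud a `bv_cloud` or N x 3 matrix.
#' @return transformed object of the same kind as `cloud`.
#' @export
apply_scaled <- function(p, lam, cloud) {
  if (!is.finite(lam) || lam <= 0) stop("apply_scaled: lam must be positive")
  is_cloud <- inherits(cloud, "bv_cloud")
  pts <- if (is_cloud) cloud$points else as.matrix(cloud)
  if (nrow(pts) < 1) stop("apply_scaled: empty cloud")
  M <- if (inherits(p, "bv_quat_pose")) quat_to_matrix(p$q) else pose_matrix(p)
  cbar <- colMeans(pts)
  scaled <- sweep(sweep(pts, 2, cbar) * lam, 2, cbar, "+")
  out <- scaled %*% t(M)
  out <- sweep(out, 2, p$t, "+")
  colnames(out) <- c("X", "Y", "Z")
  if (is_cloud) point_cloud(out, cloud$bead_indices) else out
}

#' Camera model (lumped pinhole with distortion correction)
#'
#' The imaging chain (X-ray source, intensifier, video camera) is lumped
#' into a single pinhole camera: exterior orientation (perspective centre
#' `(XC, YC, ZC)` in mm and object-to-image rotation `(omega, phi, kappa)`)
#' plus interior orientation (principal point `(xp, yp)` and principal
#' distance `c`, px) and a per-point distortion correction provider.
#'
#' @param XC,YC,ZC perspective-centre object coordinates, mm.
#' @param omega,phi,kappa object-to-image rotation angles; degrees when
#'   `degrees = TRUE`.
#' @param xp,yp principal point, px.
#' @param c principal distance, px; must be positive.
#' @param distortion function `(x, y) -> list(dx, dy)` returning corrections
#'   in px for image points; `NULL` for the identity (no distortion).
#' @param degrees logical; interpret the angles as degrees.
#' @return object of class `bv_camera`.
#' @export
camera_model <- function(XC, YC, ZC, omega, phi, kappa, xp, yp, c,
                         distortion = NULL, degrees = TRUE) {
  if (!is.finite(c) || c <= 0) stop("camera_model: principal distance must be > 0")
  a <- c(omega, phi, kappa)
  if (degrees) a <- a * pi / 180
  M <- euler_to_matrix(a[1], a[2], a[3])
  if (is.null(distortion)) distortion <- function(x, y) list(dx = 0 * x, dy = 0 * y)
  structure(list(C = c(XC, YC, ZC), angles = a, M = M,
                 xp = xp, yp = yp, c = c, distortion = distortion),
            class = "bv_camera")
}

#' @export
print.bv_camera <- function(x, ...) {
  cat("camera: C = (", paste(signif(x$C, 6), collapse = ", "), ") mm;  c =",
      x$c, "px;  pp = (", x$xp, ",", x$yp, ") px\n")
  invisible(x)
}

#' Project 3D points through a camera (collinearity equations)
#'
#' Rotates object points into image space, `(U, V, W) = M %*% (X - C)`, and
#' applies the collinearity equations
#' `x = xp - c * U / W + dx`, `y = yp - c * V / W + dy`.
#' Points in the camera's principal plane (`W = 0`) have no projection.
#'
#' @param camera a `bv_camera`.
#' @param points a `bv_cloud` or N x 3 matrix of object points, mm.
#' @return N x 2 matrix of image coordinates (columns `x`, `y`), px.
#' @export
project_points <- function(camera, points) {
  pts <- if (inherits(points, "bv_cloud")) points$points else
    matrix(as.numeric(points), ncol = 3)
  uvw <- sweep(pts, 2, camera$C) %*% t(camera$M)
  if (any(abs(uvw[, 3]) < 1e-12)) {
    bad <- which(abs(uvw[, 3]) < 1e-12)
    stop(sprintf("project_points: point(s) %s lie in the principal plane (W = 0)",
                 paste(bad, collapse = ", ")))
  }
  x0 <- camera$xp - camera$c * uvw[, 1] / uvw[, 3]
  y0 <- camera$yp - camera$c * uvw[, 2] / uvw[, 3]
  d <- camera$distortion(x0, y0)
  cbind(x = x0 + d$dx, y = y0 + d$dy)
}

#' Image-space depth of object points
#'
#' The along-axis depth `W` (third image-space coordinate) of each point.
#'
#' @inheritParams project_points
#' @return numeric vector of depths, mm.
#' @export
point_depth <- function(camera, points) {
  pts <- if (inherits(points, "bv_cloud")) points$points else
    matrix(as.numeric(points), ncol = 3)
  as.numeric(sweep(pts, 2, camera$C) %*% camera$M[3, ])
}

#' Viewing ray of an image point
#'
#' Object-space ray through the perspective centre for a measured image
#' point: the distortion correction is first removed, then the image-space
#' direction `(-(x - xp), -(y - yp), c)` (which has unit depth after
#' division by `c`) is rotated back to object space.
#'
#' @param camera a `bv_camera`.
#' @param x,y image coordinates, px (vectors allowed).
#' @return list with `origin` (the perspective centre) and `dir` (N x 3
#'   matrix of directions scaled to unit image-space depth).
#' @export
viewing_ray <- function(camera, x, y) {
  d <- camera$distortion(x, y)
  xu <- x - d$dx - camera$xp
  yu <- y - d$dy - camera$yp
  # image-space direction per unit depth W
  dir_img <- cbind(-xu / camera$c, -yu / camera$c, rep(1, length(xu)))
  dir_obj <- dir_img %*% camera$M   # t(M) %*% v per row
  list(origin = camera$C, dir = dir_obj)
}

#' Back-project an image point at a matched depth
#'
#' Lifts a 2D point into 3D along its viewing ray, assigning it the
#' image-space depth of a reference 3D point (its matched model point).
#' This is the lifting used by the back-projection precision metric.
#'
#' @param camera a `bv_camera`.
#' @param x,y image coordinates of the point(s), px.
#' @param reference3d reference 3D point(s): length-3 vector or N x 3 matrix.
#' @return N x 3 matrix of object-space points, mm.
#' @export
backproject_at_depth <- function(camera, x, y, reference3d) {
  ref <- matrix(as.numeric(reference3d), ncol = 3)
  n <- max(length(x), nrow(ref))
  x <- rep_len(x, n); y <- rep_len(y, n)
  if (nrow(ref) == 1 && n > 1) ref <- ref[rep(1, n), , drop = FALSE]
  W <- point_depth(camera, ref)
  if (any(abs(W) < 1e-9))
    stop("backproject_at_depth: reference point at the perspective centre plane")
  ray <- viewing_ray(camera, x, y)
  out <- ray$dir * W + matrix(ray$origin, n, 3, byrow = TRUE)
  colnames(out) <- c("X", "Y", "Z")
  out
}

#' Triangulate a point from a stereo pair
#'
#' Intersects the two viewing rays of corresponding image measurements. For
#' skew (noisy) rays, returns the midpoint of the common perpendicular
#' segment — the classical stereo reconstruction rule.
#'
#' @param cam1,cam2 the two `bv_camera` models.
#' @param x1,y1,x2,y2 corresponding image coordinates in each camera, px
#'   (vectors allowed).
#' @return N x 3 matrix of object-space points, mm.
#' @export
triangulate <- function(cam1, cam2, x1, y1, x2, y2) {
  r1 <- viewing_ray(cam1, x1, y1)
  r2 <- viewing_ray(cam2, x2, y2)
  n <- nrow(r1$dir)
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("X", "Y", "Z")))
  b <- r2$origin - r1$origin
  for (i in seq_len(n)) {
    d1 <- r1$dir[i, ]; d2 <- r2$dir[i, ]
    a11 <- sum(d1 * d1); a12 <- -sum(d1 * d2); a22 <- sum(d2 * d2)
    det <- a11 * a22 - a12 * a12
    if (abs(det) < 1e-12 * a11 * a22)
      stop(sprintf("triangulate: rays for point %d are (near) parallel", i))
    rhs <- c(sum(d1 * b), -sum(d2 * b))
    t1 <- (a22 * rhs[1] - a12 * rhs[2]) / det
    t2 <- (a11 * rhs[2] - a12 * rhs[1]) / det
    p1 <- r1$origin + t1 * d1
    p2 <- r2$origin + t2 * d2
    out[i, ] <- (p1 + p2) / 2
  }
  out
}
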