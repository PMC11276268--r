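# The one-step projection estimator: quaternion-constrained nonlinear least
# squares on 2D reprojection distances, with scale-augmented (non-rigid)
# mode, 3-sigma outlier rejection, covariance-based precision reporting,
# and the two-step RSA baseline (triangulation + Horn).

# rotation matrix as a polynomial in the (unnormalised) quaternion; the
# estimator differentiates this form, and the unit-norm constraint keeps the
# iterate on the sphere where it equals the true rotation
quat_rotmat_raw <- function(q) {
  q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
  matrix(c(
    q0^2 + q1^2 - q2^2 - q3^2, 2 * (q1 * q2 + q0 * q3),   2 * (q1 * q3 - q0 * q2),
    2 * (q1 * q2 - q0 * q3),   q0^2 - q1^2 + q2^2 - q3^2, 2 * (q2 * q3 + q0 * q1),
    2 * (q1 * q3 + q0 * q2),   2 * (q2 * q3 - q0 * q1),   q0^2 - q1^2 - q2^2 + q3^2
  ), 3, 3)
}

quat_rotmat_grad <- function(q) {
  q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
  list(
    2 * matrix(c(q0, q3, -q2,  -q3, q0, q1,  q2, -q1, q0), 3, 3),
    2 * matrix(c(q1, q2, q3,   q2, -q1, q0,  q3, -q0, -q1), 3, 3),
    2 * matrix(c(-q2, q1, -q0, q1, q2, q3,   q0, q3, -q2), 3, 3),
    2 * matrix(c(-q3, q0, q1,  -q0, -q3, q2, q1, q2, q3), 3, 3)
  )
}

# parameter vector <-> (quat pose, lam): theta = (Xt, Yt, Zt, q0..q3[, lam])
theta_pack <- function(qp, lam = NULL) c(qp$t, qp$q, lam)
theta_unpack <- function(theta, scaled) {
  list(t = theta[1:3], q = theta[4:7],
       lam = if (scaled) theta[8] else 1)
}

# transform model points with the raw-quaternion scaled model:
# P = R(q) (cbar + lam (p0 - cbar)) + t
transform_model <- function(theta, pts, cbar, scaled) {
  th <- theta_unpack(theta, scaled)
  R <- quat_rotmat_raw(th$q)
  s <- sweep(sweep(pts, 2, cbar) * th$lam, 2, cbar, "+")
  sweep(s %*% t(R), 2, th$t, "+")
}

#' Correspondence set for the projection estimator
#'
#' Per-camera pairs of a measured (master) 2D point and a model-point index,
#' with an active flag that the 3-sigma rejection can clear.
#'
#' @param master list per camera of N_k x 2 matrices of measured image
#'   points, px.
#' @param model_idx list per camera of integer vectors (rows of the model
#'   cloud), same lengths.
#' @return object of class `bv_corr`.
#' @export
correspondence_set <- function(master, model_idx) {
  stopifnot(length(master) == length(model_idx))
  for (k in seq_along(master)) {
    stopifnot(nrow(master[[k]]) == length(model_idx[[k]]))
    if (anyDuplicated(model_idx[[k]]))
      stop("correspondence_set: a model index appears twice within one camera")
  }
  structure(list(master = master, model_idx = model_idx,
                 active = lapply(master, function(m) rep(TRUE, nrow(m)))),
            class = "bv_corr")
}

n_active <- function(corr) sum(vapply(corr$active, sum, numeric(1)))

# residual vector (projected - master, px) over active pairs, in camera order
reproj_residuals <- function(theta, pts, cbar, cameras, corr, scaled) {
  res <- c()
  for (k in seq_along(cameras)) {
    act <- corr$active[[k]]
    if (!any(act)) next
    idx <- corr$model_idx[[k]][act]
    P <- transform_model(theta, pts[idx, , drop = FALSE], cbar, scaled)
    xy <- project_points(cameras[[k]], P)
    res <- c(res, as.numeric(t(xy - corr$master[[k]][act, , drop = FALSE])))
  }
  res
}

#' Design matrix of the projection estimator
#'
#' Analytic Jacobian of the active reprojection residuals with respect to
#' `(Xt, Yt, Zt, q0, q1, q2, q3[, lam])`, plus the gradient row of the
#' unit-quaternion constraint `g = q0^2 + q1^2 + q2^2 + q3^2`. Residual rows
#' come in (x, y) pairs per active correspondence, cameras concatenated.
#'
#' @param qp a `bv_quat_pose` (current iterate).
#' @param lam current scale, or `NULL` for rigid mode.
#' @param cloud the model `bv_cloud` (its centroid anchors the scaling).
#' @param cameras list of `bv_camera`.
#' @param corr a [correspondence_set()].
#' @return list with `A` (design matrix), `r` (residual vector, px),
#'   `g_row` (constraint gradient row) and `g_val` (current constraint
#'   value).
#' @export
build_jacobian <- function(qp, lam = NULL, cloud, cameras, corr) {
  scaled <- !is.null(lam)
  theta <- theta_pack(qp, lam)
  npar <- length(theta)
  pts <- cloud$points
  cbar <- cloud$centroid
  na <- n_active(corr)
  if (na < 4)
    stop(sprintf(
      "build_jacobian: %d active correspondences for %d unknowns: underdetermined",
      na, npar))
  th <- theta_unpack(theta, scaled)
  R <- quat_rotmat_raw(th$q)
  dR <- quat_rotmat_grad(th$q)
  A <- matrix(0, 2 * na, npar)
  r <- numeric(2 * na)
  row <- 0L
  for (k in seq_along(cameras)) {
    act <- corr$active[[k]]
    if (!any(act)) next
    cam <- cameras[[k]]
    idx <- corr$model_idx[[k]][act]
    p0 <- pts[idx, , drop = FALSE]
    centred <- sweep(p0, 2, cbar)
    s <- sweep(centred * th$lam, 2, cbar, "+")
    P <- sweep(s %*% t(R), 2, th$t, "+")
    uvw <- sweep(P, 2, cam$C) %*% t(cam$M)
    xy <- cbind(cam$xp - cam$c * uvw[, 1] / uvw[, 3],
                cam$yp - cam$c * uvw[, 2] / uvw[, 3])
    d <- cam$distortion(xy[, 1], xy[, 2])
    xy <- xy + cbind(d$dx, d$dy)
    master <- corr$master[[k]][act, , drop = FALSE]
    n <- nrow(p0)
    u <- uvw[, 1]; v <- uvw[, 2]; w <- uvw[, 3]
    # dx/dP = (-c/w) M1 + (c u / w^2) M3, dy/dP likewise with M2 and v
    dxdP <- outer(-cam$c / w, cam$M[1, ]) + outer(cam$c * u / w^2, cam$M[3, ])
    dydP <- outer(-cam$c / w, cam$M[2, ]) + outer(cam$c * v / w^2, cam$M[3, ])
    Ax <- matrix(0, n, npar); Ay <- matrix(0, n, npar)
    Ax[, 1:3] <- dxdP; Ay[, 1:3] <- dydP          # dP/dt = I
    for (j in 1:4) {
      dPq <- s %*% t(dR[[j]])                     # dP/dq_j = dR_j s
      Ax[, 3 + j] <- rowSums(dxdP * dPq)
      Ay[, 3 + j] <- rowSums(dydP * dPq)
    }
    if (scaled) {
      dPl <- centred %*% t(R)                     # dP/dlam = R (p0 - cbar)
      Ax[, 8] <- rowSums(dxdP * dPl)
      Ay[, 8] <- rowSums(dydP * dPl)
    }
    rows <- row + seq_len(2 * n)
    A[rows[c(TRUE, FALSE)], ] <- Ax
    A[rows[c(FALSE, TRUE)], ] <- Ay
    r[rows[c(TRUE, FALSE)]] <- xy[, 1] - master[, 1]
    r[rows[c(FALSE, TRUE)]] <- xy[, 2] - master[, 2]
    row <- row + 2L * n
  }
  g_row <- c(0, 0, 0, 2 * th$q, if (scaled) 0)
  list(A = A, r = r, g_row = g_row, g_val = sum(th$q^2))
}

#' One constrained Gauss-Newton step
#'
#' Solves the linearised problem with the unit-quaternion condition appended
#' as a heavily weighted pseudo-observation, optionally with
#' Levenberg-Marquardt damping added to the normal matrix.
#'
#' @param A design matrix (rows = residuals, columns = parameters).
#' @param r residual vector, px.
#' @param g_row constraint gradient row.
#' @param g_val current constraint value (target 1).
#' @param weight weight of the constraint pseudo-observation.
#' @param damping non-negative LM damping added as `damping * diag`.
#' @return parameter update vector.
#' @export
solve_constrained_step <- function(A, r, g_row, g_val, weight = 1e6,
                                   damping = 0) {
  Aaug <- rbind(A, weight * g_row)
  baug <- -c(r, weight * (g_val - 1))
  if (damping > 0) {
    Aaug <- rbind(Aaug, sqrt(damping) * diag(ncol(A)))
    baug <- c(baug, numeric(ncol(A)))
  }
  qrd <- qr(Aaug)
  if (qrd$rank < ncol(A)) {
    null_dir <- qr.Q(qr(t(Aaug)), complete = TRUE)[, ncol(A), drop = TRUE]
    stop(sprintf(
      "solve_constrained_step: rank-deficient normal matrix (rank %d of %d); null direction ~ (%s)",
      qrd$rank, ncol(A), paste(signif(null_dir, 3), collapse = ", ")))
  }
  qr.coef(qrd, baug)
}

#' Reject correspondences by the 3-sigma rule
#'
#' Pairs whose residual distance exceeds the mean distance by more than `k`
#' times the standard deviation of all active residual distances are flagged
#' inactive (batch rule: mean and deviation are computed once over the
#' current active set; only unusually large residuals are mismatches).
#' Idempotent once no pair exceeds the threshold, and a set of equal
#' residual distances rejects nothing.
#'
#' @param corr a [correspondence_set()].
#' @param residuals residual vector in the layout of [build_jacobian()]
#'   (x, y interleaved over active pairs, cameras concatenated).
#' @param k rejection multiplier (3 in the standard rule).
#' @return the correspondence set with rejected pairs deactivated.
#' @export
reject_outliers <- function(corr, residuals, k = 3) {
  stopifnot(length(residuals) == 2 * n_active(corr))
  d <- sqrt(residuals[c(TRUE, FALSE)]^2 + residuals[c(FALSE, TRUE)]^2)
  if (length(d) < 2) stop("reject_outliers: need at least 2 active pairs")
  thr <- mean(d) + k * stats::sd(d)
  bad <- d > thr
  if (all(bad)) stop("reject_outliers: all pairs rejected; degenerate data")
  pos <- 0L
  for (kk in seq_along(corr$active)) {
    act_idx <- which(corr$active[[kk]])
    nn <- length(act_idx)
    if (nn == 0) next
    corr$active[[kk]][act_idx[bad[pos + seq_len(nn)]]] <- FALSE
    pos <- pos + nn
  }
  corr
}

# one-to-one matching of projected model points to extracted targets by
# point-to-point distance: greedy global assignment over the distance
# matrix, so every bead pairs up (no observations are discarded at poor
# poses, which would reward degenerate matchings during initialisation)
match_projected_to_master <- function(xy_model, master) {
  nm <- nrow(xy_model); nk <- nrow(master)
  if (nk == 0 || nm == 0)
    return(list(model = integer(0), master = integer(0)))
  d2 <- outer(xy_model[, 1], master[, 1], "-")^2 +
    outer(xy_model[, 2], master[, 2], "-")^2
  ord <- order(d2)
  mi <- ((ord - 1) %% nm) + 1L
  ki <- ((ord - 1) %/% nm) + 1L
  used_m <- logical(nm); used_k <- logical(nk)
  model <- integer(0); mast <- integer(0)
  for (t in seq_along(ord)) {
    if (used_m[mi[t]] || used_k[ki[t]]) next
    used_m[mi[t]] <- TRUE; used_k[ki[t]] <- TRUE
    model <- c(model, mi[t]); mast <- c(mast, ki[t])
    if (all(used_m) || all(used_k)) break
  }
  o <- order(model)
  list(model = model[o], master = mast[o])
}

solver_options <- function(opts = list()) {
  defaults <- list(max_iter = 100L, tol = 1e-8, outlier_k = 3,
                   constraint_weight = 1e6, max_outer = 30L,
                   min_pairs = 4L)
  defaults[names(opts)] <- opts
  defaults
}

# inner loop: damped constrained Gauss-Newton to convergence at fixed
# correspondence, with per-round batch 3-sigma rejection
solve_pose <- function(theta, cloud, cameras, corr, scaled, opts) {
  iters <- 0L
  repeat {
    qp <- quat_pose(theta[1], theta[2], theta[3], theta[4:7])
    theta[4:7] <- qp$q
    lam <- if (scaled) theta[length(theta)] else NULL
    converged <- FALSE
    for (it in seq_len(opts$max_iter)) {
      J <- build_jacobian(qp, lam, cloud, cameras, corr)
      obj <- sum(J$r^2)
      damping <- 0
      repeat {
        dx <- solve_constrained_step(J$A, J$r, J$g_row, J$g_val,
                                     weight = opts$constraint_weight,
                                     damping = damping)
        cand <- theta + dx
        cand[4:7] <- cand[4:7] / sqrt(sum(cand[4:7]^2))
        r_new <- reproj_residuals(cand, cloud$points, cloud$centroid,
                                  cameras, corr, scaled)
        if (sum(r_new^2) <= obj + 1e-12 || damping > 1e8) break
        damping <- if (damping == 0) 1e-4 * max(diag(crossprod(J$A))) else damping * 10
      }
      theta <- cand
      qp <- quat_pose(theta[1], theta[2], theta[3], theta[4:7])
      theta[4:7] <- qp$q
      if (scaled) lam <- theta[length(theta)]
      iters <- iters + 1L
      if (max(abs(dx)) < opts$tol) { converged <- TRUE; break }
    }
    # batch 3-sigma rejection, then re-solve if anything was removed
    r_fin <- reproj_residuals(theta, cloud$points, cloud$centroid,
                              cameras, corr, scaled)
    before <- n_active(corr)
    corr2 <- tryCatch(reject_outliers(corr, r_fin, k = opts$outlier_k),
                      error = function(e) corr)
    if (n_active(corr2) == before || n_active(corr2) < opts$min_pairs) {
      return(list(theta = theta, corr = corr, converged = converged,
                  iterations = iters, residuals = r_fin))
    }
    corr <- corr2
  }
}

# covariance of (t, q[, lam]) from the weighted-constraint normal matrix,
# scaled by the a-posteriori variance factor
pose_covariance <- function(J, opts, scaled) {
  n_par_eff <- 6L + as.integer(scaled)
  red <- length(J$r) - n_par_eff
  s0_2 <- if (red > 0) sum(J$r^2) / red else NA_real_
  N <- crossprod(J$A) + opts$constraint_weight^2 * tcrossprod(J$g_row)
  Q <- tryCatch(solve(N), error = function(e) matrix(NA_real_, nrow(N), ncol(N)))
  list(cov = s0_2 * Q, s0_2 = s0_2, redundancy = red)
}

# propagate quaternion covariance to Euler angles (degrees) numerically
param_sigmas <- function(cov, theta, scaled) {
  if (any(!is.finite(cov))) {
    out <- rep(NA_real_, 6 + as.integer(scaled))
  } else {
    q <- theta[4:7]
    euler_of <- function(qq) matrix_to_euler(quat_to_matrix(qq))
    Jq <- matrix(0, 3, 4)
    h <- 1e-7
    for (j in 1:4) {
      qp <- q; qm <- q
      qp[j] <- qp[j] + h; qm[j] <- qm[j] - h
      Jq[, j] <- (euler_of(qp) - euler_of(qm)) / (2 * h)
    }
    cov_ang <- Jq %*% cov[4:7, 4:7] %*% t(Jq)
    out <- c(sqrt(pmax(0, diag(cov)[1:3])),
             sqrt(pmax(0, diag(cov_ang))) * 180 / pi,
             if (scaled) sqrt(max(0, diag(cov)[8])))
  }
  names(out) <- c("X", "Y", "Z", "omega", "phi", "kappa",
                  if (scaled) "lam")
  out
}

finalize_result <- function(theta, cloud, cameras, corr, scaled, opts,
                            converged, iterations, n_total_pairs) {
  qp <- quat_pose(theta[1], theta[2], theta[3], theta[4:7])
  lam <- if (scaled) theta[length(theta)] else NULL
  if (scaled && (lam < 0.5 || lam > 2))
    warning(sprintf("implausible scale factor %.4f (outside [0.5, 2])", lam))
  J <- build_jacobian(qp, lam, cloud, cameras, corr)
  cv <- pose_covariance(J, opts, scaled)
  sig <- param_sigmas(cv$cov, theta, scaled)
  a <- matrix_to_euler(quat_to_matrix(qp$q))
  structure(list(
    pose = pose(theta[1], theta[2], theta[3], a[1], a[2], a[3], degrees = FALSE),
    quat_pose = qp,
    lam = if (scaled) lam else NULL,
    rms_2d = sqrt(mean(J$r^2)),
    objective = sum(J$r^2),
    sigma = sig,
    covariance = cv$cov,
    iterations = iterations,
    converged = converged,
    n_rejected = n_total_pairs - n_active(corr),
    correspondence = corr,
    residuals = J$r,
    cloud = cloud,
    cameras = cameras,
    mode = if (scaled) "scaled" else "rigid"
  ), class = "bv_registration")
}

#' @export
print.bv_registration <- function(x, ...) {
  cat(sprintf("%s-mode registration (%s, %d iterations)\n", x$mode,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(x$pose)
  if (!is.null(x$lam)) cat(sprintf("  scale lambda = %.6f\n", x$lam))
  cat(sprintf("  rms 2D residual = %.4g px over %d pairs (%d rejected)\n",
              x$rms_2d, n_active(x$correspondence), x$n_rejected))
  cat("  parameter sigmas:", paste(names(x$sigma), signif(x$sigma, 3),
                                   sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' One-step projection registration
#'
#' Registers a model point cloud to measured 2D points in two (or more)
#' cameras by directly minimising the 2D reprojection distances. The outer
#' loop alternates (a) projecting the model at the current pose, (b)
#' nearest-point one-to-one correspondence with the measured master points,
#' (c) a quaternion-constrained damped Gauss-Newton solve, and (d) batch
#' 3-sigma outlier rejection, until the matching is stable and parameter
#' updates fall below tolerance.
#'
#' @param cloud model `bv_cloud` (for marker-based registration, the bead
#'   cloud).
#' @param cameras list of `bv_camera`.
#' @param master list per camera of N_k x 2 measured image points, px.
#' @param init initial `bv_pose` (e.g. from [coarse_search()]).
#' @param mode `"rigid"` or `"scaled"` (adds the centroid-anchored scale
#'   factor as an eighth unknown).
#' @param opts list of solver options: `max_iter` (inner iterations, 100),
#'   `tol` (update tolerance, 1e-8), `outlier_k` (3), `constraint_weight`
#'   (1e6), `max_outer` (outer matching rounds, 30).
#' @return object of class `bv_registration`.
#' @export
register <- function(cloud, cameras, master, init = pose(),
                     mode = c("rigid", "scaled"), opts = list()) {
  mode <- match.arg(mode)
  scaled <- mode == "scaled"
  opts <- solver_options(opts)
  if (nrow(cloud$points) < 3) stop("register: need at least 3 model points")
  qp <- as_quat_pose(init)
  theta <- theta_pack(qp, if (scaled) 1)
  prev_match <- NULL
  result <- NULL
  iters_total <- 0L
  converged <- FALSE
  n_pairs_matched <- NA_integer_
  for (outer in seq_len(opts$max_outer)) {
    P <- transform_model(theta, cloud$points, cloud$centroid, scaled)
    corr_master <- vector("list", length(cameras))
    corr_idx <- vector("list", length(cameras))
    for (k in seq_along(cameras)) {
      xy <- project_points(cameras[[k]], P)
      m <- match_projected_to_master(xy, master[[k]])
      corr_master[[k]] <- master[[k]][m$master, , drop = FALSE]
      corr_idx[[k]] <- m$model
    }
    if (sum(lengths(corr_idx)) < opts$min_pairs)
      stop(sprintf("register: only %d correspondences; need >= %d",
                   sum(lengths(corr_idx)), opts$min_pairs))
    corr <- correspondence_set(corr_master, corr_idx)
    n_pairs_matched <- n_active(corr)   # pairs offered to the final solve
    sol <- solve_pose(theta, cloud, cameras, corr, scaled, opts)
    theta_change <- max(abs(sol$theta - theta))
    theta <- sol$theta
    iters_total <- iters_total + sol$iterations
    match_sig <- lapply(corr_idx, identity)
    if (!is.null(prev_match) && identical(match_sig, prev_match) &&
        theta_change < max(opts$tol, 1e-10) * 10) {
      converged <- sol$converged
      result <- sol
      break
    }
    prev_match <- match_sig
    result <- sol
    converged <- sol$converged
  }
  finalize_result(theta, cloud, cameras, result$corr, scaled, opts,
                  converged, iters_total, n_pairs_matched)
}

#' Average per-epoch scale and re-register with the scale fixed
#'
#' Utility mirroring the constant-scale-factor workflow: run scaled-mode
#' registration over a trial's epochs, average the estimated scale factors,
#' then re-run each epoch with the scale frozen at the average (the model
#' cloud is pre-scaled about its centroid and registered rigidly).
#'
#' @param cloud model `bv_cloud`.
#' @param cameras list of `bv_camera`.
#' @param master_by_epoch list per epoch of per-camera master point lists.
#' @param inits list of initial poses (recycled if length 1).
#' @param opts solver options, as in [register()].
#' @return list with `lam_bar` (averaged scale), `per_epoch_lam` and
#'   `results` (fixed-scale registrations).
#' @export
fit_constant_scale <- function(cloud, cameras, master_by_epoch, inits,
                               opts = list()) {
  n <- length(master_by_epoch)
  if (length(inits) == 1) inits <- rep(inits, n)
  lams <- numeric(n)
  for (e in seq_len(n)) {
    r <- register(cloud, cameras, master_by_epoch[[e]], inits[[e]],
                  mode = "scaled", opts = opts)
    lams[e] <- r$lam
  }
  lam_bar <- mean(lams)
  scaled_cloud <- point_cloud(
    sweep(sweep(cloud$points, 2, cloud$centroid) * lam_bar, 2,
          cloud$centroid, "+"), cloud$bead_indices)
  results <- lapply(seq_len(n), function(e)
    register(scaled_cloud, cameras, master_by_epoch[[e]], inits[[e]],
             mode = "rigid", opts = opts))
  list(lam_bar = lam_bar, per_epoch_lam = lams, results = results)
}

#' Horn's closed-form absolute orientation
#'
#' Least-squares rigid transform between matched 3D point sets by the
#' quaternion eigenvector method: the rotation quaternion is the eigenvector
#' of the 4x4 cross-covariance form with the largest eigenvalue, and the
#' translation follows from the centroids. Minimises
#' `sum ||Q_i - (R P_i + t)||^2`.
#'
#' @param P,Q matched N x 3 point sets (N >= 3, not collinear); the
#'   transform maps `P` onto `Q`.
#' @return a `bv_pose`.
#' @export
horn_absolute_orientation <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  if (nrow(P) < 3) stop("horn_absolute_orientation: need >= 3 point pairs")
  Pb <- colMeans(P); Qb <- colMeans(Q)
  Pc <- sweep(P, 2, Pb); Qc <- sweep(Q, 2, Qb)
  if (svd(Pc)$d[2] < 1e-9 * max(svd(Pc)$d[1], 1))
    stop("horn_absolute_orientation: degenerate (collinear) configuration")
  S <- crossprod(Pc, Qc)   # S[a, b] = sum P_a Q_b
  N4 <- rbind(
    c(S[1,1] + S[2,2] + S[3,3], S[2,3] - S[3,2], S[3,1] - S[1,3], S[1,2] - S[2,1]),
    c(S[2,3] - S[3,2], S[1,1] - S[2,2] - S[3,3], S[1,2] + S[2,1], S[3,1] + S[1,3]),
    c(S[3,1] - S[1,3], S[1,2] + S[2,1], -S[1,1] + S[2,2] - S[3,3], S[2,3] + S[3,2]),
    c(S[1,2] - S[2,1], S[3,1] + S[1,3], S[2,3] + S[3,2], -S[1,1] - S[2,2] + S[3,3]))
  eg <- eigen(N4, symmetric = TRUE)
  q <- eg$vectors[, 1]
  R <- quat_to_matrix(q)
  t <- Qb - as.numeric(R %*% Pb)
  a <- matrix_to_euler(R)
  pose(t[1], t[2], t[3], a[1], a[2], a[3], degrees = FALSE)
}

#' Two-step RSA registration baseline
#'
#' The classical Roentgen stereophotogrammetry pipeline: each bead is first
#' triangulated from its stereo image pair, then the rigid transform from
#' the model beads to the triangulated beads is found by Horn's method. The
#' reported 2D RMS reprojects the resulting pose. Correspondence between
#' model beads and image measurements is given by row order; beads missing
#' (NA) in either camera are excluded with a warning.
#'
#' @param beads `bv_cloud` of model bead positions.
#' @param cameras list of two `bv_camera`.
#' @param master list of two N x 2 matrices, rows aligned with the bead
#'   cloud (NA rows for unobserved beads).
#' @return a `bv_registration` (no covariance-based sigmas).
#' @export
rsa_register <- function(beads, cameras, master) {
  stopifnot(length(cameras) == 2, length(master) == 2)
  n <- nrow(beads$points)
  ok <- stats::complete.cases(master[[1]]) & stats::complete.cases(master[[2]])
  if (any(!ok)) warning(sprintf("rsa_register: excluding %d bead(s) missing in a camera",
                                sum(!ok)))
  if (sum(ok) < 3) stop("rsa_register: fewer than 3 usable beads")
  tri <- triangulate(cameras[[1]], cameras[[2]],
                     master[[1]][ok, 1], master[[1]][ok, 2],
                     master[[2]][ok, 1], master[[2]][ok, 2])
  p <- horn_absolute_orientation(beads$points[ok, , drop = FALSE], tri)
  moved <- apply_rigid(p, beads)
  res <- c()
  for (k in 1:2) {
    xy <- project_points(cameras[[k]], moved$points[ok, , drop = FALSE])
    res <- c(res, as.numeric(t(xy - master[[k]][ok, , drop = FALSE])))
  }
  corr <- correspondence_set(lapply(master, function(m) m[ok, , drop = FALSE]),
                             list(which(ok), which(ok)))
  structure(list(
    pose = p, quat_pose = as_quat_pose(p), lam = NULL,
    rms_2d = sqrt(mean(res^2)), objective = sum(res^2),
    sigma = NULL, covariance = NULL, iterations = 1L, converged = TRUE,
    n_rejected = sum(!ok), correspondence = corr, residuals = res,
    cloud = beads, cameras = cameras, mode = "rsa"
  ), class = "bv_registration")
}

#' Accuracy report against a reference registration
#'
#' Differences of the six transformation parameters plus the RMS of
#' per-bead coordinate differences along each object axis and the Euclidean
#' distance RMS — the standard accuracy table of a marker-validated
#' model-based registration.
#'
#' @param result,truth `bv_registration` (or `bv_pose`) to compare; scale
#'   factors, when present, are applied to the bead positions.
#' @param beads `bv_cloud` of bead positions both poses refer to.
#' @return list with `dparams` (named: mm and degrees) and `rms` (named:
#'   X, Y, Z, distance; mm).
#' @export
accuracy_report <- function(result, truth, beads) {
  get_pose <- function(x) if (inherits(x, "bv_registration")) x$pose else x
  get_lam <- function(x) if (inherits(x, "bv_registration") && !is.null(x$lam))
    x$lam else 1
  pr <- get_pose(result); pt <- get_pose(truth)
  dparams <- c(pr$t - pt$t, (pr$angles - pt$angles) * 180 / pi)
  names(dparams) <- c("X", "Y", "Z", "omega", "phi", "kappa")
  br <- apply_scaled(pr, get_lam(result), beads)$points
  bt <- apply_scaled(pt, get_lam(truth), beads)$points
  d <- br - bt
  rms <- c(sqrt(colMeans(d^2)), distance = sqrt(mean(rowSums(d^2))))
  names(rms) <- c("X", "Y", "Z", "distance")
  list(dparams = dparams, rms = rms)
}
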