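# Estimator core: Jacobian correctness, constrained steps, outlier
# rejection, full registration recovery, Horn's method and the RSA baseline.

make_corr_from_truth <- function(beads, cameras, p, noise = 0, seed = NULL) {
  moved <- apply_rigid(p, beads)
  master <- lapply(cameras, function(cam) {
    xy <- project_points(cam, moved)
    if (noise > 0) xy <- xy + matrix(stats::rnorm(length(xy), sd = noise),
                                     nrow(xy), 2)
    xy
  })
  master
}

test_that("analytic Jacobian matches central finite differences", {
  set.seed(42)
  rig <- fixture_rig()
  beads <- fixture_beads()
  for (scaled in c(FALSE, TRUE)) {
    qp <- quat_pose(4, -6, 11, stats::rnorm(4))
    lam <- if (scaled) 0.97 else NULL
    master <- make_corr_from_truth(beads, rig, random_pose(tmax = 10),
                                   noise = 0.5, seed = 1)
    corr <- correspondence_set(master, list(1:7, 1:7))
    J <- build_jacobian(qp, lam, beads, rig, corr)
    theta <- c(qp$t, qp$q, lam)
    h <- 1e-6
    for (j in seq_along(theta)) {
      tp <- theta; tm <- theta
      tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
      fd <- (bvreg:::reproj_residuals(tp, beads$points, beads$centroid, rig,
                                      corr, scaled) -
             bvreg:::reproj_residuals(tm, beads$points, beads$centroid, rig,
                                      corr, scaled)) / (2 * h)
      expect_lt(max(abs(J$A[, j] - fd)), 1e-5)
    }
    # constraint row is the gradient of sum(q^2)
    expect_equal(J$g_row, c(0, 0, 0, 2 * qp$q, if (scaled) 0))
  }
  # at the identity quaternion the constraint row is (0,0,0,2,0,0,0)
  qp0 <- quat_pose(0, 0, 0, c(1, 0, 0, 0))
  master <- make_corr_from_truth(fixture_beads(), fixture_rig(), pose())
  corr <- correspondence_set(master, list(1:7, 1:7))
  J0 <- build_jacobian(qp0, NULL, fixture_beads(), fixture_rig(), corr)
  expect_equal(J0$g_row, c(0, 0, 0, 2, 0, 0, 0))
})

test_that("underdetermined systems are refused with counts", {
  rig <- fixture_rig()
  beads <- fixture_beads()
  master <- make_corr_from_truth(beads, rig, pose())
  corr <- correspondence_set(list(master[[1]][1, , drop = FALSE],
                                  master[[2]][1, , drop = FALSE]),
                             list(1L, 1L))
  expect_error(build_jacobian(quat_pose(), NULL, beads, rig, corr),
               "underdetermined")
})

test_that("constrained step is zero at a stationary point and linear in translation", {
  rig <- fixture_rig()
  beads <- fixture_beads()
  truth <- pose(2, 3, -4, 10, 5, -20)
  master <- make_corr_from_truth(beads, rig, truth)
  corr <- correspondence_set(master, list(1:7, 1:7))
  qp <- as_quat_pose(truth)
  J <- build_jacobian(qp, NULL, beads, rig, corr)
  dx <- solve_constrained_step(J$A, J$r, J$g_row, J$g_val)
  expect_lt(max(abs(dx)), 1e-9)

  # translation-only misfit: one step recovers the offset (problem linear)
  off <- pose(truth$t[1] + 1, truth$t[2] + 2, truth$t[3] + 3,
              truth$angles[1], truth$angles[2], truth$angles[3],
              degrees = FALSE)
  qp2 <- as_quat_pose(off)
  for (iter in 1:3) {   # a couple of Gauss-Newton steps absorb projective nonlinearity
    J2 <- build_jacobian(qp2, NULL, beads, rig, corr)
    dx2 <- solve_constrained_step(J2$A, J2$r, J2$g_row, J2$g_val)
    qp2 <- quat_pose(qp2$t[1] + dx2[1], qp2$t[2] + dx2[2], qp2$t[3] + dx2[3],
                     qp2$q + dx2[4:7])
  }
  expect_equal(qp2$t, truth$t, tolerance = 1e-6)
})

test_that("iterated steps reach the grid-search optimum near the truth", {
  set.seed(8)
  rig <- fixture_rig()
  beads <- fixture_beads()
  truth <- pose(1, -2, 3, 8, -12, 25)
  master <- make_corr_from_truth(beads, rig, truth, noise = 0.3)
  r <- register(beads, rig, master, init = pose(0, 0, 0, 5, -10, 20))
  # oracle: dense grid search over translations around the solution
  obj_of <- function(dx, dy, dz) {
    p <- pose(r$pose$t[1] + dx, r$pose$t[2] + dy, r$pose$t[3] + dz,
              r$pose$angles[1], r$pose$angles[2], r$pose$angles[3],
              degrees = FALSE)
    moved <- apply_rigid(p, beads)
    s <- 0
    for (k in 1:2) {
      xy <- project_points(rig[[k]], moved)
      s <- s + sum((xy - r$correspondence$master[[k]])^2)
    }
    s
  }
  g <- seq(-0.05, 0.05, by = 0.025)
  vals <- c()
  for (dx in g) for (dy in g) for (dz in g) vals <- c(vals, obj_of(dx, dy, dz))
  expect_lte(r$objective, min(vals) + 1e-9)
})

test_that("3-sigma rejection removes the constructed gross outlier only", {
  master1 <- cbind(seq(0, 1.9, by = 0.1), 0)   # 20 points
  corr <- correspondence_set(list(rbind(master1, c(5, 5))), list(1:21))
  # residuals: tight cluster of 20 at ~0.1 px, one at 5 px (50x)
  res <- as.numeric(rbind(c(stats::rnorm(20, 0.07, 0.005), 5),
                          rep(0, 21)))
  d <- sqrt(res[c(TRUE, FALSE)]^2 + res[c(FALSE, TRUE)]^2)
  # oracle by direct computation of the batch threshold
  expect_true(d[21] > mean(d) + 3 * stats::sd(d))
  expect_true(all(d[1:20] <= mean(d) + 3 * stats::sd(d)))
  out <- reject_outliers(corr, res)
  expect_equal(which(!out$active[[1]]), 21L)

  # all residuals equal: nothing rejected; idempotence
  res_eq <- rep(c(0.5, 0), 21)
  out2 <- reject_outliers(corr, res_eq)
  expect_true(all(out2$active[[1]]))
})

test_that("repeated rejection reaches a fixed point with gross outliers present", {
  set.seed(100)
  n <- 40
  d <- abs(stats::rnorm(n, 1, 0.1))
  d[1:4] <- d[1:4] * 25           # 10% gross outliers
  corr <- correspondence_set(list(cbind(seq_len(n), 0)), list(seq_len(n)))
  for (round in 1:5) {
    act <- corr$active[[1]]
    res <- as.numeric(rbind(d[act], rep(0, sum(act))))
    nxt <- tryCatch(reject_outliers(corr, res), error = function(e) corr)
    if (identical(nxt$active, corr$active)) break
    corr <- nxt
  }
  expect_lte(round, 5)
  rejected <- which(!corr$active[[1]])
  expect_true(all(1:4 %in% rejected))       # every gross outlier removed
  expect_lte(length(setdiff(rejected, 1:4)), 2)  # at most a tail inlier or two
})

test_that("noiseless marker registration is exact from the truth and from a perturbed start", {
  rig <- fixture_rig()
  beads <- fixture_beads()
  truth <- pose(3, -5, 8, 12, -25, 40)
  master <- make_corr_from_truth(beads, rig, truth)

  r0 <- register(beads, rig, master, init = truth)
  expect_true(r0$converged)
  expect_lt(r0$rms_2d, 1e-9)
  expect_equal(r0$pose$t, truth$t, tolerance = 1e-9)

  init <- pose(3 + 5, -5 - 5, 8 + 5, 12 + 5, -25 - 5, 40 + 5)
  r1 <- register(beads, rig, master, init = init)
  expect_true(r1$converged)
  expect_equal(r1$pose$t, truth$t, tolerance = 1e-6)
  expect_equal(r1$pose$angles * 180 / pi, truth$angles * 180 / pi,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("noisy registration is unbiased with plausible residual RMS", {
  set.seed(0)
  rig <- fixture_rig()
  beads <- fixture_beads()
  truth <- pose(2, 1, -3, 5, 10, -15)
  n_rep <- 100
  errs <- matrix(NA_real_, n_rep, 3)
  rms <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    master <- make_corr_from_truth(beads, rig, truth, noise = 0.5)
    r <- register(beads, rig, master, init = truth)
    errs[i, ] <- r$pose$t - truth$t
    rms[i] <- r$rms_2d
  }
  expect_gt(mean(rms), 0.25)
  expect_lt(mean(rms), 0.75)
  sem <- apply(errs, 2, stats::sd) / sqrt(n_rep)
  expect_true(all(abs(colMeans(errs)) < 3 * sem + 1e-9))
})

test_that("scaled mode recovers a known shrink factor and is unbiased at lam = 1", {
  rig <- fixture_rig()
  beads <- fixture_beads()
  truth <- pose(1, 2, 3, 10, 20, 30)
  lam_true <- 0.9923
  shrunk <- point_cloud(sweep(sweep(beads$points, 2, beads$centroid) * lam_true,
                              2, beads$centroid, "+"))
  master <- make_corr_from_truth(shrunk, rig, truth)
  r <- register(beads, rig, master, init = truth, mode = "scaled")
  expect_equal(r$lam, lam_true, tolerance = 1e-6)
  expect_equal(r$pose$t, truth$t, tolerance = 1e-5)

  # unshrunk model: lam-hat = 1
  master1 <- make_corr_from_truth(beads, rig, truth)
  r1 <- register(beads, rig, master1, init = truth, mode = "scaled")
  expect_equal(r1$lam, 1, tolerance = 1e-8)
})

test_that("fit_constant_scale averages per-epoch scales and re-registers rigidly", {
  rig <- fixture_rig()
  beads <- fixture_beads()
  lam_true <- 0.9923
  shrunk <- point_cloud(sweep(sweep(beads$points, 2, beads$centroid) * lam_true,
                              2, beads$centroid, "+"))
  set.seed(33)
  poses <- list(pose(1, 2, 3, 5, 0, 0), pose(1, 2, 3, 8, 0, 0),
                pose(1, 2, 3, 11, 0, 0))
  masters <- lapply(poses, function(p) make_corr_from_truth(shrunk, rig, p,
                                                            noise = 0.1))
  out <- fit_constant_scale(beads, rig, masters, inits = poses)
  expect_equal(out$lam_bar, lam_true, tolerance = 5e-4)
  expect_length(out$per_epoch_lam, 3)
  for (e in 1:3) {
    expect_true(out$results[[e]]$converged)
    expect_equal(out$results[[e]]$pose$t, poses[[e]]$t, tolerance = 0.1)
  }
})

test_that("Horn's method matches the SVD Procrustes oracle and beats random candidates", {
  set.seed(19)
  P <- fixture_beads()$points
  truth <- random_pose(tmax = 30)
  Q <- apply_rigid(truth, P)
  h <- horn_absolute_orientation(P, Q)
  expect_equal(pose_matrix(h), pose_matrix(truth), tolerance = 1e-10)
  expect_equal(h$t, truth$t, tolerance = 1e-9)

  # minimal 3-point case vs independent SVD orthogonal Procrustes
  P3 <- P[1:3, ]
  Q3 <- apply_rigid(truth, P3)
  h3 <- horn_absolute_orientation(P3, Q3)
  Pb <- colMeans(P3); Qb <- colMeans(Q3)
  S <- crossprod(sweep(P3, 2, Pb), sweep(Q3, 2, Qb))
  sv <- svd(S)
  Rsvd <- sv$v %*% diag(c(1, 1, det(sv$v %*% t(sv$u)))) %*% t(sv$u)
  expect_equal(pose_matrix(h3), Rsvd, tolerance = 1e-9)

  # noisy case: Horn objective below 1000 random candidate poses
  Qn <- Q + matrix(stats::rnorm(length(Q), sd = 0.3), nrow(P), 3)
  hn <- horn_absolute_orientation(P, Qn)
  obj <- function(p) sum((apply_rigid(p, P) - Qn)^2)
  best_random <- min(vapply(1:1000, function(i) obj(random_pose(tmax = 40)),
                            numeric(1)))
  expect_lt(obj(hn), best_random)

  expect_error(horn_absolute_orientation(cbind(1:5, 1:5, 1:5),
                                         cbind(2:6, 2:6, 2:6)), "collinear")
})

test_that("RSA equals the one-step method on noiseless data and trails it under noise", {
  rig <- fixture_rig()
  beads <- fixture_beads()
  truth <- pose(4, -2, 6, 15, -10, 35)
  master <- make_corr_from_truth(beads, rig, truth)
  rsa <- rsa_register(beads, rig, master)
  one <- register(beads, rig, master, init = truth)
  expect_equal(rsa$pose$t, one$pose$t, tolerance = 1e-9)
  expect_equal(pose_matrix(rsa$pose), pose_matrix(one$pose), tolerance = 1e-9)
  expect_lt(rsa$rms_2d, 1e-9)

  # with noise, the one-step fit attains a lower or equal reprojection RMS
  set.seed(1)
  wins <- 0
  for (i in 1:20) {
    m <- make_corr_from_truth(beads, rig, truth, noise = 0.5)
    a <- rsa_register(beads, rig, m)
    b <- register(beads, rig, m, init = truth)
    if (b$rms_2d <= a$rms_2d + 1e-12) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("a bead missing in one camera is excluded; under 3 beads errors", {
  rig <- fixture_rig()
  beads <- fixture_beads()
  truth <- pose(1, 1, 1, 5, 5, 5)
  master <- make_corr_from_truth(beads, rig, truth)
  master[[1]][3, ] <- NA
  expect_warning(r <- rsa_register(beads, rig, master), "excluding 1")
  expect_equal(r$pose$t, truth$t, tolerance = 1e-8)
  m2 <- lapply(master, function(m) { m[3:7, ] <- NA; m })
  expect_error(suppressWarnings(rsa_register(beads, rig, m2)), "fewer than 3")
})

test_that("accuracy_report decomposes parameter and bead errors", {
  beads <- fixture_beads()
  truth <- pose(1, 2, 3, 4, 5, 6)
  rep0 <- accuracy_report(truth, truth, beads)
  expect_true(all(rep0$dparams == 0) && all(rep0$rms == 0))

  shifted <- pose(1, 2, 3.5, 4, 5, 6)
  rep1 <- accuracy_report(shifted, truth, beads)
  expect_equal(unname(rep1$dparams["Z"]), 0.5)
  expect_equal(unname(rep1$rms["Z"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(rep1$rms["distance"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(rep1$rms[c("X", "Y")]), c(0, 0))

  # random perturbation: distance RMS equals direct per-bead computation
  set.seed(23)
  pert <- pose(1.1, 1.9, 3.2, 4.5, 4.7, 6.3)
  rep2 <- accuracy_report(pert, truth, beads)
  d <- apply_rigid(pert, beads)$points - apply_rigid(truth, beads)$points
  expect_equal(unname(rep2$rms["distance"]), sqrt(mean(rowSums(d^2))))
})

test_that("covariance-predicted sigmas shrink as 1/sqrt(k) under replication", {
  rig <- fixture_rig()
  beads <- fixture_beads()
  truth <- pose(0, 0, 0, 10, 20, 30)
  set.seed(2)
  qp <- as_quat_pose(truth)
  opts <- bvreg:::solver_options(list())
  master <- make_corr_from_truth(beads, rig, truth, noise = 0.5)
  sig_for <- function(k) {
    idx <- rep(1:7, k)
    cloudk <- point_cloud(beads$points[idx, ])
    # k independent noisy observations of each bead in each camera
    masterk <- lapply(rig, function(cam) {
      xy <- project_points(cam, apply_rigid(truth, beads))[idx, ]
      xy + matrix(stats::rnorm(length(xy), sd = 0.5), nrow(xy), 2)
    })
    corr <- correspondence_set(masterk, list(seq_along(idx), seq_along(idx)))
    J <- build_jacobian(qp, NULL, cloudk, rig, corr)
    cv <- bvreg:::pose_covariance(J, opts, FALSE)
    bvreg:::param_sigmas(cv$cov, c(qp$t, qp$q), FALSE)
  }
  s1 <- sig_for(1)
  s4 <- sig_for(4)
  expect_equal(unname(s1[1:3] / s4[1:3]), rep(2, 3), tolerance = 0.35)
})
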