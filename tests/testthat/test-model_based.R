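# Edge bank, thinning, outline extraction, one-to-one matching, the
# model-based driver and the back-projection precision metric.

disk_image <- function(n = 128, r = 40) {
  xs <- matrix(rep(0:(n - 1), each = n), n)
  ys <- matrix(rep(0:(n - 1), n), n)
  d <- sqrt((xs - (n - 1) / 2)^2 + (ys - (n - 1) / 2)^2)
  0.8 - 0.5 * (d <= r)
}

test_that("a one-filter bank equals plain canny and the union is a superset", {
  img <- disk_image()
  single <- multi_canny_bank(img, sigmas = 2, threshold_pairs = cbind(0.1, 0.3))
  expect_identical(single$edges, canny_edges(img, 2, 0.1, 0.3))

  bank <- multi_canny_bank(img, sigmas = c(1.5, 2, 3))
  for (s in c(1.5, 2, 3)) {
    lo <- exp(seq(log(0.05), log(0.2), length.out = 5))
    hi <- exp(seq(log(0.15), log(0.6), length.out = 5))
    for (tp in 1:5)
      expect_true(all(bank$edges[canny_edges(img, s, lo[tp], hi[tp])]))
  }
  expect_gte(sum(bank$edges), sum(single$edges))
  expect_error(multi_canny_bank(img, sigmas = numeric(0)), "empty")
})

test_that("larger smoothing sigma pulls the detected disk edge inward", {
  img <- disk_image(160, 50)
  bank <- multi_canny_bank(img, sigmas = c(2, 6),
                           threshold_pairs = cbind(0.1, 0.3))
  p <- bank$points
  r_of <- function(fid) {
    q <- p[p$filter_id == fid, ]
    mean(sqrt((q$x - 79.5)^2 + (q$y - 79.5)^2))
  }
  # filter 1 = sigma 2, filter 2 = sigma 6 (points deduped: sigma-6-only px)
  expect_lt(r_of(2), r_of(1) + 0.1)
})

test_that("thinning reduces thick lines to single chains and is idempotent", {
  thin_line <- matrix(0, 20, 20); thin_line[10, 3:17] <- 1
  expect_equal(thin_edges(thin_line), thin_line > 0)

  thick <- matrix(0, 20, 20); thick[9:11, 3:17] <- 1
  th <- thin_edges(thick)
  # single centreline away from the (eroded) endpoints
  expect_true(all(colSums(th[, 6:14]) == 1))
  expect_true(all(which(th, arr.ind = TRUE)[, 1] %in% 9:11))
  expect_identical(thin_edges(th), th)                  # idempotent
  # thinning only removes pixels
  expect_true(all(thick[th]== 1))
})

test_that("outline of a filled lattice is its perimeter and rings are connected", {
  # filled 10x10 lattice in 3D, projected by an orthographic-like camera
  g <- expand.grid(x = 0:9, y = 0:9)
  cloud <- point_cloud(cbind(g$x, g$y, 0))
  cam <- camera_model(5, 5, 500, 180, 0, 0, xp = 0, yp = 0, c = 500)
  ol <- project_outline(cam, pose(), 1, cloud, cell_px = 1)
  per <- g$x %in% c(0, 9) | g$y %in% c(0, 9)
  expect_setequal(ol$model_idx, which(per))

  # sphere-like cloud: outline is a closed ring, hull-consistent
  set.seed(3)
  sph <- point_cloud(bvreg:::sphere_points(1500) * 30)
  rig <- fixture_rig()
  ol2 <- project_outline(rig[[1]], pose(), 1, sph)
  xy_all <- project_points(rig[[1]], sph)
  hull <- grDevices::chull(xy_all)
  # every outline point within one cell of the hull polygon edge distance
  hx <- xy_all[hull, , drop = FALSE]
  d2seg <- function(p, a, b) {
    ab <- b - a; t <- pmax(0, pmin(1, sum((p - a) * ab) / sum(ab^2)))
    sqrt(sum((a + t * ab - p)^2))
  }
  for (i in seq_len(nrow(ol2$xy))) {
    dmin <- min(vapply(seq_len(nrow(hx)), function(j)
      d2seg(ol2$xy[i, ], hx[j, ], hx[(j %% nrow(hx)) + 1, ]), numeric(1)))
    expect_lt(dmin, 2 * ol2$cell_px)
  }
  # ring connectivity: each outline point has >= 2 neighbours within 3 cells
  # (diagonally adjacent boundary cells can put representatives up to
  # 2*sqrt(2) cells apart)
  dm <- as.matrix(stats::dist(ol2$xy))
  diag(dm) <- Inf
  expect_true(all(rowSums(dm <= 3 * ol2$cell_px) >= 2))
})

test_that("one-to-one matching follows the two-pass shortest-claim rule", {
  m <- match_one_to_one(rbind(c(0, 0), c(1, 0)), rbind(c(0.1, 0)))
  expect_equal(m$edge_idx, 1L)
  expect_equal(m$outline_idx, 1L)

  pts <- cbind(stats::runif(30), stats::runif(30))
  m2 <- match_one_to_one(pts, pts)
  expect_equal(m2$edge_idx, 1:30)
  expect_equal(m2$outline_idx, 1:30)
  expect_equal(max(m2$dist), 0)

  # brute-force oracle on random instances
  set.seed(41)
  for (rep in 1:100) {
    e <- cbind(stats::runif(50, 0, 10), stats::runif(50, 0, 10))
    o <- cbind(stats::runif(40, 0, 10), stats::runif(40, 0, 10))
    got <- match_one_to_one(e, o)
    # pass 1: each edge -> nearest outline; pass 2: keep shortest per outline
    claim <- integer(50); dist <- numeric(50)
    for (i in 1:50) {
      dd <- sqrt((o[, 1] - e[i, 1])^2 + (o[, 2] - e[i, 2])^2)
      claim[i] <- which.min(dd); dist[i] <- min(dd)
    }
    keep <- logical(50)
    for (j in unique(claim)) {
      who <- which(claim == j)
      keep[who[which.min(dist[who])]] <- TRUE
    }
    expect_equal(got$edge_idx, which(keep))
    expect_equal(got$outline_idx, claim[keep])
    expect_false(anyDuplicated(got$outline_idx) > 0)   # injective
  }
  expect_error(match_one_to_one(matrix(numeric(0), 0, 2), rbind(c(0, 0))),
               "empty")
})

test_that("model-based registration recovers a rendered pose from a 3 mm / 3 deg start", {
  ph <- make_phantom(4000, 7, seed = 4)
  rig <- make_rig(rig_spec(image_size = c(256, 256), c_px = 1700,
                           distance_mm = 1000))
  tr <- pose(2, -3, 4, 15, -10, 20)
  imgs <- lapply(rig, function(cam)
    render_silhouette_image(cam, ph, tr, edge_blur_sigma = 0.8,
                            noise_sd = 0.005, seed = 2, supersample = 4L)$image)
  init <- pose(2 + 3, -3 - 3, 4 + 3, 15 + 3, -10 - 3, 20 + 3)
  r <- register_model_based(imgs, ph, rig, init, mode = "rigid",
                            sigmas = c(1.5, 2, 2.5),
                            opts = list(max_iter = 30, tol = 1e-7))
  expect_true(r$converged)
  expect_true(all(abs(r$pose$t - tr$t) < 0.5))
  expect_true(all(abs(r$pose$angles - tr$angles) * 180 / pi < 0.5))
  expect_gte(r$n_rejected, 0)
})

test_that("edges taken from the true outline give exact recovery and zero precision metric", {
  ph <- make_phantom(2000, 6, seed = 9)
  rig <- make_rig(rig_spec(image_size = c(256, 256), c_px = 1700,
                           distance_mm = 1000))
  tr <- pose(-1, 2, -3, 8, 12, -6)
  edges <- lapply(rig, function(cam) project_outline(cam, tr, 1, ph)$xy)
  init <- pose(-1 + 2, 2 - 2, -3 + 2, 8 + 2, 12 - 2, -6 + 2)
  r <- register_model_based(NULL, ph, rig, init, mode = "rigid",
                            edges = edges, opts = list(tol = 1e-10))
  expect_true(r$converged)
  expect_lt(r$objective, 1e-12)
  expect_equal(r$pose$t, tr$t, tolerance = 1e-7)
  expect_equal(r$pose$angles, tr$angles, tolerance = 1e-7, ignore_attr = TRUE)

  prec <- precision_rms_3d(r)
  expect_lt(prec[["distance"]], 1e-8)

  # an injected 1 mm vertical offset appears ~1:1 in the metric (X is
  # perpendicular to both optical axes in this rig)
  r_off <- r
  r_off$pose <- pose(tr$t[1] + 1, tr$t[2], tr$t[3],
                     tr$angles[1], tr$angles[2], tr$angles[3], degrees = FALSE)
  prec_off <- precision_rms_3d(r_off)
  expect_equal(prec_off[["distance"]], 1, tolerance = 0.05)
  expect_equal(prec_off[["X"]], 1, tolerance = 0.05)
  expect_lt(prec_off[["Y"]], 0.2)

  # oracle: direct recomputation from rays
  lam <- 1
  moved <- apply_rigid(r_off$pose, ph)
  diffs <- NULL
  for (k in 1:2) {
    corr <- r_off$correspondence
    act <- corr$active[[k]]
    idx <- corr$model_idx[[k]][act]
    mp <- moved$points[idx, , drop = FALSE]
    mxy <- corr$master[[k]][act, , drop = FALSE]
    ray <- viewing_ray(rig[[k]], mxy[, 1], mxy[, 2])
    W <- point_depth(rig[[k]], mp)
    bp <- ray$dir * W + matrix(ray$origin, length(W), 3, byrow = TRUE)
    diffs <- rbind(diffs, bp - mp)
  }
  expect_equal(prec_off[["distance"]], sqrt(mean(rowSums(diffs^2))),
               tolerance = 1e-12)

  # metric invariant to relabeling the cameras
  r_sw <- r_off
  r_sw$cameras <- r_off$cameras[2:1]
  r_sw$correspondence <- structure(list(
    master = r_off$correspondence$master[2:1],
    model_idx = r_off$correspondence$model_idx[2:1],
    active = r_off$correspondence$active[2:1]), class = "bv_corr")
  expect_equal(precision_rms_3d(r_sw)[["distance"]], prec_off[["distance"]],
               tolerance = 1e-12)
})

test_that("a pre-shrunk model biases rigid depth more than scaled mode", {
  ph <- make_phantom(2000, 6, seed = 9)
  rig <- make_rig(rig_spec(image_size = c(256, 256), c_px = 1700,
                           distance_mm = 1000))
  tr <- pose(-1, 2, -3, 8, 12, -6)
  lam_true <- 0.992
  shrunk <- point_cloud(
    sweep(sweep(ph$points, 2, ph$centroid) * lam_true, 2, ph$centroid, "+"),
    ph$bead_indices)
  # edges rendered from the true-size bone; the registered model is shrunk
  edges <- lapply(rig, function(cam) project_outline(cam, tr, 1, ph)$xy)
  init <- pose(-1 + 2, 2 - 2, -3 + 2, 8 + 2, 12 - 2, -6 + 2)
  rr <- register_model_based(NULL, shrunk, rig, init, mode = "rigid",
                             edges = edges, opts = list(tol = 1e-9))
  rs <- register_model_based(NULL, shrunk, rig, init, mode = "scaled",
                             edges = edges, opts = list(tol = 1e-9))
  expect_equal(rs$lam, 1 / lam_true, tolerance = 2e-3)
  # depth here is the object Y axis (the rig's mean viewing direction)
  expect_gt(abs(rr$pose$t[2] - tr$t[2]), abs(rs$pose$t[2] - tr$t[2]))
})
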