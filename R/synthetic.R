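# Synthetic study fixtures: a bone-like phantom with surface beads, a
# two-camera convergent rig, rendered marker/silhouette radiographs and
# turntable-style trials. All generators are pure functions of their
# arguments and a seed.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic biplanar rig
#'
#' @param angle_deg inter-axis angle between the two optical axes, degrees,
#'   in (0, 180).
#' @param distance_mm source-to-object distance, mm.
#' @param c_px principal distance, px.
#' @param image_size image width and height, px.
#' @return object of class `bv_rig_spec`.
#' @export
rig_spec <- function(angle_deg = 60, distance_mm = 1000, c_px = 2800,
                     image_size = c(1008, 1008)) {
  if (angle_deg <= 0 || angle_deg >= 180) stop("rig_spec: angle must be in (0, 180)")
  if (any(image_size <= 0)) stop("rig_spec: image size must be positive")
  structure(list(angle_deg = angle_deg, distance_mm = distance_mm,
                 c_px = c_px, image_size = as.integer(image_size)),
            class = "bv_rig_spec")
}

# camera looking at the origin from position C, with +X (object, vertical)
# kept close to image "up"; third rotation row is the unit viewing direction
# (camera toward origin) so that depth W is positive for points near the origin
look_at_origin <- function(C, xp, yp, c_px, image_size) {
  w <- -C / sqrt(sum(C^2))
  up <- c(1, 0, 0)
  u <- c(up[2] * w[3] - up[3] * w[2],
         up[3] * w[1] - up[1] * w[3],
         up[1] * w[2] - up[2] * w[1])  # up x w
  u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])    # w x u
  M <- rbind(u, v, w)
  a <- matrix_to_euler(M)
  cam <- camera_model(C[1], C[2], C[3], a[1], a[2], a[3],
                      xp = xp, yp = yp, c = c_px, degrees = FALSE)
  cam$image_size <- as.integer(image_size)
  cam
}

#' Build a two-camera convergent rig
#'
#' Places two cameras in the Y-Z plane at the spec's source-to-object
#' distance, optical axes converging on the origin and separated by the
#' inter-axis angle; the mean viewing (depth) direction is the object-space
#' Y axis and X is the vertical axis. Principal points sit at the image
#' centre. Errors if a nominal phantom-sized sphere (radius
#' `phantom_radius_mm`) would not fit in frame.
#'
#' @param spec a [rig_spec()].
#' @param phantom_radius_mm nominal phantom radius used for the
#'   field-of-view check, mm.
#' @return list of two `bv_camera` objects.
#' @export
make_rig <- function(spec, phantom_radius_mm = 60) {
  stopifnot(inherits(spec, "bv_rig_spec"))
  half <- spec$angle_deg / 2 * pi / 180
  D <- spec$distance_mm
  C1 <- D * c(0, cos(half), sin(half))
  C2 <- D * c(0, cos(half), -sin(half))
  xp <- (spec$image_size[1] - 1) / 2
  yp <- (spec$image_size[2] - 1) / 2
  span_px <- 2 * spec$c_px * phantom_radius_mm / D
  if (span_px > min(spec$image_size) * 0.95)
    stop("make_rig: phantom would not fit in frame at the nominal distance")
  list(look_at_origin(C1, xp, yp, spec$c_px, spec$image_size),
       look_at_origin(C2, xp, yp, spec$c_px, spec$image_size))
}

# sample n points uniformly on a unit sphere
sphere_points <- function(n) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

#' Generate a bone-like phantom point cloud with surface beads
#'
#' Surface points are sampled on the union of an elongated tri-axial
#' ellipsoid (the shaft) and two unequal spherical condyles at one end;
#' the unequal condyles make the shape asymmetric so that all rotations are
#' identifiable. Beads are chosen on the surface by farthest-point sampling
#' subject to a minimum mutual separation, mimicking fiducial steel beads
#' glued to a printed bone.
#'
#' @param n_surface_points number of surface points.
#' @param n_beads number of fiducial beads (>= 3).
#' @param shape `"bone"` (ellipsoid + condyles) or `"ellipsoid"`.
#' @param seed RNG seed; the generator is deterministic given the seed.
#' @param min_bead_sep_mm minimum mutual bead separation, mm.
#' @return a `bv_cloud` with `bead_indices` marking the beads.
#' @export
make_phantom <- function(n_surface_points = 2000, n_beads = 7,
                         shape = c("bone", "ellipsoid"), seed = 1,
                         min_bead_sep_mm = 15) {
  shape <- match.arg(shape)
  if (n_beads < 3) stop("make_phantom: need at least 3 beads")
  ax <- c(22, 18, 55)                       # ellipsoid semi-axes, mm
  cond <- list(list(c = c(10, 6, 48), r = 14),
               list(c = c(-12, 4, 52), r = 11))
  inside_ell <- function(p) sum((p / ax)^2) < 1 - 1e-9
  inside_cond <- function(p) any(vapply(cond, function(s)
    sum((p - s$c)^2) < s$r^2 * (1 - 1e-9), logical(1)))
  with_seed(seed, {
    pts <- matrix(NA_real_, 0, 3)
    if (shape == "bone") {
      n_ell <- round(n_surface_points * 0.75)
      n_c <- c(round(n_surface_points * 0.15), n_surface_points)
    } else {
      n_ell <- n_surface_points
      n_c <- c(0, 0)
    }
    while (nrow(pts) < n_ell) {
      cand <- sphere_points(n_ell) * rep(ax, each = n_ell)
      keep <- !apply(cand, 1, inside_cond)
      pts <- rbind(pts, cand[keep, , drop = FALSE])
    }
    pts <- pts[seq_len(n_ell), , drop = FALSE]
    if (shape == "bone") {
      for (k in 1:2) {
        need <- if (k == 1) n_c[1] else n_surface_points - nrow(pts)
        got <- matrix(NA_real_, 0, 3)
        while (nrow(got) < need) {
          cand <- sphere_points(max(need, 50)) * cond[[k]]$r
          cand <- sweep(cand, 2, cond[[k]]$c, "+")
          other <- cond[[if (k == 1) 2 else 1]]
          keep <- !apply(cand, 1, inside_ell) &
            rowSums(sweep(cand, 2, other$c)^2) > other$r^2
          got <- rbind(got, cand[keep, , drop = FALSE])
        }
        pts <- rbind(pts, got[seq_len(need), , drop = FALSE])
      }
    }
    pts <- pts[seq_len(n_surface_points), , drop = FALSE]
    # farthest-point sampling for beads with a separation floor
    sep <- min_bead_sep_mm
    repeat {
      idx <- integer(0)
      d2min <- rep(Inf, nrow(pts))
      cur <- 1L
      for (b in seq_len(n_beads)) {
        idx <- c(idx, cur)
        d2 <- rowSums(sweep(pts, 2, pts[cur, ])^2)
        d2min <- pmin(d2min, d2)
        cur <- which.max(d2min)
        if (b < n_beads && sqrt(d2min[cur]) < sep) {
          idx <- NULL
          break
        }
      }
      if (!is.null(idx)) break
      sep <- sep * 0.8
      if (sep < 1) stop("make_phantom: cannot place beads with feasible separation")
    }
    point_cloud(pts, bead_indices = idx)
  })
}

#' Specification of a simulated motion trial
#'
#' Emulates a turntable acquisition: the phantom rotates about the object
#' vertical (X) axis in fixed increments, with i.i.d. Gaussian pixel noise
#' added to the extracted 2D bead coordinates.
#'
#' @param n_epochs number of image pairs.
#' @param rot_increment_deg per-epoch rotation about the vertical axis, degrees.
#' @param noise_px standard deviation of 2D bead coordinate noise, px.
#' @param base_pose starting `bv_pose` at epoch 1.
#' @param seed RNG seed.
#' @return object of class `bv_trial_spec`.
#' @export
trial_spec <- function(n_epochs = 10, rot_increment_deg = 3, noise_px = 0.5,
                       base_pose = pose(), seed = 1) {
  if (n_epochs < 1) stop("trial_spec: need at least one epoch")
  if (noise_px < 0) stop("trial_spec: noise must be >= 0")
  structure(list(n_epochs = n_epochs, rot_increment_deg = rot_increment_deg,
                 noise_px = noise_px, base_pose = base_pose, seed = seed),
            class = "bv_trial_spec")
}

#' Simulate a biplanar trial
#'
#' Produces per-epoch ground-truth poses and the noisy 2D bead tracks seen
#' by each camera (i.i.d. Gaussian noise on the exact projections, the
#' injection point for estimator studies). Images are not rendered here;
#' see [render_marker_image()] and [render_silhouette_image()].
#'
#' @param spec a [trial_spec()].
#' @param phantom a `bv_cloud` with beads.
#' @param rig list of two `bv_camera`.
#' @return list with `poses` (list of `bv_pose`), `tracks` (list per epoch of
#'   list per camera of N x 2 matrices) and `truth_tracks` (noise-free).
#' @export
simulate_trial <- function(spec, phantom, rig) {
  stopifnot(inherits(spec, "bv_trial_spec"))
  beads <- bead_cloud(phantom)
  with_seed(spec$seed, {
    poses <- vector("list", spec$n_epochs)
    tracks <- vector("list", spec$n_epochs)
    truth <- vector("list", spec$n_epochs)
    b <- spec$base_pose
    for (e in seq_len(spec$n_epochs)) {
      ang <- b$angles * 180 / pi
      p <- pose(b$t[1], b$t[2], b$t[3],
                ang[1] + (e - 1) * spec$rot_increment_deg, ang[2], ang[3])
      poses[[e]] <- p
      moved <- apply_rigid(p, beads)
      truth[[e]] <- lapply(rig, function(cam) project_points(cam, moved))
      tracks[[e]] <- lapply(truth[[e]], function(xy)
        xy + matrix(stats::rnorm(length(xy), sd = spec$noise_px), nrow(xy), 2))
    }
    list(poses = poses, tracks = tracks, truth_tracks = truth)
  })
}

# block-mean downsample of a [s*H, s*W] matrix by factor s
downsample_block <- function(m, s) {
  if (s == 1) return(m)
  H <- nrow(m) / s; W <- ncol(m) / s
  dim(m) <- c(s, H * s * W)
  m <- colMeans(m)                      # over sub-rows
  a <- array(m, c(H, s, W))
  a <- aperm(a, c(2, 1, 3))
  dim(a) <- c(s, H * W)
  matrix(colMeans(a), H, W)
}

# image matrix convention: value at [row, col] is the pixel with image
# coordinates x = col - 1, y = row - 1 (0-based pixel centres)
blank_image <- function(image_size, value = 0) {
  matrix(value, nrow = image_size[2], ncol = image_size[1])
}

#' Render a synthetic marker radiograph
#'
#' Dark circular bead footprints on a bright, smoothly textured background,
#' rendered with 4x supersampling to control boundary aliasing. Optionally a
#' low-intensity band is placed over part of the image so beads there have
#' low contrast (the situation that motivates intensity enhancement).
#' The exact projected bead centres are returned as ground truth.
#'
#' @param camera a `bv_camera` with an `image_size`.
#' @param beads a `bv_cloud` of bead centres (object space, mm).
#' @param pose pose applied to the beads before projection.
#' @param bead_radius_mm physical bead radius, mm (3 mm diameter beads
#'   give 1.5).
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (image scale 0..1).
#' @param low_band optional `c(y_from, y_to)` rows (px) of a dark band where
#'   bead contrast collapses; `NULL` for none.
#' @param seed RNG seed for the noise.
#' @param supersample supersampling factor.
#' @return list with `image` (matrix in [0,1], rows = y, cols = x) and
#'   `centers` (N x 2 true projected centres, px).
#' @export
render_marker_image <- function(camera, beads, pose = NULL,
                                bead_radius_mm = 1.5, noise_sd = 0.01,
                                low_band = NULL, seed = 1, supersample = 4L) {
  if (is.null(camera$image_size)) stop("render_marker_image: camera has no image size")
  if (!is.null(pose)) beads <- apply_rigid(pose, beads)
  xy <- project_points(camera, beads)
  depth <- point_depth(camera, beads)
  r_px <- bead_radius_mm * camera$c / depth
  s <- as.integer(supersample)
  W <- camera$image_size[1]; H <- camera$image_size[2]
  img <- matrix(0, H * s, W * s)
  # smooth background texture, bright field
  xs <- (seq_len(W * s) - 1) / s; ys <- (seq_len(H * s) - 1) / s
  bg <- 0.78 + 0.06 * outer(sin(ys / H * 2 * pi), cos(xs / W * 2 * pi))
  img <- bg
  # low-intensity band with a smooth (raised-cosine) transition so the band
  # boundary itself produces no detectable edge, only a contrast collapse
  wband <- rep(0, length(ys))
  if (!is.null(low_band)) {
    ramp <- 6  # px transition half-width
    up <- (ys - (low_band[1] - ramp)) / (2 * ramp)
    dn <- ((low_band[2] + ramp) - ys) / (2 * ramp)
    wband <- pmin(pmax(pmin(up, dn), 0), 1)
    wband <- (1 - cos(pi * wband)) / 2
    img <- img * (1 - wband) + 0.22 * wband
  }
  for (i in seq_len(nrow(xy))) {
    cx <- xy[i, 1] * s + (s - 1) / 2
    cy <- xy[i, 2] * s + (s - 1) / 2
    rr <- r_px[i] * s
    c0 <- max(1, floor(cx - rr)); c1 <- min(W * s, ceiling(cx + rr) + 1)
    r0 <- max(1, floor(cy - rr)); r1 <- min(H * s, ceiling(cy + rr) + 1)
    if (c0 > c1 || r0 > r1) next
    cc <- (c0:c1) - 1; rrw <- (r0:r1) - 1
    d2 <- outer((rrw - cy)^2, (cc - cx)^2, "+")
    inside <- d2 <= rr^2
    # steel beads absorb nearly all radiation: a fixed dark level, so the
    # contrast collapses where the background itself is dark
    block <- img[r0:r1, c0:c1]
    block[inside] <- 0.15
    img[r0:r1, c0:c1] <- block
  }
  img <- downsample_block(img, s)
  img <- with_seed(seed,
    img + matrix(stats::rnorm(length(img), sd = noise_sd), nrow(img)))
  img[img < 0] <- 0; img[img > 1] <- 1
  list(image = img, centers = xy)
}

#' Render a synthetic silhouette radiograph
#'
#' Projects the full phantom cloud, fills the silhouette region on a
#' supersampled occupancy grid (morphological closing), optionally erodes
#' the silhouette inward by a fixed pixel offset (emulating the systematic
#' inward offset of smoothed edge detections), blurs the boundary and adds
#' intensity noise.
#'
#' @param camera a `bv_camera` with an `image_size`.
#' @param cloud the full phantom `bv_cloud`.
#' @param pose pose applied to the cloud before projection.
#' @param lam scale applied about the cloud centroid before the pose.
#' @param edge_blur_sigma Gaussian blur of the boundary, px.
#' @param inward_offset_px systematic inward offset of the rendered
#'   silhouette boundary, px (>= 0).
#' @param noise_sd additive Gaussian intensity noise sd.
#' @param seed RNG seed for the noise.
#' @param supersample supersampling factor.
#' @return list with `image` (matrix in [0,1]) and `mask` (logical
#'   silhouette at final resolution, before blur).
#' @export
render_silhouette_image <- function(camera, cloud, pose = NULL, lam = 1,
                                    edge_blur_sigma = 1, inward_offset_px = 0,
                                    noise_sd = 0.01, seed = 1, supersample = 2L) {
  if (is.null(camera$image_size)) stop("render_silhouette_image: camera has no image size")
  if (!is.null(pose)) cloud <- apply_scaled(pose, lam, cloud)
  xy <- project_points(camera, cloud)
  s <- as.integer(supersample)
  W <- camera$image_size[1]; H <- camera$image_size[2]
  occ <- matrix(0, H * s, W * s)
  cc <- round(xy[, 1] * s + (s - 1) / 2) + 1
  rr <- round(xy[, 2] * s + (s - 1) / 2) + 1
  ok <- cc >= 1 & cc <= W * s & rr >= 1 & rr <= H * s
  occ[cbind(rr[ok], cc[ok])] <- 1
  # close gaps between projected points, then take the filled silhouette;
  # the closing kernel must bridge the typical projected point spacing
  sub <- xy[unique(round(seq(1, nrow(xy), length.out = min(400, nrow(xy))))), ,
            drop = FALSE]
  dm <- as.matrix(stats::dist(sub)); diag(dm) <- Inf
  spacing <- stats::median(apply(dm, 1, min))
  k <- max(3L, 2L * as.integer(ceiling(s * max(1.5, 1.3 * spacing))) + 1L)
  kern <- EBImage::makeBrush(k, shape = "disc")
  closed <- EBImage::closing(occ, kern)
  filled <- EBImage::fillHull(closed)
  if (inward_offset_px > 0) {
    ke <- 2L * as.integer(round(inward_offset_px * s)) + 1L
    filled <- EBImage::erode(filled, EBImage::makeBrush(ke, shape = "disc"))
  }
  img <- 0.8 - 0.5 * as.matrix(filled)
  if (edge_blur_sigma > 0)
    img <- as.matrix(EBImage::gblur(img, sigma = edge_blur_sigma * s, boundary = "replicate"))
  img <- downsample_block(img, s)
  img <- with_seed(seed,
    img + matrix(stats::rnorm(length(img), sd = noise_sd), nrow(img)))
  img[img < 0] <- 0; img[img > 1] <- 1
  mask <- downsample_block(as.matrix(filled), s) > 0.5
  list(image = img, mask = mask)
}
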