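# Feature-based (model-based) registration front end: a multi-threshold
# Canny bank for robust bone-edge extraction, morphological thinning,
# projected-outline extraction with 3D index bookkeeping, one-to-one
# edge/outline matching, the full registration driver and the
# back-projection precision metric.

#' Multi-threshold Canny edge bank
#'
#' Runs a bank of Canny detectors (all combinations of the smoothing sigmas
#' and hysteresis threshold pairs) and overlays their edge maps. Radiograph
#' contrast is low and no single parameter set finds the whole bone edge;
#' the union is more complete than any single filter. The default bank is
#' 5 sigmas x 5 threshold pairs = 25 filters.
#'
#' @param image numeric matrix in [0, 1].
#' @param sigmas vector of Gaussian sigmas, px.
#' @param threshold_pairs 2-column matrix of (low, high) hysteresis pairs;
#'   default 5 pairs spaced geometrically between loose (0.05, 0.15) and
#'   strict (0.2, 0.6).
#' @return list with `edges` (logical union map) and `points` (data frame
#'   `x`, `y`, `filter_id`: every edge pixel with the provenance of the
#'   first filter that produced it).
#' @export
multi_canny_bank <- function(image, sigmas = 4:8, threshold_pairs = NULL) {
  if (length(sigmas) == 0) stop("multi_canny_bank: empty filter bank")
  if (is.null(threshold_pairs)) {
    lo <- exp(seq(log(0.05), log(0.2), length.out = 5))
    hi <- exp(seq(log(0.15), log(0.6), length.out = 5))
    threshold_pairs <- cbind(lo, hi)
  }
  threshold_pairs <- matrix(threshold_pairs, ncol = 2)
  union <- matrix(FALSE, nrow(image), ncol(image))
  px <- list()
  fid <- 0L
  for (s in sigmas) for (tp in seq_len(nrow(threshold_pairs))) {
    fid <- fid + 1L
    e <- canny_edges(image, sigma = s, low = threshold_pairs[tp, 1],
                     high = threshold_pairs[tp, 2])
    new <- e & !union
    if (any(new)) {
      w <- which(new, arr.ind = TRUE)
      px[[length(px) + 1L]] <- data.frame(x = w[, 2] - 1, y = w[, 1] - 1,
                                          filter_id = fid)
    }
    union <- union | e
  }
  pts <- if (length(px)) do.call(rbind, px) else
    data.frame(x = numeric(0), y = numeric(0), filter_id = integer(0))
  list(edges = union, points = pts)
}

# one sub-iteration of Zhang-Suen thinning, vectorised over the image
zs_subiter <- function(m, step) {
  p2 <- shift_mat(m, -1, 0); p3 <- shift_mat(m, -1, 1); p4 <- shift_mat(m, 0, 1)
  p5 <- shift_mat(m, 1, 1);  p6 <- shift_mat(m, 1, 0);  p7 <- shift_mat(m, 1, -1)
  p8 <- shift_mat(m, 0, -1); p9 <- shift_mat(m, -1, -1)
  B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
       (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
       (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
  if (step == 1) {
    cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
      (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
  } else {
    cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
      (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
  }
  m[cond] <- 0
  m
}

#' Thin an edge map to one-pixel-wide chains
#'
#' Zhang-Suen morphological thinning. Overlaying a bank of edge detectors
#' gives multiple responses to a single physical edge; thinning reduces
#' them to a single centreline. Idempotent, and only removes pixels.
#'
#' @param edges logical or 0/1 matrix.
#' @return logical matrix of the thinned edges.
#' @export
thin_edges <- function(edges) {
  m <- (edges > 0) + 0
  repeat {
    before <- sum(m)
    m <- zs_subiter(m, 1)
    m <- zs_subiter(m, 2)
    if (sum(m) == before) break
  }
  m > 0
}

#' Edge map as a point matrix
#' @param edges logical matrix.
#' @return N x 2 matrix of 0-based pixel coordinates (columns x, y).
#' @export
edge_points <- function(edges) {
  w <- which(edges, arr.ind = TRUE)
  cbind(x = w[, 2] - 1, y = w[, 1] - 1)
}

#' Outline of the projected model point cloud
#'
#' Projects the model cloud at a pose (and optional scale) and extracts the
#' points lying on the boundary of the projected set, using an occupancy
#' grid: a cell is a boundary cell if any of its 4 neighbours is empty; one
#' projected point per boundary cell is kept (the most outward one), carrying
#' its 3D model index. These outline points are the slave data matched
#' against detected image edges.
#'
#' @param camera a `bv_camera`.
#' @param p pose (`bv_pose` or `bv_quat_pose`).
#' @param lam scale factor about the model centroid.
#' @param cloud the model `bv_cloud`.
#' @param cell_px occupancy cell size, px; default 1.5x the median
#'   nearest-neighbour spacing of the projected points.
#' @return list with `xy` (M x 2 outline image points, px) and `model_idx`
#'   (their rows in the model cloud).
#' @export
project_outline <- function(camera, p, lam = 1, cloud, cell_px = NULL) {
  moved <- apply_scaled(p, lam, cloud)
  xy <- project_points(camera, moved)
  n <- nrow(xy)
  if (n < 3) stop("project_outline: degenerate projection")
  if (is.null(cell_px)) {
    sub <- xy[unique(round(seq(1, n, length.out = min(400, n)))), , drop = FALSE]
    dm <- as.matrix(stats::dist(sub)); diag(dm) <- Inf
    cell_px <- max(1e-6, 1.5 * stats::median(apply(dm, 1, min)))
  }
  gx <- floor((xy[, 1] - min(xy[, 1])) / cell_px)
  gy <- floor((xy[, 2] - min(xy[, 2])) / cell_px)
  nx <- max(gx) + 1L; ny <- max(gy) + 1L
  occ <- matrix(FALSE, ny, nx)
  occ[cbind(gy + 1L, gx + 1L)] <- TRUE
  # sampling holes in the interior would masquerade as boundary cells:
  # close single-cell gaps, then fill enclosed holes
  solid <- occ
  if (ny >= 3 && nx >= 3) {
    solid <- EBImage::closing(occ + 0, EBImage::makeBrush(3, "box")) > 0
    solid <- EBImage::fillHull(solid + 0) > 0
  }
  nb <- shift_mat(solid, 0, 1) + shift_mat(solid, 0, -1) +
        shift_mat(solid, 1, 0) + shift_mat(solid, -1, 0)
  boundary <- solid & nb < 4
  # a boundary cell bridged by the closing holds no point; let occupied
  # cells adjacent to such empty boundary cells stand in so the ring
  # stays closed
  band <- boundary & occ
  gap <- boundary & !occ
  if (any(gap) && ny >= 3 && nx >= 3)
    band <- band |
      ((EBImage::dilate(gap + 0, EBImage::makeBrush(3, "box")) > 0) & occ)
  isb <- band[cbind(gy + 1L, gx + 1L)]
  # one representative per boundary cell: the most outward point (farthest
  # from the projected centroid), which best approximates the physical
  # silhouette boundary the image edges sit on
  cellid <- gy * nx + gx
  cand <- which(isb)
  cx <- mean(xy[, 1]); cy <- mean(xy[, 2])
  d2 <- (xy[cand, 1] - cx)^2 + (xy[cand, 2] - cy)^2
  ord <- cand[order(cellid[cand], -d2)]
  keep <- ord[!duplicated(cellid[ord])]
  list(xy = xy[keep, , drop = FALSE], model_idx = keep, cell_px = cell_px)
}

#' One-to-one edge/outline correspondence
#'
#' Two-pass rule: every edge point claims its nearest outline point; an
#' outline point claimed by several edge points keeps only the claimant at
#' minimal distance. The result is injective in outline points.
#'
#' @param edges N x 2 matrix of detected edge points, px.
#' @param outline M x 2 matrix of projected outline points, px.
#' @return list with `edge_idx` and `outline_idx` (parallel index vectors)
#'   and `dist` (their distances, px).
#' @export
match_one_to_one <- function(edges, outline) {
  edges <- as.matrix(edges); outline <- as.matrix(outline)
  if (nrow(edges) == 0 || nrow(outline) == 0)
    stop("match_one_to_one: empty input")
  d2 <- outer(edges[, 1], outline[, 1], "-")^2 +
        outer(edges[, 2], outline[, 2], "-")^2
  claim <- max.col(-d2, ties.method = "first")
  dmin <- d2[cbind(seq_len(nrow(edges)), claim)]
  ord <- order(claim, dmin)
  keep <- ord[!duplicated(claim[ord])]
  keep <- sort(keep)
  list(edge_idx = keep, outline_idx = claim[keep], dist = sqrt(dmin[keep]))
}

#' Model-based (feature-based) registration
#'
#' Full driver: the Canny bank runs once per image (edges are
#' pose-independent), then the loop alternates projected-outline
#' extraction, one-to-one matching, and the constrained least-squares solve
#' with 3-sigma rejection, until the pose is stable.
#'
#' @param images list per camera of radiograph matrices in [0, 1].
#' @param cloud the model `bv_cloud`.
#' @param cameras list of `bv_camera`.
#' @param init initial `bv_pose` (from [coarse_search()] or a previous
#'   epoch).
#' @param mode `"rigid"` or `"scaled"`.
#' @param opts solver options as in [register()].
#' @param sigmas,threshold_pairs bank parameters, see [multi_canny_bank()].
#' @param edges optional precomputed list per camera of N x 2 edge-point
#'   matrices (skips the bank).
#' @param cell_px outline occupancy cell size, px.
#' @return a `bv_registration` (with the final correspondence stored for
#'   [precision_rms_3d()]).
#' @export
register_model_based <- function(images, cloud, cameras, init = pose(),
                                 mode = c("rigid", "scaled"), opts = list(),
                                 sigmas = 4:8, threshold_pairs = NULL,
                                 edges = NULL, cell_px = NULL) {
  mode <- match.arg(mode)
  scaled <- mode == "scaled"
  opts <- solver_options(opts)
  if (is.null(edges)) {
    edges <- lapply(images, function(im)
      edge_points(thin_edges(multi_canny_bank(im, sigmas, threshold_pairs)$edges)))
  }
  if (scaled) {
    # warm start: the 8-parameter problem has shallow, strongly correlated
    # scale/depth directions; a rigid pre-fit lands inside its basin
    rigid_fit <- register_model_based(images, cloud, cameras, init,
                                      mode = "rigid", opts = opts,
                                      edges = edges, cell_px = cell_px)
    init <- rigid_fit$pose
  }
  qp <- as_quat_pose(init)
  theta <- theta_pack(qp, if (scaled) 1)
  prev_match <- NULL
  sol <- NULL
  iters_total <- 0L
  converged <- FALSE
  n_pairs_matched <- NA_integer_
  for (outer in seq_len(opts$max_outer)) {
    th <- theta_unpack(theta, scaled)
    qcur <- quat_pose(th$t[1], th$t[2], th$t[3], th$q)
    corr_master <- vector("list", length(cameras))
    corr_idx <- vector("list", length(cameras))
    for (k in seq_along(cameras)) {
      ol <- project_outline(cameras[[k]], qcur, th$lam, cloud, cell_px = cell_px)
      m <- match_one_to_one(edges[[k]], ol$xy)
      corr_master[[k]] <- edges[[k]][m$edge_idx, , drop = FALSE]
      corr_idx[[k]] <- ol$model_idx[m$outline_idx]
    }
    if (sum(lengths(corr_idx)) < opts$min_pairs)
      stop("register_model_based: too few correspondences")
    corr <- correspondence_set(corr_master, corr_idx)
    n_pairs_matched <- n_active(corr)   # pairs offered to the final solve
    sol <- solve_pose(theta, cloud, cameras, corr, scaled, opts)
    theta_change <- max(abs(sol$theta - theta))
    theta <- sol$theta
    iters_total <- iters_total + sol$iterations
    match_sig <- corr_idx
    if (!is.null(prev_match) && identical(match_sig, prev_match) &&
        theta_change < 1e-9) {
      converged <- sol$converged
      break
    }
    prev_match <- match_sig
    converged <- sol$converged
  }
  finalize_result(theta, cloud, cameras, sol$corr, scaled, opts,
                  converged, iters_total, n_pairs_matched)
}

#' Back-projection precision metric
#'
#' Registration precision as the RMS distance between registered 3D model
#' points and their matched edge points back-projected into object space at
#' the matched model point's depth. Zero for a perfect noiseless
#' registration; reported per axis and as the Euclidean distance RMS.
#'
#' @param result a converged `bv_registration` with stored correspondence.
#' @param cameras list of `bv_camera` (default: those stored in the result).
#' @param cloud model `bv_cloud` (default: stored in the result).
#' @return named vector `X`, `Y`, `Z`, `distance` (mm RMS) with attribute
#'   `n` (number of matched points used).
#' @export
precision_rms_3d <- function(result, cameras = result$cameras,
                             cloud = result$cloud) {
  corr <- result$correspondence
  if (is.null(corr)) stop("precision_rms_3d: result has no stored correspondence")
  lam <- if (is.null(result$lam)) 1 else result$lam
  moved <- apply_scaled(result$pose, lam, cloud)
  diffs <- NULL
  for (k in seq_along(cameras)) {
    act <- corr$active[[k]]
    if (!any(act)) next
    idx <- corr$model_idx[[k]][act]
    mp <- moved$points[idx, , drop = FALSE]
    mxy <- corr$master[[k]][act, , drop = FALSE]
    bp <- backproject_at_depth(cameras[[k]], mxy[, 1], mxy[, 2], mp)
    diffs <- rbind(diffs, bp - mp)
  }
  out <- c(sqrt(colMeans(diffs^2)), distance = sqrt(mean(rowSums(diffs^2))))
  names(out) <- c("X", "Y", "Z", "distance")
  attr(out, "n") <- nrow(diffs)
  out
}
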