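# Fiducial marker (bead) centre extraction from radiographs: Canny edge
# detection, 8-connected edge components, direct least-squares ellipse
# fitting, semi-axis gating and linear intensity enhancement.
#
# Images are numeric matrices with values in [0, 1]; element [r, c] is the
# pixel with image coordinates x = c - 1, y = r - 1 (0-based pixel centres).

shift_mat <- function(m, dr, dc, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  rs <- max(1, 1 + dr):min(nrow(m), nrow(m) + dr)
  cs <- max(1, 1 + dc):min(ncol(m), ncol(m) + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Canny edge detection
#'
#' Classical pipeline: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression along the quantised gradient direction, and hysteresis
#' thresholding (thresholds are fractions of the maximum gradient
#' magnitude; weak edge pixels survive only if 8-connected to a strong
#' pixel).
#'
#' @param image numeric matrix in [0, 1].
#' @param sigma Gaussian smoothing sd, px (> 0).
#' @param low,high hysteresis thresholds, fractions of the maximum gradient
#'   magnitude, `0 <= low < high <= 1`.
#' @return logical matrix of edge pixels.
#' @export
canny_edges <- function(image, sigma = 1.4, low = 0.1, high = 0.3) {
  canny_data(image, sigma, low, high)$edges
}

# full Canny state: edge map plus the gradient data needed for sub-pixel
# edge localisation
canny_data <- function(image, sigma = 1.4, low = 0.1, high = 0.3) {
  if (length(image) == 0) stop("canny_edges: empty image")
  if (sigma <= 0) stop("canny_edges: sigma must be > 0")
  if (low < 0 || high > 1 || low >= high)
    stop("canny_edges: need 0 <= low < high <= 1")
  sm <- as.matrix(EBImage::gblur(image, sigma = sigma, boundary = "replicate"))
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)   # d/dx (columns)
  ky <- t(kx)                                           # d/dy (rows)
  gx <- as.matrix(EBImage::filter2(sm, kx, boundary = "replicate"))
  gy <- as.matrix(EBImage::filter2(sm, ky, boundary = "replicate"))
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  empty <- matrix(FALSE, nrow(image), ncol(image))
  if (mmax < 1e-12)
    return(list(edges = empty, mag = mag, fwd = mag, bwd = mag,
                sector = empty + 0))
  # non-maximum suppression in 4 quantised directions
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4)
  n1 <- matrix(0, nrow(mag), ncol(mag)); n2 <- n1
  s0 <- sector == 0  # horizontal gradient: compare left/right (cols)
  s2 <- sector == 2  # vertical gradient: compare up/down (rows)
  s1 <- sector == 1  # diagonal (+x, +y)
  s3 <- sector == 3  # diagonal (-x, +y)
  # sh$e[r, c] is the magnitude at the (x+1) neighbour of pixel (r, c), etc.
  sh <- list(`e` = shift_mat(mag, 0, -1), `w` = shift_mat(mag, 0, 1),
             `s` = shift_mat(mag, -1, 0), `n` = shift_mat(mag, 1, 0),
             `se` = shift_mat(mag, -1, -1), `nw` = shift_mat(mag, 1, 1),
             `sw` = shift_mat(mag, -1, 1), `ne` = shift_mat(mag, 1, -1))
  n1[s0] <- sh$e[s0]; n2[s0] <- sh$w[s0]
  n1[s2] <- sh$s[s2]; n2[s2] <- sh$n[s2]
  n1[s1] <- sh$se[s1]; n2[s1] <- sh$nw[s1]
  n1[s3] <- sh$sw[s3]; n2[s3] <- sh$ne[s3]
  keep <- mag >= n1 & mag > n2
  strong <- keep & mag >= high * mmax
  weak <- keep & mag >= low * mmax
  # hysteresis: grow strong through weak by 8-connected propagation
  cur <- strong
  repeat {
    grown <- (EBImage::dilate(cur + 0, EBImage::makeBrush(3, "box")) > 0) & weak
    if (sum(grown) == sum(cur)) break
    cur <- grown
  }
  list(edges = cur, mag = mag, fwd = n1, bwd = n2, sector = sector)
}

# sub-pixel edge positions: parabolic interpolation of the gradient
# magnitude along the quantised gradient direction; pts are 0-based (x, y)
subpixel_refine <- function(pts, cd) {
  if (nrow(pts) == 0) return(pts)
  ij <- cbind(pts[, 2] + 1L, pts[, 1] + 1L)   # row, col
  m0 <- cd$mag[ij]; mf <- cd$fwd[ij]; mb <- cd$bwd[ij]
  den <- mb - 2 * m0 + mf
  delta <- ifelse(abs(den) > 1e-12, 0.5 * (mb - mf) / den, 0)
  delta <- pmax(-0.5, pmin(0.5, delta))
  sec <- cd$sector[ij]
  ux <- c(1, 1, 0, -1)[sec + 1]
  uy <- c(0, 1, 1, 1)[sec + 1]
  cbind(x = pts[, 1] + delta * ux, y = pts[, 2] + delta * uy)
}

# 8-connected labelling by iterative minimum-label propagation
label8 <- function(mask) {
  idx <- which(mask)
  lab <- matrix(0, nrow(mask), ncol(mask))
  lab[idx] <- idx
  repeat {
    nb <- lab
    for (d in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0),
                   c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
      s <- shift_mat(lab, d[1], d[2], fill = 0)
      s[s == 0] <- Inf
      nb <- pmin(nb, s)
    }
    nb[!mask] <- 0
    if (identical(nb, lab)) break
    lab <- nb
  }
  # compact labels
  u <- sort(unique(lab[lab > 0]))
  lab[lab > 0] <- match(lab[lab > 0], u)
  lab
}

#' Connected edge components
#'
#' Splits a binary edge map into 8-connected components and returns each as
#' a matrix of 0-based pixel coordinates.
#'
#' @param edges logical matrix (e.g. from [canny_edges()]).
#' @param min_size drop components with fewer pixels than this.
#' @return list of N x 2 matrices with columns `x`, `y` (px).
#' @export
edge_components <- function(edges, min_size = 5L) {
  lab <- label8(edges)
  n <- max(lab)
  out <- list()
  for (i in seq_len(n)) {
    w <- which(lab == i, arr.ind = TRUE)
    if (nrow(w) >= min_size)
      out[[length(out) + 1L]] <- cbind(x = w[, 2] - 1, y = w[, 1] - 1)
  }
  out
}

#' Direct least-squares ellipse fit
#'
#' Fitzgibbon-type conic fit with the ellipse constraint (4AC - B^2 = 1),
#' solved on centred/scaled coordinates for conditioning. Recovers all five
#' geometric parameters exactly on noise-free ellipse samples.
#'
#' @param pts N x 2 matrix of edge points (columns x, y, px), N >= 5.
#' @return list with `center` (x, y), `a` (semi-major), `b` (semi-minor),
#'   `theta` (major-axis orientation, radians in (-pi/2, pi/2]).
#' @export
fit_ellipse <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 5) stop("fit_ellipse: need at least 5 points")
  mx <- mean(pts[, 1]); my <- mean(pts[, 2])
  sc <- mean(sqrt((pts[, 1] - mx)^2 + (pts[, 2] - my)^2))
  if (sc < 1e-12) stop("fit_ellipse: degenerate point set")
  x <- (pts[, 1] - mx) / sc; y <- (pts[, 2] - my) / sc
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("fit_ellipse: degenerate (collinear) point set"))
  M <- S1 + S2 %*% T
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eg <- eigen(M)
  ev <- Re(eg$vectors)
  cond <- 4 * ev[1, ] * ev[3, ] - ev[2, ]^2
  ok <- which(cond > 1e-12)
  if (length(ok) == 0) stop("fit_ellipse: no ellipse solution (degenerate input)")
  a1 <- ev[, ok[which.max(Re(eg$values)[ok])]]
  conic <- c(a1, as.numeric(T %*% a1))   # A B C D E F in scaled frame
  A <- conic[1]; B <- conic[2]; C <- conic[3]
  D <- conic[4]; E <- conic[5]; Fc <- conic[6]
  den <- 4 * A * C - B^2
  x0 <- (B * E - 2 * C * D) / den
  y0 <- (B * D - 2 * A * E) / den
  F0 <- A * x0^2 + B * x0 * y0 + C * y0^2 + D * x0 + E * y0 + Fc
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eq <- eigen(Q, symmetric = TRUE)
  ax2 <- -F0 / eq$values
  if (any(ax2 <= 0)) stop("fit_ellipse: not an ellipse")
  semi <- sqrt(ax2)
  imaj <- which.max(semi)
  vmaj <- eq$vectors[, imaj]
  theta <- atan2(vmaj[2], vmaj[1])
  if (theta <= -pi / 2) theta <- theta + pi
  if (theta > pi / 2) theta <- theta - pi
  list(center = c(x = mx + sc * x0, y = my + sc * y0),
       a = sc * max(semi), b = sc * min(semi), theta = theta)
}

#' Gate ellipses by semi-axis length
#'
#' Keeps ellipses whose semi-major and semi-minor axes lie inside the given
#' closed intervals (boundary values are kept); order is preserved. Removes
#' spurious fits that are the wrong size to be a marker.
#'
#' @param ellipses list of ellipse fits (see [fit_ellipse()]).
#' @param a_range,b_range closed intervals `c(min, max)` for the semi-major
#'   and semi-minor axes, px.
#' @return the gated list.
#' @export
gate_by_semiaxis <- function(ellipses, a_range, b_range) {
  Filter(function(e)
    e$a >= a_range[1] && e$a <= a_range[2] &&
    e$b >= b_range[1] && e$b <= b_range[2], ellipses)
}

#' Linear intensity enhancement
#'
#' `gain * image + offset`, clipped to the [0, 1] working range. A monotone
#' non-decreasing mapping: enhancing cannot reorder pixel values.
#'
#' @param image numeric matrix in [0, 1].
#' @param gain positive multiplier.
#' @param offset additive offset.
#' @return enhanced image matrix.
#' @export
enhance_intensity <- function(image, gain = 1, offset = 0) {
  if (gain <= 0) stop("enhance_intensity: gain must be > 0")
  out <- gain * image + offset
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

#' Default target-extraction parameters
#'
#' The semi-axis gate defaults assume ~3 mm beads at the nominal rig
#' magnification; override for a different geometry.
#'
#' @param sigma,low,high Canny parameters.
#' @param a_range,b_range semi-axis gates, px.
#' @param gain,offset enhancement used in the retry pass.
#' @param min_component minimum edge-component size passed to the fitter.
#' @return named list of parameters.
#' @export
target_params <- function(sigma = 1.4, low = 0.1, high = 0.3,
                          a_range = c(2, 12), b_range = c(2, 12),
                          gain = 4, offset = 0, min_component = 8L) {
  list(sigma = sigma, low = low, high = high, a_range = a_range,
       b_range = b_range, gain = gain, offset = offset,
       min_component = min_component)
}

extract_pass <- function(image, params) {
  cd <- canny_data(image, params$sigma, params$low, params$high)
  comps <- edge_components(cd$edges, min_size = max(5L, params$min_component))
  fits <- list()
  for (cp in comps) {
    f <- tryCatch(fit_ellipse(subpixel_refine(cp, cd)), error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  gate_by_semiaxis(fits, params$a_range, params$b_range)
}

#' Extract marker targets from a radiograph
#'
#' Full pipeline: Canny edges, 8-connected components, per-component
#' ellipse fit, semi-axis gating. If fewer targets than expected are found
#' (beads in low-intensity regions have too little contrast), the image is
#' linearly enhanced and a second pass is merged in, deduplicating centres
#' closer than the largest accepted semi-major axis.
#'
#' @param image numeric matrix in [0, 1].
#' @param params parameter list from [target_params()].
#' @param expected optionally, the number of beads expected in frame.
#' @return data frame with columns `x`, `y` (centre, px), `a`, `b` (px),
#'   `theta` (rad); zero rows (with a warning) if nothing is found.
#' @export
extract_targets <- function(image, params = target_params(), expected = NULL) {
  fits <- extract_pass(image, params)
  if (!is.null(expected) && length(fits) < expected) {
    enhanced <- enhance_intensity(image, params$gain, params$offset)
    fits2 <- extract_pass(enhanced, params)
    if (length(fits2)) {
      dedupe_r <- max(c(vapply(fits, function(f) f$a, numeric(1)), 1))
      for (f in fits2) {
        if (length(fits) == 0) { fits <- list(f); next }
        ctrs <- t(vapply(fits, function(g) g$center, numeric(2)))
        dd <- sqrt((ctrs[, 1] - f$center[1])^2 + (ctrs[, 2] - f$center[2])^2)
        if (min(dd) > dedupe_r) fits[[length(fits) + 1L]] <- f
      }
    }
  }
  if (length(fits) == 0) {
    warning("extract_targets: no targets found")
    return(data.frame(x = numeric(0), y = numeric(0), a = numeric(0),
                      b = numeric(0), theta = numeric(0)))
  }
  data.frame(
    x = vapply(fits, function(f) unname(f$center[1]), numeric(1)),
    y = vapply(fits, function(f) unname(f$center[2]), numeric(1)),
    a = vapply(fits, function(f) f$a, numeric(1)),
    b = vapply(fits, function(f) f$b, numeric(1)),
    theta = vapply(fits, function(f) f$theta, numeric(1)))
}
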