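# Readers/writers for the on-disk formats: point clouds (ASCII PLY,
# CSV), bead CSV, two-camera calibration JSON/YAML, pose-track CSV,
# targets CSV and 8/16-bit PNG/TIFF images. Angles are serialised in
# degrees; file image coordinates use the 0-based pixel-centre convention.

#' Read a point cloud
#'
#' CSV files need `X,Y,Z` columns (header required); PLY files must be
#' ASCII with at least x/y/z vertex properties.
#'
#' @param path file path (`.csv` or `.ply`).
#' @return a `bv_cloud`.
#' @export
read_point_cloud <- function(path) {
  if (grepl("\\.ply$", path, ignore.case = TRUE)) return(read_ply(path))
  df <- utils::read.csv(path)
  need <- c("X", "Y", "Z")
  if (!all(need %in% names(df)))
    stop(sprintf("read_point_cloud: %s: missing column(s) %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")))
  m <- as.matrix(df[, need])
  if (any(!is.finite(m)))
    stop(sprintf("read_point_cloud: %s: non-finite coordinate at line %d",
                 path, which(!stats::complete.cases(m))[1] + 1L))
  point_cloud(m)
}

#' @rdname read_point_cloud
#' @param cloud a `bv_cloud`.
#' @export
write_point_cloud <- function(cloud, path) {
  if (grepl("\\.ply$", path, ignore.case = TRUE)) return(write_ply(cloud, path))
  utils::write.csv(data.frame(X = cloud$points[, 1], Y = cloud$points[, 2],
                              Z = cloud$points[, 3]), path, row.names = FALSE)
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != "ply") stop("read_ply: not a PLY file: ", path)
  hend <- match("end_header", lines)
  if (is.na(hend)) stop("read_ply: missing end_header in ", path)
  header <- lines[seq_len(hend)]
  if (!any(grepl("^format ascii", header)))
    stop("read_ply: only ASCII PLY is supported: ", path)
  vline <- grep("^element vertex", header, value = TRUE)
  if (length(vline) != 1) stop("read_ply: missing 'element vertex' in ", path)
  n <- as.integer(strsplit(vline, " ")[[1]][3])
  props <- sub("^property \\S+ ", "", grep("^property", header, value = TRUE))
  ix <- match(c("x", "y", "z"), props)
  if (any(is.na(ix))) stop("read_ply: vertex x/y/z properties not found in ", path)
  body <- lines[hend + seq_len(n)]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  point_cloud(m[, ix, drop = FALSE])
}

write_ply <- function(cloud, path) {
  n <- nrow(cloud$points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", n),
               "property double x", "property double y", "property double z",
               "end_header"), con)
  utils::write.table(format(cloud$points, trim = TRUE, digits = 17),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read/write fiducial bead coordinates
#'
#' CSV with columns `id,X,Y,Z` (mm).
#'
#' @param path file path.
#' @return data frame with `id`, `X`, `Y`, `Z`.
#' @export
read_beads <- function(path) {
  df <- utils::read.csv(path)
  need <- c("id", "X", "Y", "Z")
  if (!all(need %in% names(df)))
    stop(sprintf("read_beads: %s: missing column(s) %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")))
  df[, need]
}

#' @rdname read_beads
#' @param beads data frame with `id`, `X`, `Y`, `Z` or a `bv_cloud`.
#' @export
write_beads <- function(beads, path) {
  if (inherits(beads, "bv_cloud"))
    beads <- data.frame(id = seq_len(nrow(beads$points)),
                        X = beads$points[, 1], Y = beads$points[, 2],
                        Z = beads$points[, 3])
  utils::write.csv(beads, path, row.names = FALSE)
  invisible(path)
}

camera_from_block <- function(b, name) {
  need <- c("XC", "YC", "ZC", "omega", "phi", "kappa", "xp", "yp", "c")
  miss <- setdiff(need, names(b))
  if (length(miss))
    stop(sprintf("calibration camera '%s': missing field(s) %s", name,
                 paste(miss, collapse = ", ")))
  for (f in need) b[[f]] <- as.numeric(unlist(b[[f]]))
  degrees <- identical(b$angle_unit %||% "deg", "deg")
  dist <- NULL
  if (!is.null(b$distortion) && !identical(b$distortion$type, "none")) {
    d <- b$distortion
    if (identical(d$type, "poly")) {
      cx <- as.numeric(unlist(d$coef_x)); cy <- as.numeric(unlist(d$coef_y))
      # bivariate polynomial: terms 1, x, y, x^2, xy, y^2 (coefficients px)
      dist <- function(x, y) {
        B <- cbind(1, x, y, x^2, x * y, y^2)
        list(dx = as.numeric(B[, seq_along(cx), drop = FALSE] %*% cx),
             dy = as.numeric(B[, seq_along(cy), drop = FALSE] %*% cy))
      }
    } else if (identical(d$type, "grid")) {
      gx <- as.numeric(unlist(d$x)); gy <- as.numeric(unlist(d$y))
      DX <- matrix(as.numeric(unlist(d$dx)), length(gy), length(gx), byrow = TRUE)
      DY <- matrix(as.numeric(unlist(d$dy)), length(gy), length(gx), byrow = TRUE)
      bilin <- function(G, x, y) {
        xi <- pmin(pmax(x, gx[1]), gx[length(gx)])
        yi <- pmin(pmax(y, gy[1]), gy[length(gy)])
        i <- pmin(findInterval(xi, gx), length(gx) - 1L)
        j <- pmin(findInterval(yi, gy), length(gy) - 1L)
        tx <- (xi - gx[i]) / (gx[i + 1] - gx[i])
        ty <- (yi - gy[j]) / (gy[j + 1] - gy[j])
        (1 - ty) * ((1 - tx) * G[cbind(j, i)] + tx * G[cbind(j, i + 1)]) +
          ty * ((1 - tx) * G[cbind(j + 1, i)] + tx * G[cbind(j + 1, i + 1)])
      }
      dist <- function(x, y) list(dx = bilin(DX, x, y), dy = bilin(DY, x, y))
    } else stop(sprintf("calibration camera '%s': unknown distortion type '%s'",
                        name, d$type))
  }
  cam <- camera_model(b$XC, b$YC, b$ZC, b$omega, b$phi, b$kappa,
                      b$xp, b$yp, b$c, distortion = dist, degrees = degrees)
  if (!is.null(b$image_size)) cam$image_size <- as.integer(unlist(b$image_size))
  cam
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a two-camera calibration file
#'
#' JSON or YAML with a `cameras` list of per-camera blocks
#' `{XC, YC, ZC, omega, phi, kappa, xp, yp, c, angle_unit, distortion,
#' image_size}`. Units must be declared (`units: {object: mm, image: px}`);
#' no implicit conversion is done. Distortion may be `none`, a bivariate
#' polynomial (`poly`, coefficient vectors over 1, x, y, x^2, xy, y^2) or a
#' lookup `grid` with bilinear interpolation.
#'
#' @param path `.json`, `.yml` or `.yaml` file.
#' @return list of `bv_camera` objects.
#' @export
read_calibration <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = FALSE)
  units <- obj$units
  if (is.null(units$object) || is.null(units$image))
    stop("read_calibration: ", path, ": units block must declare object and image units")
  if (!identical(units$object, "mm") || !identical(units$image, "px"))
    stop("read_calibration: ", path, ": unsupported units (need object mm, image px)")
  cams <- obj$cameras
  if (is.null(cams) || length(cams) < 1)
    stop("read_calibration: ", path, ": no cameras block")
  if (is.data.frame(cams)) cams <- split(cams, seq_len(nrow(cams)))
  lapply(seq_along(cams), function(i)
    camera_from_block(as.list(cams[[i]]), names(cams)[i] %||% i))
}

#' Write a two-camera calibration file (JSON)
#'
#' Only identity-distortion cameras can be serialised.
#'
#' @param cameras list of `bv_camera`.
#' @param path output `.json` path.
#' @export
write_calibration <- function(cameras, path) {
  blocks <- lapply(cameras, function(cam) {
    b <- list(XC = cam$C[1], YC = cam$C[2], ZC = cam$C[3],
              omega = cam$angles[1] * 180 / pi, phi = cam$angles[2] * 180 / pi,
              kappa = cam$angles[3] * 180 / pi,
              xp = cam$xp, yp = cam$yp, c = cam$c,
              angle_unit = "deg", distortion = list(type = "none"))
    if (!is.null(cam$image_size)) b$image_size <- cam$image_size
    b
  })
  jsonlite::write_json(list(units = list(object = "mm", image = "px"),
                            cameras = blocks),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read/write a pose track
#'
#' CSV with columns `epoch, Xt, Yt, Zt, omega, phi, kappa[, lambda],
#' rms_2d, converged`; angles in degrees.
#'
#' @param path file path.
#' @return data frame of the track.
#' @export
read_pose_track <- function(path) {
  df <- utils::read.csv(path)
  need <- c("epoch", "Xt", "Yt", "Zt", "omega", "phi", "kappa")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("read_pose_track: %s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  df
}

#' @rdname read_pose_track
#' @param results list of `bv_registration` (one per epoch).
#' @export
write_pose_track <- function(results, path) {
  rows <- lapply(seq_along(results), function(e) {
    r <- results[[e]]
    a <- r$pose$angles * 180 / pi
    d <- data.frame(epoch = e, Xt = r$pose$t[1], Yt = r$pose$t[2],
                    Zt = r$pose$t[3], omega = a[1], phi = a[2], kappa = a[3],
                    rms_2d = r$rms_2d, converged = r$converged)
    if (!is.null(r$lam)) d$lambda <- r$lam
    d
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read/write extracted targets
#'
#' CSV with columns `camera_id, epoch, x_px, y_px, a_px, b_px, theta_rad`.
#'
#' @param path file path.
#' @return data frame of targets.
#' @export
read_targets <- function(path) {
  df <- utils::read.csv(path)
  need <- c("camera_id", "epoch", "x_px", "y_px")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("read_targets: %s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  df
}

#' @rdname read_targets
#' @param targets data frame as returned by [extract_targets()] plus
#'   `camera_id` and `epoch` columns (added if absent).
#' @export
write_targets <- function(targets, path) {
  if (is.null(targets$camera_id)) targets$camera_id <- 1L
  if (is.null(targets$epoch)) targets$epoch <- 1L
  out <- data.frame(camera_id = targets$camera_id, epoch = targets$epoch,
                    x_px = targets$x, y_px = targets$y,
                    a_px = targets$a %||% NA, b_px = targets$b %||% NA,
                    theta_rad = targets$theta %||% NA)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read/write grayscale images
#'
#' PNG (8- or 16-bit) or TIFF input, returned as a numeric matrix in [0, 1]
#' in the package's row = y, column = x convention. Output is 8-bit for PNG
#' and 8/16-bit for TIFF (use TIFF where quantisation matters).
#'
#' @param path image path (`.png`, `.tif`, `.tiff`).
#' @return numeric matrix.
#' @export
read_image <- function(path) {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' @rdname read_image
#' @param image numeric matrix in [0, 1].
#' @param bits bit depth for TIFF output (8 or 16).
#' @export
write_image <- function(image, path, bits = 16L) {
  image[image < 0] <- 0; image[image > 1] <- 1
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::writeTIFF(image, path, bits.per.sample = as.integer(bits))
  else png::writePNG(image, path, dpi = NULL)
  invisible(path)
}

#' Render a QA overlay of a registration
#'
#' Writes a PNG of the radiograph with the projected model outline burnt in
#' bright, for visual inspection of a model-based fit.
#'
#' @param image radiograph matrix in [0, 1].
#' @param camera a `bv_camera`.
#' @param result a `bv_registration`.
#' @param path output PNG path.
#' @export
write_overlay <- function(image, camera, result, path) {
  lam <- if (is.null(result$lam)) 1 else result$lam
  ol <- project_outline(camera, result$pose, lam, result$cloud)
  rgb <- array(rep(image, 3), c(nrow(image), ncol(image), 3))
  rr <- round(ol$xy[, 2]) + 1; cc <- round(ol$xy[, 1]) + 1
  ok <- rr >= 1 & rr <= nrow(image) & cc >= 1 & cc <= ncol(image)
  rgb[cbind(rr[ok], cc[ok], 1)] <- 1
  rgb[cbind(rr[ok], cc[ok], 2)] <- 0
  rgb[cbind(rr[ok], cc[ok], 3)] <- 0
  png::writePNG(rgb, path)
  invisible(path)
}
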