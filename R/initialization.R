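# Automatic coarse pose initialisation: 64 evenly spaced starting rotations,
# a capped registration from each, selection by the smallest RMSE.

#' Generate the 64 starting poses
#'
#' A 4 x 4 x 4 evenly spaced Euler grid — each of omega, phi, kappa in
#' {-135, -45, 45, 135} degrees — all sharing one translation guess. The
#' grid subdivides rotation space evenly so that some start is always
#' within the capture range of the iterative registration.
#'
#' @param translation_guess length-3 translation (mm) shared by all starts;
#'   typically placing the model centroid near the intersection of the two
#'   optical axes.
#' @return list of 64 `bv_pose` objects.
#' @export
generate_start_poses <- function(translation_guess = c(0, 0, 0)) {
  g <- c(-135, -45, 45, 135)
  grid <- expand.grid(omega = g, phi = g, kappa = g)
  lapply(seq_len(nrow(grid)), function(i)
    pose(translation_guess[1], translation_guess[2], translation_guess[3],
         grid$omega[i], grid$phi[i], grid$kappa[i]))
}

#' Coarse pose search over the 64 starts
#'
#' Runs a capped registration (few inner iterations, a few matching rounds)
#' from each starting pose, then lets the best few candidates run to full
#' convergence; the pose attaining the smallest 2D RMSE wins. The two-stage
#' selection is cheap (the refinement touches only `refine_top` starts) and
#' guards against a wrong basin narrowly out-scoring the right one during
#' the capped phase. Deterministic given its inputs; ties are broken by the
#' lowest pose index.
#'
#' @param cloud model `bv_cloud` (bead cloud for marker-based use).
#' @param cameras list of `bv_camera`.
#' @param master list per camera of measured 2D points, px.
#' @param translation_guess translation shared by the starts; default
#'   `c(0, 0, 0)` assumes the rig converges on the origin.
#' @param mode `"rigid"` or `"scaled"`.
#' @param coarse_iter inner-iteration cap per start.
#' @param refine_top number of best coarse candidates refined to full
#'   convergence before the final selection.
#' @param opts extra solver options for the capped runs.
#' @return list with `pose` (best pose, a `bv_pose`), `rmse` (its 2D RMSE
#'   after refinement), `index` (which start won) and `all_rmse` (the 64
#'   capped-phase RMSE values).
#' @export
coarse_search <- function(cloud, cameras, master,
                          translation_guess = c(0, 0, 0),
                          mode = "rigid", coarse_iter = 10L, refine_top = 5L,
                          opts = list()) {
  starts <- generate_start_poses(translation_guess)
  o <- solver_options(opts)
  o$max_iter <- as.integer(coarse_iter)
  o$max_outer <- 3L
  o$tol <- max(o$tol, 1e-10)
  rmse <- rep(Inf, length(starts))
  results <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    r <- tryCatch(register(cloud, cameras, master, starts[[i]],
                           mode = mode, opts = o),
                  error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(r) && is.finite(r$rms_2d)) {
      rmse[i] <- r$rms_2d
      results[[i]] <- r
    }
  }
  if (!any(is.finite(rmse)))
    stop(paste0("coarse_search: all 64 starts failed; per-start RMSE: ",
                paste(signif(rmse, 3), collapse = ", ")))
  top <- order(rmse)[seq_len(min(refine_top, sum(is.finite(rmse))))]
  best <- top[1]; best_rmse <- Inf; best_pose <- results[[top[1]]]$pose
  for (i in top) {
    rf <- tryCatch(register(cloud, cameras, master, results[[i]]$pose,
                            mode = mode, opts = opts),
                   error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(rf) && is.finite(rf$rms_2d) && rf$rms_2d < best_rmse - 1e-15) {
      best <- i; best_rmse <- rf$rms_2d; best_pose <- rf$pose
    }
  }
  list(pose = best_pose, rmse = best_rmse, index = best, all_rmse = rmse)
}
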