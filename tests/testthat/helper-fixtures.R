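# Shared fixtures: small clouds and a two-camera convergent rig built in code.

random_rotation <- function() {
  # uniform random rotation via a normalised random quaternion
  q <- stats::rnorm(4)
  quat_to_matrix(q / sqrt(sum(q^2)))
}

random_pose <- function(tmax = 50, degmax = 180) {
  R <- random_rotation()
  a <- matrix_to_euler(R)
  pose(stats::runif(1, -tmax, tmax), stats::runif(1, -tmax, tmax),
       stats::runif(1, -tmax, tmax), a[1], a[2], a[3], degrees = FALSE)
}

# a small asymmetric 7-point "bead" cloud (mm scale of a knee phantom)
fixture_beads <- function() {
  point_cloud(rbind(
    c( 25,  10,   5), c(-20,  18,  -8), c(  5, -28,  12),
    c( 15,  22, -18), c(-12,  -9,  25), c( 30,  -5, -10),
    c( -4,   3,  32)))
}

# two cameras converging on the origin at 60 deg in the XZ plane,
# matching the default synthetic rig geometry but written out directly
fixture_rig <- function(c_px = 2000, dist_mm = 1000) {
  make_rig(rig_spec(angle_deg = 60, distance_mm = dist_mm, c_px = c_px,
                    image_size = c(1008, 1008)))
}
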