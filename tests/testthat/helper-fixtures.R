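# Shared fixtures: smooth open test patches and known deformations.

# wavy rectangular sheet ~60 x 40 mm with smooth relief; mildly irregular
# so principal axes are well defined
wavy_patch <- function(nx = 24, ny = 16, spacing = 2.5, seed = 1) {
  m <- mesh_grid(nx, ny, spacing = spacing)
  v <- m$vertices
  set.seed(seed)
  v[, 1:2] <- v[, 1:2] + matrix(runif(2 * nrow(v), -0.15, 0.15) * spacing, ncol = 2)
  v[, 3] <- 5 * sin(v[, 1] / 15) + 4 * cos(v[, 2] / 18) + 0.02 * v[, 1]
  surface_mesh(v, m$faces, patch_label = "femur")
}

# genuine TPS deformation with known ground truth: displace a few
# landmarks by up to `amplitude` mm and interpolate exactly
random_tps_deformation <- function(mesh, amplitude = 2, n_landmarks = 12, seed = 1) {
  set.seed(seed)
  idx <- sample(nrow(mesh$vertices), n_landmarks)
  src <- mesh$vertices[idx, , drop = FALSE]
  dst <- src + matrix(runif(3 * n_landmarks, -amplitude, amplitude), ncol = 3)
  tps_fit(src, dst, lambda_reg = 0)
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
  )
}
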