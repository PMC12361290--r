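#' Closed-form least-squares similarity alignment
#'
#' Estimates the similarity transform (isotropic scale, proper rotation,
#' translation) minimising `sum ||s R x_i + t - y_i||^2` over paired point
#' sets, by the SVD-based closed form. The rotation is always proper
#' (`det = +1`); reflective correspondences are resolved to the best
#' rotation, never an improper transform.
#'
#' @param source_points,target_points Paired `n x 3` matrices, `n >= 3`.
#' @return A `similarity_transform`: `scale`, `rotation` (3 x 3),
#'   `translation` (length 3), and `rms` residual in mm.
#' @export
similarity_align <- function(source_points, target_points) {
  X <- as.matrix(source_points)
  Y <- as.matrix(target_points)
  if (!all(dim(X) == dim(Y)) || ncol(X) != 3L) {
    stop("point sets must be paired n x 3 matrices")
  }
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 point pairs")
  mx <- colMeans(X)
  my <- colMeans(Y)
  Xc <- sweep(X, 2, mx)
  Yc <- sweep(Y, 2, my)
  S <- crossprod(Yc, Xc) / n
  sv <- svd(S)
  if (sum(sv$d > 1e-12 * max(sv$d, 1e-300)) < 2L) {
    stop("degenerate configuration: source points are (nearly) collinear")
  }
  D <- diag(3)
  if (det(sv$u %*% t(sv$v)) < 0) D[3, 3] <- -1
  R <- sv$u %*% D %*% t(sv$v)
  var_x <- sum(Xc^2) / n
  s <- sum(diag(D) * sv$d) / var_x
  t0 <- my - s * as.numeric(R %*% mx)
  fitted <- s * X %*% t(R) + matrix(t0, n, 3, byrow = TRUE)
  out <- list(
    scale = s, rotation = R, translation = t0,
    rms = sqrt(mean(rowSums((fitted - Y)^2)))
  )
  class(out) <- "similarity_transform"
  out
}

#' Apply a similarity transform to points
#'
#' @param transform A `similarity_transform`.
#' @param points `n x 3` matrix.
#' @return Transformed `n x 3` matrix.
#' @export
apply_similarity <- function(transform, points) {
  p <- as.matrix(points)
  transform$scale * p %*% t(transform$rotation) +
    matrix(transform$translation, nrow(p), 3, byrow = TRUE)
}

identity_similarity <- function() {
  structure(
    list(scale = 1, rotation = diag(3), translation = c(0, 0, 0), rms = 0),
    class = "similarity_transform"
  )
}

#' Fit a 3-D thin-plate spline warp
#'
#' Solves the standard bordered TPS system with the 3-D kernel
#' `U(r) = r` and an affine part; `lambda_reg` is added to the kernel
#' block diagonal. With `lambda_reg = 0` the warp interpolates the
#' landmarks exactly; as `lambda_reg` grows the warp shrinks towards the
#' best affine fit. The kernel weights satisfy the polynomial side
#' conditions (`1' W = 0`, `C' W = 0`).
#'
#' @param source_landmarks,target_landmarks Paired `n x 3` matrices,
#'   `n >= 4` non-coplanar points for `lambda_reg = 0`.
#' @param lambda_reg Regularisation weight, >= 0, in mm (same scale as
#'   the kernel).
#' @return A `tps_warp`: `control_points`, `kernel_weights` (n x 3),
#'   `affine` (4 x 3, acting on `(1, x, y, z)`), `lambda_reg`.
#' @export
tps_fit <- function(source_landmarks, target_landmarks, lambda_reg = 0) {
  C <- as.matrix(source_landmarks)
  Y <- as.matrix(target_landmarks)
  if (!all(dim(C) == dim(Y)) || ncol(C) != 3L) {
    stop("landmark sets must be paired n x 3 matrices")
  }
  n <- nrow(C)
  if (n < 4L) stop("need at least 4 landmarks")
  if (lambda_reg < 0) stop("`lambda_reg` must be >= 0")
  # solve in centred unit-scale coordinates for conditioning, then map the
  # solution back to the original-coordinate representation (U(r) = r is
  # homogeneous of degree 1, so the conversion is exact)
  mu <- colMeans(C)
  sc <- mean(sqrt(rowSums(sweep(C, 2, mu)^2)))
  if (sc <= 0) stop("degenerate TPS system: coincident landmarks")
  Cn <- sweep(C, 2, mu) / sc
  # the bordered system is assembled with the biharmonic kernel -r (the
  # conditionally positive definite sign, for which +lambda on the diagonal
  # is a true roughness penalty); weights are stored for the +r convention
  K <- -as.matrix(stats::dist(Cn, diag = TRUE, upper = TRUE))
  P <- cbind(1, Cn)
  M <- rbind(
    cbind(K + (lambda_reg / sc) * diag(n), P),
    cbind(t(P), matrix(0, 4, 4))
  )
  rhs <- rbind(Y, matrix(0, 4, 3))
  sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
  if (is.null(sol)) {
    stop("degenerate TPS system (coplanar landmarks?); try lambda_reg > 0")
  }
  sol <- sol + solve(M, rhs - M %*% sol)   # one refinement step
  Wn <- -sol[seq_len(n), , drop = FALSE]
  An <- sol[n + 1:4, , drop = FALSE]
  A <- rbind(
    An[1, ] - as.numeric(mu %*% An[2:4, ]) / sc,
    An[2:4, , drop = FALSE] / sc
  )
  out <- list(
    control_points = C,
    kernel_weights = Wn / sc,
    affine = A,
    lambda_reg = lambda_reg
  )
  class(out) <- "tps_warp"
  out
}

#' Evaluate a thin-plate spline warp at points
#'
#' `f(x) = affine' (1, x) + sum_i w_i ||x - c_i||`, evaluated pointwise.
#'
#' @param warp A `tps_warp`.
#' @param points `n x 3` matrix.
#' @return Warped `n x 3` matrix.
#' @export
tps_apply <- function(warp, points) {
  p <- as.matrix(points)
  U <- cross_dist(p, warp$control_points)
  cbind(1, p) %*% warp$affine + U %*% warp$kernel_weights
}

# Euclidean distance matrix between two point sets; coordinate-wise
# differences keep full precision at small separations (the expanded
# |a|^2+|b|^2-2ab form cancels catastrophically near r = 0)
cross_dist <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 +
    outer(a[, 2], b[, 2], "-")^2 +
    outer(a[, 3], b[, 3], "-")^2
  sqrt(d2)
}

#' Bending energy of a fitted TPS warp
#'
#' Quadratic form of the kernel weights; non-negative under the polynomial
#' side conditions, zero exactly for affine warps.
#'
#' @param warp A `tps_warp`.
#' @return Scalar bending energy.
#' @export
tps_bending_energy <- function(warp) {
  K <- as.matrix(stats::dist(warp$control_points, diag = TRUE, upper = TRUE))
  # for U(r) = +r in 3-D the biharmonic energy is -W' K W on the
  # side-condition subspace
  e <- -sum(vapply(1:3, function(d) {
    w <- warp$kernel_weights[, d]
    as.numeric(t(w) %*% K %*% w)
  }, numeric(1)))
  max(e, 0)
}

# farthest-point subsample of mesh vertices, seeded start
farthest_point_sample <- function(vertices, n, seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  nv <- nrow(vertices)
  n <- min(n, nv)
  sel <- integer(n)
  sel[1] <- sample.int(nv, 1)
  d <- rowSums(sweep(vertices, 2, vertices[sel[1], ])^2)
  for (k in seq_len(n - 1L)) {
    sel[k + 1L] <- which.max(d)
    d <- pmin(d, rowSums(sweep(vertices, 2, vertices[sel[k + 1L], ])^2))
  }
  sel
}

# candidate PCA alignments of source onto target (4 proper sign flips),
# used to make ICP robust to large initial rotations
pca_init_candidates <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  es <- eigen(stats::cov(src))$vectors
  ed <- eigen(stats::cov(dst))$vectors
  if (det(es) < 0) es[, 3] <- -es[, 3]
  if (det(ed) < 0) ed[, 3] <- -ed[, 3]
  scale0 <- sqrt(sum(sweep(dst, 2, cd)^2) / sum(sweep(src, 2, cs)^2))
  flips <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  lapply(flips, function(f) {
    R <- ed %*% diag(f) %*% t(es)
    structure(
      list(scale = scale0, rotation = R,
           translation = cd - scale0 * as.numeric(R %*% cs), rms = NA_real_),
      class = "similarity_transform"
    )
  })
}

icp_similarity <- function(src_pts, subject_mesh, init, max_iter = 30,
                           tol = 1e-8) {
  tr <- init
  prev <- Inf
  for (it in seq_len(max_iter)) {
    moved <- apply_similarity(tr, src_pts)
    cp <- closest_point_on_mesh(moved, subject_mesh)
    tr <- similarity_align(src_pts, cp$points)
    if (abs(prev - tr$rms) < tol * (1 + tr$rms)) break
    prev <- tr$rms
  }
  tr
}

#' Register a subject surface to a canonical template
#'
#' Three stages: (1) a similarity initialisation by iterative closest
#' point on a seeded farthest-point vertex subset, started from
#' principal-axis alignments to tolerate large initial rotations;
#' (2) thin-plate spline refinement in which `n_control` farthest-point
#' control points on the canonical surface are paired with their current
#' closest points on the subject and the warp refitted, `iterations`
#' times; (3) a vertex correspondence built by closest-point projection
#' of every warped canonical vertex onto the subject mesh, with
#' barycentric coordinates. Correspondences farther than 3x the median
#' subject edge length are marked missing (extrapolation guard).
#'
#' @param subject_mesh,canonical_mesh `surface_mesh` objects with the same
#'   `patch_label`.
#' @param n_control Number of TPS control points (default 400).
#' @param iterations TPS refinement iterations (default 5).
#' @param lambda_reg TPS regularisation; default `1e-3 *` canonical mesh
#'   diameter.
#' @param seed Integer seed for the farthest-point sampling.
#' @param n_icp Size of the ICP vertex subset.
#' @return A `canonical_registration`: `similarity`, `warp`,
#'   `correspondence` (list with `face`, `bary`, `missing`), `rms` (mm),
#'   `warped_vertices`, `converged`.
#' @export
register_to_canonical <- function(subject_mesh, canonical_mesh,
                                  n_control = 400L, iterations = 5L,
                                  lambda_reg = NULL, seed = 1L,
                                  n_icp = 500L) {
  if (!identical(subject_mesh$patch_label, canonical_mesh$patch_label)) {
    stop("subject and canonical meshes must share the same patch_label")
  }
  cv <- canonical_mesh$vertices
  if (is.null(lambda_reg)) {
    diam <- sqrt(max(rowSums(sweep(cv, 2, colMeans(cv))^2))) * 2
    lambda_reg <- 1e-3 * diam
  }
  icp_idx <- farthest_point_sample(cv, n_icp, seed = seed)
  src <- cv[icp_idx, , drop = FALSE]
  # principal-axis candidates only: the initialisation is then exactly
  # equivariant under rigid motion of the subject
  cands <- pca_init_candidates(src, subject_mesh$vertices)
  best <- NULL
  for (init in cands) {
    tr <- tryCatch(icp_similarity(src, subject_mesh, init, max_iter = 15),
                   error = function(e) NULL)
    if (!is.null(tr) && (is.null(best) || tr$rms < best$rms)) best <- tr
  }
  if (is.null(best)) stop("similarity initialisation failed")
  sim <- icp_similarity(src, subject_mesh, best, max_iter = 30)

  ctrl_idx <- farthest_point_sample(cv, n_control, seed = seed + 1L)
  ctrl_src <- apply_similarity(sim, cv[ctrl_idx, , drop = FALSE])
  warped_ctrl <- ctrl_src
  warp <- NULL
  for (it in seq_len(iterations)) {
    cp <- closest_point_on_mesh(warped_ctrl, subject_mesh)
    warp <- tps_fit(ctrl_src, cp$points, lambda_reg = lambda_reg)
    warped_ctrl <- tps_apply(warp, ctrl_src)
  }

  all_src <- apply_similarity(sim, cv)
  warped <- if (is.null(warp)) all_src else tps_apply(warp, all_src)
  cp_all <- closest_point_on_mesh(warped, subject_mesh)
  sm <- mesh_metrics(subject_mesh)
  guard <- 3 * stats::median(sm$edge_lengths)
  missing <- cp_all$distance > guard
  rms <- sqrt(mean(cp_all$distance^2))
  converged <- rms < guard
  if (!converged) {
    warning(sprintf("registration residual RMS %.3g mm exceeds %.3g mm; flagged non-converged",
                    rms, guard))
  }
  out <- list(
    similarity = sim,
    warp = warp,
    correspondence = list(face = cp_all$face, bary = cp_all$bary, missing = missing),
    rms = rms,
    warped_vertices = warped,
    converged = converged
  )
  class(out) <- "canonical_registration"
  out
}

#' @export
print.canonical_registration <- function(x, ...) {
  cat(sprintf(
    "<canonical_registration> residual RMS %.4g mm, scale %.4g, %.1f%% correspondences missing%s\n",
    x$rms, x$similarity$scale, 100 * mean(x$correspondence$missing),
    if (x$converged) "" else " [NOT CONVERGED]"
  ))
  invisible(x)
}

#' Pull a subject field onto the canonical vertices
#'
#' Each canonical vertex receives the barycentric interpolation of the
#' subject field over its corresponded subject face. Missing subject
#' values and missing correspondences propagate to missing canonical
#' values.
#'
#' @param subject_field `surface_field` on the subject mesh.
#' @param registration A `canonical_registration` (or its
#'   `correspondence` element).
#' @param subject_mesh The subject `surface_mesh` the field lives on.
#' @return A `surface_field` on the canonical mesh.
#' @export
transfer_field <- function(subject_field, registration, subject_mesh) {
  corr <- if (inherits(registration, "canonical_registration")) {
    registration$correspondence
  } else {
    registration
  }
  if (length(subject_field$values) != nrow(subject_mesh$vertices)) {
    stop("field length does not match subject mesh vertex count")
  }
  f <- subject_mesh$faces[corr$face, , drop = FALSE]
  vals <- subject_field$values
  v1 <- vals[f[, 1]]; v2 <- vals[f[, 2]]; v3 <- vals[f[, 3]]
  out <- corr$bary[, 1] * v1 + corr$bary[, 2] * v2 + corr$bary[, 3] * v3
  m <- subject_field$missing_mask
  miss <- corr$missing |
    (m[f[, 1]] & corr$bary[, 1] > 1e-9) |
    (m[f[, 2]] & corr$bary[, 2] > 1e-9) |
    (m[f[, 3]] & corr$bary[, 3] > 1e-9)
  out[miss] <- NA_real_
  units <- subject_field$units
  if (units == "mm") out[!miss] <- pmax(out[!miss], 0)
  surface_field(out, missing_mask = miss, units = units)
}
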