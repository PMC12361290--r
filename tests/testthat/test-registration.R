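test_that("similarity_align recovers known transforms in closed form", {
  set.seed(11)
  X <- matrix(rnorm(150), ncol = 3)
  idt <- similarity_align(X, X)
  expect_equal(idt$scale, 1, tolerance = 1e-12)
  expect_lt(max(abs(idt$rotation - diag(3))), 1e-12)
  expect_lt(idt$rms, 1e-12)

  ang <- 30 * pi / 180
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  Y <- 1.3 * X %*% t(R) + matrix(c(5, -2, 1), 50, 3, byrow = TRUE)
  tr <- similarity_align(X, Y)
  expect_lt(abs(tr$scale - 1.3), 1e-8)
  expect_lt(max(abs(tr$rotation - R)), 1e-8)
  expect_lt(max(abs(tr$translation - c(5, -2, 1))), 1e-8)
  expect_lt(tr$rms, 1e-8)

  # mirrored target: result must stay a proper rotation, with residual
  mir <- X %*% diag(c(-1, 1, 1))
  ref <- similarity_align(X, mir)
  expect_equal(det(ref$rotation), 1, tolerance = 1e-10)
  expect_gt(ref$rms, 0.1)

  expect_error(similarity_align(X[1:2, ], X[1:2, ]), "at least 3")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(similarity_align(line, line), "collinear")
})

test_that("similarity_align matches a brute-force nonlinear optimiser", {
  rms_of <- function(par, X, Y) {
    s <- exp(par[1])
    axis <- par[2:4]
    th <- sqrt(sum(axis^2))
    R <- if (th < 1e-12) diag(3) else {
      a <- axis / th
      K <- rbind(c(0, -a[3], a[2]), c(a[3], 0, -a[1]), c(-a[2], a[1], 0))
      diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    }
    fitted <- s * X %*% t(R) + matrix(par[5:7], nrow(X), 3, byrow = TRUE)
    sqrt(mean(rowSums((fitted - Y)^2)))
  }
  for (case in 1:20) {
    set.seed(400 + case)
    X <- matrix(rnorm(60, sd = 2), ncol = 3)
    Y <- runif(1, 0.7, 1.4) * X %*% t(random_rotation(case)) +
      matrix(rnorm(3, sd = 3), 20, 3, byrow = TRUE) +
      matrix(rnorm(60, sd = 0.05), ncol = 3)
    cf <- similarity_align(X, Y)
    # start the general-purpose optimiser near the closed form and verify
    # it cannot do materially better
    th <- acos(pmin(pmax((sum(diag(cf$rotation)) - 1) / 2, -1), 1))
    ax <- c(cf$rotation[3, 2] - cf$rotation[2, 3],
            cf$rotation[1, 3] - cf$rotation[3, 1],
            cf$rotation[2, 1] - cf$rotation[1, 2])
    ax <- if (sum(ax^2) > 1e-12) ax / sqrt(sum(ax^2)) * th else c(0, 0, 0)
    p0 <- c(log(cf$scale), ax, cf$translation) * 1.05 + 0.01
    opt <- optim(p0, rms_of, X = X, Y = Y, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    expect_lt(cf$rms, opt$value + 1e-5)
  }
})

test_that("TPS interpolates at lambda 0, reproduces affine maps, shrinks with lambda", {
  set.seed(21)
  src <- matrix(runif(36, 0, 50), ncol = 3)
  dst <- src + matrix(rnorm(36), ncol = 3)
  warp <- tps_fit(src, dst, lambda_reg = 0)
  expect_lt(max(abs(tps_apply(warp, src) - dst)), 1e-8)
  # side conditions: weights orthogonal to polynomials
  W <- warp$kernel_weights
  expect_lt(max(abs(colSums(W))), 1e-8)
  expect_lt(max(abs(t(cbind(1, src)) %*% W)), 1e-7)

  A <- rbind(c(2, 1, -4), c(0.9, 0.1, 0), c(-0.2, 1.1, 0.3), c(0.05, 0, 0.95))
  dst_aff <- cbind(1, src) %*% A
  warp_aff <- tps_fit(src, dst_aff, lambda_reg = 0)
  expect_lt(max(abs(warp_aff$kernel_weights)), 1e-8)
  expect_lt(max(abs(warp_aff$affine - A)), 1e-6)
  # linearity: affine-fitted warp acts affinely on new points
  new_pts <- matrix(runif(30, 0, 50), ncol = 3)
  expect_lt(max(abs(tps_apply(warp_aff, new_pts) - cbind(1, new_pts) %*% A)), 1e-8)

  # bending energy is non-negative and decreases monotonically over 5
  # decades of lambda
  lambdas <- 10^seq(-2, 2, by = 1)
  energies <- vapply(lambdas, function(l) {
    tps_bending_energy(tps_fit(src, dst, lambda_reg = l))
  }, numeric(1))
  expect_true(all(energies >= 0))
  expect_true(all(diff(energies) < 0))
  # large lambda approaches the least-squares affine fit
  big <- tps_fit(src, dst, lambda_reg = 1e6)
  aff_ls <- qr.solve(cbind(1, src), dst)
  expect_lt(max(abs(tps_apply(big, new_pts) - cbind(1, new_pts) %*% aff_ls)), 1e-3)

  flat <- cbind(src[, 1:2], 0)
  expect_error(tps_fit(flat, dst, lambda_reg = 0), "lambda_reg > 0|singular")
})

test_that("registering a mesh to itself yields the identity", {
  canon <- wavy_patch(seed = 2)
  reg <- register_to_canonical(canon, canon, n_control = 150, iterations = 3,
                               seed = 7)
  expect_true(reg$converged)
  expect_lt(abs(reg$similarity$scale - 1), 1e-6)
  expect_lt(max(abs(reg$similarity$rotation - diag(3))), 1e-6)
  expect_lt(reg$rms, 1e-6)
  expect_lt(max(abs(reg$warped_vertices - canon$vertices)), 1e-4)
})

test_that("a known similarity transform is recovered through registration", {
  canon <- wavy_patch(seed = 3)
  R <- random_rotation(5)
  s_true <- 1.1
  t_true <- c(8, -14, 3)
  subj <- surface_mesh(
    s_true * canon$vertices %*% t(R) +
      matrix(t_true, nrow(canon$vertices), 3, byrow = TRUE),
    canon$faces, patch_label = "femur"
  )
  reg <- register_to_canonical(subj, canon, n_control = 200, iterations = 3,
                               seed = 1)
  expect_lt(abs(reg$similarity$scale - s_true), 1e-3)
  expect_lt(max(abs(reg$similarity$rotation - R)), 1e-3)
  expect_lt(reg$rms, 0.01)
})

test_that("registration equivariance: pre-rotating the subject leaves the residual unchanged", {
  canon <- wavy_patch(seed = 4)
  warp <- random_tps_deformation(canon, amplitude = 1.5, seed = 9)
  subj <- surface_mesh(tps_apply(warp, canon$vertices), canon$faces, "femur")
  reg1 <- register_to_canonical(subj, canon, n_control = 200, iterations = 4, seed = 3)
  R <- random_rotation(17)
  subj_rot <- surface_mesh(subj$vertices %*% t(R), subj$faces, "femur")
  reg2 <- register_to_canonical(subj_rot, canon, n_control = 200, iterations = 4, seed = 3)
  expect_lt(abs(reg1$rms - reg2$rms), 1e-6)
})

test_that("smooth deformations are recovered and fields transfer accurately", {
  canon <- wavy_patch(nx = 30, ny = 20, spacing = 2, seed = 6)
  warp_true <- random_tps_deformation(canon, amplitude = 2, seed = 12)
  subj_v <- tps_apply(warp_true, canon$vertices)
  subj <- surface_mesh(subj_v, canon$faces, patch_label = "femur")
  reg <- register_to_canonical(subj, canon, n_control = 300, iterations = 5, seed = 2)
  expect_true(reg$converged)
  expect_lt(reg$rms, 0.1)

  # smooth mm-scale test field on the subject; truth at the corresponded
  # positions is known through the generating warp
  gfun <- function(p) 2 + 0.02 * p[, 1] + 0.3 * sin(p[, 2] / 15)
  subj_field <- surface_field(gfun(subj_v), units = "mm", mesh = subj)
  transferred <- transfer_field(subj_field, reg, subj)
  truth <- gfun(tps_apply(warp_true, canon$vertices))
  ok <- !transferred$missing_mask
  expect_gt(mean(ok), 0.98)
  expect_lt(max(abs(transferred$values[ok] - truth[ok])), 0.05)
})

test_that("field transfer is barycentric: exact for constants and linear fields", {
  canon <- wavy_patch(seed = 8)
  warp_true <- random_tps_deformation(canon, amplitude = 1, seed = 3)
  subj <- surface_mesh(tps_apply(warp_true, canon$vertices), canon$faces, "femur")
  reg <- register_to_canonical(subj, canon, n_control = 200, iterations = 4, seed = 5)

  cst <- surface_field(rep(2.7, nrow(subj$vertices)), units = "mm", mesh = subj)
  tc <- transfer_field(cst, reg, subj)
  ok <- !tc$missing_mask
  expect_lt(max(abs(tc$values[ok] - 2.7)), 1e-9)

  # linear fields are reproduced exactly at the corresponded position
  a <- c(0.01, -0.02, 0.03)
  lin <- surface_field(subj$vertices %*% a + 5, mesh = subj)
  tl <- transfer_field(lin, reg, subj)
  corr_pos <- with(reg$correspondence, {
    f <- subj$faces[face, , drop = FALSE]
    bary[, 1] * subj$vertices[f[, 1], ] +
      bary[, 2] * subj$vertices[f[, 2], ] +
      bary[, 3] * subj$vertices[f[, 3], ]
  })
  truth <- corr_pos %*% a + 5
  ok <- !tl$missing_mask
  expect_lt(max(abs(tl$values[ok] - truth[ok])), 1e-6)

  # min/max bounds: transferred values never exceed the subject range
  set.seed(30)
  rough <- surface_field(runif(nrow(subj$vertices), 1, 3), mesh = subj)
  tr <- transfer_field(rough, reg, subj)
  ok <- !tr$missing_mask
  expect_gte(min(tr$values[ok]), 1)
  expect_lte(max(tr$values[ok]), 3)

  # identity correspondence copies the field exactly
  reg_id <- register_to_canonical(subj, subj, n_control = 150, iterations = 2, seed = 2)
  tid <- transfer_field(lin, reg_id, subj)
  ok <- !tid$missing_mask
  expect_lt(max(abs(tid$values[ok] - lin$values[ok])), 1e-6)
})
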