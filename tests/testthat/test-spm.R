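test_that("vertex-wise OLS equals brute-force normal equations to 1e-10", {
  for (case in 1:20) {
    set.seed(600 + case)
    n <- sample(10:30, 1)
    p <- sample(2:4, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
    colnames(X) <- c("intercept", paste0("x", seq_len(p - 1)))
    Y <- matrix(rnorm(n * 10), n, 10)
    ci <- sample(seq_len(p), 1)
    fit <- fit_vertex_glm(Y, X, contrast = ci)
    cvec <- as.numeric(seq_len(p) == ci)
    XtX_inv <- solve(t(X) %*% X)
    for (v in 1:10) {
      b <- XtX_inv %*% t(X) %*% Y[, v]
      r <- Y[, v] - X %*% b
      s2 <- sum(r^2) / (n - p)
      tv <- as.numeric(t(cvec) %*% b) / sqrt(as.numeric(t(cvec) %*% XtX_inv %*% cvec) * s2)
      expect_lt(max(abs(fit$beta[, v] - b)), 1e-10)
      expect_lt(abs(fit$sigma2[v] - s2), 1e-10)
      expect_lt(abs(fit$t[v] - tv), 1e-10)
      expect_lt(abs(fit$p[v] - 2 * pt(-abs(tv), n - p)), 1e-12)
    }
  }
})

test_that("degenerate and trivial designs behave as documented", {
  set.seed(31)
  n <- 20
  X <- cbind(intercept = 1, noise = rnorm(n))
  Y <- matrix(2, n, 15)   # constant 2 mm everywhere
  fit <- fit_vertex_glm(Y, X, contrast = "noise")
  expect_equal(unname(fit$beta["intercept", ]), rep(2, 15))
  expect_equal(fit$t, rep(0, 15))

  Xbad <- cbind(intercept = 1, a = rnorm(n), b = 0)
  Xbad[, "b"] <- 2 * Xbad[, "a"]
  expect_error(fit_vertex_glm(Y, Xbad, contrast = "a"), "collinear.*b")
})

test_that("known regression effects are recovered within sampling error", {
  set.seed(99)
  n <- 200
  V <- 150
  x <- rnorm(n)
  X <- cbind(intercept = 1, dose = x)
  Y <- outer(x, rep(0.5, V)) + 2 + matrix(rnorm(n * V, 0, 0.1), n, V)
  fit <- fit_vertex_glm(Y, X, contrast = "dose")
  se <- sqrt(fit$sigma2 * as.numeric(t(c(0, 1)) %*% solve(t(X) %*% X) %*% c(0, 1)))
  covered <- abs(fit$beta["dose", ] - 0.5) <= 3 * se
  expect_gte(mean(covered), 0.95)
})

test_that("residual smoothness matches its discrete closed form and recovers known FWHM", {
  # white noise: E[(u_i - u_j)^2] = 2 per edge, so the pooled derivative
  # variance is 2 * mean(1 / edge_length^2) and the implied FWHM is
  # sqrt(2 log(2) / mean(1 / len^2)) -- the grid mixes unit and diagonal
  # edges, so this is not a single-edge-length formula
  grid <- mesh_grid(40, 40, spacing = 1)
  em <- casm:::mesh_edges(grid)
  len2 <- rowSums((grid$vertices[em$edges[, 1], ] - grid$vertices[em$edges[, 2], ])^2)
  fwhm_pred <- sqrt(2 * log(2) / mean(1 / len2))
  set.seed(5)
  R <- matrix(rnorm(60 * nrow(grid$vertices)), 60)
  est <- estimate_smoothness(R, grid)
  expect_lt(abs(est$fwhm - fwhm_pred) / fwhm_pred, 0.25)
  expect_equal(est$resels[["R0"]], 1)

  # construct-and-recover: fields smoothed to FWHM 8 mm on a dense grid
  dense <- mesh_grid(60, 60, spacing = 1)
  R8 <- t(vapply(1:40, function(i) {
    smooth_noise_field(dense, sd = 1, fwhm = 8, seed = 7000 + i)
  }, numeric(nrow(dense$vertices))))
  est8 <- estimate_smoothness(R8, dense)
  expect_lt(abs(est8$fwhm - 8) / 8, 0.20)

  # resel proportionality: doubling the area at fixed FWHM doubles R2
  half <- mesh_grid(41, 41, spacing = 1)
  full <- mesh_grid(81, 41, spacing = 1)
  a1 <- casm:::submesh_metrics(half, rep(TRUE, nrow(half$vertices)))$total_area
  a2 <- casm:::submesh_metrics(full, rep(TRUE, nrow(full$vertices)))$total_area
  expect_equal((a2 / est8$fwhm^2) / (a1 / est8$fwhm^2), 2, tolerance = 0.01)

  expect_error(estimate_smoothness(matrix(0, 10, 5), grid), "degenerate")
})

test_that("RFT threshold reduces to the Student quantile and is monotone in resels", {
  df <- 50
  thr0 <- rft_threshold(df, c(R0 = 1, R1 = 0, R2 = 0), alpha = 0.05)
  expect_equal(thr0, qt(1 - 0.025, df), tolerance = 1e-5)
  thr0_one <- rft_threshold(df, c(R0 = 1, R1 = 0, R2 = 0), alpha = 0.05,
                            two_sided = FALSE)
  expect_equal(thr0_one, qt(1 - 0.05, df), tolerance = 1e-5)

  sweep_r2 <- seq(10, 1000, length.out = 10)
  thr <- vapply(sweep_r2, function(r2) {
    rft_threshold(df, c(R0 = 1, R1 = 5, R2 = r2), alpha = 0.05)
  }, numeric(1))
  expect_true(all(diff(thr) > 0))
  expect_true(all(thr > thr0))

  expect_error(rft_threshold(df, c(R0 = 1, R1 = 0, R2 = 0), alpha = 1.2),
               "alpha")
})

test_that("BH threshold equals the exhaustive step-up oracle", {
  expect_equal(fdr_threshold(rep(0.9, 50), rnorm(50)), Inf)

  # hand-computed: only the two smallest pass p_(k) <= 0.01 k
  p5 <- c(0.001, 0.008, 0.039, 0.041, 0.6)
  t5 <- c(5, -4, 2.2, 2.1, 0.4)
  expect_equal(fdr_threshold(p5, t5, q = 0.05), 4)

  brute_bh <- function(p, tv, q) {
    m <- length(p)
    ord <- order(p)
    best_k <- 0
    for (k in seq_len(m)) if (p[ord][k] <= k * q / m) best_k <- k
    if (best_k == 0) return(Inf)
    min(abs(tv[ord][seq_len(best_k)]))
  }
  for (rep in 1:100) {
    set.seed(800 + rep)
    m <- sample(5:200, 1)
    tv <- rnorm(m) * 2
    p <- 2 * pt(-abs(tv), df = 30)
    if (rep %% 3 == 0) p <- runif(m)   # include non-t-consistent vectors
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(fdr_threshold(p, tv, q), brute_bh(p, tv, q))
  }
})

test_that("run_spm composes the stages and flags a planted effect", {
  mesh <- mesh_grid(30, 30, spacing = 1)
  V <- nrow(mesh$vertices)
  n <- 80
  set.seed(1234)
  x <- rnorm(n)
  X <- cbind(intercept = 1, dose = x)
  ctr <- mesh$vertices[445, 1:2]
  d2 <- (mesh$vertices[, 1] - ctr[1])^2 + (mesh$vertices[, 2] - ctr[2])^2
  effect <- 0.4 * exp(-d2 / (2 * (6 / sqrt(8 * log(2)))^2 * 4))
  Y <- 2 + outer(x, effect) +
    t(vapply(1:n, function(i) smooth_noise_field(mesh, 0.25, 3, seed = 4000 + i),
             numeric(V)))
  spm <- run_spm(Y, X, mesh, contrast = "dose")
  expect_equal(spm$t_threshold_final,
               min(spm$t_threshold_rft, spm$t_threshold_fdr))
  expect_gte(spm$t_threshold_final, qt(1 - 0.025, spm$df) - 1e-9)
  eff_hat <- as.numeric(t(spm$design$contrast_vector) %*% spm$beta)
  expect_gt(cor(eff_hat, effect), 0.8)
  core <- effect > 0.3
  expect_gt(mean(spm$significant[core]), 0.5)
  # effect direction is carried by the sign of t
  expect_gt(mean(spm$t[core] > 0), 0.99)

  # permuting the covariate destroys significance
  n_perm_sig <- vapply(1:5, function(s) {
    set.seed(s)
    Xp <- cbind(intercept = 1, dose = sample(x))
    sum(run_spm(Y, Xp, mesh, contrast = "dose")$significant)
  }, numeric(1))
  expect_gte(mean(n_perm_sig == 0), 0.8)

  # glance/tidy/autoplot surfaces
  g <- glance(spm)
  expect_equal(g$n_analysed, V)
  expect_equal(g$df, n - 2)
  td <- tidy(spm)
  expect_equal(nrow(td), V)
  expect_s3_class(autoplot(spm), "ggplot")
})

test_that("run_spm on a near-constant intercept contrast marks everything", {
  mesh <- mesh_grid(12, 12, spacing = 1)
  V <- nrow(mesh$vertices)
  set.seed(3)
  Y <- matrix(2 + rnorm(30 * V, 0, 1e-4), 30, V)
  X <- cbind(intercept = 1, noise = rnorm(30))
  spm <- run_spm(Y, X, mesh, contrast = "intercept")
  expect_true(all(spm$significant))
  expect_equal(mean(spm$beta["intercept", ]), 2, tolerance = 1e-4)
})

test_that("vertices missing in any subject are excluded for all", {
  mesh <- mesh_grid(10, 10, spacing = 1)
  V <- nrow(mesh$vertices)
  set.seed(8)
  Y <- matrix(rnorm(40 * V, 2, 0.2), 40, V)
  Y[5, 1:7] <- NA
  Y[21, 5] <- NA
  X <- cbind(intercept = 1, z = rnorm(40))
  spm <- run_spm(Y, X, mesh, contrast = "z")
  expect_false(any(spm$vertex_mask[1:7]))
  expect_true(all(spm$vertex_mask[8:V]))
  expect_true(all(is.na(spm$t[1:7])))
  expect_false(any(spm$significant[1:7]))

  # export: files round-trip through the mesh reader
  dir <- withr::local_tempdir()
  paths <- write_spm_result(spm, dir, "example")
  back <- load_mesh(file.path(dir, "example.ply"))
  expect_setequal(names(back$fields), c("beta", "t", "p", "mask"))
  meta <- jsonlite::read_json(file.path(dir, "example.json"))
  expect_equal(meta$df, spm$df)
})
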