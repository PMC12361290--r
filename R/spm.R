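#' Vertex-wise ordinary least squares
#'
#' Fits the same general linear model at every vertex of a cohort
#' thickness matrix: `beta = (X'X)^-1 X'y`, error variance
#' `RSS / (n - p)`, and the contrast t-statistic
#' `c'beta / sqrt(c'(X'X)^-1 c * sigma^2)` with two-sided Student
#' p-values on `n - p` degrees of freedom. Vertices with a missing value
#' in any subject are excluded for all subjects (complete-vertex
#' analysis).
#'
#' @param thickness_matrix `n_subjects x n_vertices` matrix, mm.
#' @param design A `design_matrix` from [build_design()], or a plain
#'   numeric matrix (then `contrast` must name or index a column).
#' @param contrast Contrast column for a plain-matrix design.
#' @return A `vertex_glm` list: `beta` (p x V), `residuals` (n x V, NA at
#'   excluded vertices), `sigma2`, `t`, `p`, `df`, `vertex_mask`
#'   (TRUE = analysed), `design`.
#' @export
fit_vertex_glm <- function(thickness_matrix, design, contrast = NULL) {
  Y <- as.matrix(thickness_matrix)
  if (inherits(design, "design_matrix")) {
    X <- design$X
    cvec <- design$contrast_vector
  } else {
    X <- as.matrix(design)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (is.null(contrast)) stop("`contrast` is required for a plain design matrix")
    ci <- if (is.character(contrast)) match(contrast, colnames(X)) else contrast
    if (is.na(ci)) stop(sprintf("contrast '%s' not found in design", contrast))
    cvec <- as.numeric(seq_len(ncol(X)) == ci)
  }
  n <- nrow(Y)
  p <- ncol(X)
  if (nrow(X) != n) stop("design rows must match thickness matrix rows")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop(sprintf("design is rank deficient; collinear columns: %s",
                 paste(bad, collapse = ", ")))
  }
  df <- n - p
  if (df < 1L) stop("need n_subjects > p for at least 1 error df")
  vertex_mask <- colSums(is.na(Y)) == 0L
  V <- ncol(Y)
  beta <- matrix(NA_real_, p, V, dimnames = list(colnames(X), NULL))
  res <- matrix(NA_real_, n, V)
  sigma2 <- tval <- pval <- rep(NA_real_, V)
  if (any(vertex_mask)) {
    Yc <- Y[, vertex_mask, drop = FALSE]
    bhat <- qr.coef(qrX, Yc)
    fit <- X %*% bhat
    r <- Yc - fit
    s2 <- colSums(r^2) / df
    XtX_inv_c <- chol2inv(qr.R(qrX)) %*% cvec
    c_var <- as.numeric(t(cvec) %*% XtX_inv_c)
    num <- as.numeric(t(cvec) %*% bhat)
    den <- sqrt(c_var * s2)
    tv <- ifelse(den > 0, num / den,
                 ifelse(abs(num) < 1e-12, 0, sign(num) * Inf))
    beta[, vertex_mask] <- bhat
    res[, vertex_mask] <- r
    sigma2[vertex_mask] <- s2
    tval[vertex_mask] <- tv
    pval[vertex_mask] <- 2 * stats::pt(-abs(tv), df)
  }
  structure(
    list(beta = beta, residuals = res, sigma2 = sigma2, t = tval, p = pval,
         df = df, vertex_mask = vertex_mask,
         design = list(columns = colnames(X), contrast_vector = cvec)),
    class = "vertex_glm"
  )
}

# metrics of the sub-mesh induced by a vertex mask (faces whose three
# vertices are all retained)
submesh_metrics <- function(mesh, vertex_mask) {
  f <- mesh$faces
  keep_f <- vertex_mask[f[, 1]] & vertex_mask[f[, 2]] & vertex_mask[f[, 3]]
  fk <- f[keep_f, , drop = FALSE]
  if (nrow(fk) == 0L) {
    return(list(total_area = 0, boundary_length = 0, euler_characteristic = 0,
                mean_edge_length = NA_real_))
  }
  sub <- structure(
    list(vertices = mesh$vertices, faces = fk, patch_label = mesh$patch_label),
    class = "surface_mesh"
  )
  m <- mesh_metrics(sub)
  used <- length(unique(as.vector(fk)))
  m$euler_characteristic <- used - nrow(m$edges) + nrow(fk)
  m
}

#' Residual smoothness and resolution-element counts
#'
#' Residual vectors are normalised to unit norm per vertex; for each mesh
#' edge with both endpoints analysed, the squared difference of the
#' normalised residuals summed over subjects divided by the squared edge
#' length estimates the variance of the spatial derivative of the
#' underlying unit-variance error field. Pooling over edges gives
#' `lambda`, and `FWHM = sqrt(4 log(2) / lambda)` is the width of the
#' Gaussian kernel with that derivative variance. Resolution elements of
#' the analysed sub-mesh: `R0` its Euler characteristic, `R1` half the
#' boundary length in FWHM units, `R2` the area in FWHM^2 units.
#'
#' @param residual_matrix `n x V` residual matrix (from
#'   [fit_vertex_glm()]); columns that are all `NA` are excluded.
#' @param mesh The canonical `surface_mesh`.
#' @param vertex_mask Optional logical vector of analysed vertices;
#'   defaults to columns without `NA`.
#' @return A list: `fwhm` (mm), `resels` (named numeric, `R0`, `R1`,
#'   `R2`), `lambda`.
#' @export
estimate_smoothness <- function(residual_matrix, mesh, vertex_mask = NULL) {
  R <- as.matrix(residual_matrix)
  if (is.null(vertex_mask)) vertex_mask <- colSums(is.na(R)) == 0L
  norms <- sqrt(colSums(R^2))
  if (any(vertex_mask & (is.na(norms) | norms < 1e-14))) {
    stop("degenerate smoothness: zero-variance residuals at analysed vertices")
  }
  U <- sweep(R, 2, norms, "/")
  em <- mesh_edges(mesh)
  keep <- vertex_mask[em$edges[, 1]] & vertex_mask[em$edges[, 2]]
  e <- em$edges[keep, , drop = FALSE]
  if (nrow(e) == 0L) stop("no mesh edges between analysed vertices")
  len2 <- rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                   mesh$vertices[e[, 2], , drop = FALSE])^2)
  d2 <- colSums((U[, e[, 1], drop = FALSE] - U[, e[, 2], drop = FALSE])^2)
  lambda <- mean(d2 / len2)
  fwhm <- sqrt(4 * log(2) / lambda)
  sm <- submesh_metrics(mesh, vertex_mask)
  resels <- c(
    R0 = as.numeric(sm$euler_characteristic),
    R1 = sm$boundary_length / (2 * fwhm),
    R2 = sm$total_area / fwhm^2
  )
  list(fwhm = fwhm, resels = resels, lambda = lambda)
}

# expected Euler characteristic of the excursion set of a t field above t
expected_ec <- function(t, df, resels) {
  rho0 <- stats::pt(t, df, lower.tail = FALSE)
  rho1 <- sqrt(4 * log(2)) / (2 * pi) * (1 + t^2 / df)^(-(df - 1) / 2)
  rho2 <- (4 * log(2)) / (2 * pi)^(3 / 2) *
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df / 2) *
    t * (1 + t^2 / df)^(-(df - 1) / 2)
  resels[["R0"]] * rho0 + resels[["R1"]] * rho1 + resels[["R2"]] * rho2
}

#' Random-field-theory t threshold
#'
#' Smallest t at which the expected Euler characteristic of the excursion
#' set, summed over the 0-, 1- and 2-dimensional resel counts with the
#' standard t-field Euler-characteristic densities, drops to the tail
#' level (`alpha / 2` per tail for two-sided inference). Solved by
#' bisection to 1e-6.
#'
#' @param df Error degrees of freedom (>= 1).
#' @param resels Named numeric `R0`, `R1`, `R2`.
#' @param alpha Family-wise level in (0, 1).
#' @param two_sided If `TRUE` (default) use `alpha / 2` per tail.
#' @return The critical t value.
#' @export
rft_threshold <- function(df, resels, alpha = 0.05, two_sided = TRUE) {
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)")
  }
  if (df < 1) stop("`df` must be >= 1")
  target <- if (two_sided) alpha / 2 else alpha
  f <- function(t) expected_ec(t, df, resels) - target
  lo <- 0
  hi <- 10
  while (f(hi) > 0 && hi < 1e6) hi <- hi * 2
  if (f(lo) <= 0) return(0)
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Benjamini-Hochberg t threshold
#'
#' Step-up false-discovery-rate procedure on the non-missing vertex
#' p-values: find the largest k with `p_(k) <= k q / m`; the returned
#' threshold is the smallest `|t|` among the rejected vertices, or `Inf`
#' when nothing is rejected.
#'
#' @param p_map Vertex p-values (may contain `NA`).
#' @param t_map Matching t-statistics.
#' @param q FDR level (default 0.05).
#' @return Critical `|t|`, or `Inf` for an empty rejection set.
#' @export
fdr_threshold <- function(p_map, t_map, q = 0.05) {
  ok <- !is.na(p_map)
  p <- p_map[ok]
  tv <- abs(t_map[ok])
  m <- length(p)
  if (m == 0L) return(Inf)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) * q / m)
  if (length(k) == 0L) return(Inf)
  kmax <- max(k)
  min(tv[ord][seq_len(kmax)])
}

#' Vertex-wise statistical parametric mapping
#'
#' Composes the vertex-wise general linear model, residual smoothness
#' estimation, and the combined multiple-comparison correction: the final
#' critical value is the minimum (the less conservative) of the
#' random-field-theory peak threshold and the Benjamini-Hochberg
#' threshold, both two-sided at level `alpha`. The significance mask is
#' `|t| >=` the final threshold at analysed vertices; the sign of t
#' records the effect direction.
#'
#' @param thickness_matrix `n_subjects x n_vertices` matrix, mm.
#' @param design A `design_matrix` (or plain matrix with `contrast`).
#' @param mesh The canonical `surface_mesh` the columns live on.
#' @param alpha Significance level (default 0.05).
#' @param contrast Contrast for plain-matrix designs.
#' @param smooth_fwhm Optional pre-smoothing FWHM in mm applied to every
#'   subject's map before fitting (default 0 = off).
#' @return A `casm_spm` object; see [glance.casm_spm()] and
#'   [tidy.casm_spm()] for tabular summaries.
#' @export
run_spm <- function(thickness_matrix, design, mesh, alpha = 0.05,
                    contrast = NULL, smooth_fwhm = 0) {
  Y <- as.matrix(thickness_matrix)
  if (ncol(Y) != nrow(mesh$vertices)) {
    stop("thickness matrix columns must match mesh vertex count")
  }
  if (smooth_fwhm > 0) {
    for (i in seq_len(nrow(Y))) {
      Y[i, ] <- smooth_field(surface_field(Y[i, ]), mesh, smooth_fwhm)$values
    }
  }
  fit <- fit_vertex_glm(Y, design, contrast = contrast)
  sm <- estimate_smoothness(fit$residuals, mesh, fit$vertex_mask)
  thr_rft <- rft_threshold(fit$df, sm$resels, alpha = alpha, two_sided = TRUE)
  thr_fdr <- fdr_threshold(fit$p, fit$t, q = alpha)
  thr <- min(thr_rft, thr_fdr)
  sig <- !is.na(fit$t) & abs(fit$t) >= thr
  structure(
    list(
      beta = fit$beta, t = fit$t, p = fit$p, df = fit$df,
      sigma2 = fit$sigma2, residuals = fit$residuals,
      vertex_mask = fit$vertex_mask,
      fwhm = sm$fwhm, resels = sm$resels,
      t_threshold_rft = thr_rft, t_threshold_fdr = thr_fdr,
      t_threshold_final = thr, significant = sig, alpha = alpha,
      design = fit$design, mesh = mesh
    ),
    class = "casm_spm"
  )
}

#' @export
print.casm_spm <- function(x, ...) {
  cat(sprintf(
    paste0("<casm_spm> %d vertices analysed, df = %d, FWHM = %.2f mm\n",
           "  thresholds: RFT %.3f, FDR %s, final %.3f (alpha = %.2f)\n",
           "  significant vertices: %d (%.1f%%)\n"),
    sum(x$vertex_mask), x$df, x$fwhm,
    x$t_threshold_rft,
    if (is.finite(x$t_threshold_fdr)) sprintf("%.3f", x$t_threshold_fdr) else "Inf",
    x$t_threshold_final, x$alpha,
    sum(x$significant), 100 * mean(x$significant)
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-vertex results of an SPM fit
#'
#' @param x A `casm_spm` object.
#' @param ... Unused.
#' @return A tibble with one row per vertex: `vertex`, `beta` (contrast
#'   effect, mm per covariate unit), `t`, `p_value`, `significant`,
#'   `analysed`.
#' @method tidy casm_spm
#' @export
tidy.casm_spm <- function(x, ...) {
  cvec <- x$design$contrast_vector
  eff <- as.numeric(t(cvec) %*% x$beta)
  tibble::tibble(
    vertex = seq_along(x$t),
    beta = eff,
    t = x$t,
    p_value = x$p,
    significant = x$significant,
    analysed = x$vertex_mask
  )
}

#' One-row summary of an SPM fit
#'
#' @param x A `casm_spm` object.
#' @param ... Unused.
#' @return A one-row tibble: degrees of freedom, estimated FWHM, resel
#'   counts, the three thresholds, and significant-vertex counts.
#' @method glance casm_spm
#' @export
glance.casm_spm <- function(x, ...) {
  tibble::tibble(
    df = x$df, fwhm_mm = x$fwhm,
    resels_0 = x$resels[["R0"]], resels_1 = x$resels[["R1"]],
    resels_2 = x$resels[["R2"]],
    t_threshold_rft = x$t_threshold_rft,
    t_threshold_fdr = x$t_threshold_fdr,
    t_threshold_final = x$t_threshold_final,
    alpha = x$alpha,
    n_vertices = length(x$t),
    n_analysed = sum(x$vertex_mask),
    n_significant = sum(x$significant)
  )
}

#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
#' @export
ggplot2::autoplot

#' Plot an SPM result map
#'
#' Projects the mesh to its first two coordinates and colours vertices by
#' the chosen statistic through a blue-white-red diverging scale centred
#' at zero; non-significant vertices are washed out, mirroring the usual
#' presentation of surface statistical maps.
#'
#' @param object A `casm_spm` object.
#' @param map `"t"` (default), `"beta"` or `"p"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot casm_spm
#' @export
autoplot.casm_spm <- function(object, map = c("t", "beta", "p"), ...) {
  map <- match.arg(map)
  td <- tidy.casm_spm(object)
  td$value <- switch(map, t = td$t, beta = td$beta, p = td$p_value)
  td$x <- object$mesh$vertices[, 1]
  td$y <- object$mesh$vertices[, 2]
  lim <- max(abs(td$value), na.rm = TRUE)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$value,
                                     alpha = .data$significant), size = 1.2) +
    ggplot2::scale_colour_gradient2(low = "#b2182b", mid = "white",
                                    high = "#2166ac", limits = c(-lim, lim),
                                    name = map) +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.25, `TRUE` = 1),
                                guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "medial-lateral (mm)", y = "posterior-anterior (mm)",
      title = sprintf("%s map (final |t| threshold %.2f)", map,
                      object$t_threshold_final)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.casm_spm
#' @export
plot_spm <- function(object, map = "t", ...) autoplot.casm_spm(object, map = map, ...)

#' Export an SPM result as a mesh file plus JSON sidecar
#'
#' Writes the canonical mesh with per-vertex `beta`, `t`, `p` and `mask`
#' fields (and a colour-coded t map with non-significant vertices
#' desaturated) next to a JSON sidecar holding the degrees of freedom,
#' smoothness, resels, thresholds and design description.
#'
#' @param x A `casm_spm` object.
#' @param dir Output directory (created if needed).
#' @param name Stem for the output files.
#' @return Paths of the written files, invisibly.
#' @export
write_spm_result <- function(x, dir, name = "spm") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mesh_path <- file.path(dir, paste0(name, ".ply"))
  td <- tidy.casm_spm(x)
  tfield <- surface_field(x$t, units = "t")
  save_mesh(
    x$mesh, mesh_path,
    fields = list(
      beta = surface_field(td$beta),
      t = tfield,
      p = surface_field(x$p, units = "p"),
      mask = surface_field(as.numeric(x$significant))
    ),
    color_field = tfield, color_mask = x$significant
  )
  json_path <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(
    list(
      df = x$df, fwhm_mm = x$fwhm, resels = as.list(x$resels),
      t_threshold_rft = x$t_threshold_rft,
      t_threshold_fdr = x$t_threshold_fdr,
      t_threshold_final = x$t_threshold_final,
      alpha = x$alpha,
      design_columns = x$design$columns,
      contrast = x$design$columns[x$design$contrast_vector == 1],
      n_significant = sum(x$significant)
    ),
    json_path, auto_unbox = TRUE, digits = NA
  )
  invisible(c(mesh_path, json_path))
}
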