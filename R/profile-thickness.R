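#' Intensity profile along a vertex normal
#'
#' Image intensities sampled at regular spacing along the inward normal of
#' an outer-surface vertex. `origin_offset` locates the first sample
#' relative to the vertex (negative = outside the cartilage).
#'
#' @param samples Numeric vector of intensities, at least 8 samples.
#' @param spacing Sample spacing in mm, > 0.
#' @param origin_offset Position of the first sample in mm.
#' @return An object of class `intensity_profile`.
#' @export
intensity_profile <- function(samples, spacing, origin_offset = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 8L) stop("an intensity profile needs at least 8 samples")
  if (!is.finite(spacing) || spacing <= 0) stop("`spacing` must be > 0")
  structure(
    list(samples = samples, spacing = spacing, origin_offset = origin_offset),
    class = "intensity_profile"
  )
}

profile_positions <- function(profile) {
  profile$origin_offset + (seq_along(profile$samples) - 1) * profile$spacing
}

#' Forward model for a cartilage intensity profile
#'
#' Two point-spread-blurred intensity steps with three plateaus: outside
#' tissue, cartilage, and bone. The profile is
#' `L_out + (L_cart - L_out) * pnorm((x - x_outer)/sigma) +
#'  (L_bone - L_cart) * pnorm((x - x_inner)/sigma)`,
#' the convolution of an ideal three-level step profile with a Gaussian
#' point-spread function of scale `sigma`.
#'
#' @param x Positions along the normal, mm.
#' @param x_outer,x_inner Interface positions (outer cartilage surface and
#'   cartilage-bone interface), mm, `x_inner >= x_outer`.
#' @param sigma Gaussian PSF scale, mm.
#' @param levels Length-3 vector `(L_outside, L_cartilage, L_bone)`.
#' @return Model intensities at `x`.
#' @export
profile_forward_model <- function(x, x_outer, x_inner, sigma, levels) {
  levels[1] +
    (levels[2] - levels[1]) * stats::pnorm((x - x_outer) / sigma) +
    (levels[3] - levels[2]) * stats::pnorm((x - x_inner) / sigma)
}

# Residual sum of squares with plateaus profiled out by linear least
# squares (variable projection): for fixed interfaces and sigma the model
# is linear in (L_out, L_cart - L_out, L_bone - L_cart).
profile_rss <- function(par, x, y, psf_bounds) {
  x_outer <- par[1]
  x_inner <- par[1] + par[2]
  sigma <- par[3]
  A <- cbind(1, stats::pnorm((x - x_outer) / sigma), stats::pnorm((x - x_inner) / sigma))
  fit <- tryCatch(stats::lm.fit(A, y), error = function(e) NULL)
  if (is.null(fit)) return(list(rss = Inf))
  res <- y - A %*% fit$coefficients
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  list(
    rss = sum(res^2),
    levels = c(cf[1], cf[1] + cf[2], cf[1] + cf[2] + cf[3])
  )
}

#' Fit the blurred two-step model to an intensity profile
#'
#' Least-squares fit of [profile_forward_model()] by variable projection:
#' the three plateau levels are solved linearly for each trial of the
#' nonlinear parameters (outer interface, interface separation, PSF scale),
#' which are optimised by bounded quasi-Newton iterations from multiple
#' seeded starts. Start candidates are pairs of gradient-magnitude extrema
#' of the sampled profile, lightly jittered (seeded) to escape grid
#' alignment.
#'
#' @param profile An [intensity_profile()].
#' @param psf_bounds Lower and upper bound on the PSF sigma, mm.
#' @param seed Integer seed controlling the multi-start jitter.
#' @param n_starts Maximum number of optimisation starts.
#' @return A `profile_fit` list: `x_outer`, `x_inner`, `levels`,
#'   `sigma_psf`, `rss`, `converged`.
#' @export
fit_profile_model <- function(profile, psf_bounds = c(0.1, 1.0), seed = 1L,
                              n_starts = 8L) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (length(psf_bounds) != 2L || any(psf_bounds <= 0) || diff(psf_bounds) < 0) {
    stop("`psf_bounds` must be two positive ordered values")
  }
  x <- profile_positions(profile)
  y <- profile$samples
  if (length(y) < 6L) stop("fewer samples than model parameters")
  failed <- list(
    x_outer = NA_real_, x_inner = NA_real_, levels = rep(NA_real_, 3),
    sigma_psf = NA_real_, rss = sum((y - mean(y))^2), converged = FALSE
  )
  class(failed) <- "profile_fit"
  if (stats::sd(y) < 1e-12 * (abs(mean(y)) + 1)) return(failed)

  # candidate interfaces at local extrema of |gradient|
  g <- abs(diff(y)) / profile$spacing
  xm <- (x[-1] + x[-length(x)]) / 2
  ord <- order(g, decreasing = TRUE)
  cand <- sort(xm[ord[seq_len(min(4L, length(ord)))]])
  pairs <- expand.grid(a = cand, b = cand)
  pairs <- pairs[pairs$b > pairs$a, , drop = FALSE]
  if (nrow(pairs) == 0L) pairs <- data.frame(a = cand[1], b = cand[1] + profile$spacing)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  pairs <- pairs[order(-(g[match(pairs$a, xm)] + g[match(pairs$b, xm)])), , drop = FALSE]
  pairs <- pairs[seq_len(min(n_starts, nrow(pairs))), , drop = FALSE]
  jit <- profile$spacing * 0.2
  sigma0 <- sqrt(prod(psf_bounds))

  lo <- c(x[1] - profile$spacing, 0, psf_bounds[1])
  hi <- c(x[length(x)] + profile$spacing, diff(range(x)), psf_bounds[2])
  best <- NULL
  for (i in seq_len(nrow(pairs))) {
    p0 <- c(
      pairs$a[i] + stats::runif(1, -jit, jit),
      max(pairs$b[i] - pairs$a[i] + stats::runif(1, -jit, jit), 0),
      sigma0
    )
    p0 <- pmin(pmax(p0, lo), hi)
    opt <- tryCatch(
      stats::optim(p0, function(p) profile_rss(p, x, y, psf_bounds)$rss,
                   method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 200)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) return(failed)
  conv_ok <- best$convergence == 0
  if (!conv_ok) {
    # line search can abort with a flat gradient at an already-converged
    # optimum; accept if a derivative-free polish finds no improvement
    polish <- stats::optim(best$par, function(p) {
      p <- pmin(pmax(p, lo), hi)
      profile_rss(p, x, y, psf_bounds)$rss
    }, method = "Nelder-Mead", control = list(maxit = 200))
    if (polish$value < best$value) {
      best$par <- pmin(pmax(polish$par, lo), hi)
      best$value <- polish$value
    }
    conv_ok <- polish$value >= best$value * (1 - 1e-6) - 1e-12
  }
  full <- profile_rss(best$par, x, y, psf_bounds)
  contrast <- max(abs(diff(full$levels)))
  noise_scale <- sqrt(best$value / max(length(y) - 6, 1))
  fit <- list(
    x_outer = best$par[1],
    x_inner = best$par[1] + best$par[2],
    levels = unname(full$levels),
    sigma_psf = best$par[3],
    rss = best$value,
    converged = conv_ok && contrast > 4 * noise_scale
  )
  class(fit) <- "profile_fit"
  fit
}

#' Per-vertex thickness from intensity profiles
#'
#' Fits the blurred two-step model at every vertex and reports thickness
#' `x_inner - x_outer` in mm. Non-converged fits and separations below
#' `min_separation` are set to thickness 0 with quality flag 1
#' (denuded / unresolvable), mirroring regions of full-thickness cartilage
#' loss; all other vertices carry flag 0.
#'
#' @param outer_mesh The outer-surface `surface_mesh`.
#' @param profiles List of [intensity_profile()], one per vertex.
#' @param psf_bounds PSF sigma bounds, mm.
#' @param min_separation Smallest resolvable interface separation, mm.
#' @param seed Integer seed forwarded to the per-vertex fits.
#' @return A list with `thickness` (`surface_field`, mm) and `quality`
#'   (`surface_field`, 0 = measured, 1 = denuded/unresolvable).
#' @export
thickness_from_profiles <- function(outer_mesh, profiles,
                                    psf_bounds = c(0.1, 1.0),
                                    min_separation = 0.25, seed = 1L) {
  n <- nrow(outer_mesh$vertices)
  if (length(profiles) != n) {
    stop(sprintf("got %d profiles for %d vertices", length(profiles), n))
  }
  thick <- numeric(n)
  qual <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_profile_model(profiles[[i]], psf_bounds, seed = seed + i)
    sep <- fit$x_inner - fit$x_outer
    if (!fit$converged || !is.finite(sep) || sep < min_separation) {
      thick[i] <- 0
      qual[i] <- 1
    } else {
      thick[i] <- sep
    }
  }
  list(
    thickness = surface_field(thick, units = "mm", mesh = outer_mesh),
    quality = surface_field(qual, units = "dimensionless", mesh = outer_mesh)
  )
}

#' Per-vertex thickness from an outer/inner surface pair
#'
#' For each outer-surface vertex a ray is cast along the inward normal
#' (opposite the outward vertex normal) with a small origin offset to
#' avoid self-intersection; thickness is the distance to the first
#' intersection with the inner mesh. Rays that miss within
#' `max_thickness` fall back to the unsigned closest-point distance when
#' that distance is within `max_thickness`, and are missing otherwise.
#'
#' @param outer_mesh Outer cartilage `surface_mesh` with outward-oriented
#'   normals (away from bone).
#' @param inner_mesh Inner (cartilage-bone) `surface_mesh`.
#' @param max_thickness Physiologic ceiling in mm (default 10).
#' @return A `surface_field` of thickness in mm.
#' @export
thickness_from_surface_pair <- function(outer_mesh, inner_mesh,
                                        max_thickness = 10) {
  nrm <- vertex_normals(outer_mesh)
  fb <- face_blocks(inner_mesh)
  n <- nrow(outer_mesh$vertices)
  thick <- rep(NA_real_, n)
  miss <- logical(n)
  hit_in <- hit_out <- 0L
  for (i in seq_len(n)) {
    if (anyNA(nrm[i, ])) { miss[i] <- TRUE; next }
    d <- -nrm[i, ]  # inward
    t_hit <- ray_first_hit(outer_mesh$vertices[i, ], d, fb, eps = 1e-6)
    if (!is.na(t_hit) && t_hit <= max_thickness) {
      thick[i] <- t_hit
      hit_in <- hit_in + 1L
    } else {
      # probe the opposite direction to diagnose inconsistent winding
      t_op <- ray_first_hit(outer_mesh$vertices[i, ], nrm[i, ], fb, eps = 1e-6)
      if (!is.na(t_op) && t_op <= max_thickness) hit_out <- hit_out + 1L
      thick[i] <- NA_real_
    }
  }
  if (hit_out > n / 2 && hit_out > 2L * hit_in) {
    stop("orientation error: inward rays miss the inner surface but outward rays hit it; check face winding")
  }
  fallback <- which(is.na(thick) & !miss)
  if (length(fallback)) {
    cp <- closest_point_on_mesh(outer_mesh$vertices[fallback, , drop = FALSE], inner_mesh)
    ok <- cp$distance <= max_thickness
    thick[fallback[ok]] <- cp$distance[ok]
  }
  surface_field(thick, units = "mm", mesh = outer_mesh)
}

# seeded RNG scoping helpers: save/restore the global .Random.seed so
# seeded internals do not disturb the caller's RNG stream
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
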