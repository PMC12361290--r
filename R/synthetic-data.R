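#' Specification of a synthetic study cohort
#'
#' Default values reproduce the demographic and pathology mix of a knee
#' osteoarthritis imaging cohort of 287 patients: 22% male (Bernoulli 0.22); age
#' 66.4 (7.1) years; height 167.1 (10.0) cm; weight 78.2 (15.8) kg; BMI
#' derived as weight / height^2 so it carries the strong height/weight
#' collinearity that motivates dropping it from multivariable models;
#' KL grades distributed (54, 76, 63, 84, 10)/287 over 0-4; compartmental
#' prevalence of grade > 0 per pathology: meniscal extrusion 60% medial /
#' 16% lateral, BMLs 35% / 24% / 56% (medial / lateral / patellofemoral),
#' osteophytes 79% / 64% / 67%; medial JSN 47%, lateral JSN 15%.
#'
#' @param n_subjects Number of subjects (default 287).
#' @param prop_male Proportion of male subjects.
#' @param age_mean,age_sd,height_mean,height_sd,weight_mean,weight_sd
#'   Demographic moments (years, cm, kg).
#' @param height_sex_shift Male-female difference in mean height, cm; the
#'   marginal mean stays `height_mean` regardless.
#' @param height_weight_cor Correlation between height and weight.
#' @param kl_probs Probabilities of KL grades 0-4.
#' @param jsn_prev Named prevalence of joint space narrowing > 0
#'   (`medial`, `lateral`).
#' @param moaks_prev Named prevalence of compartmental grade > 0 for the
#'   eight MOAKS compartments.
#' @param grade_probs Conditional distribution of grades 1-3 given
#'   grade > 0.
#' @param noise_sd,noise_fwhm_scale Thickness noise SD (mm) and noise
#'   FWHM as a multiple of the mean edge length.
#' @param seed Root seed; all sampling is deterministic given it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 287L,
                        prop_male = 0.22,
                        age_mean = 66.4, age_sd = 7.1,
                        height_mean = 167.1, height_sd = 10.0,
                        weight_mean = 78.2, weight_sd = 15.8,
                        height_sex_shift = 10,
                        height_weight_cor = 0.4,
                        kl_probs = c(54, 76, 63, 84, 10) / 287,
                        jsn_prev = c(medial = 0.47, lateral = 0.15),
                        moaks_prev = c(
                          extrusion_medial = 0.60, extrusion_lateral = 0.16,
                          bml_medial = 0.35, bml_lateral = 0.24, bml_pf = 0.56,
                          ost_medial = 0.79, ost_lateral = 0.64, ost_pf = 0.67
                        ),
                        grade_probs = c(0.5, 0.35, 0.15),
                        noise_sd = 0.3, noise_fwhm_scale = 3,
                        seed = 1L) {
  stopifnot(
    n_subjects >= 1, prop_male >= 0, prop_male <= 1,
    age_sd > 0, height_sd > 0, weight_sd > 0,
    all(kl_probs >= 0), abs(sum(kl_probs) - 1) < 1e-8,
    all(jsn_prev >= 0 & jsn_prev <= 1),
    all(moaks_prev >= 0 & moaks_prev <= 1),
    abs(sum(grade_probs) - 1) < 1e-8,
    noise_sd > 0
  )
  structure(as.list(environment()), class = "cohort_spec")
}

# draw a compartmental 0-3 grade and spread it over subregions so the
# subregion maximum equals the compartment grade exactly
sample_compartment <- function(n, prevalence, n_sub, grade_probs) {
  grade <- ifelse(
    stats::runif(n) < prevalence,
    sample(1:3, n, replace = TRUE, prob = grade_probs),
    0L
  )
  out <- matrix(0L, n, n_sub)
  carrier <- sample.int(n_sub, n, replace = TRUE)
  for (i in which(grade > 0)) {
    out[i, carrier[i]] <- grade[i]
    others <- setdiff(seq_len(n_sub), carrier[i])
    extra <- stats::runif(length(others)) < 0.4
    out[i, others[extra]] <- sample.int(grade[i], sum(extra), replace = TRUE)
  }
  out
}

#' Sample a synthetic cohort table
#'
#' Demographics are drawn from the configured normals, with male subjects
#' shifted taller by `height_sex_shift` cm (marginal height moments are
#' preserved), weight correlated with height, and BMI computed as
#' weight / height^2. Pathology grades are sampled per compartment at the
#' configured prevalence and spread over MOAKS subregions so that the
#' compartmental maximum equals the drawn grade. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param n_subjects Optional override of `spec$n_subjects`.
#' @return A tibble, one row per subject: `id`, `sex` (male = 1,
#'   female = 0), `age`, `bmi`, `height`, `weight`, `kl`, `jsn_medial`,
#'   `jsn_lateral`, and the MOAKS subregion columns of
#'   `casm:::moaks_subregions()`.
#' @export
sample_cohort <- function(spec = cohort_spec(), n_subjects = NULL) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec")
  n <- if (is.null(n_subjects)) spec$n_subjects else as.integer(n_subjects)
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old), add = TRUE)

  sex <- as.integer(stats::runif(n) < spec$prop_male)
  age <- stats::rnorm(n, spec$age_mean, spec$age_sd)
  # sex-conditional means keep the marginal height mean/SD at spec values
  mu_f <- spec$height_mean - spec$height_sex_shift * spec$prop_male
  within_var <- spec$height_sd^2 -
    spec$height_sex_shift^2 * spec$prop_male * (1 - spec$prop_male)
  if (within_var <= 0) stop("height_sex_shift too large for height_sd")
  height <- stats::rnorm(n, mu_f + spec$height_sex_shift * sex, sqrt(within_var))
  r <- spec$height_weight_cor
  weight <- spec$weight_mean +
    r * spec$weight_sd * (height - spec$height_mean) / spec$height_sd +
    stats::rnorm(n, 0, spec$weight_sd * sqrt(1 - r^2))
  weight <- pmax(weight, 35)
  bmi <- weight / (height / 100)^2

  kl <- sample(0:4, n, replace = TRUE, prob = spec$kl_probs)
  draw_jsn <- function(prev) {
    ifelse(stats::runif(n) < prev,
           sample(1:3, n, replace = TRUE, prob = spec$grade_probs), 0L)
  }
  jsn_medial <- draw_jsn(spec$jsn_prev[["medial"]])
  jsn_lateral <- draw_jsn(spec$jsn_prev[["lateral"]])

  subs <- moaks_subregions()
  moaks_cols <- list()
  for (comp in names(subs)) {
    m <- sample_compartment(n, spec$moaks_prev[[comp]], length(subs[[comp]]),
                            spec$grade_probs)
    colnames(m) <- subs[[comp]]
    moaks_cols[[comp]] <- tibble::as_tibble(m)
  }
  dplyr::bind_cols(
    tibble::tibble(
      id = sprintf("S%04d", seq_len(n)),
      sex = sex, age = age, bmi = bmi, height = height, weight = weight,
      kl = kl, jsn_medial = jsn_medial, jsn_lateral = jsn_lateral
    ),
    moaks_cols
  )
}

## --------------------------------------------------------- canonical meshes

# jittered structured grid over a rectangle, optionally masked to an
# ellipse; returns a quality-bounded irregular triangulation
jittered_sheet <- function(half_x, half_y, n_target, seed, ellipse = FALSE,
                           jitter = 0.17) {
  aspect <- half_x / half_y
  area_factor <- if (ellipse) pi / 4 else 1
  ny <- max(8L, round(sqrt(n_target / (aspect * area_factor))))
  nx <- max(8L, round(aspect * ny))
  g <- mesh_grid(nx, ny, spacing = 1)
  v <- g$vertices
  v[, 1] <- (v[, 1] / (nx - 1) * 2 - 1) * half_x
  v[, 2] <- (v[, 2] / (ny - 1) * 2 - 1) * half_y
  dx <- 2 * half_x / (nx - 1)
  dy <- 2 * half_y / (ny - 1)
  interior <- v[, 1] > -half_x + dx / 2 & v[, 1] < half_x - dx / 2 &
    v[, 2] > -half_y + dy / 2 & v[, 2] < half_y - dy / 2
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  v[interior, 1] <- v[interior, 1] + stats::runif(sum(interior), -jitter, jitter) * dx
  v[interior, 2] <- v[interior, 2] + stats::runif(sum(interior), -jitter, jitter) * dy
  f <- g$faces
  if (ellipse) {
    keep <- (v[, 1] / half_x)^2 + (v[, 2] / half_y)^2 <= 1
    fkeep <- keep[f[, 1]] & keep[f[, 2]] & keep[f[, 3]]
    f <- f[fkeep, , drop = FALSE]
    used <- sort(unique(as.vector(f)))
    remap <- integer(nrow(v))
    remap[used] <- seq_along(used)
    v <- v[used, , drop = FALSE]
    f <- matrix(remap[f], ncol = 3)
  }
  list(vertices = v, faces = f)
}

#' Synthetic canonical template patch
#'
#' Generates stand-ins for the canonical femoral and tibial surfaces: the
#' femur is an open saddle-like sheet carrying two posterior condylar
#' bumps and an anterior trochlear groove; the tibiae are gently domed
#' elliptical discs. Coordinates are in mm; the first axis runs
#' medial (negative) to lateral (positive), the second posterior to
#' anterior. Triangulation is irregular (seeded jitter) but
#' quality-bounded. Deterministic given `seed`.
#'
#' @param patch_label `"femur"`, `"medial_tibia"` or `"lateral_tibia"`.
#' @param n_vertices Target vertex count (>= 200; the realised count may
#'   differ slightly).
#' @param seed Integer seed.
#' @return A `surface_mesh` with disc topology.
#' @export
make_canonical_patch <- function(patch_label = c("femur", "medial_tibia",
                                                 "lateral_tibia"),
                                 n_vertices = 1000L, seed = 1L) {
  patch_label <- match.arg(patch_label)
  if (n_vertices < 200L) stop("`n_vertices` must be >= 200")
  if (patch_label == "femur") {
    sh <- jittered_sheet(30, 25, n_vertices, seed)
    x <- sh$vertices[, 1]; y <- sh$vertices[, 2]
    z <- -0.006 * (x^2 + y^2) +
      6 * exp(-((x - 16)^2 + (y + 12)^2) / 170) +
      6 * exp(-((x + 16)^2 + (y + 12)^2) / 170) -
      4 * exp(-x^2 / 90) * stats::pnorm(y / 8)
  } else {
    sh <- jittered_sheet(16, 12, n_vertices, seed + 17L, ellipse = TRUE)
    x <- sh$vertices[, 1]; y <- sh$vertices[, 2]
    z <- 2.5 * (1 - (x / 16)^2 - (y / 12)^2)
  }
  surface_mesh(cbind(x, y, z), sh$faces, patch_label = patch_label)
}

# named landmark regions on the synthetic patches (parametric-coordinate
# analogues, not anatomical claims)
region_centers <- function(patch_label) {
  if (patch_label == "femur") {
    list(
      trochlea = c(0, 15), anterior_femur = c(0, 21),
      medial_femur = c(-18, -6), lateral_femur = c(18, -6),
      whole = NULL
    )
  } else {
    list(center = c(0, 0), whole = NULL)
  }
}

# smooth bump of given peak amplitude and FWHM (mm) centred on a named
# region; NULL centre means a spatially constant effect
region_bump <- function(mesh, region, amplitude, fwhm = 18) {
  centers <- region_centers(mesh$patch_label)
  if (!region %in% names(centers)) {
    stop(sprintf("unknown region name '%s' for patch '%s'", region,
                 mesh$patch_label))
  }
  ctr <- centers[[region]]
  if (is.null(ctr)) return(rep(amplitude, nrow(mesh$vertices)))
  sigma <- fwhm / sqrt(8 * log(2))
  d2 <- (mesh$vertices[, 1] - ctr[1])^2 + (mesh$vertices[, 2] - ctr[2])^2
  amplitude * exp(-d2 / (2 * sigma^2))
}

#' Ground-truth effect maps for the synthetic generator
#'
#' Builds the baseline thickness map (smooth, 1.5-2.5 mm, thinner on the
#' medial side) and per-covariate effect maps as smooth regional bumps.
#' Peak amplitudes default to the reported per-unit magnitudes: 0.5 mm
#' for male sex (trochlea), -0.035 mm/year for age, +0.025 mm/cm for
#' height, -0.2/+0.2 mm per KL grade (local thinning with anterior
#' thickening), -0.4 and -0.5 mm per medial / lateral JSN grade, -0.3 and
#' -0.4 mm per medial / lateral extrusion grade, -0.32 / -0.35 / -0.14 mm
#' per BML grade (medial / lateral / patellofemoral) and -0.24 mm local
#' with +0.3 mm anterior per osteophyte grade.
#'
#' @param mesh A canonical `surface_mesh` (or a named list of them, in
#'   which case a list of effect map sets is returned).
#' @param scenario `"null"`, `"demographics"`, `"pathology"` or
#'   `"custom"`.
#' @param custom_effects For `scenario = "custom"`: named list of
#'   per-vertex effect vectors.
#' @param noise_sd Marginal SD of the spatially correlated thickness
#'   noise, mm.
#' @param noise_fwhm Noise correlation FWHM in mm; default 3x the mean
#'   edge length.
#' @param effect_fwhm FWHM of the regional effect bumps, mm.
#' @param seed Integer seed (reserved for custom randomised scenarios).
#' @return An `effect_map_set`: `baseline`, `effects` (named list),
#'   `noise_sd`, `noise_fwhm`.
#' @export
make_effect_maps <- function(mesh, scenario = c("null", "demographics",
                                                "pathology", "custom"),
                             custom_effects = NULL,
                             noise_sd = 0.3, noise_fwhm = NULL,
                             effect_fwhm = 25, seed = 1L) {
  if (is.list(mesh) && !inherits(mesh, "surface_mesh")) {
    return(lapply(mesh, make_effect_maps, scenario = scenario,
                  custom_effects = custom_effects, noise_sd = noise_sd,
                  noise_fwhm = noise_fwhm, effect_fwhm = effect_fwhm,
                  seed = seed))
  }
  scenario <- match.arg(scenario)
  mm <- mesh_metrics(mesh)
  if (is.null(noise_fwhm)) noise_fwhm <- 3 * mm$mean_edge_length
  x <- mesh$vertices[, 1]
  half_x <- max(abs(x))
  is_femur <- mesh$patch_label == "femur"
  baseline <- if (is_femur) {
    2.0 + 0.4 * (x / half_x) + region_bump(mesh, "trochlea", 0.25, 25)
  } else if (mesh$patch_label == "medial_tibia") {
    1.7 + region_bump(mesh, "center", 0.4, 20)
  } else {
    2.0 + region_bump(mesh, "center", 0.4, 20)
  }
  baseline <- pmin(pmax(baseline, 1.4), 2.6)

  eff <- list()
  bump <- function(region, amp) region_bump(mesh, region, amp, effect_fwhm)
  if (scenario == "demographics") {
    if (is_femur) {
      # widespread mild thickening peaking at 0.5 mm in the trochlea
      eff$sex <- bump("trochlea", 0.4) + bump("whole", 0.1)
      eff$age <- bump("trochlea", -0.035)
      eff$height <- bump("medial_femur", 0.025) + bump("lateral_femur", 0.015)
      eff$weight <- bump("whole", 0)
    } else {
      eff$sex <- bump("center", 0.35)
      eff$age <- bump("center", -0.02)
      eff$height <- bump("center", 0.025)
      eff$weight <- bump("whole", 0)
    }
  } else if (scenario == "pathology") {
    med <- if (is_femur) "medial_femur" else "center"
    lat <- if (is_femur) "lateral_femur" else "center"
    ant <- if (is_femur) "anterior_femur" else "whole"
    on_med <- mesh$patch_label != "lateral_tibia"
    on_lat <- mesh$patch_label != "medial_tibia"
    z <- rep(0, nrow(mesh$vertices))
    eff$kl <- (if (on_med) bump(med, -0.2) else z) +
      (if (is_femur) bump(ant, 0.2) else z)
    eff$jsn_medial <- if (on_med) bump(med, -0.4) else z
    eff$jsn_lateral <- if (on_lat) bump(lat, -0.5) else z
    eff$extrusion_medial <- if (on_med) bump(med, -0.3) else z
    eff$extrusion_lateral <- if (on_lat) bump(lat, -0.4) else z
    eff$bml_medial <- if (on_med) bump(med, -0.32) else z
    eff$bml_lateral <- if (on_lat) bump(lat, -0.35) else z
    eff$bml_pf <- if (is_femur) bump("anterior_femur", -0.14) else z
    for (o in c("ost_medial", "ost_lateral", "ost_pf")) {
      # the patellofemoral local thinning is placed laterally-anteriorly so
      # it does not cancel the shared anterior thickening
      local_reg <- switch(o, ost_medial = med, ost_lateral = lat,
                          ost_pf = if (is_femur) "lateral_femur" else "center")
      on <- switch(o, ost_medial = on_med, ost_lateral = on_lat, ost_pf = is_femur)
      eff[[o]] <- (if (on) bump(local_reg, -0.24) else z) +
        (if (is_femur) bump("anterior_femur", 0.3) else z)
    }
  } else if (scenario == "custom") {
    if (is.null(custom_effects)) stop("custom scenario needs `custom_effects`")
    eff <- lapply(custom_effects, function(e) {
      if (length(e) != nrow(mesh$vertices)) stop("custom effect length mismatch")
      e
    })
  }
  structure(
    list(baseline = baseline, effects = eff, noise_sd = noise_sd,
         noise_fwhm = noise_fwhm, effect_fwhm = effect_fwhm,
         patch_label = mesh$patch_label),
    class = "effect_map_set"
  )
}

# graph-Laplacian diffusion operator matching smooth_field(), reusable
# across many fields on the same mesh
diffusion_operator <- function(mesh, fwhm) {
  n <- nrow(mesh$vertices)
  if (fwhm <= 0) return(function(M) M)
  em <- mesh_edges(mesh)
  e <- em$edges
  el2 <- rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                  mesh$vertices[e[, 2], , drop = FALSE])^2)
  deg <- tabulate(c(e[, 1], e[, 2]), nbins = n)
  tau <- 0.5 / max(deg)
  step_var <- tau * mean(deg) * mean(el2) / 2
  n_steps <- fwhm^2 / (8 * log(2) * step_var)
  k <- floor(n_steps)
  frac <- n_steps - k
  L <- Matrix::sparseMatrix(
    i = c(e[, 1], e[, 2], seq_len(n)),
    j = c(e[, 2], e[, 1], seq_len(n)),
    x = c(rep(1, 2 * nrow(e)), -deg),
    dims = c(n, n)
  )
  function(M) {
    for (s in seq_len(k)) M <- M + tau * (L %*% M)
    if (frac > 0) M <- M + frac * tau * (L %*% M)
    as.matrix(M)
  }
}

#' Matrix of independent smooth noise fields
#'
#' Columns are independent realisations of the same spatially correlated
#' Gaussian noise as [smooth_noise_field()], generated with a single
#' diffusion-operator build so large cohorts are cheap.
#'
#' @param mesh A `surface_mesh`.
#' @param n Number of independent fields (columns).
#' @param sd Marginal standard deviation of each field.
#' @param fwhm Spatial correlation FWHM, mm.
#' @param seed Integer seed.
#' @return `n_vertices x n` matrix.
#' @export
smooth_noise_matrix <- function(mesh, n, sd = 0.3, fwhm = 5, seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  Z <- matrix(stats::rnorm(nrow(mesh$vertices) * n), ncol = n)
  Z <- diffusion_operator(mesh, fwhm)(Z)
  sds <- apply(Z, 2, stats::sd)
  sweep(Z, 2, sds / sd, "/")
}

#' Smooth Gaussian noise field on a mesh
#'
#' White noise diffused to the requested correlation FWHM, then rescaled
#' to the requested marginal SD across vertices.
#'
#' @param mesh A `surface_mesh`.
#' @param sd Marginal standard deviation.
#' @param fwhm Spatial correlation FWHM, mm.
#' @param seed Integer seed.
#' @return Numeric vector, one value per vertex.
#' @export
smooth_noise_field <- function(mesh, sd = 0.3, fwhm = 5, seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  z <- stats::rnorm(nrow(mesh$vertices))
  if (fwhm > 0) {
    z <- smooth_field(surface_field(z), mesh, fwhm)$values
  }
  z / stats::sd(z) * sd
}

# linear predictor + clipped noise; the shared forward model for
# simulate_subject and simulate_cohort_dataset
true_thickness <- function(effects, covariates, noise) {
  mu <- effects$baseline
  for (k in names(effects$effects)) {
    xk <- covariates[[k]]
    if (!is.null(xk) && !is.na(xk)) mu <- mu + effects$effects[[k]] * xk
  }
  pmax(mu + noise, 0)
}

#' Simulate one subject from the generative model
#'
#' True thickness is the baseline plus covariate-weighted effect maps
#' plus spatially correlated Gaussian noise, clipped at zero (clipped
#' vertices mimic denuded bone; the clip fraction is reported as an
#' attribute). Subject geometry is the canonical mesh under a random
#' similarity transform (scale, rotation, translation) followed by a
#' random smooth thin-plate spline warp; the generating transforms are
#' returned as ground truth. Optionally emits per-vertex intensity
#' profiles generated from the deconvolution forward model at the true
#' thickness.
#'
#' @param canonical_mesh A canonical `surface_mesh`.
#' @param covariates One-row data frame / named list of covariate values.
#' @param effects An `effect_map_set` for the same mesh.
#' @param geometry_jitter List with `scale_range`, `rot_deg`,
#'   `trans_mm`, `tps_amplitude` (mm), `tps_landmarks`.
#' @param seed Integer seed.
#' @param with_profiles If `TRUE`, also generate intensity profiles.
#' @param profile_spacing,profile_sigma,profile_levels,profile_snr
#'   Forward-model settings for the optional profiles.
#' @return A list: `mesh` (subject surface), `thickness`
#'   (`surface_field` on the subject mesh), `similarity`, `warp` (ground
#'   truth), `profiles` (optional), `clip_fraction`.
#' @export
simulate_subject <- function(canonical_mesh, covariates, effects,
                             geometry_jitter = list(
                               scale_range = c(0.9, 1.1), rot_deg = 10,
                               trans_mm = 5, tps_amplitude = 2,
                               tps_landmarks = 10
                             ),
                             seed = 1L, with_profiles = FALSE,
                             profile_spacing = 0.25, profile_sigma = 0.4,
                             profile_levels = c(10, 100, 30),
                             profile_snr = 50) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  noise <- if (effects$noise_sd > 0) {
    smooth_noise_field(canonical_mesh, effects$noise_sd, effects$noise_fwhm,
                       seed = stats::runif(1, 1, 1e8))
  } else {
    rep(0, nrow(canonical_mesh$vertices))
  }
  thick <- true_thickness(effects, covariates, noise)
  clip_fraction <- mean(thick == 0)

  gj <- geometry_jitter
  zero_jitter <- gj$tps_amplitude == 0 && gj$rot_deg == 0 &&
    gj$trans_mm == 0 && diff(range(gj$scale_range)) == 0 &&
    gj$scale_range[1] == 1
  if (zero_jitter) {
    sim <- identity_similarity()
    warp <- NULL
    subj_v <- canonical_mesh$vertices
  } else {
    s <- stats::runif(1, gj$scale_range[1], gj$scale_range[2])
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- stats::runif(1, 0, gj$rot_deg * pi / 180)
    K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    tr <- stats::runif(3, -gj$trans_mm, gj$trans_mm)
    sim <- structure(
      list(scale = s, rotation = R, translation = tr, rms = 0),
      class = "similarity_transform"
    )
    moved <- apply_similarity(sim, canonical_mesh$vertices)
    idx <- sample(nrow(moved), gj$tps_landmarks)
    src <- moved[idx, , drop = FALSE]
    dst <- src + matrix(stats::runif(3 * length(idx), -gj$tps_amplitude,
                                     gj$tps_amplitude), ncol = 3)
    warp <- tps_fit(src, dst, lambda_reg = 0)
    subj_v <- tps_apply(warp, moved)
  }
  subj <- surface_mesh(subj_v, canonical_mesh$faces,
                       patch_label = canonical_mesh$patch_label)

  profiles <- NULL
  if (with_profiles) {
    x0 <- 0.5
    extent <- seq(-0.75, max(thick) + x0 + 2, by = profile_spacing)
    contrast <- abs(profile_levels[2] - profile_levels[1])
    psd <- contrast / profile_snr
    profiles <- lapply(seq_along(thick), function(i) {
      y <- profile_forward_model(extent, x0, x0 + thick[i], profile_sigma,
                                 profile_levels)
      intensity_profile(y + stats::rnorm(length(y), 0, psd),
                        spacing = profile_spacing, origin_offset = extent[1])
    })
  }
  list(
    mesh = subj,
    thickness = surface_field(thick, units = "mm", mesh = subj),
    similarity = sim, warp = warp, profiles = profiles,
    clip_fraction = clip_fraction
  )
}

#' Simulate a full cohort dataset
#'
#' Composes [sample_cohort()], [make_effect_maps()] and the thickness
#' forward model. With `output = "aligned"` the thickness matrix is built
#' directly on the canonical vertices (no geometry jitter), exercising
#' the statistical stage in isolation; with `output = "subject"` each
#' subject gets jittered geometry, exercising registration. Deterministic
#' given `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param scenario Effect scenario, see [make_effect_maps()].
#' @param mesh Canonical `surface_mesh` (default: a 1000-vertex femur).
#' @param seed Root seed; overrides `spec$seed`.
#' @param output `"aligned"` or `"subject"`.
#' @param ... Passed to [make_effect_maps()].
#' @return A list: `cohort` (tibble), `effects`, `mesh`, and either
#'   `thickness_matrix` (n_subjects x n_vertices) or `subjects` (list
#'   from [simulate_subject()]).
#' @export
simulate_cohort_dataset <- function(spec = cohort_spec(),
                                    scenario = "null",
                                    mesh = NULL,
                                    seed = spec$seed,
                                    output = c("aligned", "subject"),
                                    ...) {
  output <- match.arg(output)
  spec$seed <- as.integer(seed)
  if (is.null(mesh)) {
    mesh <- make_canonical_patch("femur", 1000L, seed = spec$seed)
  }
  cohort <- sample_cohort(spec)
  effects <- make_effect_maps(mesh, scenario, noise_sd = spec$noise_sd,
                              seed = spec$seed, ...)
  n <- nrow(cohort)
  if (output == "aligned") {
    noise <- smooth_noise_matrix(mesh, n, effects$noise_sd,
                                 effects$noise_fwhm,
                                 seed = (spec$seed * 1009L) %% 2147483647L)
    Y <- matrix(NA_real_, n, nrow(mesh$vertices))
    for (i in seq_len(n)) {
      Y[i, ] <- true_thickness(effects, cohort[i, ], noise[, i])
    }
    list(cohort = cohort, thickness_matrix = Y, effects = effects, mesh = mesh)
  } else {
    subjects <- lapply(seq_len(n), function(i) {
      simulate_subject(mesh, cohort[i, ], effects,
                       seed = (spec$seed * 2003L + i) %% 2147483647L)
    })
    list(cohort = cohort, subjects = subjects, effects = effects, mesh = mesh)
  }
}
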