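test_that("canonical patches are deterministic discs with bounded triangle quality", {
  fem <- make_canonical_patch("femur", 2000, seed = 3)
  mm <- mesh_metrics(fem)
  expect_equal(mm$euler_characteristic, 1L)
  expect_gte(nrow(fem$vertices), 1500)

  # single boundary loop: every boundary vertex has exactly two incident
  # boundary edges and the boundary edge graph is connected
  em <- mesh_edges(fem)
  be <- em$edges[em$n_incident_faces == 1L, , drop = FALSE]
  deg <- table(as.vector(be))
  expect_true(all(deg == 2L))
  visited <- c(be[1, 1])
  repeat {
    nxt <- be[be[, 1] %in% utils::tail(visited, 1) | be[, 2] %in% utils::tail(visited, 1), ]
    cand <- setdiff(unique(as.vector(nxt)), visited)
    if (length(cand) == 0) break
    visited <- c(visited, cand[1])
  }
  expect_equal(length(visited), length(unique(as.vector(be))))

  # determinism and seed sensitivity
  expect_identical(fem, make_canonical_patch("femur", 2000, seed = 3))
  expect_false(identical(fem$vertices, make_canonical_patch("femur", 2000, seed = 4)$vertices))

  # triangulation quality: edge-length CV < 0.5 and min angle > 15 degrees
  for (patch in list(fem, make_canonical_patch("medial_tibia", 800, seed = 1))) {
    met <- mesh_metrics(patch)
    expect_lt(stats::sd(met$edge_lengths) / mean(met$edge_lengths), 0.5)
    v <- patch$vertices; f <- patch$faces
    ang <- function(a, b, c) {
      u <- v[b, ] - v[a, ]; w <- v[c, ] - v[a, ]
      acos(pmin(pmax(rowSums(u * w) / sqrt(rowSums(u^2) * rowSums(w^2)), -1), 1))
    }
    angles <- cbind(ang(f[, 1], f[, 2], f[, 3]),
                    ang(f[, 2], f[, 3], f[, 1]),
                    ang(f[, 3], f[, 1], f[, 2]))
    expect_gt(min(angles) * 180 / pi, 15)
  }
  expect_error(make_canonical_patch("femur", 100), ">= 200")
})

test_that("sampled cohorts reproduce the configured moments and prevalences", {
  spec <- cohort_spec(seed = 77)
  big <- sample_cohort(spec, n_subjects = 100000)
  expect_lt(abs(mean(big$sex) - 0.22), 0.005)
  expect_lt(abs(mean(big$age) - 66.4), 0.1)
  expect_lt(abs(mean(big$height) - 167.1), 0.15)
  expect_lt(abs(mean(big$weight) - 78.2), 0.25)
  expect_lt(abs(sd(big$height) - 10.0), 0.2)
  # derived BMI lands near the configured summary and carries the
  # height/weight collinearity that motivates its exclusion
  expect_lt(abs(mean(big$bmi) - 28.0), 0.6)
  expect_gt(abs(cor(big$bmi, big$weight)), 0.6)
  # male subjects are taller on average, marginal moments preserved
  expect_gt(mean(big$height[big$sex == 1]) - mean(big$height[big$sex == 0]), 5)

  # KL multinomial and compartmental prevalences match the configuration
  kl_emp <- tabulate(big$kl + 1L, 5) / nrow(big)
  expect_lt(max(abs(kl_emp - c(54, 76, 63, 84, 10) / 287)), 0.01)
  prev <- function(cols) mean(compartment_max_score(as.matrix(big[cols])) > 0)
  subs <- casm:::moaks_subregions()
  expect_lt(abs(prev(subs$extrusion_medial) - 0.60), 0.01)
  expect_lt(abs(prev(subs$ost_medial) - 0.79), 0.01)
  expect_lt(abs(mean(big$jsn_medial > 0) - 0.47), 0.01)

  # determinism and degenerate prevalence
  expect_identical(sample_cohort(spec, 500), sample_cohort(spec, 500))
  none <- cohort_spec(moaks_prev = stats::setNames(
    rep(0, 8), names(cohort_spec()$moaks_prev)
  ), jsn_prev = c(medial = 0, lateral = 0), seed = 5)
  quiet <- sample_cohort(none, 200)
  expect_true(all(quiet[unlist(subs)] == 0))
  expect_true(all(quiet$jsn_medial == 0))
})

test_that("effect maps honor the configured scenarios and amplitudes", {
  mesh <- make_canonical_patch("femur", 1200, seed = 2)
  null_set <- make_effect_maps(mesh, "null")
  expect_length(null_set$effects, 0)
  expect_true(all(null_set$baseline >= 1.4 & null_set$baseline <= 2.6))
  # medial side thinner than lateral on the baseline
  medial <- mesh$vertices[, 1] < -10
  lateral <- mesh$vertices[, 1] > 10
  expect_lt(mean(null_set$baseline[medial]), mean(null_set$baseline[lateral]))

  demo <- make_effect_maps(mesh, "demographics")
  expect_setequal(names(demo$effects), c("sex", "age", "height", "weight"))
  expect_equal(max(demo$effects$sex), 0.5, tolerance = 0.02)
  expect_true(all(demo$effects$weight == 0))

  # the height bump has the requested width at half maximum
  h <- demo$effects$height
  ctr <- mesh$vertices[which.max(h), 1:2]
  d <- sqrt((mesh$vertices[, 1] - ctr[1])^2 + (mesh$vertices[, 2] - ctr[2])^2)
  half_width <- 2 * max(d[h >= max(h) / 2 & d < 15])
  expect_lt(abs(half_width - demo$effect_fwhm) / demo$effect_fwhm, 0.25)

  path <- make_effect_maps(mesh, "pathology")
  expect_true(all(c("kl", "jsn_medial", "bml_pf", "ost_pf") %in% names(path$effects)))
  expect_equal(min(path$effects$jsn_medial), -0.4, tolerance = 0.02)
  expect_equal(max(path$effects$ost_pf), 0.3, tolerance = 0.05)
  expect_error(region_bump(mesh, "no_such_region", 1), "unknown region")
})

test_that("the subject forward model is exact without noise and jitter", {
  mesh <- make_canonical_patch("medial_tibia", 300, seed = 9)
  eff <- make_effect_maps(mesh, "demographics", noise_sd = 0)
  eff$noise_sd <- 0
  zero_jitter <- list(scale_range = c(1, 1), rot_deg = 0, trans_mm = 0,
                      tps_amplitude = 0, tps_landmarks = 10)
  covs <- list(sex = 1, age = 70, height = 175, weight = 80)
  out <- simulate_subject(mesh, covs, eff, geometry_jitter = zero_jitter, seed = 4)
  expect_equal(out$mesh$vertices, mesh$vertices)
  truth <- pmax(eff$baseline + eff$effects$sex * 1 + eff$effects$age * 70 +
                  eff$effects$height * 175, 0)
  expect_equal(out$thickness$values, truth, tolerance = 1e-12)
  expect_equal(out$clip_fraction, 0)

  # with geometry jitter the subject is a warped copy with retained truth
  out2 <- simulate_subject(mesh, covs, eff, seed = 4)
  expect_false(isTRUE(all.equal(out2$mesh$vertices, mesh$vertices)))
  expect_s3_class(out2$similarity, "similarity_transform")
  expect_s3_class(out2$warp, "tps_warp")
})

test_that("cohort datasets are deterministic with scenario-consistent effects", {
  spec <- cohort_spec(n_subjects = 25, seed = 11)
  mesh <- make_canonical_patch("femur", 500, seed = 11)
  d1 <- simulate_cohort_dataset(spec, "null", mesh = mesh, seed = 11)
  expect_equal(dim(d1$thickness_matrix), c(25L, nrow(mesh$vertices)))
  expect_false(anyNA(d1$thickness_matrix))
  expect_true(all(d1$thickness_matrix >= 0))
  d2 <- simulate_cohort_dataset(spec, "null", mesh = mesh, seed = 11)
  expect_identical(d1$thickness_matrix, d2$thickness_matrix)
  expect_identical(d1$cohort, d2$cohort)

  demo <- simulate_cohort_dataset(spec, "demographics", mesh = mesh, seed = 3)
  expect_setequal(names(demo$effects$effects), c("sex", "age", "height", "weight"))
  # clip fraction below 1% at default settings
  expect_lt(mean(demo$thickness_matrix == 0), 0.01)

  subj <- simulate_cohort_dataset(cohort_spec(n_subjects = 3, seed = 2),
                                  "null", mesh = mesh, seed = 2,
                                  output = "subject")
  expect_length(subj$subjects, 3)
  expect_s3_class(subj$subjects[[1]]$mesh, "surface_mesh")
})

test_that("profile emission closes the loop: measured thickness tracks truth", {
  mesh <- make_canonical_patch("medial_tibia", 220, seed = 6)
  eff <- make_effect_maps(mesh, "null", noise_sd = 0.2)
  zero_jitter <- list(scale_range = c(1, 1), rot_deg = 0, trans_mm = 0,
                      tps_amplitude = 0, tps_landmarks = 10)
  out <- simulate_subject(mesh, list(), eff, geometry_jitter = zero_jitter,
                          seed = 8, with_profiles = TRUE, profile_snr = 50)
  meas <- thickness_from_profiles(mesh, out$profiles, seed = 21)
  ok <- meas$quality$values == 0
  expect_gt(mean(ok), 0.98)
  rmse <- sqrt(mean((meas$thickness$values[ok] - out$thickness$values[ok])^2))
  expect_lt(rmse, 0.05)
})
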