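#' Compartmental score as the maximum over subregions
#'
#' MOAKS features are graded 0-3 in several subregions per compartment;
#' the compartmental grade is the maximum subregion score.
#'
#' @param scores A numeric vector (one subject), or a matrix / data frame
#'   with one row per subject and one column per subregion; grades 0-3.
#' @return Per-subject compartmental grade (scalar or vector).
#' @export
compartment_max_score <- function(scores) {
  if (is.data.frame(scores)) scores <- as.matrix(scores)
  if (is.null(dim(scores))) {
    if (length(scores) == 0L) stop("empty subregion score set")
    check_grades(scores, 0, 3, "subregion score")
    return(max(scores))
  }
  if (ncol(scores) == 0L) stop("empty subregion score set")
  check_grades(scores, 0, 3, "subregion score")
  apply(scores, 1, max)
}

check_grades <- function(x, lo, hi, what) {
  bad <- !is.na(x) & (x < lo | x > hi | x != round(x))
  if (any(bad)) {
    stop(sprintf("%s out of range: values must be integers in %d-%d", what, lo, hi))
  }
  invisible(x)
}

#' Presence/absence recoding of a subregional score
#'
#' Binary subregional analyses use presence (score > 0) versus absence so
#' that a few high grades cannot dominate the fit. Subregions affected in
#' fewer than `min_affected` subjects are excluded from analysis
#' altogether to avoid reliance on a limited group.
#'
#' @param scores Per-subject subregion grades 0-3.
#' @param min_affected Smallest number of affected subjects for the
#'   covariate to be analysable (default 20).
#' @return A list with `covariate` (0/1 per subject, or `NULL` when
#'   excluded), `excluded` (logical), `n_affected`.
#' @export
binarize_subregion <- function(scores, min_affected = 20) {
  check_grades(scores, 0, 3, "subregion score")
  bin <- as.integer(scores > 0)
  n_aff <- sum(bin, na.rm = TRUE)
  excluded <- n_aff < min_affected
  list(
    covariate = if (excluded) NULL else bin,
    excluded = excluded,
    n_affected = n_aff
  )
}

# column dictionary for subregional MOAKS scores in a cohort table;
# compartment -> member subregion columns
moaks_subregions <- function() {
  list(
    extrusion_medial = c("extrusion_medial_anterior", "extrusion_medial_body"),
    extrusion_lateral = c("extrusion_lateral_anterior", "extrusion_lateral_body"),
    bml_pf = paste0("bml_pf_s", 1:4),
    bml_medial = paste0("bml_medial_s", 1:5),
    bml_lateral = paste0("bml_lateral_s", 1:5),
    ost_pf = paste0("ost_pf_s", 1:6),
    ost_medial = paste0("ost_medial_s", 1:3),
    ost_lateral = paste0("ost_lateral_s", 1:3)
  )
}

#' Catalogue of thickness model specifications
#'
#' One row per fitted contrast, mirroring the analysis plan: five
#' univariable demographic models; a multivariable demographic model over
#' sex, age, weight and height (BMI omitted for collinearity with height
#' and weight), one row per contrast; pathology models (KL, medial and
#' lateral joint space narrowing, and the eight compartmental MOAKS
#' grades) each adjusted for sex, age and height, with MOAKS compartments
#' entering as the maximum subregion score; joint-space-narrowing
#' sensitivity models additionally adjusted for ipsilateral meniscal
#' extrusion; presence/absence models per MOAKS subregion (subject to the
#' minimum-affected exclusion at design-build time); and an exploratory
#' radiographic-OA dichotomy (KL >= 2).
#'
#' @return A tibble with columns `name`, `covariates` (list), `contrast`,
#'   `adjustment_set` (list), `recoding`, `group`.
#' @export
model_catalogue <- function() {
  rows <- list()
  add <- function(name, covariates, contrast, adjustment, recoding, group) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      name = name,
      covariates = list(covariates),
      contrast = contrast,
      adjustment_set = list(adjustment),
      recoding = recoding,
      group = group
    )
  }
  demog <- c("sex", "age", "bmi", "height", "weight")
  for (d in demog) {
    add(d, c("intercept", d), d, character(0), "raw", "demographic_univariable")
  }
  multi <- c("sex", "age", "weight", "height")
  for (d in multi) {
    add(paste0("multi_", d), c("intercept", multi), d,
        setdiff(multi, d), "raw", "demographic_multivariable")
  }
  adj <- c("sex", "age", "height")
  pathology <- c(
    kl = "raw", jsn_medial = "raw", jsn_lateral = "raw",
    extrusion_medial = "compartment_max", extrusion_lateral = "compartment_max",
    bml_medial = "compartment_max", bml_lateral = "compartment_max",
    bml_pf = "compartment_max",
    ost_medial = "compartment_max", ost_lateral = "compartment_max",
    ost_pf = "compartment_max"
  )
  for (p in names(pathology)) {
    add(p, c("intercept", adj, p), p, adj, unname(pathology[p]), "pathology")
  }
  # JSN sensitivity: additionally adjusted for ipsilateral meniscal extrusion
  add("jsn_medial_adj_extrusion",
      c("intercept", adj, "extrusion_medial", "jsn_medial"),
      "jsn_medial", c(adj, "extrusion_medial"), "raw", "jsn_sensitivity")
  add("jsn_lateral_adj_extrusion",
      c("intercept", adj, "extrusion_lateral", "jsn_lateral"),
      "jsn_lateral", c(adj, "extrusion_lateral"), "raw", "jsn_sensitivity")
  for (sub in unlist(moaks_subregions(), use.names = FALSE)) {
    bname <- paste0(sub, "_binary")
    add(bname, c("intercept", adj, bname), bname, adj,
        "binary_presence", "binary_subregion")
  }
  add("roa", c("intercept", adj, "roa"), "roa", adj, "binary_presence",
      "exploratory")
  dplyr::bind_rows(rows)
}

#' Build a design matrix for a catalogued model
#'
#' Applies the model's recoding rule to the cohort table (compartmental
#' maxima for MOAKS grades, presence/absence with the minimum-affected
#' exclusion for subregional binaries, KL >= 2 for the radiographic-OA
#' dichotomy), assembles the design matrix with an intercept, and
#' validates full column rank.
#'
#' @param cohort A cohort tibble (see [sample_cohort()] for the column
#'   dictionary).
#' @param model A model name from [model_catalogue()], or one row of the
#'   catalogue tibble.
#' @param min_affected Exclusion threshold for binary subregional models.
#' @return A `design_matrix` object: `X` (n x p matrix), `contrast`
#'   (column name), `contrast_vector`, `model_name`; or an object of class
#'   `excluded_model` when the minimum-affected rule removes the model.
#' @export
build_design <- function(cohort, model, min_affected = 20) {
  cat_tbl <- model_catalogue()
  if (is.character(model)) {
    row <- cat_tbl[cat_tbl$name == model, ]
    if (nrow(row) != 1L) stop(sprintf("unknown model '%s'", model))
  } else {
    row <- model
  }
  covs <- row$covariates[[1]]
  need <- setdiff(covs, "intercept")
  subregions <- moaks_subregions()
  dat <- list(intercept = rep(1, nrow(cohort)))
  for (cv in need) {
    dat[[cv]] <- if (cv %in% names(cohort)) {
      cohort[[cv]]
    } else if (cv %in% names(subregions)) {
      compartment_max_score(as.matrix(cohort[subregions[[cv]]]))
    } else if (cv == "roa") {
      as.integer(cohort$kl >= 2)
    } else if (endsWith(cv, "_binary")) {
      sub <- sub("_binary$", "", cv)
      if (!sub %in% names(cohort)) stop(sprintf("unknown covariate '%s'", cv))
      b <- binarize_subregion(cohort[[sub]], min_affected = min_affected)
      if (b$excluded) {
        return(structure(
          list(model_name = row$name, reason = sprintf(
            "only %d affected subjects (< %d)", b$n_affected, min_affected
          )),
          class = "excluded_model"
        ))
      }
      b$covariate
    } else {
      stop(sprintf("unknown covariate '%s'", cv))
    }
  }
  if (anyNA(unlist(dat, use.names = FALSE))) {
    stop("missing covariate values among modeled subjects")
  }
  X <- do.call(cbind, dat)
  colnames(X) <- names(dat)
  p <- ncol(X)
  if (nrow(X) <= p + 1L) stop("need n_subjects > p + 1")
  qrX <- qr(X)
  if (qrX$rank < p) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop(sprintf("design is rank deficient; collinear columns: %s",
                 paste(drop_cols, collapse = ", ")))
  }
  cvec <- as.numeric(colnames(X) == row$contrast)
  structure(
    list(X = X, contrast = row$contrast, contrast_vector = cvec,
         model_name = row$name),
    class = "design_matrix"
  )
}
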