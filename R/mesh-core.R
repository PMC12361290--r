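#' Construct a triangle surface mesh
#'
#' A `surface_mesh` is the geometry carrier for canonical templates and
#' subject surfaces: vertex coordinates in millimetres, triangular faces,
#' and a patch label identifying the anatomical patch the mesh models.
#'
#' @param vertices Numeric matrix, `n x 3`, vertex coordinates in mm.
#' @param faces Integer matrix, `m x 3`, 1-based vertex indices per triangle.
#' @param patch_label One of `"femur"`, `"medial_tibia"`, `"lateral_tibia"`,
#'   or any other label; purely descriptive but must match between subject
#'   and canonical meshes during registration.
#' @param validate If `TRUE` (default), check the structural invariants:
#'   in-range indices, no degenerate (zero-area) triangles, edge-manifoldness
#'   (every edge in at most two faces), and a single connected component.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, patch_label = "femur", validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("`faces` must be an m x 3 matrix")
  mesh <- structure(
    list(vertices = vertices, faces = faces, patch_label = patch_label),
    class = "surface_mesh"
  )
  if (validate) validate_mesh(mesh)
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf(
    "<surface_mesh> patch '%s': %d vertices, %d faces\n",
    x$patch_label, nrow(x$vertices), nrow(x$faces)
  ))
  invisible(x)
}

#' Validate structural invariants of a surface mesh
#'
#' Checks that all face indices are in range, that no triangle is degenerate
#' (area below 1e-12 mm^2 or a repeated vertex index), that every edge is
#' shared by at most two faces, and that the mesh is a single connected
#' component. Throws an informative error naming the violated invariant.
#'
#' @param mesh A `surface_mesh`.
#' @return The mesh, invisibly, if valid.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  if (any(!is.finite(v))) stop("mesh invariant violated: non-finite vertex coordinates")
  if (nrow(f) > 0L) {
    if (any(f < 1L) || any(f > n)) {
      bad <- which(f < 1L | f > n, arr.ind = TRUE)[1, 1]
      stop(sprintf(
        "mesh invariant violated: face %d has vertex index out of range [1, %d]",
        bad, n
      ))
    }
    rep_idx <- f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]
    if (any(rep_idx)) {
      stop(sprintf(
        "mesh invariant violated: face %d repeats a vertex index",
        which(rep_idx)[1]
      ))
    }
    a <- triangle_areas(v, f)
    if (any(a <= 1e-12)) {
      stop(sprintf(
        "mesh invariant violated: face %d is degenerate (area <= 1e-12 mm^2)",
        which(a <= 1e-12)[1]
      ))
    }
    ek <- edge_keys(f)
    cnt <- table(ek)
    if (any(cnt > 2L)) {
      stop("mesh invariant violated: non-manifold edge shared by more than 2 faces")
    }
    comp <- connected_components(n, f)
    used <- unique(as.vector(f))
    if (length(unique(comp[used])) > 1L) {
      stop("mesh invariant violated: more than one connected component")
    }
  }
  invisible(mesh)
}

triangle_areas <- function(v, f) {
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# canonical "i-j" keys with i < j for the 3m directed half-edges
edge_keys <- function(f) {
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "-")
}

# unique undirected edges as a 2-column matrix plus incidence count
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "-")
  first <- !duplicated(key)
  edges <- cbind(pmin(e[first, 1], e[first, 2]), pmax(e[first, 1], e[first, 2]))
  counts <- as.integer(table(key)[key[first]])
  list(edges = edges, n_incident_faces = counts)
}

connected_components <- function(n, f) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(f))) {
    a <- find(f[k, 1]); b <- find(f[k, 2]); c <- find(f[k, 3])
    parent[b] <- a
    parent[find(c)] <- find(a)
  }
  vapply(seq_len(n), find, integer(1))
}

#' Construct a per-vertex scalar field
#'
#' A `surface_field` binds one scalar per mesh vertex with an explicit
#' missingness mask and a units tag. Missing data is always carried as the
#' mask, never as sentinel values.
#'
#' @param values Numeric vector, one value per vertex. `NA` entries are
#'   marked missing automatically.
#' @param missing_mask Logical vector; `TRUE` marks a vertex without a value.
#' @param units Units string: `"mm"` for thickness, `"t"` for t-statistics,
#'   `"p"` for p-values, `"dimensionless"` otherwise.
#' @param mesh Optional `surface_mesh`; if given, the length of `values`
#'   is checked against the vertex count, and p-value / thickness range
#'   invariants are enforced on the non-missing entries.
#' @return An object of class `surface_field`.
#' @export
surface_field <- function(values, missing_mask = is.na(values),
                          units = "dimensionless", mesh = NULL) {
  values <- as.numeric(values)
  missing_mask <- as.logical(missing_mask) | is.na(values)
  if (length(missing_mask) != length(values)) {
    stop("`missing_mask` must have the same length as `values`")
  }
  if (!is.null(mesh) && length(values) != nrow(mesh$vertices)) {
    stop(sprintf(
      "field length %d does not match mesh vertex count %d",
      length(values), nrow(mesh$vertices)
    ))
  }
  ok <- !missing_mask
  if (units == "p" && any(values[ok] < 0 | values[ok] > 1)) {
    stop("p-value field must lie in [0, 1] where not missing")
  }
  if (units == "mm" && any(values[ok] < 0)) {
    stop("thickness field must be >= 0 where not missing")
  }
  structure(
    list(values = values, missing_mask = missing_mask, units = units),
    class = "surface_field"
  )
}

#' @export
print.surface_field <- function(x, ...) {
  ok <- !x$missing_mask
  cat(sprintf(
    "<surface_field> %d vertices (%d missing), units '%s', range [%.4g, %.4g]\n",
    length(x$values), sum(x$missing_mask), x$units,
    if (any(ok)) min(x$values[ok]) else NA, if (any(ok)) max(x$values[ok]) else NA
  ))
  invisible(x)
}

## ---------------------------------------------------------------- mesh I/O

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("ply", "vtk", "obj")) {
    stop(sprintf("cannot infer mesh format from extension '%s'", ext))
  }
  ext
}

#' Read a triangle mesh (with optional per-vertex fields) from disk
#'
#' Supports ASCII PLY (per-vertex float properties beyond x/y/z become
#' `surface_field`s), legacy ASCII VTK PolyData (SCALARS point data arrays
#' become fields), and Wavefront OBJ (geometry only). The loaded mesh is
#' validated against the structural invariants.
#'
#' @param path File path.
#' @param format `"ply"`, `"vtk"` or `"obj"`; inferred from the extension
#'   when omitted.
#' @param patch_label Patch label to attach to the mesh.
#' @return A list with elements `mesh` (a `surface_mesh`) and `fields`
#'   (a named list of `surface_field`s, possibly empty).
#' @export
load_mesh <- function(path, format = guess_format(path), patch_label = "femur") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  out <- switch(format,
    ply = read_ply_ascii(path),
    vtk = read_vtk_polydata(path),
    obj = read_obj(path),
    stop(sprintf("unsupported mesh format '%s'", format))
  )
  mesh <- surface_mesh(out$vertices, out$faces, patch_label = patch_label)
  fields <- lapply(out$fields, function(vals) {
    units <- "dimensionless"
    surface_field(vals, units = units, mesh = mesh)
  })
  list(mesh = mesh, fields = fields)
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1]) != "ply") {
    stop(sprintf("PLY parse error at line 1: expected 'ply' magic in %s", path))
  }
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) stop("PLY parse error: missing 'end_header'")
  header <- trimws(lines[seq_len(hdr_end)])
  if (!any(grepl("^format\\s+ascii", header))) {
    stop("PLY parse error: only ASCII PLY is supported")
  }
  n_vert <- n_face <- 0L
  vprops <- character(0)
  current <- ""
  for (h in header) {
    tok <- strsplit(h, "\\s+")[[1]]
    if (tok[1] == "element") {
      current <- tok[2]
      if (current == "vertex") n_vert <- as.integer(tok[3])
      if (current == "face") n_face <- as.integer(tok[3])
    } else if (tok[1] == "property" && current == "vertex" && tok[2] != "list") {
      vprops <- c(vprops, tok[3])
    }
  }
  if (!all(c("x", "y", "z") %in% vprops)) {
    stop("PLY parse error: vertex element lacks x/y/z properties")
  }
  body <- lines[(hdr_end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n_vert + n_face) {
    stop(sprintf(
      "PLY parse error: expected %d data records, found %d",
      n_vert + n_face, length(body)
    ))
  }
  vdat <- matrix(NA_real_, n_vert, length(vprops))
  for (i in seq_len(n_vert)) {
    x <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
    bad <- is.na(x[seq_along(vprops)]) & !is.nan(x[seq_along(vprops)])
    if (length(x) < length(vprops) || any(bad)) {
      stop(sprintf("PLY parse error at vertex record %d", i))
    }
    vdat[i, ] <- x[seq_along(vprops)]
  }
  faces <- matrix(0L, n_face, 3)
  for (j in seq_len(n_face)) {
    x <- suppressWarnings(as.integer(strsplit(trimws(body[n_vert + j]), "\\s+")[[1]]))
    if (length(x) < 4L || is.na(x[1]) || x[1] != 3L) {
      stop(sprintf("PLY parse error at face record %d: only triangles supported", j))
    }
    faces[j, ] <- x[2:4] + 1L  # PLY is 0-based
  }
  vertices <- vdat[, match(c("x", "y", "z"), vprops), drop = FALSE]
  extra <- setdiff(vprops, c("x", "y", "z", "red", "green", "blue", "alpha"))
  fields <- stats::setNames(
    lapply(extra, function(p) vdat[, match(p, vprops)]),
    extra
  )
  list(vertices = vertices, faces = faces, fields = fields)
}

read_vtk_polydata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lt <- trimws(lines)
  if (!grepl("^# vtk DataFile", lines[1])) {
    stop("VTK parse error at line 1: missing '# vtk DataFile' header")
  }
  if (!any(toupper(lt) == "ASCII")) stop("VTK parse error: only ASCII VTK is supported")
  pi_ <- grep("^POINTS\\s", lt)[1]
  if (is.na(pi_)) stop("VTK parse error: no POINTS section")
  n_vert <- as.integer(strsplit(lt[pi_], "\\s+")[[1]][2])
  nums <- numeric(0)
  i <- pi_ + 1L
  while (length(nums) < 3L * n_vert && i <= length(lt)) {
    nums <- c(nums, suppressWarnings(as.numeric(strsplit(lt[i], "\\s+")[[1]])))
    i <- i + 1L
  }
  if (length(nums) < 3L * n_vert || anyNA(nums[seq_len(3 * n_vert)])) {
    stop("VTK parse error: POINTS section truncated or non-numeric")
  }
  vertices <- matrix(nums[seq_len(3 * n_vert)], ncol = 3, byrow = TRUE)
  fi <- grep("^POLYGONS\\s", lt)[1]
  if (is.na(fi)) stop("VTK parse error: no POLYGONS section")
  n_face <- as.integer(strsplit(lt[fi], "\\s+")[[1]][2])
  faces <- matrix(0L, n_face, 3)
  for (j in seq_len(n_face)) {
    x <- suppressWarnings(as.integer(strsplit(lt[fi + j], "\\s+")[[1]]))
    if (length(x) < 4L || x[1] != 3L) {
      stop(sprintf("VTK parse error at polygon record %d: only triangles supported", j))
    }
    faces[j, ] <- x[2:4] + 1L
  }
  fields <- list()
  pd <- grep("^POINT_DATA\\s", lt)
  if (length(pd)) {
    k <- pd[1] + 1L
    while (k <= length(lt)) {
      if (grepl("^SCALARS\\s", lt[k])) {
        nm <- strsplit(lt[k], "\\s+")[[1]][2]
        k <- k + 1L
        if (k <= length(lt) && grepl("^LOOKUP_TABLE", lt[k])) k <- k + 1L
        vals <- numeric(0)
        while (length(vals) < n_vert && k <= length(lt)) {
          vals <- c(vals, suppressWarnings(as.numeric(strsplit(lt[k], "\\s+")[[1]])))
          k <- k + 1L
        }
        fields[[nm]] <- vals[seq_len(n_vert)]
      } else {
        k <- k + 1L
      }
    }
  }
  list(vertices = vertices, faces = faces, fields = fields)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  vertices <- t(vapply(vl, function(l) {
    x <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]][2:4]))
    if (anyNA(x)) stop(sprintf("OBJ parse error in vertex line: '%s'", l))
    x
  }, numeric(3)))
  dimnames(vertices) <- NULL
  faces <- t(vapply(fl, function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1]][-1]
    if (length(tok) != 3L) stop("OBJ parse error: only triangular faces supported")
    idx <- suppressWarnings(as.integer(sub("/.*$", "", tok)))
    if (anyNA(idx)) stop(sprintf("OBJ parse error in face line: '%s'", l))
    idx
  }, integer(3)))
  dimnames(faces) <- NULL
  list(vertices = vertices, faces = faces, fields = list())
}

#' Write a triangle mesh with per-vertex fields to disk
#'
#' Writes ASCII PLY (fields as named float vertex properties), legacy VTK
#' PolyData (fields as SCALARS point data), or OBJ (geometry only). For PLY
#' a colour export is available: `color_field` is mapped through a
#' blue-white-red diverging colormap (symmetric about zero for signed units
#' such as `"t"`), and vertices where `color_mask` is `FALSE` are
#' desaturated towards grey, so non-significant regions appear washed out.
#'
#' @param mesh A `surface_mesh`.
#' @param path Output path.
#' @param fields Named list of `surface_field`s to store (missing entries
#'   are written as NaN).
#' @param format `"ply"`, `"vtk"` or `"obj"`; inferred from extension.
#' @param color_field Optional `surface_field` to encode as RGB (PLY only).
#' @param color_mask Optional logical vector; `FALSE` vertices are
#'   desaturated in the colour export.
#' @return The path, invisibly.
#' @export
save_mesh <- function(mesh, path, fields = list(), format = guess_format(path),
                      color_field = NULL, color_mask = NULL) {
  n <- nrow(mesh$vertices)
  for (nm in names(fields)) {
    if (length(fields[[nm]]$values) != n) {
      stop(sprintf("field '%s' length does not match mesh vertex count", nm))
    }
  }
  switch(format,
    ply = write_ply_ascii(mesh, path, fields, color_field, color_mask),
    vtk = write_vtk_polydata(mesh, path, fields),
    obj = write_obj(mesh, path),
    stop(sprintf("unsupported mesh format '%s'", format))
  )
  invisible(path)
}

#' Map field values to diverging RGB colours
#'
#' Blue-white-red diverging map; signed units (`"t"` or any field spanning
#' zero) are mapped symmetrically so zero hits the neutral white midpoint.
#' Vertices where `mask` is `FALSE` are blended 80% towards grey.
#'
#' @param field A `surface_field`.
#' @param mask Optional logical significance mask.
#' @return Integer matrix `n x 3` of RGB values in 0..255.
#' @export
field_colors <- function(field, mask = NULL) {
  v <- field$values
  ok <- !field$missing_mask
  symmetric <- field$units == "t" ||
    (any(ok) && min(v[ok]) < 0 && max(v[ok]) > 0)
  if (symmetric) {
    m <- max(abs(v[ok]), 1e-12)
    u <- (v / m + 1) / 2          # 0 .. 1, 0.5 at value 0
  } else {
    lo <- if (any(ok)) min(v[ok]) else 0
    hi <- if (any(ok)) max(v[ok]) else 1
    u <- if (hi > lo) (v - lo) / (hi - lo) else rep(0.5, length(v))
  }
  u <- pmin(pmax(u, 0), 1)
  # piecewise-linear blue (0) -> white (0.5) -> red (1)
  r <- ifelse(u <= 0.5, 2 * u, 1)
  g <- ifelse(u <= 0.5, 2 * u, 2 * (1 - u))
  b <- ifelse(u <= 0.5, 1, 2 * (1 - u))
  rgb <- cbind(r, g, b)
  if (!is.null(mask)) {
    w <- ifelse(mask, 0, 0.8)     # desaturation weight towards grey
    rgb <- rgb * (1 - w) + 0.65 * w
  }
  rgb[field$missing_mask, ] <- 0.65
  round(255 * rgb)
}

write_ply_ascii <- function(mesh, path, fields, color_field, color_mask) {
  n <- nrow(mesh$vertices)
  m <- nrow(mesh$faces)
  fnames <- names(fields)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", n),
    "property float x", "property float y", "property float z",
    if (length(fnames)) sprintf("property float %s", fnames),
    if (!is.null(color_field)) {
      c("property uchar red", "property uchar green", "property uchar blue")
    },
    sprintf("element face %d", m),
    "property list uchar int vertex_indices",
    "end_header"
  ), con)
  dat <- mesh$vertices
  for (nm in fnames) {
    v <- fields[[nm]]$values
    v[fields[[nm]]$missing_mask] <- NaN
    dat <- cbind(dat, v)
  }
  rows <- apply(dat, 1, function(r) paste(format(r, digits = 9, trim = TRUE, scientific = FALSE), collapse = " "))
  if (!is.null(color_field)) {
    rgb <- field_colors(color_field, color_mask)
    rows <- paste(rows, rgb[, 1], rgb[, 2], rgb[, 3])
  }
  writeLines(rows, con)
  writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
}

write_vtk_polydata <- function(mesh, path, fields) {
  n <- nrow(mesh$vertices)
  m <- nrow(mesh$faces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0", "surface mesh", "ASCII", "DATASET POLYDATA",
    sprintf("POINTS %d float", n)
  ), con)
  writeLines(apply(mesh$vertices, 1, function(r) {
    paste(format(r, digits = 9, trim = TRUE, scientific = FALSE), collapse = " ")
  }), con)
  writeLines(sprintf("POLYGONS %d %d", m, 4L * m), con)
  writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  if (length(fields)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(fields)) {
      v <- fields[[nm]]$values
      v[fields[[nm]]$missing_mask] <- NaN
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(v, digits = 9, trim = TRUE, scientific = FALSE), con)
    }
  }
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(mesh$vertices, 1, function(r) {
    paste("v", paste(format(r, digits = 9, trim = TRUE, scientific = FALSE), collapse = " "))
  }), con)
  writeLines(paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
}

## ------------------------------------------------- differential geometry

#' Per-vertex unit normals
#'
#' Angle-weighted average of incident face normals, normalised to unit
#' length. Orientation follows the face winding (counter-clockwise seen
#' from outside gives outward normals). Isolated vertices (no incident
#' face) receive `NA` normals.
#'
#' @param mesh A `surface_mesh`.
#' @return Numeric matrix `n x 3`; rows are unit vectors, `NA` for
#'   isolated vertices.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  nrm <- matrix(0, n, 3)
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  fn <- fn / sqrt(rowSums(fn^2))
  corner_angle <- function(at, b, c) {
    u <- v[b, , drop = FALSE] - v[at, , drop = FALSE]
    w <- v[c, , drop = FALSE] - v[at, , drop = FALSE]
    cosang <- rowSums(u * w) / (sqrt(rowSums(u^2)) * sqrt(rowSums(w^2)))
    acos(pmin(pmax(cosang, -1), 1))
  }
  ang <- cbind(
    corner_angle(f[, 1], f[, 2], f[, 3]),
    corner_angle(f[, 2], f[, 3], f[, 1]),
    corner_angle(f[, 3], f[, 1], f[, 2])
  )
  for (k in 1:3) {
    w <- ang[, k]
    idx <- f[, k]
    for (d in 1:3) {
      nrm[, d] <- nrm[, d] + unname(tapply_sum(idx, w * fn[, d], n))
    }
  }
  len <- sqrt(rowSums(nrm^2))
  isolated <- !(seq_len(n) %in% as.vector(f))
  nrm <- nrm / len
  nrm[isolated | len < 1e-300, ] <- NA_real_
  nrm
}

# fast grouped sum into a length-n vector
tapply_sum <- function(idx, vals, n) {
  out <- numeric(n)
  acc <- rowsum(vals, idx)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

#' Global mesh metrics
#'
#' Total surface area, the undirected edge list with lengths, total
#' boundary length (edges with exactly one incident face), Euler
#' characteristic V - E + F, and the mean edge length.
#'
#' @param mesh A `surface_mesh`.
#' @return A list with `total_area` (mm^2), `edges` (two-column index
#'   matrix), `edge_lengths` (mm), `boundary_length` (mm),
#'   `euler_characteristic`, `mean_edge_length` (mm).
#' @export
mesh_metrics <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  em <- mesh_edges(mesh)
  el <- sqrt(rowSums((v[em$edges[, 1], , drop = FALSE] -
                      v[em$edges[, 2], , drop = FALSE])^2))
  boundary <- em$n_incident_faces == 1L
  list(
    total_area = sum(triangle_areas(v, f)),
    edges = em$edges,
    edge_lengths = el,
    boundary_length = sum(el[boundary]),
    euler_characteristic = nrow(v) - nrow(em$edges) + nrow(f),
    mean_edge_length = mean(el)
  )
}

#' Smooth a per-vertex field along the mesh
#'
#' Iterative graph-Laplacian diffusion whose effective kernel has the
#' requested full width at half maximum, measured in mm along mesh edges.
#' The number of diffusion steps is derived from the FWHM, the mean squared
#' edge length and the mean vertex degree; a fractional final step removes
#' the integer-step quantisation. The symmetric Laplacian update preserves
#' the field mean over non-missing vertices exactly. `fwhm = 0` returns the
#' input unchanged; missing vertices are excluded from all averages and
#' remain missing.
#'
#' @param field A `surface_field`.
#' @param mesh The `surface_mesh` the field lives on.
#' @param fwhm Kernel full width at half maximum in mm; must be >= 0.
#' @return A smoothed `surface_field` with the same units and mask.
#' @export
smooth_field <- function(field, mesh, fwhm) {
  if (length(fwhm) != 1L || is.na(fwhm) || fwhm < 0) {
    stop("`fwhm` must be a single non-negative number (mm)")
  }
  if (fwhm == 0) return(field)
  x <- field$values
  ok <- !field$missing_mask
  em <- mesh_edges(mesh)
  keep <- ok[em$edges[, 1]] & ok[em$edges[, 2]]
  e <- em$edges[keep, , drop = FALSE]
  if (nrow(e) == 0L) return(field)
  el2 <- rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                  mesh$vertices[e[, 2], , drop = FALSE])^2)
  deg <- tabulate(c(e[, 1], e[, 2]), nbins = length(x))
  tau <- 0.5 / max(deg)
  # per-axis variance added per step: tau * mean degree * mean edge^2 / 2
  step_var <- tau * mean(deg[ok]) * mean(el2) / 2
  n_steps <- fwhm^2 / (8 * log(2) * step_var)
  k <- floor(n_steps)
  frac <- n_steps - k
  n <- length(x)
  L <- Matrix::sparseMatrix(
    i = c(e[, 1], e[, 2], which(ok)),
    j = c(e[, 2], e[, 1], which(ok)),
    x = c(rep(1, 2 * nrow(e)), -deg[ok]),
    dims = c(n, n)
  )
  y <- x
  y[!ok] <- 0
  for (s in seq_len(k)) y <- y + tau * as.numeric(L %*% y)
  if (frac > 0) y <- y + frac * tau * as.numeric(L %*% y)
  y[!ok] <- NA_real_
  surface_field(y, missing_mask = field$missing_mask, units = field$units)
}

## ------------------------------------------------------ fixture surfaces

#' Icosahedron mesh
#'
#' Unit icosahedron (vertices on the unit sphere), optionally subdivided
#' and reprojected to the sphere: `mesh_sphere(k)` performs `k` rounds of
#' 1-to-4 subdivision giving a geodesic sphere tessellation.
#'
#' @param radius Sphere radius in mm.
#' @return A closed `surface_mesh`.
#' @export
mesh_icosahedron <- function(radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2)) * radius
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  surface_mesh(v, f, patch_label = "sphere")
}

#' @rdname mesh_icosahedron
#' @param subdivisions Number of 1-to-4 subdivision rounds (0 = icosahedron).
#' @export
mesh_sphere <- function(subdivisions = 3, radius = 1) {
  mesh <- mesh_icosahedron(radius)
  for (s in seq_len(subdivisions)) {
    v <- mesh$vertices
    f <- mesh$faces
    em <- mesh_edges(mesh)
    key <- paste(em$edges[, 1], em$edges[, 2], sep = "-")
    mid_idx <- stats::setNames(nrow(v) + seq_along(key), key)
    mids <- (v[em$edges[, 1], , drop = FALSE] + v[em$edges[, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2)) * radius
    v2 <- rbind(v, mids)
    ek <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "-")
    m12 <- mid_idx[ek(f[, 1], f[, 2])]
    m23 <- mid_idx[ek(f[, 2], f[, 3])]
    m31 <- mid_idx[ek(f[, 3], f[, 1])]
    f2 <- rbind(
      cbind(f[, 1], m12, m31),
      cbind(f[, 2], m23, m12),
      cbind(f[, 3], m31, m23),
      cbind(m12, m23, m31)
    )
    mesh <- surface_mesh(v2, unname(f2), patch_label = "sphere", validate = FALSE)
  }
  validate_mesh(mesh)
  mesh
}

#' Regular flat triangulated grid in the z = 0 plane
#'
#' Useful as a controlled open patch: counter-clockwise winding gives all
#' normals (0, 0, 1).
#'
#' @param nx,ny Number of vertices along x and y.
#' @param spacing Grid spacing in mm.
#' @return An open `surface_mesh` with disc topology.
#' @export
mesh_grid <- function(nx = 10, ny = 10, spacing = 1) {
  g <- expand.grid(x = seq_len(nx) - 1, y = seq_len(ny) - 1)
  v <- cbind(g$x * spacing, g$y * spacing, 0)
  idx <- function(i, j) (j - 1L) * nx + i
  f <- NULL
  for (j in seq_len(ny - 1)) {
    for (i in seq_len(nx - 1)) {
      a <- idx(i, j); b <- idx(i + 1, j); c <- idx(i + 1, j + 1); d <- idx(i, j + 1)
      f <- rbind(f, c(a, b, c), c(a, c, d))
    }
  }
  surface_mesh(v, f, patch_label = "grid")
}
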