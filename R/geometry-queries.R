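# Low-level geometric queries shared by thickness measurement and
# registration: ray/mesh intersection and closest-point projection with
# barycentric coordinates.

# Precompute per-face vertex coordinate blocks for repeated queries.
face_blocks <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  list(
    A = v[f[, 1], , drop = FALSE],
    B = v[f[, 2], , drop = FALSE],
    C = v[f[, 3], , drop = FALSE]
  )
}

# First intersection of a single ray with the mesh (Moller-Trumbore,
# vectorised over faces). Returns the ray parameter of the nearest hit
# with t > eps, or NA if the ray misses.
ray_first_hit <- function(origin, dir, fb, eps = 1e-6) {
  e1 <- fb$B - fb$A
  e2 <- fb$C - fb$A
  # h = dir x e2
  h1 <- dir[2] * e2[, 3] - dir[3] * e2[, 2]
  h2 <- dir[3] * e2[, 1] - dir[1] * e2[, 3]
  h3 <- dir[1] * e2[, 2] - dir[2] * e2[, 1]
  a <- e1[, 1] * h1 + e1[, 2] * h2 + e1[, 3] * h3
  ok <- abs(a) > 1e-12
  s1 <- origin[1] - fb$A[, 1]
  s2 <- origin[2] - fb$A[, 2]
  s3 <- origin[3] - fb$A[, 3]
  u <- (s1 * h1 + s2 * h2 + s3 * h3) / a
  ok <- ok & u >= -1e-9 & u <= 1 + 1e-9
  q1 <- s2 * e1[, 3] - s3 * e1[, 2]
  q2 <- s3 * e1[, 1] - s1 * e1[, 3]
  q3 <- s1 * e1[, 2] - s2 * e1[, 1]
  v <- (dir[1] * q1 + dir[2] * q2 + dir[3] * q3) / a
  ok <- ok & v >= -1e-9 & u + v <= 1 + 1e-9
  tt <- (e2[, 1] * q1 + e2[, 2] * q2 + e2[, 3] * q3) / a
  ok <- ok & tt > eps
  if (!any(ok)) return(NA_real_)
  min(tt[ok])
}

# Closest point on each candidate triangle for paired (point, triangle)
# rows (Ericson's region classification, fully vectorised).
closest_point_on_triangles <- function(P, A, B, C) {
  dot <- function(x, y) rowSums(x * y)
  ab <- B - A; ac <- C - A; ap <- P - A
  d1 <- dot(ab, ap); d2 <- dot(ac, ap)
  bp <- P - B
  d3 <- dot(ab, bp); d4 <- dot(ac, bp)
  cp <- P - C
  d5 <- dot(ab, cp); d6 <- dot(ac, cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4

  n <- nrow(P)
  out <- matrix(NA_real_, n, 3)
  bary <- matrix(NA_real_, n, 3)
  done <- rep(FALSE, n)

  set_rows <- function(idx, pts, bc) {
    out[idx, ] <<- pts
    bary[idx, ] <<- bc
    done[idx] <<- TRUE
  }
  r <- !done & d1 <= 0 & d2 <= 0
  if (any(r)) set_rows(r, A[r, , drop = FALSE], cbind(1, 0, 0)[rep(1, sum(r)), , drop = FALSE])
  r <- !done & d3 >= 0 & d4 <= d3
  if (any(r)) set_rows(r, B[r, , drop = FALSE], cbind(0, 1, 0)[rep(1, sum(r)), , drop = FALSE])
  r <- !done & d6 >= 0 & d5 <= d6
  if (any(r)) set_rows(r, C[r, , drop = FALSE], cbind(0, 0, 1)[rep(1, sum(r)), , drop = FALSE])
  r <- !done & vc <= 0 & d1 >= 0 & d3 <= 0
  if (any(r)) {
    w <- d1[r] / (d1[r] - d3[r])
    set_rows(r, A[r, , drop = FALSE] + ab[r, , drop = FALSE] * w, cbind(1 - w, w, 0))
  }
  r <- !done & vb <= 0 & d2 >= 0 & d6 <= 0
  if (any(r)) {
    w <- d2[r] / (d2[r] - d6[r])
    set_rows(r, A[r, , drop = FALSE] + ac[r, , drop = FALSE] * w, cbind(1 - w, 0, w))
  }
  r <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  if (any(r)) {
    w <- (d4[r] - d3[r]) / ((d4[r] - d3[r]) + (d5[r] - d6[r]))
    set_rows(r, B[r, , drop = FALSE] + (C[r, , drop = FALSE] - B[r, , drop = FALSE]) * w,
             cbind(0, 1 - w, w))
  }
  r <- !done
  if (any(r)) {
    denom <- 1 / (va[r] + vb[r] + vc[r])
    v <- vb[r] * denom
    w <- vc[r] * denom
    set_rows(r, A[r, , drop = FALSE] + ab[r, , drop = FALSE] * v + ac[r, , drop = FALSE] * w,
             cbind(1 - v - w, v, w))
  }
  list(points = out, bary = bary)
}

# k-nearest mesh vertices for each query point, computed in blocks to
# bound memory; returns an n x k index matrix.
knn_vertices <- function(points, vertices, k = 8L, block = 512L) {
  n <- nrow(points)
  k <- min(k, nrow(vertices))
  out <- matrix(0L, n, k)
  v2 <- rowSums(vertices^2)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    p <- points[idx, , drop = FALSE]
    d2 <- outer(rowSums(p^2), v2, "+") - 2 * p %*% t(vertices)
    out[idx, ] <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  }
  out
}

# Exact closest point on the mesh restricted to faces incident to the k
# nearest vertices of each query point. Returns per-point distance, face
# index and barycentric coordinates.
closest_point_on_mesh <- function(points, mesh, k = 8L) {
  n <- nrow(points)
  f <- mesh$faces
  nn <- knn_vertices(points, mesh$vertices, k = k)
  # vertex -> incident face lists
  vf <- split(rep(seq_len(nrow(f)), 3), as.vector(f))
  vf_idx <- vector("list", nrow(mesh$vertices))
  vf_idx[as.integer(names(vf))] <- vf
  cand_faces <- lapply(seq_len(n), function(i) {
    unique(unlist(vf_idx[nn[i, ]], use.names = FALSE))
  })
  counts <- lengths(cand_faces)
  pt_idx <- rep(seq_len(n), counts)
  fc_idx <- unlist(cand_faces, use.names = FALSE)
  P <- points[pt_idx, , drop = FALSE]
  A <- mesh$vertices[f[fc_idx, 1], , drop = FALSE]
  B <- mesh$vertices[f[fc_idx, 2], , drop = FALSE]
  C <- mesh$vertices[f[fc_idx, 3], , drop = FALSE]
  cp <- closest_point_on_triangles(P, A, B, C)
  d2 <- rowSums((P - cp$points)^2)
  # argmin per query point
  ord <- order(pt_idx, d2)
  first <- ord[!duplicated(pt_idx[ord])]
  res_pt <- match(seq_len(n), pt_idx[first])
  sel <- first[res_pt]
  list(
    distance = sqrt(d2[sel]),
    face = fc_idx[sel],
    bary = cp$bary[sel, , drop = FALSE],
    points = cp$points[sel, , drop = FALSE]
  )
}
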