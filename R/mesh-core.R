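#' Triangulated surface mesh
#'
#' Construct a validated triangulated surface mesh. All coordinates are in
#' millimetres. Duplicate vertices (within `merge_tol`) are merged so that
#' faces share indices, and zero-area faces are dropped.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param normals optional numeric matrix, n x 3, per-vertex outward unit
#'   normals.
#' @param merge_tol duplicate-vertex merge tolerance in mm.
#' @return An object of class `surface_mesh`: a list with elements `vertices`,
#'   `faces` and (optionally) `normals`.
#' @export
surface_mesh <- function(vertices, faces, normals = NULL, merge_tol = 1e-9) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3) stop("vertices must be an n x 3 matrix")
  if (nrow(vertices) == 0) stop("mesh has no vertices")
  if (!all(is.finite(vertices))) {
    bad <- which(!apply(is.finite(vertices), 1, all))[1]
    stop(sprintf("non-finite vertex coordinate at vertex %d", bad))
  }
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3) stop("faces must be an m x 3 matrix of vertex indices")
  if (nrow(faces) == 0) stop("mesh has no faces")
  if (anyNA(faces) || min(faces) < 1 || max(faces) > nrow(vertices)) {
    stop("face index out of range")
  }

  # merge duplicate vertices so faces share indices
  key <- apply(round(vertices / max(merge_tol, .Machine$double.eps)), 1,
               paste, collapse = ",")
  first <- !duplicated(key)
  remap <- match(key, key[first])  # original row -> merged row (1..n_unique)
  if (any(!first)) {
    keep <- which(first)
    vertices <- vertices[keep, , drop = FALSE]
    if (!is.null(normals)) normals <- as.matrix(normals)[keep, , drop = FALSE]
    faces[] <- remap[faces]
  }

  # drop degenerate (zero-area) faces
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  cc <- vertices[faces[, 3], , drop = FALSE]
  cr <- vec_cross(b - a, cc - a)
  area2 <- sqrt(rowSums(cr^2))
  faces <- faces[area2 > 1e-12, , drop = FALSE]
  if (nrow(faces) == 0) stop("mesh degenerate: all faces have zero area")

  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    if (!identical(dim(normals), dim(vertices))) {
      stop("normals must match vertices in dimension")
    }
    len <- sqrt(rowSums(normals^2))
    if (any(abs(len - 1) > 1e-6)) stop("normals must be unit length (within 1e-6)")
  }

  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh: %d vertices, %d faces%s>\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$normals)) "" else ", with normals"))
  invisible(x)
}

#' @export
is_surface_mesh <- function(x) inherits(x, "surface_mesh")

# row-wise cross product of two n x 3 matrices
vec_cross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Anatomical landmark set
#'
#' Named 3D points in mm. The alignment and sectioning steps require
#' `mid_patella`, `mid_patellar_tendon` and `distal_tibia`.
#'
#' @param points named list (or 3-column matrix with rownames) of 3D points.
#' @param require character vector of names that must each appear exactly once.
#' @return An object of class `landmark_set`: a named k x 3 matrix.
#' @export
landmark_set <- function(points,
                         require = c("mid_patella", "mid_patellar_tendon",
                                     "distal_tibia")) {
  if (is.list(points)) {
    nm <- names(points)
    points <- do.call(rbind, lapply(points, function(p) as.numeric(p)))
    rownames(points) <- nm
  }
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("landmarks must be 3D points")
  nm <- rownames(points)
  if (is.null(nm)) stop("landmarks must be named")
  for (r in require) {
    k <- sum(nm == r)
    if (k != 1) stop(sprintf("landmark '%s' must appear exactly once (found %d)", r, k))
  }
  if (!all(is.finite(points))) stop("landmark coordinates must be finite")
  structure(points, class = c("landmark_set", "matrix"))
}

#' Rigid transform
#'
#' A proper rigid-body transform: 3x3 rotation (orthonormal, det +1) plus a
#' translation in mm, applied as `v' = R v + t`.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation vector, mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!identical(dim(rotation), c(3L, 3L)) || length(translation) != 3) {
    stop("rotation must be 3x3 and translation length 3")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must be orthonormal with determinant +1 (within 1e-9)")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform()

#' Compose rigid transforms
#'
#' `rt_compose(a, b)` returns the transform "apply `b`, then `a`".
#' @param a,b `rigid_transform` objects.
#' @rdname rigid_transform
#' @export
rt_compose <- function(a, b) {
  R <- a$rotation %*% b$rotation
  # re-orthonormalise to keep long compositions inside the invariant
  s <- svd(R)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  rigid_transform(R, as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname rigid_transform
#' @export
rt_inverse <- function(a) {
  rigid_transform(t(a$rotation), as.numeric(-t(a$rotation) %*% a$translation))
}

#' @rdname rigid_transform
#' @export
rt_apply_points <- function(a, pts) {
  pts <- as.matrix(pts)
  out <- pts %*% t(a$rotation)
  out <- sweep(out, 2, a$translation, "+")
  dimnames(out) <- dimnames(pts)
  out
}

#' Rotation angle (degrees) and translation norm (mm) of a rigid transform.
#' @param a a `rigid_transform`.
#' @return list with `angle_deg` and `translation_mm`.
#' @export
rt_magnitude <- function(a) {
  ct <- (sum(diag(a$rotation)) - 1) / 2
  list(angle_deg = acos(min(1, max(-1, ct))) * 180 / pi,
       translation_mm = sqrt(sum(a$translation^2)))
}

#' Rotation by angle (degrees) about a unit axis
#' @param axis length-3 axis (normalised internally).
#' @param angle_deg rotation angle in degrees.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rectification region masks
#'
#' Maps each of the seven rectification regions (PT, FH, MP, LP, TC, DE, LMC)
#' to a set of limb-mesh vertex indices. The expected carve/build direction of
#' each region is fixed by convention: builds add material (socket relieved),
#' carves remove material from the mould (socket presses in).
#'
#' @param masks named list of integer vertex-index vectors (1-based).
#' @param mesh optional `surface_mesh` the indices must be valid for.
#' @return An object of class `region_mask_set`.
#' @export
region_mask_set <- function(masks, mesh = NULL) {
  required <- names(region_directions())
  if (!all(required %in% names(masks))) {
    stop("missing region(s): ",
         paste(setdiff(required, names(masks)), collapse = ", "))
  }
  masks <- lapply(masks[required], function(ix) sort(unique(as.integer(ix))))
  if (!is.null(mesh)) {
    nv <- nrow(mesh$vertices)
    for (r in required) {
      if (length(masks[[r]]) && (min(masks[[r]]) < 1 || max(masks[[r]]) > nv)) {
        stop(sprintf("region '%s' has vertex indices outside the mesh", r))
      }
    }
  }
  structure(masks, class = "region_mask_set")
}

#' @rdname region_mask_set
#' @export
region_directions <- function() {
  c(PT = "carve", FH = "build", MP = "carve", LP = "carve",
    TC = "build", DE = "build", LMC = "carve")
}

#' The eight design variables, in the order the correlation matrix uses.
#' @export
design_variables <- function() c("PT", "MP", "LP", "FH", "DE", "VR", "TC", "LMC")

#' Principal axis of a mesh
#'
#' Largest-eigenvalue eigenvector of the vertex covariance matrix, sign-fixed
#' to point from mid-limb toward the vertex farthest from the centroid (the
#' distal direction for an open limb scan).
#'
#' @param mesh a `surface_mesh` with at least 4 non-coplanar vertices.
#' @return list with unit `axis` and `centroid`.
#' @export
principal_axis <- function(mesh) {
  V <- mesh$vertices
  if (nrow(V) < 4) stop("principal axis needs at least 4 vertices")
  centroid <- colMeans(V)
  ev <- eigen(stats::cov(V), symmetric = TRUE)
  if (ev$values[1] <= 0) stop("degenerate axis: vertices are coplanar or coincident")
  if ((ev$values[1] - ev$values[2]) / ev$values[1] < 0.01) {
    stop("degenerate axis: largest two covariance eigenvalues within 1%")
  }
  axis <- ev$vectors[, 1]
  d <- sweep(V, 2, centroid)
  # sign rule: distal is the direction in which the shape tapers (radial
  # spread about the axis decreases), the anatomical convention for residual
  # limb scans; shapes without taper fall back to pointing at the vertex
  # farthest from the centroid
  proj <- as.numeric(d %*% axis)
  radial <- sqrt(pmax(rowSums(d^2) - proj^2, 0))
  taper <- suppressWarnings(stats::cor(proj, radial))
  if (is.finite(taper) && abs(taper) > 0.05) {
    if (taper > 0) axis <- -axis
  } else {
    far <- which.max(rowSums(d^2))
    if (proj[far] < 0) axis <- -axis
  }
  list(axis = axis / sqrt(sum(axis^2)), centroid = centroid)
}

#' Apply a rigid transform to a mesh
#' @param mesh a `surface_mesh`.
#' @param transform a `rigid_transform`.
#' @return the transformed `surface_mesh` (faces unchanged; normals rotated).
#' @export
apply_transform <- function(mesh, transform) {
  V <- rt_apply_points(transform, mesh$vertices)
  N <- mesh$normals
  if (!is.null(N)) N <- N %*% t(transform$rotation)
  structure(list(vertices = V, faces = mesh$faces, normals = N),
            class = "surface_mesh")
}

#' Per-vertex outward unit normals
#'
#' Area-weighted average of incident face normals. Orientation is flipped
#' globally if the mean normal points toward the centroid (outward convention
#' for star-shaped limb geometry).
#'
#' @param mesh a `surface_mesh`.
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  if (!is.null(mesh$normals)) return(mesh$normals)
  V <- mesh$vertices
  F <- mesh$faces
  fn <- vec_cross(V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE],
                  V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE])
  # fn has length 2*area: area weighting is built in
  acc <- matrix(0, nrow(V), 3)
  for (k in 1:3) {
    acc[, 1] <- acc[, 1] + unname(rowsum_safe(fn[, 1], F[, k], nrow(V)))
    acc[, 2] <- acc[, 2] + unname(rowsum_safe(fn[, 2], F[, k], nrow(V)))
    acc[, 3] <- acc[, 3] + unname(rowsum_safe(fn[, 3], F[, k], nrow(V)))
  }
  len <- sqrt(rowSums(acc^2))
  len[len == 0] <- 1
  N <- acc / len
  centroid <- colMeans(V)
  if (mean(rowSums(N * sweep(V, 2, centroid))) < 0) N <- -N
  N
}

rowsum_safe <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Cross-sectional area of a mesh cut by a plane
#'
#' Intersects each triangle with the plane, chains the resulting segments into
#' closed contours (endpoints matched within `chain_tol`), and returns the sum
#' of absolute polygon areas (shoelace formula in plane coordinates) over all
#' contours, in mm^2.
#'
#' @param mesh a `surface_mesh`.
#' @param plane_point point on the plane.
#' @param plane_normal plane normal (normalised internally).
#' @param chain_tol endpoint matching tolerance, mm.
#' @return total section area, mm^2.
#' @export
cross_section_area <- function(mesh, plane_point, plane_normal, chain_tol = 1e-6) {
  segs <- section_segments(mesh, plane_point, plane_normal)
  if (is.null(segs)) {
    stop("empty section: plane does not intersect the mesh")
  }
  contours <- chain_segments(segs$p1, segs$p2, chain_tol)
  total <- 0
  for (poly in contours) {
    total <- total + abs(shoelace_area(poly))
  }
  total
}

# 2D intersection segments of the mesh with a plane, in plane coordinates
section_segments <- function(mesh, plane_point, plane_normal) {
  n <- plane_normal / sqrt(sum(plane_normal^2))
  V <- mesh$vertices
  F <- mesh$faces
  d <- as.numeric(sweep(V, 2, plane_point) %*% n)
  s <- d[F]
  dim(s) <- dim(F)
  smin <- pmin(s[, 1], s[, 2], s[, 3])
  smax <- pmax(s[, 1], s[, 2], s[, 3])
  cut <- which(smin < 0 & smax > 0)
  if (!length(cut)) return(NULL)
  # plane basis
  e1 <- if (abs(n[1]) < 0.9) vec_cross(matrix(n, 1), matrix(c(1, 0, 0), 1)) else
    vec_cross(matrix(n, 1), matrix(c(0, 1, 0), 1))
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- vec_cross(matrix(n, 1), e1)

  p1 <- matrix(NA_real_, length(cut), 2)
  p2 <- matrix(NA_real_, length(cut), 2)
  for (i in seq_along(cut)) {
    f <- cut[i]
    vid <- F[f, ]
    dv <- d[vid]
    pts <- list()
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      da <- dv[e[1]]; db <- dv[e[2]]
      if ((da < 0 && db > 0) || (da > 0 && db < 0)) {
        tt <- da / (da - db)
        p <- V[vid[e[1]], ] + tt * (V[vid[e[2]], ] - V[vid[e[1]], ])
        pts[[length(pts) + 1]] <- p
      } else if (da == 0) {
        pts[[length(pts) + 1]] <- V[vid[e[1]], ]
      }
    }
    if (length(pts) < 2) next
    q <- unique(do.call(rbind, pts))
    if (nrow(q) < 2) next
    rel <- sweep(q[1:2, , drop = FALSE], 2, plane_point)
    uv <- cbind(rel %*% t(e1), rel %*% t(e2))
    p1[i, ] <- uv[1, ]
    p2[i, ] <- uv[2, ]
  }
  ok <- stats::complete.cases(p1) & stats::complete.cases(p2)
  if (!any(ok)) return(NULL)
  list(p1 = p1[ok, , drop = FALSE], p2 = p2[ok, , drop = FALSE])
}

# chain 2D segments into closed contours; error if any contour stays open
chain_segments <- function(p1, p2, tol) {
  n <- nrow(p1)
  key <- function(p) paste(round(p[1] / tol), round(p[2] / tol))
  ends <- rbind(p1, p2)
  keys <- apply(ends, 1, function(p) key(p))
  # adjacency: endpoint key -> segment ids
  adj <- split(rep(seq_len(n), 2), keys)
  used <- logical(n)
  contours <- list()
  for (start in seq_len(n)) {
    if (used[start]) next
    used[start] <- TRUE
    pts <- list(p1[start, ])
    cur <- p2[start, ]
    start_key <- key(p1[start, ])
    repeat {
      pts[[length(pts) + 1]] <- cur
      ck <- key(cur)
      if (ck == start_key) break
      cand <- setdiff(adj[[ck]], which(used))
      if (is.null(cand) || !length(cand)) {
        stop("open contour: section polyline could not be closed")
      }
      nxt <- cand[1]
      used[nxt] <- TRUE
      cur <- if (key(p1[nxt, ]) == ck) p2[nxt, ] else p1[nxt, ]
    }
    poly <- do.call(rbind, pts)
    if (nrow(poly) >= 4) contours[[length(contours) + 1]] <- poly[-nrow(poly), , drop = FALSE]
  }
  if (!length(contours)) stop("open contour: no closed section polyline found")
  contours
}

shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1)
  sum(x * y[j] - x[j] * y) / 2
}
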