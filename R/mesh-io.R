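#' Read a surface mesh from STL or PLY
#'
#' STL is detected as binary or ASCII automatically; PLY must be ASCII
#' (format `ascii 1.0`). Duplicate vertices within 1e-9 mm are merged so that
#' faces share indices (STL stores each triangle's vertices independently).
#'
#' @param path file path.
#' @param format `"stl"`, `"ply"`, or `NULL` to infer from the extension.
#' @return a `surface_mesh`.
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  format <- match.arg(tolower(format), c("stl", "ply"))
  switch(format, stl = read_stl(path), ply = read_ply(path))
}

#' Write a surface mesh to STL or PLY
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @param format `"stl"` (ASCII), `"stl_binary"`, or `"ply"` (ASCII).
#' @param scalar optional per-vertex scalar written as a PLY `quality`
#'   property (e.g. a deviation map for visualisation); PLY only.
#' @export
write_mesh <- function(mesh, path, format = NULL, scalar = NULL) {
  if (!is_surface_mesh(mesh)) stop("mesh must be a surface_mesh")
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("stl", "stl_binary", "ply"))
  switch(format,
    stl = write_stl_ascii(mesh, path),
    stl_binary = write_stl_binary(mesh, path),
    ply = write_ply(mesh, path, scalar = scalar))
  invisible(path)
}

stl_is_binary <- function(path) {
  head <- readBin(path, "raw", n = 84)
  if (length(head) < 84) return(FALSE)
  txt <- rawToChar(head[1:5])
  if (identical(tolower(txt), "solid")) {
    # some binary files still start with "solid": check size consistency
    ntri <- readBin(head[81:84], "integer", size = 4, endian = "little")
    expected <- 84 + 50 * as.numeric(ntri)
    return(file.size(path) == expected)
  }
  TRUE
}

read_stl <- function(path) {
  if (stl_is_binary(path)) read_stl_binary(path) else read_stl_ascii(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) stop("STL format error: no 'vertex' records in ", path)
  toks <- strsplit(trimws(vl), "\\s+")
  bad <- which(vapply(toks, length, 1L) != 4)
  if (length(bad)) {
    stop("STL format error: malformed vertex record: ", vl[bad[1]])
  }
  coords <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(toks, `[`, 2:4))), ncol = 3, byrow = TRUE))
  if (anyNA(coords) || !all(is.finite(coords))) {
    bad <- which(!apply(is.finite(coords), 1, all))[1]
    stop("STL format error: non-finite coordinate in record: ", vl[bad])
  }
  if (nrow(coords) %% 3 != 0) {
    stop("STL format error: vertex count not a multiple of 3")
  }
  faces <- matrix(seq_len(nrow(coords)), ncol = 3, byrow = TRUE)
  surface_mesh(coords, faces)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  ntri <- readBin(con, "integer", size = 4, endian = "little")
  if (is.na(ntri) || ntri <= 0) stop("STL format error: bad triangle count")
  rec <- readBin(con, "raw", n = 50 * ntri)
  if (length(rec) < 50 * ntri) stop("STL format error: truncated binary file")
  dim(rec) <- c(50, ntri)
  fl <- readBin(as.vector(rec[1:48, ]), "numeric", size = 4,
                n = 12L * ntri, endian = "little")
  dim(fl) <- c(12, ntri)
  coords <- t(matrix(as.numeric(fl[4:12, ]), nrow = 3))
  if (!all(is.finite(coords))) stop("STL format error: non-finite coordinate")
  faces <- matrix(seq_len(nrow(coords)), ncol = 3, byrow = TRUE)
  surface_mesh(coords, faces)
}

write_stl_ascii <- function(mesh, path) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  n <- vec_cross(b - a, cc - a)
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  fmt <- function(m) sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3])
  out <- c("solid socketmap",
           as.vector(rbind(paste0("  facet normal ", fmt(n)),
                           "    outer loop",
                           paste0("      vertex ", fmt(a)),
                           paste0("      vertex ", fmt(b)),
                           paste0("      vertex ", fmt(cc)),
                           "    endloop",
                           "  endfacet")),
           "endsolid socketmap")
  writeLines(out, path)
}

write_stl_binary <- function(mesh, path) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  n <- vec_cross(b - a, cc - a)
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80)), con)
  writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
  block <- t(cbind(n, a, b, cc))  # 12 floats per triangle, column = triangle
  for (i in seq_len(nrow(F))) {
    writeBin(as.numeric(block[, i]), con, size = 4, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply") {
    stop("PLY format error: missing 'ply' magic line")
  }
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stop("PLY format error: no end_header")
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("^format\\s+ascii", trimws(hdr)))) {
    stop("PLY format error: only ASCII PLY is supported")
  }
  nv <- as.integer(sub(".*element\\s+vertex\\s+(\\d+).*", "\\1",
                       grep("element\\s+vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element\\s+face\\s+(\\d+).*", "\\1",
                       grep("element\\s+face", hdr, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("PLY format error: missing vertex/face elements")
  body <- lines[(hdr_end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) stop("PLY format error: truncated body")
  vtok <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  coords <- matrix(as.numeric(unlist(lapply(vtok, `[`, 1:3))), ncol = 3, byrow = TRUE)
  if (anyNA(coords) || !all(is.finite(coords))) {
    stop("PLY format error: non-finite vertex coordinate")
  }
  ftok <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- t(vapply(ftok, function(tk) {
    k <- as.integer(tk[1])
    if (is.na(k) || k != 3) stop("PLY format error: non-triangular face")
    as.integer(tk[2:4]) + 1L
  }, integer(3)))
  surface_mesh(coords, faces)
}

write_ply <- function(mesh, path, scalar = NULL) {
  V <- mesh$vertices
  F <- mesh$faces
  props <- c("property float x", "property float y", "property float z")
  vlines <- sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3])
  if (!is.null(scalar)) {
    if (length(scalar) != nrow(V)) stop("scalar must have one value per vertex")
    s <- ifelse(is.na(scalar), 0, scalar)
    props <- c(props, "property float quality")
    vlines <- sprintf("%s %.9g", vlines, s)
  }
  hdr <- c("ply", "format ascii 1.0", "comment socketmap",
           sprintf("element vertex %d", nrow(V)), props,
           sprintf("element face %d", nrow(F)),
           "property list uchar int vertex_indices", "end_header")
  flines <- sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L)
  writeLines(c(hdr, vlines, flines), path)
}

#' Read / write landmark JSON (name -> [x, y, z] in mm)
#' @param path JSON file path.
#' @return a `landmark_set`.
#' @export
read_landmarks <- function(path) {
  landmark_set(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_landmarks
#' @param landmarks a `landmark_set`.
#' @export
write_landmarks <- function(landmarks, path) {
  lst <- lapply(seq_len(nrow(landmarks)), function(i) as.numeric(landmarks[i, ]))
  names(lst) <- rownames(landmarks)
  jsonlite::write_json(lst, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read / write region-mask JSON
#'
#' On disk, vertex indices are 0-based (the common convention in mesh
#' toolchains); in R they are 1-based.
#' @param path JSON file path.
#' @param mesh optional mesh to validate indices against.
#' @export
read_masks <- function(path, mesh = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  region_mask_set(lapply(raw, function(ix) as.integer(ix) + 1L), mesh = mesh)
}

#' @rdname read_masks
#' @param masks a `region_mask_set`.
#' @export
write_masks <- function(masks, path) {
  jsonlite::write_json(lapply(unclass(masks), function(ix) as.integer(ix) - 1L),
                       path, auto_unbox = FALSE)
  invisible(path)
}

#' Read / write rigid-transform JSON (rotation row-major + translation + rms)
#' @param path JSON file path.
#' @export
read_transform <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(raw$rotation, 3, 3, byrow = TRUE), raw$translation)
}

#' @rdname read_transform
#' @param transform a `rigid_transform`.
#' @param rms optional residual RMS (mm) stored alongside.
#' @export
write_transform <- function(transform, path, rms = NULL) {
  obj <- list(rotation = as.numeric(t(transform$rotation)),
              translation = as.numeric(transform$translation))
  if (!is.null(rms)) obj$rms <- rms
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
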