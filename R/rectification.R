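#' Signed limb-to-socket deviation map
#'
#' For every limb vertex, casts a ray along its outward normal in both
#' directions and takes the nearest socket-surface intersection. The sign
#' convention follows rectification-map practice: positive = carve (socket
#' surface inward of the limb), negative = build (socket outward). Vertices
#' with no intersection within `cutoff` mm are `NA` (missing) and excluded
#' from region statistics.
#'
#' @param limb `surface_mesh`; normals computed by area-weighted face-normal
#'   averaging when absent.
#' @param socket_aligned `surface_mesh` already in the limb frame.
#' @param cutoff missing-intersection cutoff, mm.
#' @return numeric vector of class `deviation_map`, one signed value (mm) per
#'   limb vertex, `NA` where missing.
#' @export
compute_deviation_map <- function(limb, socket_aligned, cutoff = 50) {
  N <- vertex_normals(limb)
  idx <- mesh_index_build(socket_aligned$vertices, socket_aligned$faces - 1L)
  hit <- mesh_index_raycast(idx, limb$vertices, N, cutoff)
  if (all(is.na(hit$t))) {
    stop("meshes appear disjoint: no limb normal intersects the socket within ",
         cutoff, " mm")
  }
  # hit at +t along the outward normal = socket outside the limb = build (< 0)
  structure(-hit$t, class = "deviation_map")
}

#' @export
print.deviation_map <- function(x, ...) {
  v <- unclass(x)
  cat(sprintf("<deviation_map: %d vertices, %d missing, range [%.2f, %.2f] mm>\n",
              length(v), sum(is.na(v)), min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

#' Rectification size of one region
#'
#' The 98th percentile (linear interpolation between order statistics) of the
#' masked deviations, oriented so the region's expected direction is positive
#' (carve: +map, build: -map) and floored at 0. The percentile, rather than
#' the maximum, suppresses noise from individual vertices. The raw signed
#' percentile is attached as attribute `raw` for diagnostics.
#'
#' @param map a `deviation_map`.
#' @param mask_vertices integer vertex indices of the region.
#' @param direction `"carve"` or `"build"`.
#' @param probs percentile used (default 0.98).
#' @param region optional region name for error messages.
#' @return region size, mm (>= 0).
#' @export
region_size <- function(map, mask_vertices, direction = c("carve", "build"),
                        probs = 0.98, region = NULL) {
  direction <- match.arg(direction)
  name <- if (is.null(region)) "region" else paste0("region '", region, "'")
  d <- unclass(map)[mask_vertices]
  n_missing <- sum(is.na(d))
  if (length(d) && n_missing / length(d) > 0.5) {
    stop(name, ": more than half of the masked vertices have no deviation value")
  }
  d <- d[!is.na(d)]
  if (length(d) < 10) {
    stop(name, ": fewer than 10 usable masked vertices")
  }
  if (direction == "build") d <- -d
  raw <- unname(stats::quantile(d, probs, type = 7))
  structure(max(0, raw), raw = raw)
}

#' Volume reduction between limb and socket
#'
#' Mean over `n_sections` equally spaced cross-sections (planes perpendicular
#' to the limb principal axis, spanning the axial levels of the mid patellar
#' tendon and distal tibia landmarks, endpoints inclusive) of the relative
#' area difference (A_limb - A_socket) / A_limb, in percent.
#'
#' @param limb,socket_aligned `surface_mesh` objects in a common frame.
#' @param landmarks `landmark_set` with `mid_patellar_tendon` and
#'   `distal_tibia`.
#' @param n_sections number of section planes.
#' @return VR in percent, with attribute `per_section` (data frame of level,
#'   limb and socket areas).
#' @export
volume_reduction <- function(limb, socket_aligned, landmarks, n_sections = 10) {
  for (lm in c("mid_patellar_tendon", "distal_tibia")) {
    if (!lm %in% rownames(landmarks)) stop("missing landmark: ", lm)
  }
  pa <- principal_axis(limb)
  lev <- function(p) sum((p - pa$centroid) * pa$axis)
  l0 <- lev(landmarks["mid_patellar_tendon", ])
  l1 <- lev(landmarks["distal_tibia", ])
  levels <- seq(l0, l1, length.out = n_sections)
  a_limb <- a_sock <- numeric(n_sections)
  for (i in seq_len(n_sections)) {
    pt <- pa$centroid + levels[i] * pa$axis
    a_limb[i] <- tryCatch(cross_section_area(limb, pt, pa$axis),
                          error = function(e) {
      stop(sprintf("section %d (axial level %.2f mm) failed on the limb: %s",
                   i, levels[i], conditionMessage(e)))
    })
    a_sock[i] <- tryCatch(cross_section_area(socket_aligned, pt, pa$axis),
                          error = function(e) {
      stop(sprintf("section %d (axial level %.2f mm) failed on the socket: %s",
                   i, levels[i], conditionMessage(e)))
    })
  }
  vr <- mean((a_limb - a_sock) / a_limb) * 100
  attr(vr, "per_section") <- data.frame(level = levels, area_limb = a_limb,
                                        area_socket = a_sock)
  vr
}

#' Extract the full rectification profile of an aligned pair
#'
#' Runs [compute_deviation_map()], [region_size()] for the seven regions and
#' [volume_reduction()], returning the eight design variables. The deviation
#' map is attached as attribute `map` for rendering, and the raw signed
#' percentiles as attribute `raw_sizes`.
#'
#' @param limb `surface_mesh`.
#' @param socket_aligned `surface_mesh` in the limb frame.
#' @param landmarks limb `landmark_set`.
#' @param masks a `region_mask_set` on the limb mesh.
#' @param socket_id,design optional metadata carried into the profile.
#' @param cutoff missing-intersection cutoff for the deviation map, mm.
#' @return a [rectification_profile()].
#' @export
extract_profile <- function(limb, socket_aligned, landmarks, masks,
                            socket_id = NA_character_, design = NA_character_,
                            cutoff = 50) {
  if (!inherits(masks, "region_mask_set")) stop("masks must be a region_mask_set")
  map <- compute_deviation_map(limb, socket_aligned, cutoff = cutoff)
  dirs <- region_directions()
  sizes <- raw <- stats::setNames(numeric(length(dirs)), names(dirs))
  for (r in names(dirs)) {
    s <- region_size(map, masks[[r]], dirs[[r]], region = r)
    sizes[[r]] <- s
    raw[[r]] <- attr(s, "raw")
  }
  vr <- volume_reduction(limb, socket_aligned, landmarks)
  prof <- rectification_profile(PT = sizes[["PT"]], FH = sizes[["FH"]],
                                MP = sizes[["MP"]], LP = sizes[["LP"]],
                                TC = sizes[["TC"]], DE = sizes[["DE"]],
                                LMC = sizes[["LMC"]], VR = as.numeric(vr),
                                socket_id = socket_id, design = design)
  attr(prof, "map") <- map
  attr(prof, "raw_sizes") <- raw
  attr(prof, "per_section") <- attr(vr, "per_section")
  prof
}

#' Displace a limb mesh by a deviation map
#'
#' Builds the socket surface implied by a per-vertex signed deviation map
#' (positive = carve = inward), by displacing each limb vertex along its
#' outward normal by `-map`. Missing values displace by 0.
#'
#' @param limb `surface_mesh`.
#' @param map a `deviation_map` (or numeric vector, one value per vertex).
#' @return a `surface_mesh`.
#' @export
deviation_to_socket <- function(limb, map) {
  v <- unclass(map)
  if (length(v) != nrow(limb$vertices)) {
    stop("map must have one value per limb vertex")
  }
  v[is.na(v)] <- 0
  N <- vertex_normals(limb)
  surface_mesh(limb$vertices - N * v, limb$faces)
}

#' Profile as a one-row tibble
#' @param profile a `rectification_profile`.
#' @return tibble with socket_id, design, the seven sizes (mm) and VR (pct).
#' @export
profile_row <- function(profile) {
  tibble::tibble(socket_id = profile$socket_id, design = profile$design,
                 PT = profile$PT, FH = profile$FH, MP = profile$MP,
                 LP = profile$LP, TC = profile$TC, DE = profile$DE,
                 LMC = profile$LMC, VR = profile$VR)
}
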