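#' Synthetic residual-limb specification
#'
#' Defines a tapered limb-like surface of revolution with a rounded distal
#' cap, used as a stand-in for restricted 3D limb scans. Defaults describe a
#' plausible adult transtibial residuum: 180 mm long, 55 mm proximal radius
#' tapering linearly to 35 mm at the start of a 30 mm elliptical cap.
#' The canonical frame points the distal direction along +z, anterior along
#' +x and lateral along +y.
#'
#' @param length total limb length, mm (including the distal cap).
#' @param proximal_radius radius at the open proximal end, mm.
#' @param distal_radius radius where the cap begins, mm.
#' @param cap_height axial height of the rounded distal cap, mm.
#' @param radius_fun optional monotone function z -> radius (mm) overriding
#'   the linear taper over the shaft.
#' @param n_angular,n_axial mesh resolution; at least 90 x 60 for the
#'   parameter-recovery guarantees to hold.
#' @param seed integer seed recorded with generated objects.
#' @return an object of class `limb_spec`.
#' @export
limb_spec <- function(length = 180, proximal_radius = 55, distal_radius = 35,
                      cap_height = 30, radius_fun = NULL,
                      n_angular = 180, n_axial = 120, seed = 1L) {
  stopifnot(length > 0, proximal_radius > 0, distal_radius > 0,
            cap_height > 0, cap_height < length)
  if (n_angular < 90 || n_axial < 60) {
    stop("resolution below minimum (90 angular x 60 axial)")
  }
  structure(list(length = length, proximal_radius = proximal_radius,
                 distal_radius = distal_radius, cap_height = cap_height,
                 radius_fun = radius_fun, n_angular = as.integer(n_angular),
                 n_axial = as.integer(n_axial), seed = as.integer(seed)),
            class = "limb_spec")
}

# shaft radius at axial position z (0 = proximal, shaft ends at length - cap)
limb_radius <- function(spec, z) {
  z_cap <- spec$length - spec$cap_height
  if (!is.null(spec$radius_fun)) return(spec$radius_fun(pmin(z, z_cap)))
  spec$proximal_radius +
    (spec$distal_radius - spec$proximal_radius) * pmin(z, z_cap) / z_cap
}

#' Generate a synthetic limb
#'
#' Builds the surface-of-revolution mesh for a [limb_spec()], together with
#' anatomically placed landmarks (mid patella and mid patellar tendon
#' proximal-anterior, distal tibia just above the cap), the seven
#' rectification-region vertex masks and the anterior sub-patellar mask used
#' to drive ICP. Deterministic for a given spec.
#'
#' @param spec a `limb_spec`.
#' @return a list of class `synthetic_limb` with elements `mesh`
#'   (`surface_mesh`), `landmarks` (`landmark_set`), `masks`
#'   (`region_mask_set`), `anterior` (integer vertex indices), `param`
#'   (per-vertex cylindrical parameters) and `spec`.
#' @export
generate_limb <- function(spec = limb_spec()) {
  L <- spec$length
  z_cap <- L - spec$cap_height
  na <- spec$n_angular
  nz <- spec$n_axial
  n_shaft <- max(10L, as.integer(round(nz * z_cap / L)))
  n_caprings <- max(6L, nz - n_shaft)

  theta <- 2 * pi * (seq_len(na) - 1) / na
  z_shaft <- seq(0, z_cap, length.out = n_shaft)
  phi_cap <- (seq_len(n_caprings - 1) / n_caprings) * (pi / 2)
  z_rings <- c(z_shaft, z_cap + spec$cap_height * sin(phi_cap))
  r_cap_base <- limb_radius(spec, z_cap)
  r_rings <- c(limb_radius(spec, z_shaft), r_cap_base * cos(phi_cap))
  nring <- length(z_rings)

  zz <- rep(z_rings, each = na)
  rr <- rep(r_rings, each = na)
  th <- rep(theta, times = nring)
  V <- cbind(rr * cos(th), rr * sin(th), zz)
  apex <- c(0, 0, L)
  V <- rbind(V, apex)
  nv <- nrow(V)

  # ring-to-ring quads split into two triangles, outward orientation
  i <- rep(seq_len(na), times = nring - 1)
  j <- rep(seq_len(nring - 1), each = na)
  a <- (j - 1) * na + i
  b <- (j - 1) * na + (i %% na) + 1
  cc <- j * na + i
  d <- j * na + (i %% na) + 1
  F1 <- cbind(a, b, d)
  F2 <- cbind(a, d, cc)
  # cap fan to apex
  top <- (nring - 1) * na + seq_len(na)
  topn <- (nring - 1) * na + (seq_len(na) %% na) + 1
  F3 <- cbind(top, topn, rep(nv, na))
  mesh <- surface_mesh(V, rbind(F1, F2, F3))

  # per-vertex parameters; the apex gets theta 0, phi pi/2
  vp <- list(theta = c(th, 0), z = c(zz, L), radius = c(rr, 0),
             phi = c(rep(0, na * n_shaft),
                     rep(phi_cap, each = na), pi / 2))

  surf_pt <- function(z) c(limb_radius(spec, z), 0, z)
  landmarks <- landmark_set(list(
    mid_patella = surf_pt(0.11 * L),
    mid_patellar_tendon = surf_pt(0.195 * L),
    distal_tibia = surf_pt(0.78 * L)))

  deg <- vp$theta * 180 / pi
  deg <- ifelse(deg > 180, deg - 360, deg)
  in_sector <- function(lo, hi) deg >= lo & deg <= hi
  in_band <- function(lo, hi) vp$z >= lo * L & vp$z <= hi * L
  masks <- region_mask_set(list(
    PT = which(in_sector(-25, 25) & in_band(0.15, 0.25)),
    FH = which(in_sector(70, 110) & in_band(0.14, 0.25)),
    MP = which(in_sector(-60, -20) & in_band(0.28, 0.62)),
    LP = which(in_sector(20, 60) & in_band(0.28, 0.62)),
    TC = which(in_sector(-15, 15) & in_band(0.30, 0.60)),
    DE = which(vp$z >= z_cap - 1e-9),
    LMC = which((in_sector(75, 105) | in_sector(-105, -75)) & in_band(0.02, 0.11))
  ), mesh = mesh)
  anterior <- which(in_sector(-45, 45) & vp$z >= 0.195 * L & vp$z <= 0.4 * L)

  structure(list(mesh = mesh, landmarks = landmarks, masks = masks,
                 anterior = anterior, param = vp, spec = spec),
            class = "synthetic_limb")
}

#' Rectification profile
#'
#' The eight design variables of one socket: seven local rectification sizes
#' in mm (each a magnitude in the region's expected carve/build direction)
#' and the volume reduction VR in percent.
#'
#' @param PT,FH,MP,LP,TC,DE,LMC region sizes, mm (>= 0).
#' @param VR volume reduction, percent (negative only for sockets globally
#'   larger than the limb, which callers should flag).
#' @param socket_id,design optional metadata (design in PTB/TSB/PTB-SC).
#' @return an object of class `rectification_profile` (named list).
#' @export
rectification_profile <- function(PT = 0, FH = 0, MP = 0, LP = 0, TC = 0,
                                  DE = 0, LMC = 0, VR = 0,
                                  socket_id = NA_character_,
                                  design = NA_character_) {
  sizes <- c(PT = PT, FH = FH, MP = MP, LP = LP, TC = TC, DE = DE, LMC = LMC)
  if (any(sizes < 0)) stop("rectification sizes must be non-negative")
  if (!is.na(design) && !design %in% c("PTB", "TSB", "PTB-SC")) {
    stop("design must be PTB, TSB or PTB-SC")
  }
  structure(c(as.list(sizes), list(VR = VR, socket_id = socket_id,
                                   design = design)),
            class = "rectification_profile")
}

#' @export
print.rectification_profile <- function(x, ...) {
  cat("<rectification_profile>\n")
  for (r in names(region_directions())) {
    cat(sprintf("  %-4s %5.2f mm (%s)\n", r, x[[r]], region_directions()[[r]]))
  }
  cat(sprintf("  VR   %5.2f %%\n", x$VR))
  invisible(x)
}

# plateaued-cosine falloff: 1 inside rho <= plateau, smooth to 0 at rho = 1
bump_falloff <- function(rho, plateau = 0.35) {
  f <- numeric(length(rho))
  f[rho <= plateau] <- 1
  mid <- rho > plateau & rho < 1
  f[mid] <- 0.5 * (1 + cos(pi * (rho[mid] - plateau) / (1 - plateau)))
  f
}

#' Generate a synthetic socket from a limb and a known profile
#'
#' The socket is the limb surface with (1) an exact radial scaling by
#' `sqrt(1 - VR/100)` about the limb axis, so that every cross-sectional area
#' shrinks by VR percent, and (2) a plateaued-cosine displacement bump per
#' rectification region (inward for carves, outward for builds) anchored so
#' that the limb-to-socket deviation at the bump plateau equals the requested
#' size. An optional rigid pose perturbation and i.i.d. vertex noise are
#' applied last and recorded in the ground truth.
#'
#' @param limb a `synthetic_limb` from [generate_limb()].
#' @param profile a [rectification_profile()] of true sizes.
#' @param pose optional `rigid_transform` perturbation applied to the socket.
#' @param noise_sd i.i.d. Gaussian noise s.d. added to socket vertex
#'   coordinates, mm.
#' @param support_frac bump support half-extent as a fraction of the region
#'   mask half-extent.
#' @param seed RNG seed for the vertex noise.
#' @return list with `mesh` (`surface_mesh`) and `truth` (profile, bump
#'   centres/widths, pose, noise s.d., seed).
#' @export
generate_socket <- function(limb, profile, pose = NULL, noise_sd = 0,
                            support_frac = 0.7, seed = limb$spec$seed) {
  stopifnot(inherits(limb, "synthetic_limb"),
            inherits(profile, "rectification_profile"))
  mesh <- limb$mesh
  vp <- limb$param
  V <- mesh$vertices
  s <- sqrt(1 - profile$VR / 100)
  shrink <- vp$radius * (1 - s)

  # region geometry in (theta, z); DE is handled on the cap in phi
  L <- limb$spec$length
  regions <- list(
    PT = list(th = 0, z = 0.20 * L, hw_th = 25, hw_z = 0.05 * L),
    FH = list(th = 90, z = 0.195 * L, hw_th = 20, hw_z = 0.055 * L),
    MP = list(th = -40, z = 0.45 * L, hw_th = 20, hw_z = 0.17 * L),
    LP = list(th = 40, z = 0.45 * L, hw_th = 20, hw_z = 0.17 * L),
    TC = list(th = 0, z = 0.45 * L, hw_th = 15, hw_z = 0.15 * L),
    LMC = list(th = c(90, -90), z = 0.065 * L, hw_th = 15, hw_z = 0.045 * L))

  deg <- vp$theta * 180 / pi
  deg <- ifelse(deg > 180, deg - 360, deg)
  dirs <- region_directions()
  # normal component of the radial VR shrink: offsetting a cone radially by
  # dr moves the surface dr * (n . rhat) along its normal, and the bump field
  # must cancel exactly that for plateau deviations to equal the true sizes
  N <- vertex_normals(mesh)
  rlen <- pmax(vp$radius, 1e-12)
  ndotr <- (N[, 1] * V[, 1] + N[, 2] * V[, 2]) / rlen
  ndotr[vp$radius < 1e-9] <- 0
  shrink_n <- shrink * ndotr
  total <- numeric(nrow(V))  # bump falloff-weighted target field
  centres <- list()
  expected <- list()  # analytic 98th-percentile deviation per region
  for (r in names(regions)) {
    size <- profile[[r]]
    g <- regions[[r]]
    centres[[r]] <- list(theta_deg = g$th, z_mm = g$z,
                         width_theta_deg = g$hw_th * support_frac,
                         width_z_mm = g$hw_z * support_frac)
    sgn <- if (dirs[[r]] == "build") 1 else -1
    if (size <= 0) {  # no rectification: the reduced surface stands
      ix <- limb$masks[[r]]
      expected[[r]] <- max(0, unname(stats::quantile(-sgn * shrink_n[ix],
                                                     0.98, type = 7)))
      next
    }
    f <- numeric(nrow(V))
    for (thc in g$th) {
      dth <- (deg - thc + 180) %% 360 - 180
      rho <- sqrt((dth / (g$hw_th * support_frac))^2 +
                  ((vp$z - g$z) / (g$hw_z * support_frac))^2)
      f <- pmax(f, bump_falloff(rho))
    }
    total <- total + f * (sgn * size + shrink_n)
    # deviation the construction actually places over the mask, oriented in
    # the region's expected direction (a carve smaller than the global VR
    # shrink is masked by it in the 98th-percentile measurement)
    ix <- limb$masks[[r]]
    dev_r <- f[ix] * size - sgn * (1 - f[ix]) * shrink_n[ix]
    expected[[r]] <- unname(stats::quantile(dev_r, 0.98, type = 7))
  }
  # distal end elongation: bump over the cap, apex-centred
  centres$DE <- list(theta_deg = NA, z_mm = L,
                     width_phi = support_frac * pi / 2)
  ix_de <- limb$masks$DE
  if (profile$DE > 0) {
    rho_de <- 1 - vp$phi / (pi / 2)
    f_de <- bump_falloff(rho_de / support_frac * 0.999)
    f_de[vp$z < L - limb$spec$cap_height - 1e-9] <- 0
    total <- total + f_de * (profile$DE + shrink_n)
    expected$DE <- unname(stats::quantile(
      f_de[ix_de] * profile$DE - (1 - f_de[ix_de]) * shrink_n[ix_de],
      0.98, type = 7))
  } else {
    expected$DE <- max(0, unname(stats::quantile(-shrink_n[ix_de], 0.98,
                                                 type = 7)))
  }

  # exact radial VR, then bump fields (anchored to the unreduced limb, so the
  # deviation at each plateau equals the true size) applied along limb normals
  Vr <- cbind(V[, 1] * s, V[, 2] * s, V[, 3])
  Vs <- Vr + N * total
  socket <- surface_mesh(Vs, mesh$faces)

  if (noise_sd > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
    socket$vertices <- socket$vertices +
      matrix(stats::rnorm(length(socket$vertices), 0, noise_sd),
             ncol = 3)
  }
  if (!is.null(pose)) socket <- apply_transform(socket, pose)

  truth <- list(profile = profile, bump_centres = centres,
                expected_measured = unlist(expected)[names(dirs)],
                pose = pose, noise_sd = noise_sd, seed = seed)
  list(mesh = socket, truth = truth)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}
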