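#' Least-squares rigid fit (Kabsch)
#'
#' Rigid transform T minimising sum ||T(source_i) - target_i||^2.
#'
#' @param source,target n x 3 matrices of paired points.
#' @return a `rigid_transform`, with attribute `rms` (residual RMS, mm).
#' @export
kabsch <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (!all(dim(source) == dim(target)) || ncol(source) != 3 || nrow(source) < 3) {
    stop("kabsch needs matched n x 3 point sets, n >= 3")
  }
  cs <- colMeans(source); ct <- colMeans(target)
  H <- crossprod(sweep(source, 2, cs), sweep(target, 2, ct))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- rigid_transform(R, ct - as.numeric(R %*% cs))
  res <- rt_apply_points(tr, source) - target
  attr(tr, "rms") <- sqrt(mean(rowSums(res^2)))
  tr
}

# minimal rotation carrying unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) {
    # opposite: rotate pi about any axis orthogonal to a
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- ax - sum(ax * a) * a
    return(rotation_about_axis(ax, 180))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + c_)
}

#' Coarse socket-to-limb alignment
#'
#' Stage one of the registration: aligns the two principal axes, then fixes
#' the remaining axial rotation and translation by a least-squares (Kabsch)
#' fit of the mid patella and distal tibia landmark pairs plus the two mesh
#' centroids. Returns the transform mapping the socket into the limb frame.
#'
#' @param limb,socket `surface_mesh` objects.
#' @param limb_landmarks,socket_landmarks `landmark_set`s containing
#'   `mid_patella` and `distal_tibia`.
#' @return a `rigid_transform` with attribute `rms` (landmark residual RMS).
#' @export
coarse_align <- function(limb, socket, limb_landmarks, socket_landmarks) {
  for (lm in c("mid_patella", "distal_tibia")) {
    if (!lm %in% rownames(limb_landmarks) || !lm %in% rownames(socket_landmarks)) {
      stop("missing landmark: ", lm)
    }
  }
  pa_l <- principal_axis(limb)
  pa_s <- principal_axis(socket)
  R0 <- rotation_between(pa_s$axis, pa_l$axis)
  # rotate the socket about its centroid onto the limb axis direction
  t0 <- pa_s$centroid - as.numeric(R0 %*% pa_s$centroid)
  T0 <- rigid_transform(R0, t0)

  src <- rbind(socket_landmarks["mid_patella", ],
               socket_landmarks["distal_tibia", ],
               pa_s$centroid)
  tgt <- rbind(limb_landmarks["mid_patella", ],
               limb_landmarks["distal_tibia", ],
               pa_l$centroid)
  T1 <- kabsch(rt_apply_points(T0, src), tgt)
  out <- rt_compose(T1, T0)
  attr(out, "rms") <- attr(T1, "rms")
  out
}

#' ICP refinement on the anterior sub-patellar region
#'
#' Point-to-point ICP restricted to a vertex mask on the limb: each iteration
#' finds, for every masked limb vertex, the nearest point on the socket
#' surface (point-to-triangle via a spatial index, ties broken by lowest
#' triangle index), solves the Kabsch fit on the pairs and applies it to the
#' socket. Stops when the RMS improvement falls below `tol` or after
#' `max_iter` iterations.
#'
#' @param limb,socket `surface_mesh` objects, coarsely aligned already.
#' @param anterior_mask integer vertex indices on the limb mesh.
#' @param max_iter maximum iterations.
#' @param tol RMS improvement threshold, mm.
#' @param max_pair_dist optional cut: pairs farther than this (mm) are
#'   dropped from the fit (off by default; the study conditions are
#'   low-noise scans where trimming is unnecessary).
#' @return list with `transform` (cumulative `rigid_transform`, socket ->
#'   limb frame increment), `rms` (final), `rms_trace`, `iterations`,
#'   `converged`.
#' @export
icp_align <- function(limb, socket, anterior_mask, max_iter = 50, tol = 1e-4,
                      max_pair_dist = Inf) {
  anterior_mask <- as.integer(anterior_mask)
  if (!length(anterior_mask)) stop("empty anterior mask")
  if (min(anterior_mask) < 1 || max(anterior_mask) > nrow(limb$vertices)) {
    stop("anterior mask indices outside the limb mesh")
  }
  Q <- limb$vertices[anterior_mask, , drop = FALSE]
  idx <- mesh_index_build(socket$vertices, socket$faces - 1L)
  Tcum <- rt_identity()
  rms_trace <- numeric(0)
  prev_rms <- Inf
  converged <- FALSE
  iters <- 0L
  while (iters < max_iter) {
    iters <- iters + 1L
    # query limb points in the socket's native frame
    Qs <- rt_apply_points(rt_inverse(Tcum), Q)
    cl <- mesh_index_closest(idx, Qs)
    src <- rt_apply_points(Tcum, cl$point)  # current socket-frame positions
    keep <- cl$distance <= max_pair_dist
    if (sum(keep) < 3) stop("fewer than 3 ICP pairs within max_pair_dist")
    Tinc <- kabsch(src[keep, , drop = FALSE], Q[keep, , drop = FALSE])
    Tcum <- rt_compose(Tinc, Tcum)
    res <- rt_apply_points(Tinc, src[keep, , drop = FALSE]) - Q[keep, , drop = FALSE]
    rms <- sqrt(mean(rowSums(res^2)))
    rms_trace <- c(rms_trace, rms)
    if (prev_rms - rms < tol) {
      converged <- TRUE
      break
    }
    prev_rms <- rms
  }
  list(transform = Tcum,
       rms = if (length(rms_trace)) rms_trace[length(rms_trace)] else NA_real_,
       rms_trace = rms_trace, iterations = iters, converged = converged)
}

#' Full two-stage socket-to-limb alignment
#'
#' Composes [coarse_align()] then [icp_align()], with an optional override
#' transform composed last. The override is the deterministic stand-in for
#' manual inspection-and-adjustment of registered pairs: supplying a
#' correction known from an external QA step reproduces it exactly.
#'
#' @param limb,socket `surface_mesh` objects.
#' @param limb_landmarks,socket_landmarks `landmark_set`s.
#' @param anterior_mask limb vertex indices driving the ICP stage.
#' @param override optional `rigid_transform` composed after ICP.
#' @param max_iter,tol passed to [icp_align()].
#' @return list with `transform` (socket -> limb frame), `coarse`, `icp`
#'   (stage diagnostics) and `rms`.
#' @export
align_pair <- function(limb, socket, limb_landmarks, socket_landmarks,
                       anterior_mask, override = NULL,
                       max_iter = 50, tol = 1e-4) {
  Tc <- coarse_align(limb, socket, limb_landmarks, socket_landmarks)
  socket_c <- apply_transform(socket, Tc)
  icp <- icp_align(limb, socket_c, anterior_mask, max_iter = max_iter, tol = tol)
  Tt <- rt_compose(icp$transform, Tc)
  if (!is.null(override)) Tt <- rt_compose(override, Tt)
  list(transform = Tt,
       coarse = list(transform = Tc, rms = attr(Tc, "rms")),
       icp = icp[c("transform", "rms", "rms_trace", "iterations", "converged")],
       rms = icp$rms)
}
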