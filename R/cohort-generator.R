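#' Statistical structure for a synthetic design cohort
#'
#' Describes the joint distribution a synthetic cohort is drawn from: normal
#' marginals per design variable (defaults centred on the published category
#' mid values with spreads matching the published 10th-90th percentile
#' ranges), a Spearman rank-correlation target coupled through a Gaussian
#' copula (default: the published pairwise correlation pattern), a PTB/TSB
#' mixture weight with per-design mean shifts, and optional explicit
#' conditional rules of the form "P(target = high | conditioning at its 90th
#' percentile) = p", which override the copula entry for that pair.
#'
#' @param marginals named list of `c(mean, sd)` per design variable.
#' @param rank_target 8 x 8 Spearman correlation target (unit diagonal).
#' @param rules list of rules, each `list(target=, conditioning=, prob=)`.
#' @param tsb_weight,ptbsc_weight mixture weights for TSB and PTB-SC labels.
#' @param design_shift named list of mean shifts applied to TSB sockets.
#' @return object of class `cohort_structure`.
#' @export
cohort_structure <- function(marginals = NULL, rank_target = NULL,
                             rules = list(),
                             tsb_weight = 21 / 163, ptbsc_weight = 7 / 163,
                             design_shift = NULL) {
  if (is.null(marginals)) marginals <- default_marginals()
  if (is.null(rank_target)) rank_target <- default_rank_target()
  if (is.null(design_shift)) {
    design_shift <- list(LP = -1.2, MP = -0.7, DE = -2.0, VR = 2.5)
  }
  vars <- design_variables()
  stopifnot(all(vars %in% names(marginals)),
            identical(dim(rank_target), c(8L, 8L)))
  structure(list(marginals = marginals, rank_target = rank_target,
                 rules = rules, tsb_weight = tsb_weight,
                 ptbsc_weight = ptbsc_weight, design_shift = design_shift),
            class = "cohort_structure")
}

# normal marginals implied by the published low/mid/high exemplars: the mid
# value as the mean, (high - low) / (2 * 1.2816) as the s.d.
default_marginals <- function() {
  ex <- list(PT = c(4.1, 5.8, 7.4), FH = c(1.0, 2.1, 3.8),
             MP = c(1.9, 3.2, 4.7), LP = c(2.1, 3.6, 5.1),
             TC = c(1.4, 2.7, 4.4), DE = c(1.5, 5.8, 10),
             LMC = c(3.0, 5.5, 9.3), VR = c(1.5, 4.3, 9.9))
  z90 <- stats::qnorm(0.9)
  lapply(ex, function(v) c(mean = v[2], sd = (v[3] - v[1]) / (2 * z90)))
}

# published-style Spearman target, order PT, MP, LP, FH, DE, VR, TC, LMC
default_rank_target <- function() {
  v <- design_variables()
  m <- diag(8)
  dimnames(m) <- list(v, v)
  set <- function(a, b, r) { m[a, b] <<- r; m[b, a] <<- r }
  set("PT", "MP", 0.18); set("PT", "LP", 0.18); set("PT", "FH", 0.11)
  set("PT", "DE", -0.15); set("PT", "VR", -0.17); set("PT", "TC", 0.10)
  set("PT", "LMC", -0.20)
  set("MP", "LP", 0.66); set("MP", "FH", -0.17); set("MP", "DE", 0.05)
  set("MP", "VR", -0.13); set("MP", "TC", -0.40); set("MP", "LMC", 0.16)
  set("LP", "FH", -0.26); set("LP", "DE", 0.11); set("LP", "VR", -0.25)
  set("LP", "TC", -0.35); set("LP", "LMC", -0.07)
  set("FH", "DE", -0.32); set("FH", "VR", 0.38); set("FH", "TC", 0.37)
  set("FH", "LMC", 0.01)
  set("DE", "VR", -0.19); set("DE", "TC", -0.18); set("DE", "LMC", -0.09)
  set("VR", "TC", 0.21); set("VR", "LMC", 0.22)
  set("TC", "LMC", -0.14)
  m
}

# normal-score correlation r such that, for standard bivariate normal scores,
# P(Z_target > qnorm(q_cut) | Z_cond = qnorm(q_at)) equals prob
solve_rule_correlation <- function(prob, q_cut = 2 / 3, q_at = 0.9) {
  zc <- stats::qnorm(q_cut)
  za <- stats::qnorm(q_at)
  f <- function(r) 1 - stats::pnorm((zc - r * za) / sqrt(1 - r^2)) - prob
  stats::uniroot(f, c(-0.995, 0.995), tol = 1e-10)$root
}

#' Generate a synthetic design cohort
#'
#' Draws `n` rectification profiles from a Gaussian copula over the eight
#' design variables (Spearman target converted to the normal-score scale via
#' `2 sin(pi rho / 6)`; conditional rules override their pair), assigns
#' PTB/TSB/PTB-SC labels from the mixture weights, applies the TSB mean
#' shifts, floors the seven local sizes at 0 (VR may stay negative, flagged),
#' and samples demographics from published-style marginals. The generating
#' structure and seed are attached as attributes.
#'
#' @param n number of sockets.
#' @param structure a [cohort_structure()].
#' @param seed integer seed.
#' @return a design cohort tibble with attributes `structure`, `seed` and
#'   `copula_correlation`.
#' @export
generate_cohort_table <- function(n = 163, structure = cohort_structure(),
                                  seed = 1L) {
  vars <- design_variables()
  P <- 2 * sin(pi * structure$rank_target / 6)
  diag(P) <- 1
  for (rule in structure$rules) {
    r <- solve_rule_correlation(rule$prob)
    P[rule$target, rule$conditioning] <- r
    P[rule$conditioning, rule$target] <- r
  }
  ev <- eigen(P, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    if (min(ev$values) < -0.05) stop("correlation target is not positive definite")
    vals <- pmax(ev$values, 1e-8)
    P <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    P <- stats::cov2cor(P)
  }

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  Z <- MASS::mvrnorm(n, mu = rep(0, 8), Sigma = P)
  colnames(Z) <- vars
  X <- sapply(vars, function(v) {
    m <- structure$marginals[[v]]
    m[["mean"]] + m[["sd"]] * Z[, v]
  })

  u <- stats::runif(n)
  design <- ifelse(u < structure$tsb_weight, "TSB",
                   ifelse(u < structure$tsb_weight + structure$ptbsc_weight,
                          "PTB-SC", "PTB"))
  for (v in names(structure$design_shift)) {
    X[design == "TSB", v] <- X[design == "TSB", v] + structure$design_shift[[v]]
  }
  local <- setdiff(vars, "VR")
  X[, local] <- pmax(X[, local], 0)
  oversized <- X[, "VR"] < 0  # socket globally larger than the limb

  demo <- sample_demographics(n)
  out <- tibble::as_tibble(as.data.frame(X))
  out <- dplyr::bind_cols(
    tibble::tibble(socket_id = sprintf("SYN%03d", seq_len(n)), design = design),
    out, demo)
  out$vr_oversized <- oversized
  attr(out, "structure") <- structure
  attr(out, "seed") <- seed
  attr(out, "copula_correlation") <- P
  as_design_cohort(out)
}

# demographics drawn from published-style cohort marginals
sample_demographics <- function(n) {
  reasons <- c("dysvascularity", "trauma", "infection", "neuro",
               "neoplasia", "congenital")
  reason_w <- c(63, 47, 26, 10, 6, 3)
  k_w <- c(22, 61, 74, 6)
  scs_w <- c(3, 3, 21, 54, 48, 28)
  tibble::tibble(
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(51, 111)),
    age = pmin(94, pmax(19, stats::rnorm(n, 57.7, 15.4))),
    reason = sample(reasons, n, replace = TRUE, prob = reason_w),
    time_since_amputation = pmin(70, pmax(0.14, stats::rlnorm(n, log(1.2), 1.4))),
    k_level = sample(1:4, n, replace = TRUE, prob = k_w),
    scs = sample(5:10, n, replace = TRUE, prob = scs_w))
}
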