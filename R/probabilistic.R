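#' Gaussian kernel density estimate of a rectification-size sample
#'
#' Gaussian-kernel KDE with bandwidth by Scott's rule,
#' `h = sd(values) * n^(-1/5)`, evaluable at arbitrary points.
#'
#' @param values numeric sample (>= 5 values, non-degenerate).
#' @param bandwidth optional bandwidth override, in the variable's unit.
#' @return object of class `size_kde` with `$density(x)`, `$values`, `$h`.
#' @export
fit_kde <- function(values, bandwidth = NULL) {
  values <- as.numeric(values)
  if (length(values) < 5) stop("KDE needs at least 5 values")
  s <- stats::sd(values)
  if (s == 0) stop("degenerate sample: zero variance")
  h <- if (is.null(bandwidth)) s * length(values)^(-1 / 5) else bandwidth
  density <- function(x) {
    vapply(x, function(q) mean(stats::dnorm(q, mean = values, sd = h)),
           numeric(1))
  }
  structure(list(density = density, values = values, h = h,
                 support = c(min(values) - 4 * h, max(values) + 4 * h)),
            class = "size_kde")
}

#' Percentiles of a fitted KDE
#'
#' Integrates the density to a CDF on a 512-point grid over the support and
#' inverts it by monotone linear interpolation.
#'
#' @param kde a `size_kde`.
#' @param probs probabilities in (0, 1).
#' @param n_grid CDF grid size.
#' @return percentile values in the variable's unit.
#' @export
kde_percentiles <- function(kde, probs, n_grid = 512) {
  if (any(probs <= 0 | probs >= 1)) stop("probs must lie in (0, 1)")
  grid <- seq(kde$support[1], kde$support[2], length.out = n_grid)
  f <- kde$density(grid)
  dx <- diff(grid)
  cdf <- c(0, cumsum((f[-1] + f[-n_grid]) / 2 * dx))
  cdf <- cdf / cdf[n_grid]
  # make strictly monotone for interpolation
  cdf <- cummax(cdf + seq_len(n_grid) * 1e-15)
  stats::approx(cdf, grid, xout = probs, rule = 2)$y
}

#' Size categories of one design variable
#'
#' Splits the fitted KDE at its 33rd and 67th percentiles to define the
#' low/mid/high category limits, and reduces each category to an exemplar
#' single value at the KDE's 10th, 50th and 90th percentiles.
#'
#' @param values numeric sample of one design variable.
#' @param bandwidth optional KDE bandwidth override.
#' @return object of class `size_categories`: cut_low, cut_high and the
#'   three exemplars.
#' @export
fit_size_categories <- function(values, bandwidth = NULL) {
  kde <- fit_kde(values, bandwidth = bandwidth)
  q <- kde_percentiles(kde, c(0.10, 1 / 3, 0.50, 2 / 3, 0.90))
  structure(list(cut_low = q[2], cut_high = q[4],
                 exemplar_low = q[1], exemplar_mid = q[3], exemplar_high = q[5],
                 kde = kde),
            class = "size_categories")
}

#' Fit categories for every design variable in a cohort
#'
#' @param cohort a design cohort.
#' @param variables variable names (default the eight design variables).
#' @return named list of `size_categories`.
#' @export
fit_all_categories <- function(cohort, variables = design_variables()) {
  cohort <- as_design_cohort(cohort)
  stats::setNames(lapply(variables, function(v) fit_size_categories(cohort[[v]])),
                  variables)
}

#' Categorise a value as low / mid / high
#'
#' Half-open convention: `low` if value < cut_low, `mid` if
#' cut_low <= value < cut_high, `high` otherwise.
#'
#' @param value numeric vector.
#' @param cuts a `size_categories`.
#' @return factor with levels low, mid, high.
#' @export
categorize <- function(value, cuts) {
  lev <- c("low", "mid", "high")
  out <- ifelse(value < cuts$cut_low, "low",
                ifelse(value < cuts$cut_high, "mid", "high"))
  factor(out, levels = lev)
}

#' Gaussian naive Bayes model of one rectification conditioned on another
#'
#' The target variable's values are categorised (low/mid/high) with its
#' fitted cuts; class priors are the empirical class frequencies and the
#' class-conditional distribution of the conditioning variable is Gaussian
#' with the within-class mean and variance (variance floored at
#' `1e-9 * overall variance`). Classes with fewer than `min_class` members
#' fall back to the pooled variance, with a warning.
#'
#' @param cohort a design cohort.
#' @param target name of the rectification being predicted.
#' @param conditioning name of the rectification already chosen.
#' @param cuts a `size_categories` for the target (fitted from the cohort if
#'   omitted).
#' @param min_class minimum class size for a class-specific variance.
#' @return object of class `conditional_nb`.
#' @export
fit_conditional_nb <- function(cohort, target, conditioning, cuts = NULL,
                               min_class = 5) {
  cohort <- as_design_cohort(cohort)
  if (is.null(cuts)) cuts <- fit_size_categories(cohort[[target]])
  cls <- categorize(cohort[[target]], cuts)
  x <- cohort[[conditioning]]
  counts <- table(cls)
  if (any(counts == 0)) {
    stop("empty target class '", names(counts)[counts == 0][1],
         "': use coarser category cuts")
  }
  mu <- tapply(x, cls, mean)
  v <- tapply(x, cls, stats::var)
  pooled <- stats::var(x - mu[as.integer(cls)])
  small <- counts < min_class
  if (any(small)) {
    warning("class(es) ", paste(names(counts)[small], collapse = ", "),
            " have fewer than ", min_class, " sockets; using pooled variance")
    v[small] <- pooled
  }
  floor_eps <- 1e-9 * stats::var(x)
  v <- pmax(v, floor_eps)
  structure(list(target = target, conditioning = conditioning,
                 priors = as.numeric(counts) / sum(counts),
                 mu = as.numeric(mu), sigma2 = as.numeric(v),
                 classes = names(counts), cuts = cuts,
                 variance_floor = floor_eps),
            class = "conditional_nb")
}

#' Conditional category probabilities
#'
#' `P(class | x)` proportional to `prior * N(x; mu_class, sigma2_class)`,
#' normalised over low/mid/high.
#'
#' @param model a `conditional_nb`.
#' @param x conditioning value(s).
#' @return matrix, one row per x, columns low/mid/high summing to 1.
#' @export
conditional_probabilities <- function(model, x) {
  x <- as.numeric(x)
  lik <- vapply(seq_along(model$classes), function(c_) {
    model$priors[c_] *
      stats::dnorm(x, model$mu[c_], sqrt(model$sigma2[c_]))
  }, numeric(length(x)))
  lik <- matrix(lik, nrow = length(x))
  out <- lik / rowSums(lik)
  colnames(out) <- model$classes
  out
}

#' Most-probable template design given one chosen rectification
#'
#' Sets the chosen variable to its exemplar value at the chosen category,
#' then for every other design variable fits a naive Bayes model with that
#' variable as target and the chosen one as conditioning, evaluates the
#' category probabilities at the exemplar, and selects the argmax category
#' (ties break toward the lower category — the conservative rectification).
#' Each selected category is reported with its exemplar size.
#'
#' @param cohort a design cohort.
#' @param cuts named list of `size_categories` for all eight variables
#'   (fitted from the cohort if omitted).
#' @param chosen_variable,chosen_category the initial clinical decision.
#' @return tibble: variable, category, exemplar (size in the variable's
#'   unit), and the three probabilities.
#' @export
generate_template <- function(cohort, cuts = NULL, chosen_variable = "VR",
                              chosen_category = c("high", "mid", "low")) {
  chosen_category <- match.arg(chosen_category)
  cohort <- as_design_cohort(cohort)
  if (is.null(cuts)) cuts <- fit_all_categories(cohort)
  if (!all(design_variables() %in% names(cuts))) {
    stop("cuts must be fitted for all eight design variables")
  }
  exemplar <- function(ct, cat) switch(cat, low = ct$exemplar_low,
                                       mid = ct$exemplar_mid,
                                       high = ct$exemplar_high)
  x_star <- exemplar(cuts[[chosen_variable]], chosen_category)
  lev <- c("low", "mid", "high")
  rows <- lapply(design_variables(), function(v) {
    if (v == chosen_variable) {
      pr <- stats::setNames(as.numeric(lev == chosen_category), lev)
      cat <- chosen_category
    } else {
      nb <- fit_conditional_nb(cohort, target = v,
                               conditioning = chosen_variable,
                               cuts = cuts[[v]])
      pr <- conditional_probabilities(nb, x_star)[1, ]
      # argmax with ties toward the lower category
      cat <- lev[which(pr == max(pr))[1]]
    }
    tibble::tibble(variable = v, category = cat,
                   exemplar = exemplar(cuts[[v]], cat),
                   p_low = pr[["low"]], p_mid = pr[["mid"]],
                   p_high = pr[["high"]])
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "chosen") <- list(variable = chosen_variable,
                              category = chosen_category, value = x_star)
  out
}

#' Render a template as a deviation map on a limb mesh
#'
#' Builds a smooth per-vertex signed field on any supplied limb: within each
#' rectification region a carve/build bump with peak equal to the template's
#' exemplar size and cosine falloff to the mask boundary, plus a global
#' volume-reduction term — a uniform carve of
#' `(1 - sqrt(1 - VR/100)) * local radius` over the sectioned span between
#' the mid patellar tendon and distal tibia levels (cosine-tapered just
#' outside it). Positive = carve, negative = build.
#'
#' @param template tibble from [generate_template()].
#' @param limb a `surface_mesh`.
#' @param masks a `region_mask_set` on the limb.
#' @param landmarks limb `landmark_set`.
#' @param plateau fraction of each region's extent holding the full peak.
#' @return a `deviation_map` over the limb vertices.
#' @export
render_template_map <- function(template, limb, masks, landmarks,
                                plateau = 0.35) {
  V <- limb$vertices
  nv <- nrow(V)
  pa <- principal_axis(limb)
  lev <- as.numeric(sweep(V, 2, pa$centroid) %*% pa$axis)
  radial <- sqrt(rowSums((sweep(V, 2, pa$centroid) -
                            outer(lev, pa$axis))^2))
  dirs <- region_directions()
  sizes <- stats::setNames(template$exemplar, template$variable)
  bumps <- numeric(nv)
  f_tot <- numeric(nv)  # bump coverage, used to blend the VR term out of
                        # regions so plateau deviations equal the exemplars

  for (r in names(dirs)) {
    if (!r %in% names(sizes)) stop("template missing region: ", r)
    ix <- masks[[r]]
    if (!length(ix)) stop("empty mask for region: ", r)
    size <- sizes[[r]]
    if (size == 0) next
    if (r == "DE") {
      # apex-centred: distance from the distal-most mask vertex
      apex <- V[ix[which.max(lev[ix])], ]
      dd <- sqrt(rowSums(sweep(V, 2, apex)^2))
      f <- bump_falloff(dd / (max(dd[ix]) + 1e-9), plateau)
    } else {
      # one bump per contiguous angular sector of the mask (the supracondylar
      # region has a medial and a lateral patch), each sized from its own
      # vertex cloud (axial level and angle about the axis)
      ang <- atan2(V[, 2] - pa$centroid[2], V[, 1] - pa$centroid[1])
      f <- numeric(nv)
      for (sec in split_angular_sectors(ang[ix])) {
        sx <- ix[sec]
        ctr_ang <- atan2(mean(sin(ang[sx])), mean(cos(ang[sx])))
        dang <- (ang - ctr_ang + pi) %% (2 * pi) - pi
        hw_ang <- max(abs((ang[sx] - ctr_ang + pi) %% (2 * pi) - pi)) + 1e-9
        ctr_lev <- mean(range(lev[sx]))
        hw_lev <- diff(range(lev[sx])) / 2 + 1e-9
        rho <- sqrt((dang / hw_ang)^2 + ((lev - ctr_lev) / hw_lev)^2)
        f <- pmax(f, bump_falloff(rho, plateau))
      }
    }
    keep <- rep(FALSE, nv)
    keep[ix] <- TRUE
    f[!keep] <- 0   # confined to the mask
    sgn <- if (dirs[[r]] == "carve") 1 else -1
    bumps <- bumps + sgn * size * f
    f_tot <- pmax(f_tot, f)
  }

  vr <- sizes[["VR"]]
  l0 <- sum((landmarks["mid_patellar_tendon", ] - pa$centroid) * pa$axis)
  l1 <- sum((landmarks["distal_tibia", ] - pa$centroid) * pa$axis)
  span <- sort(c(l0, l1))
  taper <- 0.06 * (span[2] - span[1])
  w <- rep(0, nv)
  inside <- lev >= span[1] & lev <= span[2]
  w[inside] <- 1
  below <- lev < span[1] & lev > span[1] - taper
  w[below] <- 0.5 * (1 + cos(pi * (span[1] - lev[below]) / taper))
  above <- lev > span[2] & lev < span[2] + taper
  w[above] <- 0.5 * (1 + cos(pi * (lev[above] - span[2]) / taper))
  map <- bumps + (1 - f_tot) * w * (1 - sqrt(1 - vr / 100)) * radial
  structure(map, class = "deviation_map")
}

# indices of contiguous angular clusters (gaps wider than gap_deg split them)
split_angular_sectors <- function(ang, gap_deg = 30) {
  ord <- order(ang)
  a <- ang[ord]
  gaps <- diff(a)
  wrap <- (a[1] + 2 * pi) - a[length(a)]
  cutpts <- which(gaps > gap_deg * pi / 180)
  if (!length(cutpts) || length(a) < 2) return(list(seq_along(ang)))
  # rotate so the sequence starts just after the largest gap (incl. the wrap)
  allgaps <- c(gaps, wrap)
  start <- which.max(allgaps) %% length(a) + 1
  idx <- c(seq(start, length(a)), seq_len(start - 1))
  a_rot <- ang[ord][idx]
  d <- diff(a_rot %% (2 * pi))
  d[d < 0] <- d[d < 0] + 2 * pi
  breaks <- c(0, which(d > gap_deg * pi / 180), length(a))
  out <- list()
  for (k in seq_len(length(breaks) - 1)) {
    out[[k]] <- ord[idx][(breaks[k] + 1):breaks[k + 1]]
  }
  out
}
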