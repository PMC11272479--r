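#' Validate a design cohort table
#'
#' A design cohort is a tibble with one row per socket: the eight design
#' variables (PT, MP, LP, FH, DE, VR, TC, LMC) plus demographics — `sex`
#' (F/M), `age` (years), `reason` (dysvascularity, trauma, infection, neuro,
#' neoplasia, congenital), `time_since_amputation` (years), `design`
#' (PTB/TSB/PTB-SC), `k_level` (1-4) and optional `scs` (1-10). Missing
#' demographic columns are tolerated; present ones are validated.
#'
#' @param cohort a data frame.
#' @return the cohort as a tibble, invisibly validated.
#' @export
as_design_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  if (!nrow(cohort)) stop("empty cohort")
  if ("design" %in% names(cohort)) {
    bad <- setdiff(stats::na.omit(unique(cohort$design)), c("PTB", "TSB", "PTB-SC"))
    if (length(bad)) stop("unknown design label(s): ", paste(bad, collapse = ", "))
  }
  if ("k_level" %in% names(cohort)) {
    k <- stats::na.omit(cohort$k_level)
    if (length(k) && (any(k < 1) || any(k > 4))) stop("k_level must be in 1..4")
  }
  if ("scs" %in% names(cohort)) {
    s <- stats::na.omit(cohort$scs)
    if (length(s) && (any(s < 1) || any(s > 10))) stop("scs must be in [1, 10]")
  }
  cohort
}

#' Stratified cohort summary
#'
#' Per-stratum demographics in the style of a cohort characteristics table:
#' socket count and share of the total, sex and design counts, mean (s.d.)
#' age, median (range) time since amputation, K-level counts with their
#' count-weighted mean, and mean SCS. Means are reported to one decimal and
#' percentage shares to the nearest integer (the usual printed rounding);
#' unrounded values are kept in `*_exact` columns. Single-member strata
#' report the s.d. as `NA` and collapse the range to a point.
#'
#' @param cohort a design cohort (see [as_design_cohort()]).
#' @param strata grouping column name, or `"overall"` for a single stratum.
#' @return a tibble, one row per stratum.
#' @export
cohort_summary <- function(cohort, strata = "overall") {
  cohort <- as_design_cohort(cohort)
  if (strata != "overall" && !strata %in% names(cohort)) {
    stop("unknown stratum key: ", strata)
  }
  g <- if (strata == "overall") rep("overall", nrow(cohort)) else cohort[[strata]]
  total <- nrow(cohort)
  col_or_na <- function(nm) if (nm %in% names(cohort)) cohort[[nm]] else
    rep(NA_real_, total)
  res <- lapply(split(seq_len(total), g), function(ix) {
    n <- length(ix)
    age <- col_or_na("age")[ix]
    tsa <- col_or_na("time_since_amputation")[ix]
    k <- col_or_na("k_level")[ix]
    scs <- col_or_na("scs")[ix]
    sex <- if ("sex" %in% names(cohort)) cohort$sex[ix] else rep(NA, n)
    des <- if ("design" %in% names(cohort)) cohort$design[ix] else rep(NA, n)
    k_mean <- mean(k, na.rm = TRUE)
    tibble::tibble(
      n = n,
      share_pct = round(100 * n / total),
      share_pct_exact = 100 * n / total,
      n_F = sum(sex == "F", na.rm = TRUE),
      n_M = sum(sex == "M", na.rm = TRUE),
      n_PTB = sum(des == "PTB", na.rm = TRUE),
      n_TSB = sum(des == "TSB", na.rm = TRUE),
      n_PTBSC = sum(des == "PTB-SC", na.rm = TRUE),
      tsb_share_pct = round(100 * sum(des == "TSB", na.rm = TRUE) / n),
      age_mean = round(mean(age, na.rm = TRUE), 1),
      age_sd = if (sum(!is.na(age)) > 1) round(stats::sd(age, na.rm = TRUE), 1)
               else NA_real_,
      tsa_median = round(stats::median(tsa, na.rm = TRUE), 1),
      tsa_min = suppressWarnings(min(tsa, na.rm = TRUE)),
      tsa_max = suppressWarnings(max(tsa, na.rm = TRUE)),
      k1 = sum(k == 1, na.rm = TRUE), k2 = sum(k == 2, na.rm = TRUE),
      k3 = sum(k == 3, na.rm = TRUE), k4 = sum(k == 4, na.rm = TRUE),
      k_mean = round(k_mean, 1),
      k_mean_exact = k_mean,
      scs5 = sum(scs == 5, na.rm = TRUE), scs6 = sum(scs == 6, na.rm = TRUE),
      scs7 = sum(scs == 7, na.rm = TRUE), scs8 = sum(scs == 8, na.rm = TRUE),
      scs9 = sum(scs == 9, na.rm = TRUE), scs10 = sum(scs == 10, na.rm = TRUE),
      scs_mean = round(mean(scs, na.rm = TRUE), 1))
  })
  out <- dplyr::bind_rows(res, .id = "stratum")
  out$tsa_min[!is.finite(out$tsa_min)] <- NA_real_
  out$tsa_max[!is.finite(out$tsa_max)] <- NA_real_
  out
}

#' Mann-Whitney U test of two rectification-size samples
#'
#' U from rank sums with midrank ties. The two-sided p-value is exact (full
#' enumeration of the rank distribution) when the combined sample size is at
#' most 16 and there are no ties, and otherwise uses the normal approximation
#' with tie-corrected variance and continuity correction.
#'
#' @param group_a,group_b numeric vectors of sizes.
#' @param exact_max combined size at or below which the exact branch is used.
#' @return list with `U` (statistic for `group_a`), `p` (two-sided), and
#'   `method`.
#' @export
mann_whitney_u <- function(group_a, group_b, exact_max = 16) {
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  use_exact <- (length(group_a) + length(group_b)) <= exact_max && !ties
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            exact = use_exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (use_exact) "exact" else "normal approximation")
}

#' Bonferroni adjustment with explicit family size
#'
#' `p_adj = min(1, m * p)`. The family size defaults to 8, one test per
#' design variable in the PTB/TSB comparison.
#'
#' @param pvalues numeric vector of raw p-values.
#' @param m family size (must be at least `length(pvalues)`).
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(pvalues, m = 8) {
  if (m < length(pvalues)) stop("m must be at least the number of p-values")
  pmin(1, m * pvalues)
}

#' Spearman correlation matrix of the eight design variables
#'
#' Pairwise Spearman rho (Pearson correlation of midranks) with two-sided
#' p-values from the t approximation on n - 2 degrees of freedom. Constant
#' variables yield `NA` (undefined), not 0. Positive rho arises where both
#' rectifications are builds or both carves; the carve/build direction of
#' each variable is attached as attribute `direction`.
#'
#' @param cohort a design cohort containing the eight variable columns.
#' @param variables variable names (default [design_variables()]).
#' @return list with `rho` and `p` (symmetric matrices, unit/NA diagonal),
#'   and `n`.
#' @export
spearman_matrix <- function(cohort, variables = design_variables()) {
  cohort <- as_design_cohort(cohort)
  miss <- setdiff(variables, names(cohort))
  if (length(miss)) stop("cohort lacks variable(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(cohort[variables])
  n <- nrow(X)
  if (n < 4) stop("need at least 4 profiles for the correlation matrix")
  k <- length(variables)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) { rho[i, j] <- 1; next }
      x <- X[, i]; y <- X[, j]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next  # undefined: stays NA
      r <- stats::cor(x, y, method = "spearman")
      rho[i, j] <- r
      if (abs(r) < 1) {
        tt <- r * sqrt((n - 2) / (1 - r^2))
        p[i, j] <- 2 * stats::pt(-abs(tt), df = n - 2)
      } else {
        p[i, j] <- 0
      }
    }
  }
  diag(p) <- NA_real_
  dir <- c(region_directions(), VR = "carve")[variables]
  structure(list(rho = rho, p = p, n = n), direction = dir)
}

#' Merge PTB-SC sockets into the PTB group
#'
#' The two-group (PTB vs TSB) comparisons treat supracondylar PTB variants
#' as PTB by default.
#'
#' @param design character vector of design labels.
#' @param merge_sc merge PTB-SC into PTB (default TRUE).
#' @return character vector with levels PTB/TSB.
#' @export
two_group_design <- function(design, merge_sc = TRUE) {
  out <- design
  if (merge_sc) out[out == "PTB-SC"] <- "PTB"
  out
}

#' PTB vs TSB comparison for each design variable
#'
#' Mann-Whitney U per variable with Bonferroni adjustment over the family of
#' eight tests.
#'
#' @param cohort a design cohort with `design` and the eight variables.
#' @param merge_sc treat PTB-SC as PTB (default TRUE).
#' @param m Bonferroni family size.
#' @return tibble: variable, direction, medians, U, p, p_adjusted.
#' @export
compare_designs <- function(cohort, merge_sc = TRUE, m = 8) {
  cohort <- as_design_cohort(cohort)
  grp <- two_group_design(cohort$design, merge_sc)
  vars <- design_variables()
  rows <- lapply(vars, function(v) {
    a <- cohort[[v]][grp == "PTB"]
    b <- cohort[[v]][grp == "TSB"]
    mw <- mann_whitney_u(a, b)
    tibble::tibble(variable = v,
                   median_PTB = stats::median(a), median_TSB = stats::median(b),
                   U = mw$U, p = mw$p, method = mw$method)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- bonferroni_adjust(out$p, m = m)
  out
}

#' Expand a printed counts table into a per-socket cohort
#'
#' Reconstructs a per-socket demographic cohort from a stratified counts
#' table (one row per stratum with sex, design and K-level counts), the form
#' in which published cohort tables print their data. Within a stratum the
#' count columns are treated as independent marginals.
#'
#' @param counts data frame with columns `reason`, `n`, `F`, `M`, `PTB`,
#'   `TSB`, `PTBSC`, `k1`..`k4`.
#' @return a design cohort tibble with columns `sex`, `design`, `reason`,
#'   `k_level`.
#' @export
cohort_from_counts <- function(counts) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    stopifnot(r$F + r$M == r$n, r$PTB + r$TSB + r$PTBSC == r$n,
              r$k1 + r$k2 + r$k3 + r$k4 == r$n)
    tibble::tibble(
      reason = rep(r$reason, r$n),
      sex = rep(c("F", "M"), c(r$F, r$M)),
      design = rep(c("PTB", "TSB", "PTB-SC"), c(r$PTB, r$TSB, r$PTBSC)),
      k_level = rep(1:4, c(r$k1, r$k2, r$k3, r$k4)))
  })
  as_design_cohort(dplyr::bind_rows(rows))
}

#' Read the bundled cohort counts table
#'
#' The per-stratum demographic counts of the training cohort (reason for
#' amputation by sex, design and K-level), as printed in published summary
#' form. The `unrecorded` row carries the sockets whose reason stratum is
#' not listed, so the expanded cohort reproduces the overall totals.
#'
#' @return data frame of counts suitable for [cohort_from_counts()].
#' @export
reference_cohort_counts <- function() {
  path <- system.file("extdata", "cohort_counts.csv", package = "socketmap")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a deposited rectification cohort CSV
#'
#' Loads a processed cohort table (socket_id, design and the eight design
#' variables, plus any demographics) from a local copy of the study's
#' deposited dataset. The deposited data must be downloaded separately by
#' the user; this package ships no patient-derived data.
#'
#' @param path path to the downloaded CSV.
#' @return a design cohort tibble.
#' @export
read_deposited_cohort <- function(path) {
  if (!file.exists(path)) {
    stop("deposited cohort file not found: ", path,
         "\nDownload the study's processed dataset and pass its local path.")
  }
  as_design_cohort(utils::read.csv(path, stringsAsFactors = FALSE))
}
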