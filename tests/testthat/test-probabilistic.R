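test_that("the KDE is a normalised mean of Gaussians with Scott bandwidth", {
  set.seed(61)
  x <- c(rnorm(80, 3, 0.8), rnorm(80, 9, 0.8))
  k <- fit_kde(x)
  expect_equal(k$h, sd(x) * length(x)^(-1 / 5), tolerance = 1e-12)

  grid <- seq(k$support[1], k$support[2], length.out = 4001)
  f <- k$density(grid)
  integral <- sum((f[-1] + f[-length(f)]) / 2 * diff(grid))
  expect_equal(integral, 1, tolerance = 1e-3)

  # direct kernel-sum oracle at a query point
  q <- 4.2
  expect_equal(k$density(q), mean(dnorm(q, x, k$h)), tolerance = 1e-14)

  # two well-separated clusters give a bimodal density
  mid <- 2:(length(f) - 1)
  n_max <- sum(f[mid] > f[mid - 1] & f[mid] > f[mid + 1])
  expect_equal(n_max, 2)

  expect_error(fit_kde(rep(2, 10)), "zero variance")
  expect_error(fit_kde(c(1, 2)), "at least 5")
})

test_that("KDE percentiles invert the CDF monotonically and match closed forms", {
  set.seed(62)
  x <- rnorm(4000)
  k <- fit_kde(x)
  q <- kde_percentiles(k, c(1 / 3, 2 / 3))
  expect_equal(q, qnorm(c(1 / 3, 2 / 3)), tolerance = 0.05)

  # symmetric sample: median at the symmetry point
  xs <- c(5 - abs(rnorm(500)), 5 + abs(rnorm(500)))
  ks <- fit_kde(xs)
  expect_equal(kde_percentiles(ks, 0.5), 5, tolerance = 0.05)

  probs <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(kde_percentiles(k, probs)) >= 0))
  expect_error(kde_percentiles(k, c(0, 0.5)), "in \\(0, 1\\)")
})

test_that("categorisation uses half-open cuts and matches an interval oracle", {
  set.seed(63)
  cuts <- fit_size_categories(rnorm(200, 5, 1.5))
  expect_lte(cuts$cut_low, cuts$cut_high)
  expect_lte(cuts$exemplar_low, cuts$exemplar_mid)
  expect_lte(cuts$exemplar_mid, cuts$exemplar_high)

  expect_equal(as.character(categorize(cuts$cut_low, cuts)), "mid")
  expect_equal(as.character(categorize(-100, cuts)), "low")

  v <- runif(1000, -2, 12)
  oracle <- cut(v, c(-Inf, cuts$cut_low, cuts$cut_high, Inf),
                labels = c("low", "mid", "high"), right = FALSE)
  expect_equal(as.character(categorize(v, cuts)), as.character(oracle))
})

test_that("KDE terciles split a large sample into approximate thirds", {
  set.seed(64)
  x <- rlnorm(163, log(4), 0.5)   # right-skewed like rectification sizes
  cuts <- fit_size_categories(x)
  shares <- table(categorize(x, cuts)) / length(x)
  expect_true(all(abs(shares - 1 / 3) <= 0.07))
})

test_that("the Gaussian NB fit matches per-class moments and an independent classifier", {
  set.seed(65)
  n <- 150
  cls_true <- rep(c(1, 2, 3), each = n / 3)
  target <- c(rnorm(n / 3, 2, 0.4), rnorm(n / 3, 5, 0.4), rnorm(n / 3, 8, 0.4))
  cond <- rnorm(n, cls_true * 2, 0.7)
  coh <- tibble::tibble(DE = target, VR = cond)
  cuts <- fit_size_categories(coh$DE)
  nb <- fit_conditional_nb(coh, "DE", "VR", cuts)

  # balanced, well-separated clusters: priors exactly one third
  expect_equal(nb$priors, rep(1 / 3, 3), tolerance = 1e-12)

  # within-class moments match a direct group-by computation
  cls <- categorize(coh$DE, cuts)
  for (i in 1:3) {
    expect_equal(nb$mu[i], mean(cond[as.integer(cls) == i]), tolerance = 1e-12)
    expect_equal(nb$sigma2[i], var(cond[as.integer(cls) == i]),
                 tolerance = 1e-12)
  }

  # posteriors agree with e1071's Gaussian naive Bayes on the same data
  ref <- e1071::naiveBayes(data.frame(VR = cond), cls)
  at <- c(1.7, 4.0, 6.3)
  expect_equal(unname(conditional_probabilities(nb, at)),
               unname(predict(ref, data.frame(VR = at), type = "raw")),
               tolerance = 1e-9)

  # probabilities are a valid distribution
  pr <- conditional_probabilities(nb, seq(0, 8, by = 0.5))
  expect_true(all(abs(rowSums(pr) - 1) < 1e-12))
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("NB posteriors equal the closed-form Bayes rule on constructed Gaussians", {
  model <- structure(list(target = "DE", conditioning = "VR",
                          priors = c(0.5, 0.2, 0.3),
                          mu = c(1, 4, 7), sigma2 = c(0.5, 1, 2),
                          classes = c("low", "mid", "high")),
                     class = "conditional_nb")
  x <- c(0.3, 3.3, 9)
  lik <- sapply(1:3, function(c_) model$priors[c_] *
                  dnorm(x, model$mu[c_], sqrt(model$sigma2[c_])))
  expect_equal(unname(conditional_probabilities(model, x)),
               unname(lik / rowSums(lik)), tolerance = 1e-12)

  # identical class conditionals and equal priors: exactly one third each
  flat <- structure(list(target = "a", conditioning = "b",
                         priors = rep(1 / 3, 3), mu = rep(2, 3),
                         sigma2 = rep(1, 3),
                         classes = c("low", "mid", "high")),
                    class = "conditional_nb")
  expect_equal(unname(conditional_probabilities(flat, 1.1)[1, ]),
               rep(1 / 3, 3), tolerance = 1e-14)
})

test_that("NB conditioning on an independent variable yields flat class means", {
  set.seed(66)
  n <- 600
  coh <- tibble::tibble(DE = rnorm(n, 5, 2), VR = rnorm(n, 4, 1.5))
  nb <- fit_conditional_nb(coh, "DE", "VR")
  se <- sqrt(nb$sigma2 / (n / 3))
  expect_true(all(abs(nb$mu - mean(coh$VR)) < 2.5 * max(se)))

  # an empty target class is a hard error
  cuts <- fit_size_categories(coh$DE)
  cuts$cut_low <- -50; cuts$cut_high <- -40
  expect_error(fit_conditional_nb(coh, "DE", "VR", cuts), "empty target class")
})

test_that("templates select the most probable category with lower-category ties", {
  set.seed(67)
  n <- 163
  # high VR sockets built with low paratibial carves (and vice versa)
  vr <- rnorm(n, 4.3, 3)
  mp <- 6 - 0.8 * vr + rnorm(n, 0, 0.4)
  lp <- 6.5 - 0.8 * vr + rnorm(n, 0, 0.4)
  other <- function() rnorm(n, 5, 1)
  coh <- tibble::tibble(PT = other(), MP = pmax(mp, 0), LP = pmax(lp, 0),
                        FH = other(), DE = other(), VR = vr,
                        TC = other(), LMC = other())
  tpl <- generate_template(coh, chosen_variable = "VR",
                           chosen_category = "high")
  expect_equal(tpl$category[tpl$variable == "MP"], "low")
  expect_equal(tpl$category[tpl$variable == "LP"], "low")
  expect_equal(tpl$category[tpl$variable == "VR"], "high")
  expect_true(all(abs(rowSums(as.matrix(tpl[, c("p_low", "p_mid", "p_high")]))
                      - 1) < 1e-9))

  # no association and symmetric class likelihoods: exact tie, lower wins
  n3 <- 90
  target <- rep(c(1, 5, 9), each = n3 / 3) + rep(runif(n3 / 3, -0.2, 0.2), 3)
  cond_pattern <- rnorm(n3 / 3, 4, 1)
  coh2 <- tibble::tibble(PT = target, MP = rep(cond_pattern, 3),
                         LP = rnorm(n3, 5, 1), FH = rnorm(n3, 5, 1),
                         DE = rnorm(n3, 5, 1), VR = rep(cond_pattern, 3),
                         TC = rnorm(n3, 5, 1), LMC = rnorm(n3, 5, 1))
  tpl2 <- generate_template(coh2, chosen_variable = "VR",
                            chosen_category = "mid")
  row_pt <- tpl2[tpl2$variable == "PT", ]
  expect_equal(c(row_pt$p_low, row_pt$p_mid, row_pt$p_high), rep(1 / 3, 3),
               tolerance = 1e-9)
  expect_equal(row_pt$category, "low")
})

test_that("rendered template maps round-trip through the extractor", {
  limb <- test_limb()
  prof <- test_profile()
  tpl <- tibble::tibble(
    variable = design_variables(),
    category = "mid",
    exemplar = unname(unlist(prof[design_variables()])))

  map <- render_template_map(tpl, limb$mesh, limb$masks, limb$landmarks)
  sock <- deviation_to_socket(limb$mesh, map)
  got <- extract_profile(limb$mesh, sock, limb$landmarks, limb$masks)
  truth <- profile_sizes(prof)
  est <- profile_sizes(got)
  expect_true(all(abs(est - truth) / truth < 0.10))
  expect_lt(abs(got$VR - prof$VR) / prof$VR, 0.10)

  # all-zero template: zero map
  tpl0 <- tpl; tpl0$exemplar <- 0
  map0 <- render_template_map(tpl0, limb$mesh, limb$masks, limb$landmarks)
  expect_lt(max(abs(unclass(map0))), 1e-12)

  # VR-only template: positive on the sectioned barrel, zero distal build
  tplv <- tpl; tplv$exemplar <- ifelse(tplv$variable == "VR", 6, 0)
  mapv <- unclass(render_template_map(tplv, limb$mesh, limb$masks,
                                      limb$landmarks))
  barrel <- limb$param$z > 40 & limb$param$z < 135
  expect_true(all(mapv[barrel] > 0))
  expect_true(all(mapv[limb$masks$DE] >= 0))
})
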