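test_that("the fitted normalizer standardizes its own fit rows exactly", {
  set.seed(201)
  tab <- as_parameter_table(tibble::tibble(
    animal_id = paste0("m", 1:40), group = "g",
    normal = rnorm(40), skewed = rlnorm(40), shifted = rnorm(40, -50, 5)
  ))
  model <- fit_normalizer(tab)
  z <- apply_normalizer(model, tab)
  for (col in colnames(z)) {
    expect_lt(abs(mean(z[, col])), 1e-10)
    expect_equal(sd(z[, col]), 1)
  }
  # transform is strictly monotone per parameter
  ord <- order(tab$skewed)
  expect_true(all(diff(z[ord, "skewed"]) > 0))
  # constant column is a hard error naming the parameter
  bad <- as_parameter_table(tibble::tibble(animal_id = paste0("m", 1:5),
                                           group = "g", flat = 1, ok = rnorm(5)))
  expect_error(fit_normalizer(bad), "flat.*constant|constant.*flat")
})

test_that("lambda selection matches the profile-likelihood oracle", {
  skip_if_not_installed("MASS")
  set.seed(211)
  grid <- seq(-2, 2, by = 0.01)
  for (y in list(rlnorm(60), rnorm(60, 10), rgamma(60, 2, 1) + 0.5)) {
    got <- boxcox_lambda(y, grid)
    bc <- MASS::boxcox(y ~ 1, lambda = grid, plotit = FALSE)
    expect_equal(got, bc$x[which.max(bc$y)], tolerance = 0.011)
  }
  # near-normal input keeps lambda near 1
  near_normal <- rnorm(200, mean = 20, sd = 1)
  lam <- boxcox_lambda(near_normal + (1 - min(near_normal)))
  expect_gte(lam, 0.5)
  expect_lte(lam, 1.6)
  # lognormal input is pulled toward the log transform
  lam_log <- boxcox_lambda(rlnorm(500))
  expect_lt(abs(lam_log), 0.3)
})

test_that("PCA reproduces the closed-form eigenvalues of a correlated pair", {
  set.seed(221)
  n <- 200000   # essentially population-level
  f <- rnorm(n)
  rho <- 0.8
  x <- cbind(a = sqrt(rho) * f + sqrt(1 - rho) * rnorm(n),
             b = sqrt(rho) * f + sqrt(1 - rho) * rnorm(n))
  x <- scale(x)
  run <- run_pca(x)
  expect_equal(run$component_sds, c(sqrt(1.8), sqrt(0.2)), tolerance = 0.01)
  # trace conservation and orthonormal loadings
  expect_equal(sum(run$component_sds^2), 2, tolerance = 1e-6)
  expect_equal(t(run$loadings) %*% run$loadings, diag(2),
               tolerance = 1e-8, ignore_attr = TRUE)
  # deterministic sign convention: peak loading entry is positive
  for (j in 1:2) expect_gt(run$loadings[which.max(abs(run$loadings[, j])), j], 0)
})

test_that("component selection is strict at the threshold", {
  run <- structure(list(component_sds = c(1.9, 1.4, 1.0, 0.7)), class = "pca_run")
  expect_equal(select_components(run, 1), c(1L, 2L))     # SD exactly 1 excluded
  expect_equal(select_components(run, 1.39), c(1L, 2L))
  expect_error(select_components(run, 2), "no component")
})

test_that("a single full-data resample reproduces the direct PCA loading order", {
  set.seed(241)
  # three-parameter block with high mutual correlation: only PC1 is selected
  n <- 50
  f <- rnorm(n)
  tab <- as_parameter_table(tibble::tibble(
    animal_id = paste0("m", 1:n), group = "g",
    a = sqrt(0.7) * f + sqrt(0.3) * rnorm(n),
    b = sqrt(0.7) * f + sqrt(0.3) * rnorm(n),
    c = sqrt(0.7) * f + sqrt(0.3) * rnorm(n)
  ))
  cfg <- study_config(n_resamples = 1, train_fraction = 1)
  rk <- resampled_parameter_ranking(tab, cfg, seed = 241)
  direct <- fit_reference_pca(tab, cfg)
  expect_equal(direct$selected, 1L)
  direct_order <- names(sort(-abs(direct$loadings[, 1])))
  expect_equal(rk$ranking$parameter, direct_order)
})

test_that("rankings are invariant to parameter column order", {
  set.seed(251)
  gen <- generate_dataset(severity_spec(), seed = 251)
  tab <- gen$table
  cfg <- study_config(n_resamples = 10)
  rk1 <- resampled_parameter_ranking(tab, cfg, seed = 7)
  perm <- c(meta_columns(), sample(parameter_names(tab)))
  rk2 <- resampled_parameter_ranking(as_parameter_table(tab[, perm]), cfg, seed = 7)
  expect_equal(rk1$ranking, rk2$ranking)
})

test_that("a dominant planted factor attains mean rank 1 across resamples", {
  set.seed(261)
  n <- 80
  f <- rnorm(n)
  # "hub" carries the factor almost alone; satellites echo it weakly, so
  # the hub's loading share on the single selected component dominates
  tab <- as_parameter_table(tibble::tibble(
    animal_id = paste0("m", 1:n), group = rep(c("g1", "g2"), n / 2),
    hub = f + 0.1 * rnorm(n),
    s1 = 0.75 * f + 0.66 * rnorm(n),
    s2 = 0.75 * f + 0.66 * rnorm(n),
    s3 = 0.75 * f + 0.66 * rnorm(n)
  ))
  cfg <- study_config(n_resamples = 100)
  rk <- resampled_parameter_ranking(tab, cfg, seed = 261)
  hub_row <- rk$ranking[rk$ranking$parameter == "hub", ]
  expect_equal(hub_row$mean_rank, 1)
  expect_gte(hub_row$top1_count, 95)
})

test_that("composite scores follow the selected components and their orientation", {
  set.seed(271)
  gen <- generate_dataset(severity_spec(), seed = 271)
  cfg <- study_config(group_burden_map = list(ctrl = 0, mid = "exclude", sev = 1))
  ref <- fit_reference_pca(gen$table, cfg)
  cs <- compute_composite_scores(gen$table, ref, cfg)
  m <- length(attr(cs, "selected"))
  expect_true(all(cs$composite > 0 & cs$composite <= m))

  # sign-flipping a component's loadings leaves the composite unchanged
  ref_flip <- ref
  j <- ref$selected[1]
  ref_flip$loadings[, j] <- -ref_flip$loadings[, j]
  ref_flip$scores[, j] <- -ref_flip$scores[, j]
  cs_flip <- compute_composite_scores(gen$table, ref_flip, cfg)
  expect_equal(cs$composite, cs_flip$composite)

  # burdened group scores higher on average than control
  means <- tapply(cs$composite, cs$group, mean)
  expect_gt(means[["sev"]], means[["ctrl"]])
})

test_that("a single selected component gives a composite that is an ECDF of it", {
  set.seed(281)
  n <- 40
  f <- rnorm(n)
  tab <- as_parameter_table(tibble::tibble(
    animal_id = paste0("m", 1:n), group = rep(c("lo", "hi"), each = n / 2),
    a = sqrt(0.7) * f + sqrt(0.3) * rnorm(n),
    b = sqrt(0.7) * f + sqrt(0.3) * rnorm(n),
    c = sqrt(0.7) * f + sqrt(0.3) * rnorm(n)
  ))
  cfg <- study_config(group_burden_map = list(lo = 0, hi = 1))
  ref <- fit_reference_pca(tab, cfg)
  expect_equal(ref$selected, 1L)
  cs <- compute_composite_scores(tab, ref, cfg)
  sign1 <- attr(cs, "pc_signs")[1]
  expect_equal(order(cs$composite), order(sign1 * ref$scores[, 1]))
})

test_that("an animal at the training median of both components scores 1.0", {
  # constructed 9-animal training set: the mid-rank ECDF of the median
  # element is (4 + 0.5) / 9 = 0.5 on each component, summing to 1
  train <- c(-4, -3, -2, -1, 0, 1, 2, 3, 4)
  expect_equal(sevcms:::mid_ecdf(train, 0), 0.5)
  expect_equal(sevcms:::mid_ecdf(train, 0) + sevcms:::mid_ecdf(train, 0), 1)
  # and above/below the whole set maps to 1 / 0
  expect_equal(sevcms:::mid_ecdf(train, 99), 1)
  expect_equal(sevcms:::mid_ecdf(train, -99), 0)
})

test_that("no parameter is systematically favored on structureless data", {
  # across independent null datasets the top-ranked parameter is uniform
  # over parameters (within one dataset the winner is sticky because the
  # resamples share most of their rows, so uniformity is a between-
  # dataset property)
  spec <- synthetic_spec(
    groups = tibble::tibble(label = c("a", "b", "c"), burden = c(0, 0, 1),
                            size = rep(20, 3)),
    n_parameters = 10
  )
  winners <- vapply(1:60, function(seed) {
    gen <- generate_dataset(spec, seed = 500 + seed)
    rk <- resampled_parameter_ranking(
      gen$table, study_config(n_resamples = 1), seed = seed)
    rk$ranking$parameter[1]
  }, character(1))
  counts <- table(factor(winners, levels = sprintf("p%02d", 1:10)))
  set.seed(99)
  p <- stats::chisq.test(counts, simulate.p.value = TRUE, B = 5000)$p.value
  expect_gt(p, 0.01)
})
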