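test_that("the DP solution matches exhaustive contiguous-partition search", {
  set.seed(301)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    k <- sample(2:4, 1)
    x <- round(rnorm(n), 2)
    if (length(unique(x)) < k) next
    got <- kmeans_1d(x, k)
    ora <- oracle_kmeans_1d(x, k)
    expect_equal(got$tot_withinss, ora$cost, tolerance = 1e-9)
    expect_equal(got$centers, ora$centers, tolerance = 1e-9)
  }
})

test_that("the DP optimum is never beaten by random-restart Lloyd iterations", {
  set.seed(311)
  x <- c(rnorm(30), rnorm(25, 4), rnorm(20, 9))
  for (k in 2:4) {
    dp <- kmeans_1d(x, k)
    lloyd_best <- min(vapply(1:50, function(i)
      stats::kmeans(x, k, nstart = 1)$tot.withinss, numeric(1)))
    expect_lte(dp$tot_withinss, lloyd_best + 1e-8)
  }
})

test_that("two well-separated masses split at the midpoint threshold", {
  x <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  fit <- kmeans_1d(x, 2)
  expect_equal(fit$centers, c(0.1, 10.1))
  expect_equal(fit$cluster, c(1, 1, 1, 2, 2, 2))

  cfg <- study_config(cluster_resamples = 50, ci_level = 0.95)
  model <- fit_cluster_thresholds(x, 2, cfg, seed = 1)
  # every bootstrap that keeps both masses yields threshold ~5.1-5.2;
  # the rare resample drawn from a single mass splits inside it instead
  expect_gte(mean(abs(model$boot_thresholds - 5.15) < 0.2), 0.9)
  expect_lt(abs(median(model$boot_thresholds) - 5.15), 0.2)
  expect_equal(model$center_means, c(0.1, 10.1))

  # k = 1: no thresholds
  m1 <- fit_cluster_thresholds(x, 1, cfg, seed = 1)
  expect_length(m1$thresholds, 0)

  expect_error(fit_cluster_thresholds(rep(1, 10), 2, cfg), "distinct|equal")
  expect_error(fit_cluster_thresholds(c(1, 2), 3, cfg), "distinct")
})

test_that("threshold confidence borders contain the mean and widen with level", {
  set.seed(321)
  x <- c(rnorm(40), rnorm(40, 3))
  cfg95 <- study_config(cluster_resamples = 100, ci_level = 0.95)
  cfg80 <- study_config(cluster_resamples = 100, ci_level = 0.80)
  m95 <- fit_cluster_thresholds(x, 2, cfg95, seed = 5)
  m80 <- fit_cluster_thresholds(x, 2, cfg80, seed = 5)
  ci95 <- m95$threshold_ci
  ci80 <- m80$threshold_ci
  expect_true(all(ci95$lower <= m95$thresholds & m95$thresholds <= ci95$upper))
  expect_gte(ci95$upper - ci95$lower, ci80$upper - ci80$lower)
  # thresholds strictly increasing when k > 2
  m3 <- fit_cluster_thresholds(c(rnorm(30), rnorm(30, 4), rnorm(30, 8)), 3,
                               cfg95, seed = 5)
  expect_true(all(diff(m3$thresholds) > 0))
})

test_that("thresholds are reproducible and permutation-invariant", {
  set.seed(331)
  x <- rnorm(60)
  cfg <- study_config(cluster_resamples = 50)
  a <- fit_cluster_thresholds(x, 3, cfg, seed = 9)
  b <- fit_cluster_thresholds(x, 3, cfg, seed = 9)
  expect_identical(a$thresholds, b$thresholds)
  expect_identical(a$boot_thresholds, b$boot_thresholds)
  c_ <- fit_cluster_thresholds(sample(x), 3, cfg, seed = 9)
  expect_equal(a$thresholds, c_$thresholds)
})

test_that("the scree elbow is the maximum second difference and config wins", {
  ev <- c(0.6, 0.3, 0.05, 0.03, 0.02)
  # brute force: argmax of v[i] - 2 v[i+1] + v[i+2]
  sd2 <- vapply(1:3, function(i) ev[i] - 2 * ev[i + 1] + ev[i + 2], numeric(1))
  expect_equal(which.max(sd2), 2L)
  pick <- suggest_k(ev, study_config())
  expect_equal(pick$k, 2L)
  expect_equal(pick$source, "elbow")

  pick6 <- suggest_k(ev, study_config(cluster_k = 6))
  expect_equal(pick6$k, 6L)
  expect_equal(pick6$suggested, 2L)
  expect_equal(pick6$source, "config")

  expect_error(suggest_k(c(0.6, 0.4), study_config()), "length >= 3")
})

test_that("severity assignment respects thresholds with boundary to the higher side", {
  model <- structure(list(k = 3L, thresholds = c(1, 2),
                          boot_thresholds = matrix(c(1, 2), 1)),
                     class = "cluster_model")
  got <- assign_severity(c(0.5, 1, 1.5, 2, 99, NA), model)
  expect_equal(got$cluster, c(1L, 2L, 2L, 3L, 3L, NA))
  expect_equal(got$reason[6], "missing composite score")
})

test_that("allocation percentages sum to 100 per group and flag top clusters", {
  assignments <- tibble::tibble(
    animal_id = paste0("m", 1:12),
    model = "syn",
    group = rep(c("a", "b"), each = 6),
    score = 1:12,
    cluster = c(1L, 1L, 1L, 2L, 2L, 3L, 2L, 3L, 3L, 3L, 3L, 3L),
    reason = NA_character_
  )
  alloc <- allocation_table(assignments, k = 3)
  sums <- tapply(alloc$by_group$pct, alloc$by_group$group, sum)
  expect_equal(as.vector(sums), c(100, 100), tolerance = 1e-9)
  top <- alloc$top_share
  expect_equal(top$top_share[top$group == "a"], 100 * 3 / 6)   # clusters 2+3
  expect_equal(top$top_share[top$group == "b"], 100 * 6 / 6)

  # all animals in one cluster: that column is 100
  one <- allocation_table(dplyr::mutate(assignments, cluster = 2L), k = 3)
  expect_equal(one$wide$cluster_2, c(100, 100))
  expect_equal(one$wide$cluster_1, c(0, 0))
})

test_that("pooled assignment counts animal-by-resample units", {
  model <- structure(list(k = 2L, thresholds = 1,
                          boot_thresholds = matrix(c(0.4, 1.6), 2)),
                     class = "cluster_model")
  got <- assign_severity(c(1, 1), model, pooled = TRUE)
  expect_equal(nrow(got), 4)
  # score 1 falls above threshold 0.4 but below 1.6
  expect_equal(sort(unique(got$cluster[got$resample == 1])), 2L)
  expect_equal(sort(unique(got$cluster[got$resample == 2])), 1L)
})
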