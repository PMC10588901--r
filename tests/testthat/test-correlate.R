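test_that("Spearman rho matches the rank-correlation oracle", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(1, 3, 2, 5, 4)
  tab <- as_parameter_table(tibble::tibble(animal_id = paste0("m", 1:5),
                                           group = "g", x = x, y = y))
  res <- spearman_matrix(tab)
  expect_equal(res$r["x", "y"], 0.8)
  expect_equal(res$r["x", "y"], oracle_spearman(x, y))
  expect_equal(res$r["x", "x"], 1)

  # identical vectors: perfect correlation
  tab2 <- as_parameter_table(tibble::tibble(animal_id = paste0("m", 1:5),
                                            group = "g", a = x, b = x))
  expect_equal(spearman_matrix(tab2)$r["a", "b"], 1)

  # ties go through mid-ranks
  set.seed(11)
  xt <- sample(rep(1:4, 3)); yt <- sample(rep(1:3, 4))
  expect_equal(spearman_rho(xt, yt)$rho, oracle_spearman(xt, yt))
})

test_that("exact permutation p-values agree with exhaustive enumeration", {
  # perfect concordance at n = 3: one-sided p = 1/6
  expect_equal(spearman_exact_p(1:3, 1:3, alternative = "greater"), 1 / 6)
  expect_equal(oracle_perm_p(1:3, 1:3, "greater"), 1 / 6)

  set.seed(21)
  for (n in c(4, 5, 6)) {
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(spearman_exact_p(x, y), oracle_perm_p(x, y))
    xt <- sample(n, replace = TRUE); yt <- rnorm(n)  # with ties
    expect_equal(spearman_exact_p(xt, yt), oracle_perm_p(xt, yt))
  }
})

test_that("exact and t-approximate p-values agree closely at n >= 8 under the null", {
  set.seed(31)
  diffs <- replicate(40, {
    x <- rnorm(8); y <- rnorm(8)
    rho <- oracle_spearman(x, y)
    t_p <- if (abs(rho) >= 1) 0 else
      2 * stats::pt(-abs(rho * sqrt(6 / (1 - rho^2))), df = 6)
    abs(spearman_exact_p(x, y) - t_p)
  })
  expect_lt(max(diffs), 0.05)
})

test_that("the matrix is symmetric with unit diagonal and handles undefined pairs", {
  set.seed(41)
  tab <- as_parameter_table(tibble::tibble(
    animal_id = paste0("m", 1:12), group = "g",
    a = rnorm(12), b = rnorm(12),
    const = 1,
    sparse = c(rnorm(2), rep(NA, 10))
  ))
  res <- spearman_matrix(tab)
  expect_identical(res$r, t(res$r))
  expect_identical(res$p, t(res$p))
  expect_equal(unname(diag(res$r)), rep(1, 4))
  expect_true(is.na(res$r["a", "const"]))    # constant column: undefined
  expect_true(is.na(res$r["a", "sparse"]))   # < 3 complete pairs
  expect_equal(res$n_pairs["a", "sparse"], 2)
  defined <- res$r[upper.tri(res$r)]
  expect_true(all(abs(defined[!is.na(defined)]) <= 1))
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(51)
  for (i in 1:5) {
    x <- rnorm(30); y <- 0.5 * x + rnorm(30)
    base <- spearman_rho(x, y)$rho
    expect_equal(spearman_rho(exp(x), y)$rho, base)
    expect_equal(spearman_rho(x, y^3)$rho, base)
    expect_equal(spearman_rho(qlogis(pnorm(x)), exp(y))$rho, base)
  }
})

test_that("pair flagging applies strict cut-offs on r and p", {
  r <- matrix(c(1, 0.79, 0.68, 0.79, 1, 0.9, 0.68, 0.9, 1), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  p <- matrix(c(0, 1e-5, 1e-5, 1e-5, 0, 0.2, 1e-5, 0.2, 0), 3, 3,
              dimnames = dimnames(r))
  corr <- structure(list(r = r, p = p, n_pairs = matrix(50, 3, 3)),
                    class = "correlation_result")
  rep <- flag_pairs(corr, study_config())
  pair <- function(p1, p2) rep$pairs[rep$pairs$parameter_1 == p1 &
                                       rep$pairs$parameter_2 == p2, ]
  expect_true(pair("a", "b")$significant)    # r = 0.79, p tiny
  expect_true(pair("a", "b")$redundant)
  expect_true(pair("a", "c")$significant)    # r = 0.68: significant only
  expect_false(pair("a", "c")$redundant)
  expect_false(pair("b", "c")$significant)   # r = 0.9 but p = 0.2
  expect_false(pair("b", "c")$redundant)
})

test_that("pruning respects keep-rules and leaves no redundant pair", {
  set.seed(61)
  n <- 60
  light <- rnorm(n)
  overnight <- light + rnorm(n, sd = 0.45)    # highly correlated pair
  other <- rnorm(n)
  tab <- as_parameter_table(tibble::tibble(
    animal_id = paste0("m", 1:n), group = "g",
    burrow_light = light, burrow_overnight = overnight, other = other
  ))
  corr <- spearman_matrix(tab)
  expect_gt(corr$r["burrow_light", "burrow_overnight"], 0.7)
  rep <- flag_pairs(corr, study_config())
  pruned <- prune_parameters(tab, rep, keep_rules = "burrow_light")
  expect_true("burrow_light" %in% parameter_names(pruned$table))
  expect_false("burrow_overnight" %in% parameter_names(pruned$table))
  expect_equal(pruned$report$dropped$rule, "keep_rule")

  # re-running the flagging on the pruned table finds no redundant pair
  rep2 <- flag_pairs(spearman_matrix(pruned$table), study_config())
  expect_equal(nrow(rep2$redundant_pairs), 0)

  expect_warning(prune_parameters(tab, rep, keep_rules = "nonexistent"),
                 "unknown parameters")

  # empty redundant set: identity
  tab0 <- tab[, c("animal_id", "group", "other", "burrow_light")]
  rep0 <- flag_pairs(spearman_matrix(as_parameter_table(tab0)), study_config())
  pr0 <- prune_parameters(as_parameter_table(tab0), rep0)
  expect_setequal(parameter_names(pr0$table), c("other", "burrow_light"))
})

test_that("a redundancy chain drops the hub and keeps the ends", {
  set.seed(71)
  # noise scale tuned so a~b and b~c clear the 0.7 cut while the induced
  # a~c correlation (~0.65) stays below it
  n <- 200
  b <- rnorm(n)
  a <- b + rnorm(n, sd = 0.72)
  c_ <- b + rnorm(n, sd = 0.72)
  tab <- as_parameter_table(tibble::tibble(
    animal_id = paste0("m", 1:n), group = "g", a = a, b = b, c = c_
  ))
  corr <- spearman_matrix(tab)
  rep <- flag_pairs(corr, study_config())
  # fixture demands the chain structure a~b, b~c without a~c
  red <- rep$redundant_pairs
  has <- function(p1, p2) any((red$parameter_1 == p1 & red$parameter_2 == p2) |
                                (red$parameter_1 == p2 & red$parameter_2 == p1))
  expect_true(has("a", "b") && has("b", "c") && !has("a", "c"))

  pruned <- prune_parameters(tab, rep)
  survivors <- parameter_names(pruned$table)
  expect_setequal(survivors, c("a", "c"))

  # brute force: the surviving set is redundancy-free and maximal
  all_sets <- unlist(lapply(1:3, function(m)
    utils::combn(c("a", "b", "c"), m, simplify = FALSE)), recursive = FALSE)
  ok_sets <- Filter(function(s) {
    pairs <- if (length(s) < 2) list() else
      utils::combn(s, 2, simplify = FALSE)
    !any(vapply(pairs, function(pr) has(pr[1], pr[2]), logical(1)))
  }, all_sets)
  max_size <- max(lengths(ok_sets))
  expect_equal(length(survivors), max_size)
})

test_that("manual post-correlation exclusions are applied with their reason", {
  tab <- tiny_table()
  rep <- flag_pairs(spearman_matrix(tab), study_config())
  pruned <- prune_parameters(tab, rep,
                             manual_exclusions = c(fcm = "lower sensitivity"))
  expect_false("fcm" %in% parameter_names(pruned$table))
  expect_match(pruned$report$dropped$rule[
    pruned$report$dropped$parameter == "fcm"], "manual: lower sensitivity")
})
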