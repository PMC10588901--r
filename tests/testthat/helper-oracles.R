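# Independent brute-force oracles and shared fixtures. These stay
# deliberately naive: they re-derive expected values by enumeration or
# first principles, never through the package's own code paths.

# all permutations of 1..n, one per row (recursive, independent of the
# package's internal enumerator)
oracle_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- oracle_perms(n - 1L)
    cbind(first, matrix(setdiff(seq_len(n), first)[rest], nrow(rest)))
  }))
}

# Spearman rho as the product-moment correlation of mid-rank vectors
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# permutation p-value by exhaustive enumeration over y's rank labels
oracle_perm_p <- function(x, y, alternative = "two.sided") {
  rx <- rank(x); ry <- rank(y)
  obs <- stats::cor(rx, ry)
  perms <- oracle_perms(length(y))
  rho <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
  eps <- 1e-12
  switch(alternative,
         two.sided = mean(abs(rho) >= abs(obs) - eps),
         greater   = mean(rho >= obs - eps),
         less      = mean(rho <= obs + eps))
}

# AUC by explicit enumeration of every positive-negative pair
oracle_auc <- function(pos, neg) {
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# optimal 1-D k-means by exhaustive search over contiguous partitions of
# the sorted data (compositions of n into k positive parts)
oracle_kmeans_1d <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  ss <- function(v) sum((v - mean(v))^2)
  best <- list(cost = Inf)
  splits <- utils::combn(n - 1, k - 1, simplify = FALSE)
  if (k == 1) splits <- list(integer(0))
  for (cut in splits) {
    bounds <- c(0, cut, n)
    segs <- lapply(seq_len(k), function(m) xs[(bounds[m] + 1):bounds[m + 1]])
    cost <- sum(vapply(segs, ss, numeric(1)))
    if (cost < best$cost) {
      best <- list(cost = cost, centers = vapply(segs, mean, numeric(1)))
    }
  }
  best
}

# standard three-group severity fixture: planted latent severity factor
# on parameters p03/p07/p11 with shifts 0 / 0.75 / 1.5 SD
severity_spec <- function(n_per_group = 20, effect = 1.5, rho = 0.5,
                          missing_rate = 0) {
  synthetic_spec(
    groups = tibble::tibble(label = c("ctrl", "mid", "sev"),
                            burden = c(0, 0, 1),
                            size = rep(n_per_group, 3)),
    n_parameters = 15,
    effects = list(p03 = c(mid = effect / 2, sev = effect),
                   p07 = c(mid = effect / 2, sev = effect),
                   p11 = c(mid = effect / 2, sev = effect)),
    correlation_blocks = list(c(3, 7, 11)), rho = rho,
    missing_rate = missing_rate
  )
}

# tiny deterministic table used across io/preselect tests
tiny_table <- function() {
  as_parameter_table(tibble::tibble(
    animal_id = c("m1", "m2", "m3", "m4"),
    model = "kainate",
    group = c("naive", "sham", "treated", "treated"),
    burrowing = c(90, 85, 30, 10),
    irwin = c(0, 1, 6, 8),
    fcm = c(110, 120, 310, NA)
  ))
}

write_tiny_csv <- function(path, lines) {
  writeLines(lines, path)
  path
}
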