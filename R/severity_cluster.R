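# Ordered severity clustering: globally optimal 1-D k-means by dynamic
# programming over contiguous partitions, bootstrap threshold confidence
# borders, and per-animal severity assignment.

#' Globally optimal one-dimensional k-means
#'
#' In one dimension every optimal k-means partition is contiguous in the
#' sorted order, so the global optimum is found exactly by dynamic
#' programming over contiguous segment boundaries (cost of a segment =
#' its sum of squared deviations from the segment mean, computed from
#' prefix sums). No random initialisation, no local optima.
#'
#' @param x Numeric vector (length >= k, at least k distinct values).
#' @param k Number of clusters.
#' @return A list: `centers` (sorted ascending), `cluster` (assignment of
#'   each element of `x`, 1 = lowest center), `withinss` (per-cluster sum
#'   of squares), `tot_withinss`.
#' @export
kmeans_1d <- function(x, k) {
  stopifnot(k >= 1)
  if (any(is.na(x))) stop("x must not contain missing values.", call. = FALSE)
  n <- length(x)
  if (length(unique(x)) < k) {
    stop("need at least k = ", k, " distinct values (got ",
         length(unique(x)), ").", call. = FALSE)
  }
  ord <- order(x)
  xs <- x[ord]
  cs <- c(0, cumsum(xs))
  cs2 <- c(0, cumsum(xs^2))
  # cost of segment i..j (1-based, inclusive)
  seg_cost <- function(i, j) {
    s <- cs[j + 1] - cs[i]
    q <- cs2[j + 1] - cs2[i]
    q - s^2 / (j - i + 1)
  }
  # D[m, j]: optimal cost of splitting xs[1..j] into m segments
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)   # start index of the last segment
  for (j in 1:n) {
    D[1, j] <- seg_cost(1, j)
    B[1, j] <- 1L
  }
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        starts <- m:j
        s <- cs[j + 1] - cs[starts]
        q <- cs2[j + 1] - cs2[starts]
        costs <- D[m - 1, starts - 1] + (q - s^2 / (j - starts + 1))
        best <- which.min(costs)
        D[m, j] <- costs[best]
        B[m, j] <- starts[best]
      }
    }
  }
  # backtrack segment boundaries
  bounds <- integer(k + 1)
  bounds[k + 1] <- n
  j <- n
  for (m in k:1) {
    bounds[m] <- B[m, j] - 1L
    j <- B[m, j] - 1L
  }
  centers <- numeric(k)
  withinss <- numeric(k)
  cl_sorted <- integer(n)
  for (m in 1:k) {
    seg <- (bounds[m] + 1L):bounds[m + 1]
    centers[m] <- mean(xs[seg])
    withinss[m] <- seg_cost(bounds[m] + 1L, bounds[m + 1])
    cl_sorted[seg] <- m
  }
  cluster <- integer(n)
  cluster[ord] <- cl_sorted
  list(centers = centers, cluster = cluster,
       withinss = withinss, tot_withinss = D[k, n])
}

#' Suggest the number of severity clusters from a scree sequence
#'
#' Scans the explained-variance sequence for its elbow, defined as the
#' index maximising the second difference `v[i] - 2 v[i+1] + v[i+2]`
#' (the sharpest flattening of the scree). A `cluster_k` set in the
#' config always overrides the suggestion; both are recorded.
#'
#' @param x A `"pca_run"` (its `explained_fraction` is used) or a numeric
#'   explained-variance sequence of length >= 3.
#' @param config A [study_config()]; `cluster_k` overrides.
#' @return A list: `k` (the value to use), `suggested` (elbow index),
#'   `source` (`"config"` or `"elbow"`).
#' @export
suggest_k <- function(x, config = study_config()) {
  ev <- if (inherits(x, "pca_run")) x$explained_fraction else as.numeric(x)
  if (length(ev) < 3L) {
    stop("explained-variance sequence must have length >= 3.", call. = FALSE)
  }
  second_diff <- ev[1:(length(ev) - 2)] - 2 * ev[2:(length(ev) - 1)] +
    ev[3:length(ev)]
  elbow <- which.max(second_diff)
  if (!is.null(config$cluster_k)) {
    list(k = config$cluster_k, suggested = elbow, source = "config")
  } else {
    list(k = elbow, suggested = elbow, source = "elbow")
  }
}

#' Fit severity-cluster thresholds with bootstrap confidence borders
#'
#' Fits the globally optimal 1-D k-means to the training composite
#' scores, then re-fits it on `n_resamples` bootstrap resamples of those
#' scores. Each fit yields `k - 1` thresholds (midpoints between
#' adjacent sorted centers, which reproduce nearest-center assignment
#' exactly in 1-D); the model's thresholds are the resample means and
#' their confidence borders the percentile interval at `ci_level`.
#'
#' @param training_scores Numeric composite scores (larger = more
#'   severe); a `"composite_scores"` tibble is accepted.
#' @param k Number of ordered severity clusters; cluster `k` is the
#'   highest severity level.
#' @param config A [study_config()]; `cluster_resamples` and `ci_level`
#'   are used.
#' @param seed Integer seed for the bootstrap; falls back to `config$seed`.
#' @return A list of class `"cluster_model"`: `k`, `center_means` (full-
#'   data centers, ascending), `thresholds` (k-1, strictly increasing),
#'   `threshold_ci` (tibble `threshold`, `mean`, `lower`, `upper`),
#'   `boot_thresholds` (resamples-by-(k-1) matrix), `n_resamples`,
#'   `ci_level`, `seed`.
#' @export
fit_cluster_thresholds <- function(training_scores, k, config = study_config(),
                                   seed = NULL) {
  if (inherits(training_scores, "composite_scores")) {
    training_scores <- training_scores$composite
  }
  # sorting makes the bootstrap invariant to the input score order
  x <- sort(training_scores[!is.na(training_scores)])
  if (length(unique(x)) < k) {
    stop("fewer than k = ", k, " distinct training scores.", call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("training scores are all equal.", call. = FALSE)
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)

  full <- kmeans_1d(x, k)
  n_res <- config$cluster_resamples
  boot <- matrix(NA_real_, n_res, max(k - 1, 0))
  for (b in seq_len(n_res)) {
    xs <- sample(x, length(x), replace = TRUE)
    tries <- 0L
    while (length(unique(xs)) < k && tries < 100L) {
      xs <- sample(x, length(x), replace = TRUE)
      tries <- tries + 1L
    }
    if (length(unique(xs)) < k) {
      stop("bootstrap resamples cannot supply k distinct values.", call. = FALSE)
    }
    fit <- kmeans_1d(xs, k)
    if (k > 1) {
      boot[b, ] <- (fit$centers[-k] + fit$centers[-1]) / 2
    }
  }
  if (k > 1) {
    thr <- colMeans(boot)
    alpha <- 1 - config$ci_level
    ci <- apply(boot, 2, stats::quantile, probs = c(alpha / 2, 1 - alpha / 2),
                names = FALSE)
    threshold_ci <- tibble::tibble(
      threshold = seq_len(k - 1), mean = thr,
      lower = ci[1, ], upper = ci[2, ]
    )
  } else {
    thr <- numeric(0)
    threshold_ci <- tibble::tibble(threshold = integer(), mean = numeric(),
                                   lower = numeric(), upper = numeric())
  }
  structure(
    list(k = as.integer(k), center_means = full$centers, thresholds = thr,
         threshold_ci = threshold_ci, boot_thresholds = boot,
         n_resamples = n_res, ci_level = config$ci_level, seed = seed,
         disclaimer = paste(
           "Severity levels are relative to the models analysed;",
           "they are not directly translatable to regulatory severity categories.")),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d severity levels (%d = highest)\n", x$k, x$k))
  if (x$k > 1) {
    cat("  thresholds (mean of", x$n_resamples, "bootstraps):",
        paste(sprintf("%.3f", x$thresholds), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.cluster_model <- function(x, ...) x$threshold_ci

#' @rdname tidiers
#' @export
glance.cluster_model <- function(x, ...) {
  tibble::tibble(k = x$k, n_resamples = x$n_resamples, ci_level = x$ci_level,
                 min_center = min(x$center_means), max_center = max(x$center_means))
}

#' Assign animals to ordered severity clusters
#'
#' An animal with composite score `s` is assigned to cluster
#' `1 + #(thresholds at or below s)`; a score exactly on a boundary goes
#' to the higher cluster. Cluster `k` is the highest severity level.
#' With `pooled = TRUE` every bootstrap threshold set in the model is
#' applied, producing one assignment per animal-by-resample unit.
#'
#' @param scores Numeric composite scores or a `"composite_scores"`
#'   tibble (its `animal_id`, `model`, `group` travel along).
#' @param model A [fit_cluster_thresholds()] model.
#' @param pooled Assign under every bootstrap threshold set instead of
#'   the mean thresholds. Default `FALSE`.
#' @return A tibble: `animal_id` (when available), `model`, `group`,
#'   `score`, `cluster` (and `resample` when pooled). Animals with a
#'   missing score are kept with `cluster = NA` and a `reason`.
#' @export
assign_severity <- function(scores, model, pooled = FALSE) {
  meta <- NULL
  if (inherits(scores, "composite_scores")) {
    meta <- scores[c("animal_id", "model", "group")]
    scores <- scores$composite
  }
  assign_one <- function(thr) {
    vapply(scores, function(s) {
      if (is.na(s)) return(NA_integer_)
      1L + sum(thr <= s)
    }, integer(1))
  }
  base_meta <- meta %||% tibble::tibble(
    animal_id = as.character(seq_along(scores)),
    model = NA_character_, group = NA_character_
  )
  if (!pooled) {
    out <- dplyr::bind_cols(base_meta,
                            tibble::tibble(score = scores,
                                           cluster = assign_one(model$thresholds)))
  } else {
    out <- purrr::map_dfr(seq_len(nrow(model$boot_thresholds)), function(b) {
      dplyr::bind_cols(base_meta,
                       tibble::tibble(resample = b, score = scores,
                                      cluster = assign_one(model$boot_thresholds[b, ])))
    })
  }
  out$reason <- ifelse(is.na(out$score), "missing composite score", NA_character_)
  out
}

#' Group-level severity allocation table
#'
#' Tabulates, per group (and per model-by-group when models are present),
#' the percentage of animals (or animal-by-resample units, for pooled
#' assignments) allocated to each severity cluster; every row sums to
#' 100. Also reports the combined share of the configured top clusters
#' (by default the two highest), the summary used to compare burdened
#' and control groups.
#'
#' @param assignments An [assign_severity()] tibble.
#' @param k Number of clusters (defaults to the highest observed).
#' @param top_clusters Cluster indices summed into `top_share`; defaults
#'   to `k` and `k - 1`.
#' @return A list of class `"allocation_result"`: `by_group` (long
#'   tibble `model`, `group`, `cluster`, `n`, `pct`), `wide` (groups-by-
#'   clusters percentage table), `top_share` (per group), `n_units`.
#' @export
allocation_table <- function(assignments, k = NULL, top_clusters = NULL) {
  a <- assignments[!is.na(assignments$cluster), ]
  if (!nrow(a)) stop("no assigned animals.", call. = FALSE)
  k <- k %||% max(a$cluster)
  top_clusters <- top_clusters %||% unique(pmax(c(k, k - 1), 1))
  empty <- setdiff(unique(assignments$group), unique(a$group))
  if (length(empty)) {
    warning("group(s) with no assigned animals omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  by_group <- a |>
    dplyr::count(.data$model, .data$group, .data$cluster) |>
    dplyr::group_by(.data$model, .data$group) |>
    tidyr::complete(cluster = seq_len(k), fill = list(n = 0L)) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  wide <- by_group |>
    dplyr::select("model", "group", "cluster", "pct") |>
    tidyr::pivot_wider(names_from = "cluster", values_from = "pct",
                       names_prefix = "cluster_")
  top_share <- by_group |>
    dplyr::group_by(.data$model, .data$group) |>
    dplyr::summarise(
      top_share = sum(.data$pct[.data$cluster %in% top_clusters]),
      n_units = sum(.data$n), .groups = "drop"
    )
  structure(
    list(by_group = by_group, wide = wide, top_share = top_share,
         k = k, top_clusters = top_clusters, n_units = nrow(a)),
    class = "allocation_result"
  )
}

#' @export
print.allocation_result <- function(x, ...) {
  cat(sprintf("<allocation_result> %d units over %d clusters; top clusters {%s}\n",
              x$n_units, x$k, paste(x$top_clusters, collapse = ", ")))
  print(x$wide)
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.allocation_result <- function(x, ...) x$by_group
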