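# Normalization (positivity shift -> Box-Cox -> standardize) and the
# resampled-PCA parameter ranking that drives the composite score.

#' Box-Cox transform at a fixed lambda
#'
#' `(y^lambda - 1) / lambda`, or `log(y)` at `lambda = 0`; `y` must be
#' strictly positive.
#'
#' @param y Positive numeric vector.
#' @param lambda Transform exponent.
#' @return The transformed vector.
#' @export
boxcox_transform <- function(y, lambda) {
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

#' Box-Cox profile log-likelihood over a lambda grid
#'
#' One-sample profile log-likelihood
#' `-n/2 log(varMLE(z_lambda)) + (lambda - 1) sum(log y)`, evaluated for
#' every grid value at once.
#'
#' @param y Positive numeric vector.
#' @param lambdas Numeric grid of candidate exponents.
#' @return Numeric vector of log-likelihoods, one per grid value.
#' @export
boxcox_loglik <- function(y, lambdas) {
  n <- length(y)
  ly <- log(y)
  z <- exp(outer(ly, lambdas))          # y^lambda, n x L
  z <- sweep(z - 1, 2, lambdas, "/")
  z[, abs(lambdas) < 1e-12] <- ly
  v <- colMeans(z^2) - colMeans(z)^2
  -n / 2 * log(v) + (lambdas - 1) * sum(ly)
}

#' Maximum-likelihood Box-Cox lambda
#'
#' Maximises [boxcox_loglik()] on the canonical grid `[-2, 2]` in steps
#' of 0.01.
#'
#' @param y Positive numeric vector.
#' @param grid Candidate lambda grid.
#' @return The grid value with the highest profile log-likelihood.
#' @export
boxcox_lambda <- function(y, grid = seq(-2, 2, by = 0.01)) {
  ll <- boxcox_loglik(y, grid)
  grid[which.max(ll)]
}

#' Fit the per-parameter normalization model
#'
#' For each parameter (on its observed fit rows): shift the values to
#' strictly positive support (`shift = 1 - min`, so the fit minimum maps
#' to 1), apply a Box-Cox transformation with lambda chosen by maximum
#' profile log-likelihood on the grid `[-2, 2]` in steps of 0.01, then
#' center and scale the transformed values to mean 0 and standard
#' deviation 1. The composed transform is strictly monotone per
#' parameter. Missing values are ignored during fitting and stay missing
#' after application.
#'
#' @param table A parameter table (or numeric matrix) of fit rows,
#'   typically a training subset.
#' @param parameters Optional subset of parameter names.
#' @return A list of class `"normalization_model"` with a per-parameter
#'   tibble `params` (`parameter`, `shift`, `lambda`, `mean`, `sd`,
#'   `n_fit`, `floor`) recording the fitted transform.
#' @export
fit_normalizer <- function(table, parameters = NULL) {
  m <- if (is.matrix(table)) table else {
    table <- as_parameter_table(table)
    param_matrix(table, parameters %||% parameter_names(table))
  }
  fits <- purrr::map_dfr(colnames(m), function(pp) {
    x <- m[, pp]
    x <- x[!is.na(x)]
    if (length(x) < 2L || stats::sd(x) == 0) {
      stop("parameter '", pp, "' is constant (or near-empty) on the fit rows; ",
           "cannot normalize.", call. = FALSE)
    }
    shift <- 1 - min(x)
    y <- x + shift
    lambda <- boxcox_lambda(y)
    z <- boxcox_transform(y, lambda)
    tibble::tibble(parameter = pp, shift = shift, lambda = lambda,
                   mean = mean(z), sd = stats::sd(z), n_fit = length(x),
                   floor = 0.5)  # positive floor for out-of-support new values
  })
  structure(list(params = fits), class = "normalization_model")
}

#' Apply a fitted normalization model
#'
#' Applies each parameter's shift, Box-Cox and standardization to new
#' data. A new value falling at or below the positivity shift (possible
#' only outside the fit range) is clamped to the model's positive floor
#' so the transform stays defined; missing cells stay missing.
#'
#' @param model A [fit_normalizer()] model.
#' @param table A parameter table or numeric matrix containing the fitted
#'   parameters.
#' @return A numeric matrix (rows as in `table`, columns = fitted
#'   parameters) with each fitted column standardized on the fit rows.
#' @export
apply_normalizer <- function(model, table) {
  m <- if (is.matrix(table)) table else {
    param_matrix(as_parameter_table(table), model$params$parameter)
  }
  out <- m[, model$params$parameter, drop = FALSE]
  for (i in seq_len(nrow(model$params))) {
    f <- model$params[i, ]
    y <- out[, f$parameter] + f$shift
    y[!is.na(y) & y <= 0] <- f$floor
    out[, f$parameter] <- (boxcox_transform(y, f$lambda) - f$mean) / f$sd
  }
  out
}

# Training-median imputation of residual missing cells in a normalized
# matrix; medians come from the (normalized) training rows.
impute_median <- function(m, train_medians = NULL) {
  med <- train_medians %||% apply(m, 2, stats::median, na.rm = TRUE)
  n_imputed <- 0L
  for (j in seq_len(ncol(m))) {
    idx <- is.na(m[, j])
    if (any(idx)) {
      m[idx, j] <- med[j]
      n_imputed <- n_imputed + sum(idx)
    }
  }
  attr(m, "n_imputed") <- n_imputed
  m
}

#' Principal component analysis of a normalized matrix
#'
#' Eigen-decomposition of the covariance of the normalized (and, if
#' needed, median-imputed) matrix via [stats::prcomp()]. Components are
#' ordered by standard deviation, and each loading vector follows a
#' deterministic sign convention: its largest-magnitude entry is
#' positive. On fully standardized input the squared component standard
#' deviations sum to the number of parameters.
#'
#' @param x A numeric animals-by-parameters matrix, already normalized;
#'   residual missing cells are imputed with the column median.
#' @param sd_threshold Components with standard deviation strictly above
#'   this are marked selected. Default 1.
#' @return A list of class `"pca_run"`: `component_sds`, `loadings`
#'   (orthonormal parameters-by-components), `scores`
#'   (animals-by-components), `selected` (indices), `explained_fraction`,
#'   `n_imputed`.
#' @export
run_pca <- function(x, sd_threshold = 1) {
  if (nrow(x) < 3L) stop("PCA needs at least 3 rows.", call. = FALSE)
  x <- impute_median(x)
  fit <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  rot <- fit$rotation
  sco <- fit$x
  for (j in seq_len(ncol(rot))) {
    peak <- which.max(abs(rot[, j]))
    if (rot[peak, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  sds <- fit$sdev
  structure(
    list(component_sds = sds, loadings = rot, scores = sco,
         selected = which(sds > sd_threshold),
         explained_fraction = sds^2 / sum(sds^2),
         n_imputed = attr(x, "n_imputed")),
    class = "pca_run"
  )
}

#' @export
print.pca_run <- function(x, ...) {
  cat(sprintf("<pca_run> %d components; %d selected (SD > threshold); PC1 %.1f%% of variance (SD %.2f)\n",
              length(x$component_sds), length(x$selected),
              100 * x$explained_fraction[1], x$component_sds[1]))
  invisible(x)
}

#' @rdname tidiers
#' @export
glance.pca_run <- function(x, ...) {
  tibble::tibble(component = seq_along(x$component_sds),
                 sd = x$component_sds,
                 explained_fraction = x$explained_fraction,
                 selected = seq_along(x$component_sds) %in% x$selected)
}

#' Select principal components by the SD rule
#'
#' Components with standard deviation strictly greater than the threshold
#' are retained; a component at exactly the threshold is excluded.
#'
#' @param run A [run_pca()] result.
#' @param sd_threshold Positive threshold, default 1.
#' @return Integer indices `1..m` of the selected components.
#' @export
select_components <- function(run, sd_threshold = 1) {
  stopifnot(sd_threshold > 0)
  sel <- which(run$component_sds > sd_threshold)
  if (!length(sel)) {
    stop("no component has SD > ", sd_threshold,
         "; review the threshold or the input scaling.", call. = FALSE)
  }
  sel
}

#' Fit the reference normalization and PCA on a full data set
#'
#' Convenience wrapper: fits the normalizer on all rows of the table,
#' normalizes, imputes residual missing cells with the column median and
#' runs the PCA. The normalizer and the fit row ids travel with the
#' result so new data can be projected consistently.
#'
#' @param table A parameter table.
#' @param config A [study_config()] (`sd_threshold` is used).
#' @return A `"pca_run"` with extra fields `normalizer`, `train_medians`
#'   and `animal_id`.
#' @export
fit_reference_pca <- function(table, config = study_config()) {
  table <- as_parameter_table(table)
  norm <- fit_normalizer(table)
  z <- apply_normalizer(norm, table)
  med <- apply(z, 2, stats::median, na.rm = TRUE)
  run <- run_pca(impute_median(z, med), sd_threshold = config$sd_threshold)
  run$normalizer <- norm
  run$train_medians <- med
  run$animal_id <- table$animal_id
  run
}

# One stratified training draw: round(frac * n_g) rows per group, at
# least 2 per stratum, without replacement.
draw_training_rows <- function(groups, frac, stratify = TRUE) {
  n <- length(groups)
  if (!stratify || !length(unique(groups))) {
    return(sort(sample.int(n, max(2L, round(frac * n)))))
  }
  idx <- unlist(lapply(split(seq_len(n), groups), function(rows) {
    take <- round(frac * length(rows))
    if (take < 2L) {
      stop("group stratum with ", length(rows),
           " row(s) yields a training stratum smaller than 2.", call. = FALSE)
    }
    sample(rows, take)
  }), use.names = FALSE)
  sort(idx)
}

#' Rank parameters by resampled PCA eigenvector loadings
#'
#' The core of the composite-measure-scheme procedure. For each of
#' `n_resamples` runs a random training subset (default 80% of the rows,
#' stratified by group) is drawn; the normalizer and PCA are fitted on
#' that subset; components with SD above the threshold are selected; and
#' within each selected component the parameters are ranked by absolute
#' loading, rank 1 being the largest. A parameter's primary rank in a
#' run is the rank of its peak single-component variance contribution
#' (eigenvalue times squared loading, maximised over the selected
#' components): a parameter that persistently anchors one strong
#' component ranks first run after run, while parameters whose high
#' loadings merely churn across sampling-noise components average out.
#' Primary ranks are averaged over runs into the per-parameter mean
#' rank and top-N membership counts; the per-component loading ranks of
#' every run are kept alongside.
#'
#' @param table A parameter table.
#' @param config A [study_config()]; `train_fraction`, `n_resamples`,
#'   `sd_threshold`, `stratify_resampling`, `freeze_components` are used.
#' @param seed Integer seed for the resampling stream; falls back to
#'   `config$seed`.
#' @param top_n Membership cut-off for the top-N count column (default 5).
#' @return A list of class `"ranking_result"`:
#'   \describe{
#'     \item{ranking}{tibble, one row per parameter, sorted by
#'       `mean_rank` (mean primary rank over resamples): `parameter`,
#'       `mean_rank`, `best_rank`, `mean_peak_contribution`,
#'       `top1_count`, `topn_count`, `n_units`, `mean_loading_rank`}
#'     \item{ranks}{long tibble of every (resample, component,
#'       parameter) per-component loading rank}
#'     \item{primary}{long tibble of the per-resample primary ranks and
#'       peak contributions}
#'     \item{run_log}{seed, train fraction, resample count,
#'       stratification, frozen component selection}
#'   }
#' @export
resampled_parameter_ranking <- function(table, config = study_config(),
                                        seed = NULL, top_n = 5L) {
  table <- as_parameter_table(table)
  pars <- parameter_names(table)
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)

  frozen_sel <- NULL
  if (config$freeze_components) {
    frozen_sel <- fit_reference_pca(table, config)$selected
  }

  runs <- purrr::map(seq_len(config$n_resamples), function(run_id) {
    rows <- draw_training_rows(table$group, config$train_fraction,
                               config$stratify_resampling)
    train <- table[rows, ]
    norm <- fit_normalizer(train)
    z <- apply_normalizer(norm, train)
    pca <- run_pca(z, sd_threshold = config$sd_threshold)
    sel <- frozen_sel %||% select_components(pca, config$sd_threshold)
    sel <- sel[sel <= ncol(pca$loadings)]
    # per-component loading ranks (rank 1 = largest |loading|)
    pc_ranks <- purrr::map_dfr(sel, function(pc) {
      load <- abs(pca$loadings[, pc])
      ord <- order(-load, names(load))
      tibble::tibble(resample = run_id, component = pc,
                     parameter = names(load)[ord],
                     rank = seq_along(ord))
    })
    # primary rank: peak single-component variance contribution
    # (eigenvalue x squared loading over the selected components)
    contrib <- sweep(pca$loadings[, sel, drop = FALSE]^2, 2,
                     pca$component_sds[sel]^2, "*")
    peak <- apply(contrib, 1, max)
    ordp <- order(-peak, names(peak))
    primary <- tibble::tibble(
      resample = run_id, parameter = names(peak)[ordp],
      peak_contribution = peak[ordp], run_rank = seq_along(ordp)
    )
    list(pc_ranks = pc_ranks, primary = primary)
  })
  ranks <- dplyr::bind_rows(purrr::map(runs, "pc_ranks"))
  primary <- dplyr::bind_rows(purrr::map(runs, "primary"))

  ranking <- primary |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      mean_rank = mean(.data$run_rank),
      best_rank = min(.data$run_rank),
      mean_peak_contribution = mean(.data$peak_contribution),
      top1_count = sum(.data$run_rank == 1L),
      topn_count = sum(.data$run_rank <= top_n),
      n_units = dplyr::n(),
      .groups = "drop"
    )
  mean_pc <- ranks |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(mean_loading_rank = mean(.data$rank), .groups = "drop")
  ranking <- ranking |>
    dplyr::left_join(mean_pc, by = "parameter") |>
    dplyr::arrange(.data$mean_rank, .data$parameter)
  # guarantee every input parameter appears even if never ranked
  missing_pars <- setdiff(pars, ranking$parameter)
  if (length(missing_pars)) {
    ranking <- dplyr::bind_rows(
      ranking,
      tibble::tibble(parameter = missing_pars, mean_rank = NA_real_,
                     best_rank = NA_integer_,
                     mean_peak_contribution = NA_real_,
                     top1_count = 0L, topn_count = 0L, n_units = 0L,
                     mean_loading_rank = NA_real_)
    )
  }
  structure(
    list(ranking = ranking, ranks = ranks, primary = primary,
         run_log = list(seed = seed, train_fraction = config$train_fraction,
                        n_resamples = config$n_resamples,
                        stratified = config$stratify_resampling,
                        frozen_components = frozen_sel,
                        top_n = as.integer(top_n))),
    class = "ranking_result"
  )
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("<ranking_result> %d parameters over %d resamples; top of the list:\n",
              nrow(x$ranking), x$run_log$n_resamples))
  print(utils::head(x$ranking, 5))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.ranking_result <- function(x, ...) x$ranking

#' Top-N slice of a parameter ranking
#'
#' @param result A [resampled_parameter_ranking()] result.
#' @param n Number of rows (default 30, the conventional report length).
#' @return The first `n` rows of the ranking tibble, sorted by mean rank.
#' @export
top_parameters <- function(result, n = 30L) {
  utils::head(result$ranking, n)
}
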