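# Composite severity scores: ranked sums of the selected principal
# components of a reference PCA, oriented so larger = more burdened.

# Mid-rank empirical CDF of `train` evaluated at `s`: (#below + half the
# ties) / n. A training point maps into (0, 1); values above the whole
# training set map to 1.
mid_ecdf <- function(train, s) {
  n <- length(train)
  vapply(s, function(v) {
    if (is.na(v)) return(NA_real_)
    (sum(train < v) + 0.5 * sum(train == v)) / n
  }, numeric(1))
}

#' Composite severity scores from a reference PCA
#'
#' Projects the animals onto the reference components, orients each
#' selected component so that its score correlates non-negatively with
#' the burden indicator (so larger always means more burdened), and
#' combines the selected components into one scalar score per animal.
#' The default `rank_sum` variant rank-normalizes each animal's component
#' score through the mid-rank empirical CDF of the reference (training)
#' scores and sums those fractions across selected components, giving a
#' score in `(0, m]` for `m` selected components; the `score_sum` variant
#' instead takes the variance-weighted sum of the oriented raw component
#' scores.
#'
#' @param table A parameter table of animals to score.
#' @param run A [fit_reference_pca()] result (carries the normalizer,
#'   training medians and training scores).
#' @param config A [study_config()]; `composite_variant` and, for
#'   orientation, `group_burden_map` are used.
#' @param pc_signs Optional explicit orientation signs (+1/-1), one per
#'   selected component, overriding the burden-anchored orientation.
#'   Required when no group in the table is mapped to a burden label.
#' @return A tibble of class `"composite_scores"`: `animal_id`, `model`,
#'   `group`, `composite`, plus one `pc<j>` column per selected
#'   component with the oriented component score. Attributes `variant`,
#'   `pc_signs` and `selected` record the construction.
#' @export
compute_composite_scores <- function(table, run, config = study_config(),
                                     pc_signs = NULL) {
  table <- as_parameter_table(table)
  sel <- run$selected
  if (!length(sel)) stop("reference run has no selected components.", call. = FALSE)

  z <- apply_normalizer(run$normalizer, table)
  z <- impute_median(z, run$train_medians)
  scores <- z %*% run$loadings[, sel, drop = FALSE]
  train_scores <- run$scores[, sel, drop = FALSE]

  if (is.null(pc_signs)) {
    gbm <- config$group_burden_map
    mapped <- names(gbm)[!vapply(gbm, identical, logical(1), "exclude")]
    if (!length(mapped)) {
      stop("no burden-labelled groups to anchor component orientation; ",
           "supply `pc_signs` explicitly.", call. = FALSE)
    }
    # orientation is anchored on the reference (training) animals
    train_tab <- table[match(run$animal_id, table$animal_id), , drop = FALSE]
    burden <- vapply(train_tab$group, function(g) {
      v <- gbm[[g]]
      if (is.null(v) || identical(v, "exclude")) NA_real_ else as.numeric(v)
    }, numeric(1))
    if (all(is.na(burden)) || length(unique(stats::na.omit(burden))) < 2L) {
      stop("burden indicator is constant or absent on the reference animals; ",
           "supply `pc_signs` explicitly.", call. = FALSE)
    }
    pc_signs <- vapply(seq_along(sel), function(j) {
      cc <- stats::cor(train_scores[, j], burden, use = "complete.obs")
      if (is.na(cc) || cc >= 0) 1 else -1
    }, numeric(1))
  }
  stopifnot(length(pc_signs) == length(sel), all(pc_signs %in% c(-1, 1)))

  oriented <- sweep(scores, 2, pc_signs, "*")
  oriented_train <- sweep(train_scores, 2, pc_signs, "*")

  composite <- switch(config$composite_variant,
    rank_sum = {
      fr <- vapply(seq_along(sel), function(j)
        mid_ecdf(oriented_train[, j], oriented[, j]), numeric(nrow(oriented)))
      rowSums(matrix(fr, nrow = nrow(oriented)))
    },
    score_sum = {
      w <- run$component_sds[sel]^2
      as.vector(oriented %*% (w / sum(w)))
    }
  )

  out <- tibble::tibble(
    animal_id = table$animal_id,
    model = table$model,
    group = table$group,
    composite = composite
  )
  pc_cols <- stats::setNames(as.data.frame(oriented),
                             paste0("pc", sel))
  out <- dplyr::bind_cols(out, tibble::as_tibble(pc_cols))
  attr(out, "variant") <- config$composite_variant
  attr(out, "pc_signs") <- pc_signs
  attr(out, "selected") <- sel
  class(out) <- c("composite_scores", class(out))
  out
}
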