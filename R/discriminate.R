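#' Build binary burden labels from the group mapping
#'
#' Maps each animal's group to the binary burden classifier: 1 = with
#' burden (e.g. treated/epileptic/mutant animals), 0 = without burden
#' (e.g. sham-operated or wild-type controls). Groups mapped to
#' `"exclude"` (typically naive, non-implanted animals) are left out of
#' ROC screening entirely. A group present in the table but absent from
#' the mapping is a hard error.
#'
#' @param table A parameter table.
#' @param config A [study_config()] whose `group_burden_map` covers every
#'   group in the table.
#' @return A list of class `"burden_labels"`: `labels` (tibble
#'   `animal_id`, `group`, `label`), `excluded` (animal ids), `mapping`
#'   (group -> label provenance tibble).
#' @export
make_burden_labels <- function(table, config) {
  table <- as_parameter_table(table)
  gbm <- config$group_burden_map
  missing_groups <- setdiff(unique(table$group), names(gbm))
  if (length(missing_groups)) {
    stop("group_burden_map has no entry for group(s): ",
         paste(missing_groups, collapse = ", "), call. = FALSE)
  }
  lab <- vapply(table$group, function(g) {
    v <- gbm[[g]]
    if (identical(v, "exclude")) NA_real_ else as.numeric(v)
  }, numeric(1))
  keep <- !is.na(lab)
  structure(
    list(
      labels = tibble::tibble(animal_id = table$animal_id[keep],
                              group = table$group[keep],
                              label = as.integer(lab[keep])),
      excluded = table$animal_id[!keep],
      mapping = tibble::tibble(group = names(gbm),
                               label = vapply(gbm, function(v)
                                 if (identical(v, "exclude")) "exclude"
                                 else as.character(v), character(1)))
    ),
    class = "burden_labels"
  )
}

# Mann-Whitney AUC by mid-ranks: (concordant + 0.5 * tied) / (n_pos * n_neg).
auc_rank <- function(scores, labels) {
  r <- rank(scores)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve and AUC for one parameter against the burden classifier
#'
#' The AUC is the Mann-Whitney probability that a randomly chosen
#' with-burden animal scores higher than a without-burden one, with ties
#' counted 0.5. The ROC curve enumerates every distinct score as a
#' threshold (predict burden when score >= threshold), running from
#' (0, 0) to (1, 1); its trapezoidal area equals the rank AUC.
#'
#' @param scores Numeric vector, one value per labelled animal (missing
#'   scores are dropped pairwise with a warning).
#' @param labels A `"burden_labels"` object, or an integer vector of 0/1
#'   aligned with `scores`.
#' @param parameter Optional parameter name carried into the result.
#' @param direction `"auto"` (default) reports `auc` for the
#'   larger-score-means-burden orientation and flags when the oriented
#'   AUC `max(auc, 1 - auc)` required flipping; `"greater"` fixes the
#'   larger-score orientation, `"less"` the smaller-score orientation.
#' @return A list of class `"roc_result"`: `parameter`, `auc`,
#'   `auc_oriented`, `flipped`, `n_pos`, `n_neg`, and `curve` (tibble
#'   `fpr`, `tpr`, `threshold`).
#' @export
compute_auc <- function(scores, labels, parameter = NA_character_,
                        direction = c("auto", "greater", "less")) {
  direction <- match.arg(direction)
  if (inherits(labels, "burden_labels")) labels <- labels$labels$label
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length.", call. = FALSE)
  }
  keep <- !is.na(scores) & !is.na(labels)
  if (any(!keep)) {
    warning(sum(!keep), " animal(s) dropped for missing score/label.",
            call. = FALSE)
    scores <- scores[keep]; labels <- labels[keep]
  }
  if (!length(scores)) stop("no usable scores.", call. = FALSE)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both burden classes must be non-empty (n_pos = ", n_pos,
         ", n_neg = ", n_neg, ").", call. = FALSE)
  }
  auc <- auc_rank(scores, labels)
  if (direction == "less") {
    scores <- -scores
    auc <- 1 - auc
  }
  # curve: thresholds descending over distinct scores, rule score >= t
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[labels == 1L] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[labels == 0L] >= t), numeric(1))
  structure(
    list(parameter = parameter, auc = auc,
         auc_oriented = max(auc, 1 - auc),
         flipped = direction == "auto" && auc < 0.5,
         n_pos = n_pos, n_neg = n_neg,
         curve = tibble::tibble(fpr = fpr, tpr = tpr, threshold = thr)),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %s: AUC %.3f (oriented %.3f), %d pos / %d neg\n",
              if (is.na(x$parameter)) "scores" else x$parameter,
              x$auc, x$auc_oriented, x$n_pos, x$n_neg))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname tidiers
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(parameter = x$parameter, auc = x$auc,
                 auc_oriented = x$auc_oriented, flipped = x$flipped,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Per-parameter discriminatory screening
#'
#' Runs [compute_auc()] for every parameter (optionally within each
#' model) against the configured burden classifier and returns one tidy
#' row per parameter.
#'
#' @param table A parameter table.
#' @param config A [study_config()] with a complete `group_burden_map`.
#' @param parameters Parameters to screen; defaults to all.
#' @param by_model Compute AUCs separately per `model`. Default `FALSE`.
#' @return A tibble: `model` (if `by_model`), `parameter`, `auc`,
#'   `auc_oriented`, `flipped`, `n_pos`, `n_neg`. The full curves are in
#'   the `roc` list-column.
#' @export
roc_screen <- function(table, config, parameters = NULL, by_model = FALSE) {
  table <- as_parameter_table(table)
  pars <- parameters %||% parameter_names(table)
  chunks <- if (by_model) split(table, table$model) else list(all = table)
  purrr::imap_dfr(chunks, function(tab, model_name) {
    lab <- make_burden_labels(tab, config)
    included <- tab[tab$animal_id %in% lab$labels$animal_id, ]
    labels <- lab$labels$label[match(included$animal_id, lab$labels$animal_id)]
    purrr::map_dfr(pars, function(pp) {
      res <- suppressWarnings(compute_auc(included[[pp]], labels, parameter = pp))
      out <- glance.roc_result(res)
      out$roc <- list(res)
      out
    }) |>
      dplyr::mutate(model = if (by_model) model_name else NA_character_,
                    .before = 1)
  })
}
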