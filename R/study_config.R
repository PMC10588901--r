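#' Study configuration for a composite-measure-scheme run
#'
#' Collects every tunable of the severity-assessment workflow in one
#' validated object: the group-to-burden mapping used for ROC screening,
#' manual parameter exclusions, correlation cut-offs, the missingness
#' cut-off for preselection, the resampled-PCA settings and the
#' severity-cluster settings.
#'
#' @param group_burden_map Named list or vector mapping each group label to
#'   `0` (without burden), `1` (with burden) or `"exclude"` (left out of ROC
#'   screening, e.g. naive non-implanted groups).
#' @param exclusion_list Named character vector of manual parameter
#'   exclusions: names are parameter names, values are free-text reasons
#'   (e.g. `c(body_weight = "strain differences")`). An unnamed character
#'   vector is accepted; reasons default to `"manual"`.
#' @param groups Optional character vector declaring the allowed group
#'   labels. When given, `load_table()` rejects unknown labels.
#' @param r_significant Absolute Spearman coefficient above which a pair is
#'   flagged significant (strict `>`). Default 0.5.
#' @param r_redundant Absolute Spearman coefficient above which a pair is
#'   flagged redundant (strict `>`). Default 0.7.
#' @param p_cut Two-sided p-value below which a correlation counts
#'   (strict `<`). Default 0.05.
#' @param missingness_cut Fraction of missing values above which a
#'   parameter is removed in preselection (strict `>`). Default 0.2.
#' @param train_fraction Fraction of rows drawn (without replacement) into
#'   each training set of the resampled PCA. Default 0.8.
#' @param n_resamples Number of training resamples for the PCA ranking.
#'   Default 100.
#' @param sd_threshold Principal components with standard deviation
#'   strictly greater than this are retained. Default 1.
#' @param cluster_k Number of severity clusters. `NULL` defers to
#'   [suggest_k()].
#' @param cluster_resamples Number of bootstrap resamples for the cluster
#'   thresholds. Default 100.
#' @param ci_level Confidence level for the threshold confidence borders.
#'   Default 0.95.
#' @param stratify_resampling Stratify the 80% training draws by group so a
#'   small group can never be emptied. Default `TRUE`.
#' @param freeze_components Select components once from a full-data fit and
#'   reuse that selection in every resample, instead of re-selecting per
#'   resample. Default `FALSE`.
#' @param composite_variant `"rank_sum"` (empirical-CDF ranked sums over the
#'   selected components, the default) or `"score_sum"`
#'   (variance-weighted sum of oriented component scores).
#' @param holm_adjust Apply a Holm adjustment to correlation p-values
#'   before flagging. Default `FALSE` (raw cut-offs).
#' @param seed Integer seed recorded with the run; stages derive their own
#'   streams from it.
#'
#' @return A list of class `"study_config"`.
#' @examples
#' cfg <- study_config(
#'   group_burden_map = list(naive = "exclude", sham = 0, treated = 1),
#'   cluster_k = 6, seed = 1
#' )
#' cfg$r_redundant
#' @export
study_config <- function(group_burden_map = list(),
                         exclusion_list = character(),
                         groups = NULL,
                         r_significant = 0.5,
                         r_redundant = 0.7,
                         p_cut = 0.05,
                         missingness_cut = 0.2,
                         train_fraction = 0.8,
                         n_resamples = 100L,
                         sd_threshold = 1,
                         cluster_k = NULL,
                         cluster_resamples = 100L,
                         ci_level = 0.95,
                         stratify_resampling = TRUE,
                         freeze_components = FALSE,
                         composite_variant = c("rank_sum", "score_sum"),
                         holm_adjust = FALSE,
                         seed = NULL) {
  composite_variant <- match.arg(composite_variant)
  stopifnot(
    r_significant > 0, r_redundant > 0, p_cut > 0,
    missingness_cut >= 0, missingness_cut <= 1,
    train_fraction > 0, train_fraction <= 1,
    n_resamples >= 1, sd_threshold > 0,
    cluster_resamples >= 1, ci_level > 0, ci_level < 1
  )
  if (!is.null(cluster_k) && cluster_k < 1) {
    stop("`cluster_k` must be >= 1.", call. = FALSE)
  }
  gbm <- as.list(group_burden_map)
  bad <- names(gbm)[!vapply(gbm, function(v)
    identical(v, 0) || identical(v, 1) || identical(v, 0L) ||
      identical(v, 1L) || identical(v, "exclude"), logical(1))]
  if (length(bad)) {
    stop("`group_burden_map` values must be 0, 1 or \"exclude\"; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  excl <- exclusion_list
  if (length(excl) && is.null(names(excl))) {
    excl <- stats::setNames(rep("manual", length(excl)), excl)
  } else if (length(excl)) {
    excl <- stats::setNames(as.character(excl), names(excl))
  }
  structure(
    list(
      group_burden_map = gbm,
      exclusion_list = excl,
      groups = groups,
      r_significant = r_significant,
      r_redundant = r_redundant,
      p_cut = p_cut,
      missingness_cut = missingness_cut,
      train_fraction = train_fraction,
      n_resamples = as.integer(n_resamples),
      sd_threshold = sd_threshold,
      cluster_k = if (is.null(cluster_k)) NULL else as.integer(cluster_k),
      cluster_resamples = as.integer(cluster_resamples),
      ci_level = ci_level,
      stratify_resampling = isTRUE(stratify_resampling),
      freeze_components = isTRUE(freeze_components),
      composite_variant = composite_variant,
      holm_adjust = isTRUE(holm_adjust),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "study_config"
  )
}

#' Read a study configuration from YAML or JSON
#'
#' The file mirrors the arguments of [study_config()]; unknown keys are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `"study_config"` object.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- names(formals(study_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$exclusion_list) && is.list(raw$exclusion_list)) {
    raw$exclusion_list <- unlist(raw$exclusion_list)
  }
  do.call(study_config, raw)
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat("  groups mapped:", length(x$group_burden_map),
      "| manual exclusions:", length(x$exclusion_list), "\n")
  cat("  correlation cut-offs: |r| >", x$r_significant, "(significant), >",
      x$r_redundant, "(redundant), p <", x$p_cut, "\n")
  cat("  preselection: remove if missing fraction >", x$missingness_cut, "\n")
  cat("  resampled PCA:", x$n_resamples, "runs of",
      paste0(round(100 * x$train_fraction), "%"),
      "training draws, keep components with SD >", x$sd_threshold, "\n")
  cat("  clustering: k =", if (is.null(x$cluster_k)) "(suggest)" else x$cluster_k,
      "|", x$cluster_resamples, "bootstrap resamples | CI level", x$ci_level, "\n")
  invisible(x)
}
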