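# End-to-end composite-measure-scheme workflow: preselection ->
# correlation pruning -> ROC screening -> resampled PCA ranking ->
# composite scores -> severity clustering -> allocation.

# Per-stage seed derived from the global seed and the stage name, so a
# stage can be re-run on its own and still reproduce.
stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

#' Run the full severity-assessment workflow
#'
#' Executes the complete composite-measure-scheme pipeline on one or
#' more parameter tables: combine, preselect (missingness + manual
#' exclusions), Spearman correlation with redundancy pruning, optional
#' per-parameter ROC screening against the burden classifier, the
#' resampled Box-Cox/PCA parameter ranking, ranked-sum composite
#' severity scores, severity-cluster threshold fitting with bootstrap
#' confidence borders, per-animal assignment and group allocation
#' tables. Identical input, config and seed reproduce the report
#' bit for bit.
#'
#' @param tables A parameter table or list of tables ([combine_tables()]
#'   is applied, with dedupe on).
#' @param config A [study_config()].
#' @param keep_rules,manual_exclusions Passed to [prune_parameters()].
#' @param roc Run the ROC screening stage (needs a complete
#'   `group_burden_map`). Default `TRUE` when any group is mapped.
#' @param seed Overrides `config$seed`.
#' @return A list of class `"cms_report"` with elements `config`, `seed`,
#'   `combined`, `preselection`, `correlation`, `redundancy`, `pruned`,
#'   `auc` (or `NULL`), `reference_pca`, `ranking`, `composite`,
#'   `k_choice`, `cluster_model`, `assignments`, `allocation`,
#'   `timings`, `version`.
#' @export
run_workflow <- function(tables, config, keep_rules = character(),
                         manual_exclusions = character(),
                         roc = length(config$group_burden_map) > 0,
                         seed = NULL) {
  seed <- seed %||% config$seed
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage, start) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), start, units = "secs"))
  }
  with_stage <- function(stage, expr) {
    start <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("workflow stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    tick(stage, start)
    res
  }

  combined <- with_stage("combine", combine_tables(tables, dedupe = TRUE))
  presel <- with_stage("preselect", apply_preselection(combined, config))
  corr <- with_stage("correlate", spearman_matrix(presel$table))
  report <- with_stage("flag", flag_pairs(corr, config))
  pruned <- with_stage("prune",
                       prune_parameters(presel$table, report, keep_rules,
                                        manual_exclusions))
  auc_tab <- if (roc) {
    with_stage("roc", roc_screen(pruned$table, config))
  } else NULL

  ref <- with_stage("reference_pca", fit_reference_pca(pruned$table, config))
  ranking <- with_stage("ranking", {
    resampled_parameter_ranking(pruned$table, config,
                                seed = stage_seed(seed, "ranking"))
  })
  composite <- with_stage("composite",
                          compute_composite_scores(pruned$table, ref, config))
  k_choice <- with_stage("suggest_k", suggest_k(ref, config))
  cl <- with_stage("cluster",
                   fit_cluster_thresholds(composite, k_choice$k, config,
                                          seed = stage_seed(seed, "cluster")))
  assign <- with_stage("assign", assign_severity(composite, cl))
  alloc <- with_stage("allocate", allocation_table(assign, k = cl$k))

  structure(
    list(config = config, seed = seed, combined = combined,
         preselection = presel, correlation = corr, redundancy = pruned$report,
         pruned = pruned$table, auc = auc_tab, reference_pca = ref,
         ranking = ranking, composite = composite, k_choice = k_choice,
         cluster_model = cl, assignments = assign, allocation = alloc,
         timings = timings,
         total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
         version = as.character(utils::packageVersion("sevcms"))),
    class = "cms_report"
  )
}

#' @export
print.cms_report <- function(x, ...) {
  cat("<cms_report>\n")
  cat(sprintf("  %d animals, %d -> %d -> %d parameters (combined -> preselected -> pruned)\n",
              nrow(x$combined), length(parameter_names(x$combined)),
              length(x$preselection$retained), length(parameter_names(x$pruned))))
  cat(sprintf("  PCA: %d selected components; PC1 %.1f%% of variance\n",
              length(x$reference_pca$selected),
              100 * x$reference_pca$explained_fraction[1]))
  cat(sprintf("  clusters: k = %d (%s); seed %s; %.1fs total\n",
              x$cluster_model$k, x$k_choice$source,
              if (is.null(x$seed)) "unset" else x$seed, x$total_seconds))
  invisible(x)
}

#' @rdname tidiers
#' @export
glance.cms_report <- function(x, ...) {
  tibble::tibble(
    n_animals = nrow(x$combined),
    n_parameters_input = length(parameter_names(x$combined)),
    n_parameters_preselected = length(x$preselection$retained),
    n_parameters_pruned = length(parameter_names(x$pruned)),
    n_selected_components = length(x$reference_pca$selected),
    pc1_explained_pct = 100 * x$reference_pca$explained_fraction[1],
    k = x$cluster_model$k,
    seed = if (is.null(x$seed)) NA_integer_ else x$seed
  )
}

#' Write a workflow report bundle to disk
#'
#' Writes the standard CSV/JSON/figure bundle: correlation r and p
#' matrices, preselection ledger, redundancy drops, per-parameter AUC
#' table, component SD/explained-variance table, top-30 ranking,
#' composite scores, cluster thresholds with confidence borders,
#' allocation table, a JSON run summary, and the standard figures
#' (correlation heatmap, ROC curves, PC1-by-PC2 scatter, scree plot,
#' stacked allocation bars).
#'
#' @param report A [run_workflow()] result.
#' @param out_dir Output directory (created if absent).
#' @param figures Also write PNG figures. Default `TRUE`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir, figures = TRUE) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  paths <- character()
  put_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(tibble::as_tibble(df), p, na = "")
    paths <<- c(paths, p)
  }
  mat_df <- function(m) {
    tibble::as_tibble(as.data.frame(m), rownames = "parameter")
  }
  put_csv(mat_df(report$correlation$r), "correlation_r.csv")
  put_csv(mat_df(report$correlation$p), "correlation_p.csv")
  put_csv(tidy(report$preselection), "preselection.csv")
  put_csv(report$redundancy$dropped, "redundancy_dropped.csv")
  if (!is.null(report$auc)) {
    put_csv(dplyr::select(report$auc, -dplyr::any_of("roc")), "auc.csv")
  }
  put_csv(glance(report$reference_pca), "components.csv")
  put_csv(top_parameters(report$ranking, 30L), "ranking_top30.csv")
  put_csv(tibble::as_tibble(report$composite), "composite_scores.csv")
  put_csv(tidy(report$cluster_model), "cluster_thresholds.csv")
  put_csv(report$assignments, "assignments.csv")
  put_csv(report$allocation$wide, "allocation.csv")

  summary_path <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(
    list(
      version = report$version,
      seed = report$seed,
      glance = as.list(glance(report)),
      k_choice = report$k_choice,
      timings = report$timings,
      cluster_disclaimer = report$cluster_model$disclaimer
    ),
    summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  paths <- c(paths, summary_path)

  if (figures) {
    put_fig <- function(plot, name, width = 7, height = 5) {
      p <- file.path(out_dir, name)
      ggplot2::ggsave(p, plot, width = width, height = height, dpi = 150)
      paths <<- c(paths, p)
    }
    put_fig(plot_correlation_heatmap(report$correlation), "correlation_heatmap.png")
    if (!is.null(report$auc)) put_fig(plot_roc_curves(report$auc), "roc_curves.png")
    put_fig(plot_pca_scatter(report$reference_pca, report$pruned), "pca_scatter.png")
    put_fig(plot_scree(report$reference_pca), "scree.png")
    put_fig(plot_allocation(report$allocation), "allocation.png")
  }
  invisible(paths)
}

#' Validate config and data without computing
#'
#' Dry-run check used by the command-line wrapper: combines the tables,
#' checks the schema, group vocabulary and burden mapping, and reports
#' what the workflow would do.
#'
#' @inheritParams run_workflow
#' @return Invisibly, a list with the combined dimensions; errors
#'   describe any validation failure.
#' @export
validate_workflow_inputs <- function(tables, config) {
  combined <- combine_tables(tables, dedupe = TRUE)
  pars <- parameter_names(combined)
  if (!length(pars)) stop("no parameter columns found.", call. = FALSE)
  if (length(config$group_burden_map)) {
    missing_groups <- setdiff(unique(combined$group), names(config$group_burden_map))
    if (length(missing_groups)) {
      stop("group_burden_map misses group(s): ",
           paste(missing_groups, collapse = ", "), call. = FALSE)
    }
  }
  invisible(list(n_animals = nrow(combined), n_parameters = length(pars),
                 groups = unique(combined$group)))
}
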