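#' Per-parameter missingness fractions
#'
#' Fraction of animals with a missing value, per parameter. Fractions are
#' invariant to row order and to the values of observed cells.
#'
#' @param table A parameter table.
#' @return A tibble with columns `parameter` and `missingness` (fraction in
#'   `[0, 1]`), in table column order.
#' @export
compute_missingness <- function(table) {
  table <- as_parameter_table(table)
  if (nrow(table) == 0L) stop("table has no rows.", call. = FALSE)
  pars <- parameter_names(table)
  tibble::tibble(
    parameter = pars,
    missingness = unname(vapply(table[pars], function(x) mean(is.na(x)),
                                numeric(1)))
  )
}

#' Preselect parameters by data integrity and manual exclusion
#'
#' Removes every parameter whose missingness fraction strictly exceeds
#' `config$missingness_cut` (a parameter at exactly the cut-off is kept),
#' then removes the parameters on the config's manual exclusion list.
#' Rows (animals) are never dropped. Every removal is logged with its
#' reason and missingness fraction, so the preselection ledger accounts
#' for the full input inventory.
#'
#' @param table A parameter table.
#' @param config A [study_config()]; `missingness_cut` and
#'   `exclusion_list` are used.
#' @return A list with class `"preselection_result"`:
#'   \describe{
#'     \item{table}{the table restricted to retained parameters}
#'     \item{retained}{character vector of retained parameter names}
#'     \item{removed}{tibble `parameter`, `reason`
#'       (`"missingness"`/`"manual"`), `detail`, `missingness_fraction`}
#'     \item{missingness}{the full [compute_missingness()] tibble}
#'   }
#' @export
apply_preselection <- function(table, config = study_config()) {
  table <- as_parameter_table(table)
  miss <- compute_missingness(table)
  pars <- miss$parameter

  drop_missing <- miss$parameter[miss$missingness > config$missingness_cut]
  manual <- config$exclusion_list
  absent <- setdiff(names(manual), pars)
  if (length(absent)) {
    warning("exclusion_list names not present in table: ",
            paste(absent, collapse = ", "), call. = FALSE)
    manual <- manual[setdiff(names(manual), absent)]
  }
  drop_manual <- setdiff(names(manual), drop_missing)

  removed <- dplyr::bind_rows(
    tibble::tibble(parameter = drop_missing, reason = "missingness",
                   detail = sprintf("missing fraction > %g", config$missingness_cut)),
    tibble::tibble(parameter = drop_manual, reason = "manual",
                   detail = unname(manual[drop_manual]))
  )
  removed <- dplyr::left_join(removed, miss, by = "parameter")
  removed <- dplyr::rename(removed, missingness_fraction = "missingness")
  retained <- setdiff(pars, removed$parameter)
  if (!length(retained)) {
    stop("preselection removed every parameter; review missingness_cut and exclusion_list.",
         call. = FALSE)
  }
  out <- table[, c(meta_columns(), retained)]
  structure(
    list(table = as_parameter_table(out), retained = retained,
         removed = removed, missingness = miss),
    class = "preselection_result"
  )
}

#' @export
print.preselection_result <- function(x, ...) {
  cat(sprintf("<preselection> retained %d parameters, removed %d (%s)\n",
              length(x$retained), nrow(x$removed),
              if (nrow(x$removed)) paste0(
                sum(x$removed$reason == "missingness"), " missingness, ",
                sum(x$removed$reason == "manual"), " manual") else "none"))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.preselection_result <- function(x, ...) {
  dplyr::left_join(x$missingness, x$removed[c("parameter", "reason", "detail")],
                   by = "parameter") |>
    dplyr::mutate(retained = is.na(.data$reason))
}
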