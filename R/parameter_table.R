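#' @importFrom rlang .data
NULL

# Reserved metadata column names; every other column is a measured parameter.
.meta_cols <- c("animal_id", "model", "group", "age_bracket", "sex")

#' Metadata column names of a parameter table
#' @return Character vector of the reserved metadata column names.
#' @export
meta_columns <- function() .meta_cols

#' Parameter (non-metadata) columns of a table
#'
#' @param table A parameter table (tibble with an `animal_id` column).
#' @return Character vector of parameter column names, in table order.
#' @export
parameter_names <- function(table) {
  setdiff(names(table), .meta_cols)
}

#' Validate and canonicalise an animals-by-parameters table
#'
#' A parameter table is an ordinary tibble with one row per animal (or per
#' animal-by-timepoint record), the reserved metadata columns `animal_id`,
#' `model`, `group`, `age_bracket`, `sex`, and one numeric column per
#' measured parameter. Missing measurements are `NA`; they are never
#' treated as zero.
#'
#' @param df A data frame. Must contain `animal_id`; absent metadata
#'   columns are added (`sex` defaults to `"unknown"`, others to `NA`).
#' @param config Optional [study_config()]; when it declares a group
#'   vocabulary, unknown group labels are an error.
#' @return A tibble with metadata columns first, parameters after, class
#'   `"parameter_table"` prepended for printing.
#' @examples
#' as_parameter_table(tibble::tibble(
#'   animal_id = c("m1", "m2"), group = "sham",
#'   burrowing = c(90, 80), irwin = c(0, 2)
#' ))
#' @export
as_parameter_table <- function(df, config = NULL) {
  df <- tibble::as_tibble(df)
  if (!"animal_id" %in% names(df)) {
    stop("a parameter table needs an `animal_id` column.", call. = FALSE)
  }
  df$animal_id <- as.character(df$animal_id)
  dup <- unique(df$animal_id[duplicated(df$animal_id)])
  if (length(dup)) {
    stop("duplicate animal_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  for (m in setdiff(.meta_cols, names(df))) {
    df[[m]] <- if (m == "sex") "unknown" else NA_character_
  }
  df <- dplyr::relocate(df, dplyr::all_of(.meta_cols))
  pars <- parameter_names(df)
  not_num <- pars[!vapply(df[pars], is.numeric, logical(1))]
  if (length(not_num)) {
    stop("parameter columns must be numeric: ",
         paste(not_num, collapse = ", "), call. = FALSE)
  }
  if (!is.null(config) && !is.null(config$groups)) {
    bad <- setdiff(unique(stats::na.omit(df$group)), config$groups)
    if (length(bad)) {
      stop("unknown group label(s): ", paste(bad, collapse = ", "),
           "; allowed: ", paste(config$groups, collapse = ", "), call. = FALSE)
    }
  }
  class(df) <- unique(c("parameter_table", class(df)))
  df
}

#' Read an animals-by-parameters CSV/TSV file
#'
#' Reads a UTF-8, header-first, `.`-decimal CSV or TSV. The tokens `""`,
#' `"NA"` and `"NaN"` in parameter columns become missing values. A
#' non-numeric token in a parameter column is a hard error naming the row
#' and column, as is a duplicated `animal_id`.
#'
#' @param path File path; `.tsv`/`.tab`/`.txt` are read tab-separated,
#'   anything else comma-separated.
#' @inheritParams as_parameter_table
#' @return A validated parameter table (see [as_parameter_table()]).
#' @export
load_table <- function(path, config = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  reader <- if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) {
    readr::read_tsv
  } else {
    readr::read_csv
  }
  raw <- suppressWarnings(reader(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  ))
  na_tokens <- c("", "NA", "NaN")
  for (col in setdiff(names(raw), .meta_cols)) {
    x <- raw[[col]]
    x[x %in% na_tokens] <- NA_character_
    parsed <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(parsed))
    if (length(bad)) {
      stop(sprintf(
        "non-numeric value %s in parameter column '%s', data row %d",
        dQuote(x[bad[1]], q = FALSE), col, bad[1]
      ), call. = FALSE)
    }
    raw[[col]] <- parsed
  }
  for (col in intersect(names(raw), .meta_cols)) {
    raw[[col]][raw[[col]] %in% na_tokens] <- NA_character_
  }
  as_parameter_table(raw, config)
}

#' Write a parameter table to CSV
#'
#' Inverse of [load_table()]: `load_table(write_table(x, f))` is
#' value-identical to `x`, including missing cells.
#'
#' @param table A parameter table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path, na = "")
  invisible(path)
}

#' Combine several parameter tables into one data set
#'
#' Takes the union of parameter columns; a cell absent from a source table
#' is missing in the combined table. With `dedupe = TRUE` an animal
#' appearing in several tables (e.g. a naive group shared between two
#' subprojects) is kept once: its metadata must agree across appearances
#' (a conflict is a hard error) and its parameter cells are merged by
#' coalescing, so disjoint measurements from different tables line up on
#' one row.
#'
#' @param tables A list of parameter tables (a single table is accepted).
#' @param dedupe Collapse records sharing an `animal_id`. Default `TRUE`.
#' @return A combined parameter table.
#' @examples
#' a <- as_parameter_table(tibble::tibble(animal_id = c("n1", "k1"),
#'                                        group = c("naive", "treated"),
#'                                        irwin = c(0, 4)))
#' b <- as_parameter_table(tibble::tibble(animal_id = c("n1", "h1"),
#'                                        group = c("naive", "treated"),
#'                                        burrowing = c(95, 20)))
#' combine_tables(list(a, b))
#' @export
combine_tables <- function(tables, dedupe = TRUE) {
  if (inherits(tables, "data.frame")) tables <- list(tables)
  tables <- Filter(Negate(is.null), tables)
  if (!length(tables)) stop("no tables to combine.", call. = FALSE)
  tables <- lapply(tables, as_parameter_table)
  combined <- dplyr::bind_rows(lapply(tables, tibble::as_tibble))
  if (dedupe && anyDuplicated(combined$animal_id)) {
    ids <- unique(combined$animal_id)
    merged <- lapply(ids, function(id) {
      rows <- combined[combined$animal_id == id, , drop = FALSE]
      if (nrow(rows) == 1L) return(rows)
      for (m in setdiff(.meta_cols, "animal_id")) {
        vals <- unique(stats::na.omit(rows[[m]]))
        vals <- setdiff(vals, "unknown")
        if (length(vals) > 1L) {
          stop(sprintf(
            "conflicting metadata for animal_id '%s': %s has values {%s}",
            id, m, paste(vals, collapse = ", ")
          ), call. = FALSE)
        }
      }
      out <- rows[1, , drop = FALSE]
      for (col in names(rows)) {
        v <- rows[[col]]
        obs <- v[!is.na(v) & !(col == "sex" & v == "unknown")]
        if (length(unique(obs)) > 1L && !(col %in% .meta_cols)) {
          warning(sprintf(
            "animal_id '%s': conflicting values for parameter '%s'; keeping the first.",
            id, col
          ), call. = FALSE)
          obs <- obs[1]
        }
        if (length(obs)) out[[col]] <- obs[1]
      }
      out
    })
    combined <- dplyr::bind_rows(merged)
  }
  as_parameter_table(combined)
}

#' @export
print.parameter_table <- function(x, ...) {
  pars <- parameter_names(x)
  cat(sprintf("# A parameter table: %d animals x %d parameters\n",
              nrow(x), length(pars)))
  NextMethod()
}

# Numeric matrix view (animals x parameters), rownames = animal_id.
param_matrix <- function(table, parameters = parameter_names(table)) {
  m <- as.matrix(tibble::as_tibble(table)[parameters])
  storage.mode(m) <- "double"
  rownames(m) <- table$animal_id
  m
}
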