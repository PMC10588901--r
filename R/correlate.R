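# Spearman correlation with tie-aware mid-ranks, pairwise-complete
# observations, and exact permutation p-values at small n.

# All permutations of 1..n as an (n! x n) matrix; n <= 9 in practice.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Spearman correlation of one pair
#'
#' Tie-corrected Spearman coefficient: the product-moment correlation of
#' the two mid-rank vectors, computed on complete pairs only.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list: `rho`, `n` (complete pairs), `defined` (`FALSE` when
#'   fewer than 3 complete pairs or a constant vector makes the
#'   coefficient undefined).
#' @export
spearman_rho <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) return(list(rho = NA_real_, n = n, defined = FALSE))
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, n = n, defined = FALSE))
  }
  list(rho = stats::cor(rx, ry), n = n, defined = TRUE)
}

#' Exact permutation p-value for a Spearman correlation
#'
#' Enumerates all `n!` assignments of one variable's ranks against the
#' other and reports the proportion of permutations whose Spearman
#' coefficient is at least as extreme as the observed one. Tie patterns
#' are preserved because observed mid-ranks are permuted. Intended for
#' small samples (`n <= 8`, at most `40320` permutations).
#'
#' @param x,y Numeric vectors of equal length; incomplete pairs dropped.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return The exact p-value.
#' @examples
#' spearman_exact_p(1:3, 1:3, alternative = "greater") # 1/6
#' @export
spearman_exact_p <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  if (n > 8L) stop("exact enumeration is limited to n <= 8.", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  obs <- stats::cor(rx, ry)
  perms <- all_permutations(n)
  rxc <- (rx - mean(rx)) / (stats::sd(rx) * sqrt(n - 1))
  ryc <- (ry - mean(ry)) / (stats::sd(ry) * sqrt(n - 1))
  rho_all <- as.vector(matrix(ryc[perms], nrow(perms), n) %*% rxc)
  eps <- 1e-12
  switch(alternative,
    two.sided = mean(abs(rho_all) >= abs(obs) - eps),
    greater   = mean(rho_all >= obs - eps),
    less      = mean(rho_all <= obs + eps)
  )
}

# Two-sided p for rho: exact enumeration at n <= 8, else t approximation.
spearman_p <- function(rho, n, x = NULL, y = NULL) {
  if (is.na(rho) || n < 3L) return(NA_real_)
  if (n <= 8L && !is.null(x)) return(spearman_exact_p(x, y))
  if (abs(rho) >= 1) return(0)
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}

#' Pairwise Spearman correlation matrix with p-values
#'
#' Computes tie-corrected (mid-rank) Spearman coefficients for every
#' parameter pair on pairwise-complete observations, with two-sided
#' p-values from the large-sample t approximation, replaced by exact
#' permutation enumeration when a pair has 8 or fewer complete
#' observations. Pairs with fewer than 3 complete observations, or with a
#' constant column, are undefined: flagged `NA` rather than propagated.
#'
#' @param table A parameter table.
#' @param parameters Optional subset of parameter names.
#' @return A list of class `"correlation_result"` with symmetric matrices
#'   `r` (unit diagonal) and `p`, and `n_pairs` (complete observations per
#'   pair).
#' @export
spearman_matrix <- function(table, parameters = NULL) {
  table <- as_parameter_table(table)
  pars <- parameters %||% parameter_names(table)
  m <- param_matrix(table, pars)
  p <- length(pars)
  r_mat <- matrix(NA_real_, p, p, dimnames = list(pars, pars))
  p_mat <- r_mat
  n_mat <- matrix(0L, p, p, dimnames = list(pars, pars))
  diag(r_mat) <- 1
  diag(p_mat) <- 0
  diag(n_mat) <- colSums(!is.na(m))
  if (p >= 2) {
    for (i in 1:(p - 1)) {
      for (j in (i + 1):p) {
        fit <- spearman_rho(m[, i], m[, j])
        n_mat[i, j] <- n_mat[j, i] <- fit$n
        if (fit$defined) {
          ok <- stats::complete.cases(m[, i], m[, j])
          r_mat[i, j] <- r_mat[j, i] <- fit$rho
          p_mat[i, j] <- p_mat[j, i] <-
            spearman_p(fit$rho, fit$n, m[ok, i], m[ok, j])
        }
      }
    }
  }
  structure(list(r = r_mat, p = p_mat, n_pairs = n_mat),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %d parameters, %d defined pairs\n",
              ncol(x$r), sum(!is.na(x$r[upper.tri(x$r)]))))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.correlation_result <- function(x, ...) {
  pars <- colnames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    parameter_1 = pars[idx[, 1]],
    parameter_2 = pars[idx[, 2]],
    r = x$r[idx],
    p = x$p[idx],
    n = x$n_pairs[idx]
  )
}

#' Flag significant and redundant parameter pairs
#'
#' A pair is significant when `|r|` strictly exceeds the significance
#' cut-off and `p` falls strictly below the p cut-off; redundant when
#' `|r|` strictly exceeds the (higher) redundancy cut-off under the same p
#' gate. With the default cut-offs (0.5 / 0.7 / 0.05) every redundant pair
#' is also significant.
#'
#' @param corr A [spearman_matrix()] result.
#' @param config A [study_config()]; cut-offs and `holm_adjust` are used.
#' @return A list of class `"redundancy_report"` with `pairs` (long tibble
#'   with `significant`/`redundant` flags), `significant_pairs`,
#'   `redundant_pairs`, and an empty `dropped` ledger filled by
#'   [prune_parameters()].
#' @export
flag_pairs <- function(corr, config = study_config()) {
  pairs <- tidy.correlation_result(corr)
  p_use <- if (config$holm_adjust) stats::p.adjust(pairs$p, "holm") else pairs$p
  pairs$p_adjusted <- if (config$holm_adjust) p_use else NA_real_
  pairs$significant <- !is.na(pairs$r) &
    abs(pairs$r) > config$r_significant & p_use < config$p_cut
  pairs$redundant <- !is.na(pairs$r) &
    abs(pairs$r) > config$r_redundant & p_use < config$p_cut
  structure(
    list(
      pairs = pairs,
      significant_pairs = pairs[pairs$significant, ],
      redundant_pairs = pairs[pairs$redundant, ],
      dropped = tibble::tibble(parameter = character(), partner = character(),
                               rule = character(), r = numeric())
    ),
    class = "redundancy_report"
  )
}

#' @export
print.redundancy_report <- function(x, ...) {
  cat(sprintf("<redundancy_report> %d significant, %d redundant pairs, %d parameters dropped\n",
              nrow(x$significant_pairs), nrow(x$redundant_pairs), nrow(x$dropped)))
  invisible(x)
}

#' Prune redundant parameters under keep-rules
#'
#' Iteratively removes parameters until no remaining pair is redundant.
#' At each step, among parameters involved in a redundant pair, the one
#' to drop is chosen by (in order): lowest preference under `keep_rules`
#' (an ordered list of parameter names to prefer keeping; unlisted
#' parameters rank below all listed ones), then highest total `|r|` over
#' its remaining redundant partners (the hub of a redundancy chain goes
#' first), then reverse-lexicographic name order. Manual post-correlation
#' exclusions are applied afterwards with their stated reason.
#'
#' @param table A parameter table.
#' @param report A [flag_pairs()] report for this table.
#' @param keep_rules Ordered character vector of parameters to prefer
#'   keeping (earlier = stronger preference). Names absent from the table
#'   draw a warning.
#' @param manual_exclusions Named character vector: parameter name ->
#'   reason, removed regardless of redundancy (e.g. a lower-sensitivity
#'   variant of a retained assay).
#' @return A list: `table` (pruned), `report` (the input report with its
#'   `dropped` ledger filled).
#' @export
prune_parameters <- function(table, report, keep_rules = character(),
                             manual_exclusions = character()) {
  table <- as_parameter_table(table)
  pars <- parameter_names(table)
  unknown <- setdiff(keep_rules, pars)
  if (length(unknown)) {
    warning("keep_rules name unknown parameters: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  pref <- match(pars, keep_rules)           # NA = unlisted = least preferred
  pref[is.na(pref)] <- length(keep_rules) + 1L
  names(pref) <- pars

  red <- report$redundant_pairs
  remaining <- pars
  dropped <- list()
  repeat {
    live <- red[red$parameter_1 %in% remaining & red$parameter_2 %in% remaining, ]
    if (!nrow(live)) break
    members <- unique(c(live$parameter_1, live$parameter_2))
    # total |r| over live redundant partners, per member
    deg <- vapply(members, function(pp)
      sum(abs(live$r[live$parameter_1 == pp | live$parameter_2 == pp])),
      numeric(1))
    cand <- members[pref[members] == max(pref[members])]
    rule <- if (length(cand) < length(members)) "keep_rule" else "total_abs_r"
    if (length(cand) > 1L) {
      tied <- cand[deg[cand] == max(deg[cand])]
      if (length(tied) < length(cand)) rule <- "total_abs_r"
      cand <- tied
    }
    if (length(cand) > 1L) {
      cand <- sort(cand, decreasing = TRUE)[1]
      rule <- "lexicographic"
    }
    drop <- cand
    part <- live[live$parameter_1 == drop | live$parameter_2 == drop, ]
    partner <- ifelse(part$parameter_1 == drop, part$parameter_2, part$parameter_1)
    dropped[[length(dropped) + 1L]] <- tibble::tibble(
      parameter = drop, partner = partner[which.max(abs(part$r))],
      rule = rule, r = part$r[which.max(abs(part$r))]
    )
    remaining <- setdiff(remaining, drop)
  }

  manual <- manual_exclusions[names(manual_exclusions) %in% remaining]
  if (length(manual)) {
    dropped[[length(dropped) + 1L]] <- tibble::tibble(
      parameter = names(manual), partner = NA_character_,
      rule = paste0("manual: ", unname(manual)), r = NA_real_
    )
    remaining <- setdiff(remaining, names(manual))
  }
  report$dropped <- if (length(dropped)) dplyr::bind_rows(dropped) else report$dropped
  out <- table[, c(meta_columns(), remaining)]
  list(table = as_parameter_table(out), report = report)
}
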