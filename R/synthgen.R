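# Synthetic severity-assessment data with planted ground truth: group
# mean shifts on informative parameters, block-correlated noise,
# optional lognormal margins and MCAR missingness.

#' Specify a synthetic severity-assessment dataset
#'
#' Describes a multi-group animals-by-parameters dataset with known
#' ground truth: which parameters are informative (carry group mean
#' shifts on the standardized latent scale), which parameters are
#' mutually correlated (equicorrelated blocks built from a shared latent
#' factor), which have lognormal margins (to exercise the Box-Cox
#' stage), and the completely-at-random missingness rate.
#'
#' @param groups A data frame with columns `label`, `burden` (0, 1 or
#'   `"exclude"`) and `size` (>= 2), one row per group.
#' @param n_parameters Total number of parameters (named `p01`, `p02`,
#'   ...).
#' @param effects Named list: parameter name -> named numeric vector of
#'   per-group standardized mean shifts (groups absent from a vector
#'   shift by 0). Parameters named here are the informative set.
#' @param correlation_blocks List of integer vectors of parameter
#'   indices; within a block, every pair has correlation `rho`.
#' @param rho Within-block correlation, one value per block (recycled).
#'   Must lie in `[0, 1)` for the shared-factor construction.
#' @param lognormal Parameter names (or indices) whose observed values
#'   are `exp()` of the latent normal scale.
#' @param missing_rate MCAR missingness fraction in `[0, 0.5]`.
#' @param age_brackets Optional character vector of age-bracket labels
#'   cycled over animals within each group.
#' @param model Model label stamped on every record.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(groups,
                           n_parameters = 15L,
                           effects = list(),
                           correlation_blocks = list(),
                           rho = 0.6,
                           lognormal = character(),
                           missing_rate = 0,
                           age_brackets = NULL,
                           model = "synthetic") {
  groups <- tibble::as_tibble(groups)
  stopifnot(all(c("label", "burden", "size") %in% names(groups)),
            all(groups$size >= 2),
            missing_rate >= 0, missing_rate <= 0.5)
  rho <- rep_len(rho, max(length(correlation_blocks), 1L))
  if (length(correlation_blocks) && any(rho < 0 | rho >= 1)) {
    stop("within-block rho must lie in [0, 1) for the shared-factor construction.",
         call. = FALSE)
  }
  par_names <- sprintf("p%02d", seq_len(n_parameters))
  effects <- lapply(effects, function(v) unlist(v))   # accept nested lists (YAML)
  eff_names <- names(effects)
  idx <- suppressWarnings(as.integer(eff_names))
  names(effects) <- ifelse(!is.na(idx), par_names[idx], eff_names)
  if (!all(names(effects) %in% par_names)) {
    stop("effects name unknown parameters: ",
         paste(setdiff(names(effects), par_names), collapse = ", "), call. = FALSE)
  }
  if (is.numeric(lognormal)) lognormal <- par_names[lognormal]
  structure(
    list(groups = groups, n_parameters = as.integer(n_parameters),
         parameters = par_names, effects = effects,
         correlation_blocks = correlation_blocks, rho = rho,
         lognormal = lognormal, missing_rate = missing_rate,
         age_brackets = age_brackets, model = model),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic dataset with ground truth
#'
#' Draws the dataset described by a [synthetic_spec()]. Correlated blocks
#' use the shared-factor construction `x = sqrt(rho) f + sqrt(1 - rho) e`
#' (unit variance, pairwise correlation `rho` within the block); group
#' shifts are added on the latent standardized scale, so for a normal
#' parameter with shift difference `d` between the burdened and control
#' class the expected AUC is `pnorm(d / sqrt(2))` — a closed form the
#' ground-truth object carries for every parameter. Lognormal parameters
#' exponentiate the latent value, which leaves AUCs and Spearman
#' correlations unchanged (both are rank statistics). Missing cells are
#' planted completely at random.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; same seed, same dataset, bit for bit.
#' @return A list: `table` (a parameter table), `truth` (a list:
#'   `informative`, `severity_order` — group labels by ascending planted
#'   mean burden —, `expected_auc` tibble, `missing_mask`).
#' @export
generate_dataset <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  g <- spec$groups
  n <- sum(g$size)
  p <- spec$n_parameters
  group_of <- rep(g$label, g$size)

  # latent standardized draws with block correlation
  e <- matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, spec$parameters))
  x <- e
  if (length(spec$correlation_blocks)) {
    for (b in seq_along(spec$correlation_blocks)) {
      block <- spec$correlation_blocks[[b]]
      r <- spec$rho[b]
      f <- stats::rnorm(n)
      x[, block] <- sqrt(r) * f + sqrt(1 - r) * e[, block]
    }
  }
  # planted group shifts on informative parameters
  shift_mat <- matrix(0, nrow(g), p, dimnames = list(g$label, spec$parameters))
  for (pp in names(spec$effects)) {
    sh <- spec$effects[[pp]]
    shift_mat[names(sh), pp] <- sh
  }
  x <- x + shift_mat[group_of, , drop = FALSE]
  # margins
  for (pp in spec$lognormal) x[, pp] <- exp(x[, pp])
  # MCAR missingness
  mask <- matrix(stats::runif(n * p) < spec$missing_rate, n, p,
                 dimnames = list(NULL, spec$parameters))
  x[mask] <- NA_real_

  table <- dplyr::bind_cols(
    tibble::tibble(
      animal_id = sprintf("a%04d", seq_len(n)),
      model = spec$model,
      group = group_of,
      age_bracket = if (is.null(spec$age_brackets)) NA_character_ else
        as.character(unlist(lapply(g$size, function(s)
          rep_len(spec$age_brackets, s)))),
      sex = "unknown"
    ),
    tibble::as_tibble(x)
  )

  # expected AUC per parameter: mixture of pairwise binormal AUCs
  pos <- g[g$burden %in% c(1, "1"), ]
  neg <- g[g$burden %in% c(0, "0"), ]
  expected_auc <- tibble::tibble(parameter = spec$parameters,
                                 expected_auc = NA_real_)
  if (nrow(pos) && nrow(neg)) {
    expected_auc$expected_auc <- unname(vapply(spec$parameters, function(pp) {
      num <- 0; den <- 0
      for (i in seq_len(nrow(pos))) for (j in seq_len(nrow(neg))) {
        w <- pos$size[i] * neg$size[j]
        d <- shift_mat[pos$label[i], pp] - shift_mat[neg$label[j], pp]
        num <- num + w * stats::pnorm(d / sqrt(2))
        den <- den + w
      }
      num / den
    }, numeric(1)))
  }
  planted_burden <- if (length(spec$effects)) {
    rowMeans(shift_mat[, names(spec$effects), drop = FALSE])
  } else {
    stats::setNames(rep(0, nrow(g)), g$label)
  }
  severity_order <- g$label[order(planted_burden[g$label])]

  list(
    table = as_parameter_table(table),
    truth = list(
      informative = names(spec$effects),
      severity_order = severity_order,
      expected_auc = expected_auc,
      missing_mask = mask,
      shifts = shift_mat
    )
  )
}
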