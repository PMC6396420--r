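#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fetal-fraction profile
#'
#' One row per template length with the labelled counts and the per-length
#' fetal fraction.
#'
#' @param x A `nipgeno_ff_profile`.
#' @param ... Ignored.
#' @return A tibble (`tlen`, `count_fetal`, `count_shared`, `ff`).
#' @exportS3Method generics::tidy
tidy.nipgeno_ff_profile <- function(x, ...) x$table

#' One-row summary of a fetal-fraction profile
#'
#' @param x A `nipgeno_ff_profile`.
#' @param ... Ignored.
#' @return A one-row tibble: total fraction, labelled counts, estimator
#'   settings.
#' @exportS3Method generics::glance
glance.nipgeno_ff_profile <- function(x, ...) {
  tibble(
    total_ff = x$total_ff, a = x$a, b = x$b,
    n_bins_estimated = sum(x$table$count_fetal + x$table$count_shared >=
                             x$min_count),
    min_count = x$min_count, max_tlen = x$max_tlen,
    method = x$method, fixed = x$fixed
  )
}

#' Tidy a recalibration model
#'
#' Feature importances of the underlying forest, sorted descending.
#'
#' @param x A `nipgeno_recal_model`.
#' @param ... Ignored.
#' @return A tibble (`feature`, `importance`).
#' @exportS3Method generics::tidy
tidy.nipgeno_recal_model <- function(x, ...) {
  imp <- ranger::importance(x$fit)
  if (length(imp) == 0L) {
    return(tibble(feature = character(), importance = numeric()))
  }
  tibble(feature = names(imp), importance = unname(imp)) |>
    arrange(dplyr::desc(.data$importance))
}

#' One-row summary of a recalibration model
#'
#' @param x A `nipgeno_recal_model`.
#' @param ... Ignored.
#' @return A one-row tibble: target category and type, pooling strategy,
#'   sizes and held-out AUC.
#' @exportS3Method generics::glance
glance.nipgeno_recal_model <- function(x, ...) {
  tibble(
    category = x$category, var_type = x$var_type, strategy = x$strategy,
    num_trees = x$num_trees, n_train = x$n_train, n_holdout = x$n_holdout,
    holdout_auc = x$holdout_auc
  )
}
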