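#' Post-hoc depth and posterior-probability filters
#'
#' The caller itself applies only lenient pre-filters; confidence filtering is
#' post hoc. This keeps calls whose cfDNA depth lies in
#' `[min_depth, max_depth]` and whose maximum posterior exceeds `min_pp`
#' (all optional).
#'
#' @param results Posterior tibble from [genotype_all()].
#' @param min_depth,max_depth Inclusive depth bounds on `n_obs`; `NULL`
#'   disables a bound.
#' @param min_pp Minimum of the called genotype's posterior (strict `>`);
#'   `NULL` disables.
#' @return Filtered tibble, with an attribute `"n_removed"`.
#' @export
filter_calls <- function(results, min_depth = NULL, max_depth = NULL,
                         min_pp = NULL) {
  keep <- rep(TRUE, nrow(results))
  if (!is.null(min_depth)) keep <- keep & results$n_obs >= min_depth
  if (!is.null(max_depth)) keep <- keep & results$n_obs <= max_depth
  if (!is.null(min_pp)) {
    pp <- pmax(results$q00, results$q01, results$q11)
    keep <- keep & pp > min_pp
  }
  out <- results[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Evaluate calls against a truth table, per category
#'
#' Accuracy is the fraction of sites whose called genotype matches the truth.
#' The ROC-AUC scores the heterozygosity decision: for single-parent
#' heterozygous categories the binary outcome is het vs. hom fetus, and for
#' double-heterozygous sites het vs. either homozygote; both are scored by the
#' heterozygous posterior `q01`. Baseline accuracies are 0.5 for the
#' single-parent categories and 1/3 for double-heterozygous sites. Categories
#' with fewer than two distinct truth labels get `NA` AUC.
#'
#' @param results Posterior tibble from [genotype_all()] (must include
#'   `category`).
#' @param truth Tibble with `site_id` and `g_fetus`, covering every evaluated
#'   site.
#' @return Tibble: `category`, `n_sites`, `accuracy`, `auc`.
#' @export
evaluate_calls <- function(results, truth) {
  df <- inner_join(as_tibble(results), select(truth, "site_id", "g_fetus"),
                   by = "site_id")
  if (nrow(df) < nrow(results)) {
    stop("truth does not cover every evaluated site", call. = FALSE)
  }
  df |>
    group_by(.data$category) |>
    summarise(
      n_sites = n(),
      accuracy = mean(.data$called == .data$g_fetus),
      auc = safe_auc(.data$g_fetus == "0/1", .data$q01),
      .groups = "drop"
    )
}

safe_auc <- function(label, score) {
  if (length(unique(label)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = label, predictor = score,
                                 levels = c(FALSE, TRUE), direction = "<",
                                 quiet = TRUE)))
}
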