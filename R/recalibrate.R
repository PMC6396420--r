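#' Per-variant feature extraction for recalibration
#'
#' Builds one fixed-schema feature row per posterior result from metadata the
#' caller does not model directly — depth, allele counts and balance,
#' per-allele fragment-length and quality summaries, pairing — together with
#' the caller's own probabilistic output (posteriors, log-likelihoods, call,
#' entropies). Alleles with zero observations have their quality and length
#' features imputed to 0 and flagged by a presence indicator, so a vector is
#' never missing values. Strand balance is not available: the evidence store
#' does not retain strand.
#'
#' @param results Posterior tibble from [genotype_all()].
#' @param store Evidence store the results were computed from.
#' @param sites Site tibble.
#' @param profile Fetal-fraction profile used for genotyping.
#' @return A tibble with `site_id`, a fixed feature column set, and an
#'   attribute `"schema_version"`.
#' @export
extract_features <- function(results, store, sites, profile) {
  obs <- as_tibble(store)
  per_allele <- obs |>
    group_by(.data$site_id) |>
    summarise(
      depth = n(),
      n_ref = sum(.data$allele == "REF"),
      n_alt = sum(.data$allele == "ALT"),
      frac_improper = mean(!.data$properly_paired),
      mean_tlen_ref = mean0(.data$tlen[.data$allele == "REF"]),
      sd_tlen_ref = sd0(.data$tlen[.data$allele == "REF"]),
      mean_tlen_alt = mean0(.data$tlen[.data$allele == "ALT"]),
      sd_tlen_alt = sd0(.data$tlen[.data$allele == "ALT"]),
      mean_baseq_ref = mean0(.data$base_quality[.data$allele == "REF"]),
      mean_baseq_alt = mean0(.data$base_quality[.data$allele == "ALT"]),
      mean_mapq_ref = mean0(.data$map_quality[.data$allele == "REF"]),
      mean_mapq_alt = mean0(.data$map_quality[.data$allele == "ALT"]),
      .groups = "drop"
    )

  df <- as_tibble(results) |>
    left_join(select(sites, "site_id", "var_type", "g_mother", "g_father"),
              by = "site_id") |>
    left_join(per_allele, by = "site_id")
  zero_cols <- c("depth", "n_ref", "n_alt", "frac_improper",
                 "mean_tlen_ref", "sd_tlen_ref", "mean_tlen_alt",
                 "sd_tlen_alt", "mean_baseq_ref", "mean_baseq_alt",
                 "mean_mapq_ref", "mean_mapq_alt")
  for (cc in zero_cols) df[[cc]][is.na(df[[cc]])] <- 0

  pr <- mendelian_prior(df$g_mother, df$g_father)
  feats <- tibble(
    site_id = df$site_id,
    var_type_snp = as.integer(df$var_type == "SNP"),
    cat_maternal = as.integer(df$category == "MATERNAL_ONLY_HET"),
    cat_paternal = as.integer(df$category == "PATERNAL_ONLY_HET"),
    cat_double = as.integer(df$category == "DOUBLE_HET"),
    gm_00 = as.integer(df$g_mother == "0/0"),
    gm_01 = as.integer(df$g_mother == "0/1"),
    gm_11 = as.integer(df$g_mother == "1/1"),
    gf_00 = as.integer(df$g_father == "0/0"),
    gf_01 = as.integer(df$g_father == "0/1"),
    gf_11 = as.integer(df$g_father == "1/1"),
    depth = df$depth,
    n_ref = df$n_ref,
    n_alt = df$n_alt,
    allelic_balance = if_else(df$depth > 0, df$n_alt / pmax(df$depth, 1), 0),
    has_ref = as.integer(df$n_ref > 0),
    has_alt = as.integer(df$n_alt > 0),
    frac_improper = df$frac_improper,
    mean_tlen_ref = df$mean_tlen_ref,
    sd_tlen_ref = df$sd_tlen_ref,
    mean_tlen_alt = df$mean_tlen_alt,
    sd_tlen_alt = df$sd_tlen_alt,
    mean_baseq_ref = df$mean_baseq_ref,
    mean_baseq_alt = df$mean_baseq_alt,
    mean_mapq_ref = df$mean_mapq_ref,
    mean_mapq_alt = df$mean_mapq_alt,
    q00 = df$q00, q01 = df$q01, q11 = df$q11,
    max_pp = pmax(df$q00, df$q01, df$q11),
    ll00 = clamp_ll(df$ll00), ll01 = clamp_ll(df$ll01),
    ll11 = clamp_ll(df$ll11),
    called_00 = as.integer(df$called == "0/0"),
    called_01 = as.integer(df$called == "0/1"),
    called_11 = as.integer(df$called == "1/1"),
    prior_entropy = entropy3(pr$p00, pr$p01, pr$p11),
    posterior_entropy = entropy3(df$q00, df$q01, df$q11),
    total_ff = profile$total_ff,
    ff_mode_ld = as.integer(df$ff_mode == "LENGTH_DEPENDENT")
  )
  attr(feats, "schema_version") <- FEATURE_SCHEMA_VERSION
  feats
}

mean0 <- function(x) if (length(x) == 0L) 0 else mean(x)
sd0 <- function(x) if (length(x) < 2L) 0 else sd(x)
clamp_ll <- function(x) pmax(x, -745)  # keep log-likelihoods finite

entropy3 <- function(p1, p2, p3) {
  term <- function(p) ifelse(p > 0, -p * log(p), 0)
  term(p1) + term(p2) + term(p3)
}

feature_cols <- function(feats) setdiff(names(feats), "site_id")

# Training-pool rule per target model: maternal-only and double-het SNP
# models train within their own category (SNPs only); the paternal-only SNP
# model pools SNPs from all three categories (its own error rate is too low
# to learn from alone); indel models pool SNPs and indels within the same
# category.
training_pool <- function(category, var_type, cat_vec, snp_vec) {
  if (var_type == "SNP") {
    if (category == "PATERNAL_ONLY_HET") snp_vec == 1L
    else snp_vec == 1L & cat_vec == category
  } else {
    cat_vec == category
  }
}

#' Train a per-category recalibration model
#'
#' Fits a seeded random forest (probability forest) on labelled feature
#' vectors, predicting whether a call is correct. The training pool follows
#' the per-category strategy described in [extract_features()]'s details
#' (`strategy = "pooled"`); `strategy = "within"` always trains strictly
#' within category and variant type. Class imbalance is handled by inverse
#' class-frequency case weights. A held-out split (default 25%) is scored
#' and stored for reporting.
#'
#' @param features Feature tibble from [extract_features()].
#' @param correct Logical vector: was the call correct?
#' @param category Category the model will score.
#' @param var_type `"SNP"` or `"INDEL"`.
#' @param strategy `"pooled"` (default) or `"within"`.
#' @param seed Integer seed.
#' @param holdout Fraction of the pool held out for validation.
#' @param num_trees Forest size.
#' @return A `nipgeno_recal_model`.
#' @export
recal_train <- function(features, correct, category,
                        var_type = c("SNP", "INDEL"),
                        strategy = c("pooled", "within"), seed,
                        holdout = 0.25, num_trees = 500L) {
  var_type <- match.arg(var_type)
  strategy <- match.arg(strategy)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(nrow(features) == length(correct))
  check_schema(features)

  cat_vec <- dplyr::case_when(
    features$cat_maternal == 1L ~ "MATERNAL_ONLY_HET",
    features$cat_paternal == 1L ~ "PATERNAL_ONLY_HET",
    features$cat_double == 1L ~ "DOUBLE_HET",
    .default = "OTHER"
  )
  pool <- if (strategy == "pooled") {
    training_pool(category, var_type, cat_vec, features$var_type_snp)
  } else {
    cat_vec == category &
      features$var_type_snp == as.integer(var_type == "SNP")
  }
  x <- features[pool, feature_cols(features)]
  y <- factor(correct[pool], levels = c(FALSE, TRUE))
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }

  withr::with_seed(seed, {
    n <- nrow(x)
    test_idx <- sample.int(n, size = max(1L, round(holdout * n)))
    train_idx <- setdiff(seq_len(n), test_idx)
    ytr <- y[train_idx]
    wts <- (1 / table(ytr))[as.character(ytr)]
    fit <- ranger::ranger(
      x = x[train_idx, ], y = ytr,
      probability = TRUE, num.trees = num_trees,
      importance = "impurity",
      case.weights = as.numeric(wts),
      seed = seed, num.threads = 1L
    )
    held_score <- stats::predict(fit, data = x[test_idx, ],
                                 num.threads = 1L)$predictions[, "TRUE"]
    held_auc <- safe_auc(y[test_idx] == "TRUE", held_score)
  })

  structure(
    list(
      category = category, var_type = var_type, strategy = strategy,
      schema_version = attr(features, "schema_version"),
      feature_names = feature_cols(features),
      fit = fit, seed = as.integer(seed), num_trees = as.integer(num_trees),
      n_train = length(train_idx), n_holdout = length(test_idx),
      holdout_auc = held_auc
    ),
    class = "nipgeno_recal_model"
  )
}

#' @export
print.nipgeno_recal_model <- function(x, ...) {
  cat(sprintf(
    "<nipgeno recalibration model: %s %s, %d trees, holdout AUC %.3f>\n",
    x$category, x$var_type, x$num_trees,
    ifelse(is.na(x$holdout_auc), NA, x$holdout_auc)))
  invisible(x)
}

check_schema <- function(features, model = NULL) {
  ver <- attr(features, "schema_version") %||% "<missing>"
  if (!identical(ver, FEATURE_SCHEMA_VERSION)) {
    stop(sprintf("feature schema version mismatch: got '%s', expected '%s'",
                 ver, FEATURE_SCHEMA_VERSION), call. = FALSE)
  }
  if (!is.null(model)) {
    if (!identical(model$schema_version, ver) ||
        !identical(model$feature_names, feature_cols(features))) {
      stop("features do not match the model's schema", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Score feature vectors with a recalibration model
#'
#' @param model A `nipgeno_recal_model`.
#' @param features Feature tibble with the model's schema.
#' @return Numeric vector in `[0, 1]`: probability the call is correct.
#' @export
recal_apply <- function(model, features) {
  stopifnot(inherits(model, "nipgeno_recal_model"))
  check_schema(features, model)
  as.numeric(stats::predict(model$fit,
                            data = features[model$feature_names],
                            num.threads = 1L)$predictions[, "TRUE"])
}

#' Filter calls by recalibration score
#'
#' Keeps results whose score is at least `tau` (the conventional operating
#' point is 0.7) and reports per-category retained counts, plus retained
#' accuracy when truth is supplied.
#'
#' @param results Posterior tibble (must include `category`).
#' @param scores Numeric vector aligned with `results`.
#' @param tau Score threshold.
#' @param truth Optional truth tibble (`site_id`, `g_fetus`).
#' @return List: `results` (filtered tibble with a `recal_score` column) and
#'   `report` (per-category tibble).
#' @export
filter_by_score <- function(results, scores, tau = 0.7, truth = NULL) {
  stopifnot(nrow(results) == length(scores))
  results <- mutate(as_tibble(results), recal_score = scores)
  kept <- filter(results, .data$recal_score >= tau)
  report <- results |>
    group_by(.data$category) |>
    summarise(n_total = n(),
              n_retained = sum(.data$recal_score >= tau),
              .groups = "drop")
  if (!is.null(truth)) {
    acc <- kept |>
      inner_join(select(truth, "site_id", "g_fetus"), by = "site_id") |>
      group_by(.data$category) |>
      summarise(accuracy_retained = mean(.data$called == .data$g_fetus),
                .groups = "drop")
    report <- left_join(report, acc, by = "category")
  }
  list(results = kept, report = report)
}

#' Save / load a recalibration model
#'
#' Serialization is RDS-based; a reloaded model scores identically to the
#' original.
#'
#' @param model A `nipgeno_recal_model`.
#' @param path Output path (`.rds`).
#' @return `write_recal_model()` returns `path` invisibly;
#'   `read_recal_model()` the model.
#' @export
write_recal_model <- function(model, path) {
  stopifnot(inherits(model, "nipgeno_recal_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_recal_model
#' @export
read_recal_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "nipgeno_recal_model")) {
    stop("not a nipgeno recalibration model: ", path, call. = FALSE)
  }
  model
}
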