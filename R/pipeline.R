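#' Assemble a pipeline run configuration
#'
#' Collects every tunable of the preprocess → fetal-fraction → genotype →
#' evaluate chain into one serializable list. Unspecified values take the
#' package defaults; the resolved configuration, package version and input
#' hashes are written next to the outputs for provenance.
#'
#' @param mother_vcf,father_vcf Parental VCF paths.
#' @param cfdna_bam Indexed cfDNA alignment file (alternative to `store`).
#' @param store Pre-extracted evidence store path (alternative to
#'   `cfdna_bam`).
#' @param out_dir Output directory, created if absent.
#' @param truth_vcf Optional single-sample VCF of true fetal genotypes; when
#'   given, evaluation metrics are produced.
#' @param epsilon Emission error probability.
#' @param ff_mode `"LENGTH_DEPENDENT"` or `"FIXED"`.
#' @param min_count,max_tlen Fetal-fraction profile parameters.
#' @param min_mapq,min_baseq Evidence extraction quality gates.
#' @param min_depth,max_depth,min_pp Optional post-hoc call filters
#'   (disabled by default).
#' @param seed Integer seed recorded with the run.
#' @return A `nipgeno_run_config` list.
#' @export
pipeline_config <- function(mother_vcf, father_vcf, cfdna_bam = NULL,
                            store = NULL, out_dir, truth_vcf = NULL,
                            epsilon = 1e-3,
                            ff_mode = c("LENGTH_DEPENDENT", "FIXED"),
                            min_count = 50L, max_tlen = 500L,
                            min_mapq = 20L, min_baseq = 13L,
                            min_depth = NULL, max_depth = NULL, min_pp = NULL,
                            seed = 1L) {
  ff_mode <- match.arg(ff_mode)
  if (is.null(cfdna_bam) && is.null(store)) {
    stop("either cfdna_bam or store must be given", call. = FALSE)
  }
  structure(
    list(mother_vcf = mother_vcf, father_vcf = father_vcf,
         cfdna_bam = cfdna_bam, store = store, out_dir = out_dir,
         truth_vcf = truth_vcf, epsilon = epsilon, ff_mode = ff_mode,
         min_count = as.integer(min_count), max_tlen = as.integer(max_tlen),
         min_mapq = as.integer(min_mapq), min_baseq = as.integer(min_baseq),
         min_depth = min_depth, max_depth = max_depth, min_pp = min_pp,
         seed = as.integer(seed)),
    class = "nipgeno_run_config"
  )
}

#' Run the noninvasive genotyping pipeline
#'
#' Executes the stages in order — load parental variants, build or load the
#' evidence store, estimate the fetal-fraction profile, genotype, write the
#' fetal VCF, and (when truth is available) evaluate — short-circuiting on
#' the first failure. Reruns with identical configuration and inputs
#' reproduce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return List with `sites`, `store`, `profile`, `results`, `metrics`
#'   (`NULL` without truth) and the output paths, invisibly printable via
#'   [report()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "nipgeno_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  sites <- load_parental_variants(config$mother_vcf, config$father_vcf)
  store <- if (!is.null(config$store)) {
    read_store(config$store)
  } else {
    extract_observations(config$cfdna_bam, sites,
                         min_mapq = config$min_mapq,
                         min_baseq = config$min_baseq)
  }

  profile <- if (any(sites$category == "FETAL_INFORMATIVE")) {
    estimate_per_length_ff(store, sites, min_count = config$min_count,
                           max_tlen = config$max_tlen)
  } else {
    stop("no fetal-informative sites; supply a fixed fetal fraction by ",
         "running genotype_all() with ff_profile_fixed()", call. = FALSE)
  }
  write_ff_profile(profile, file.path(config$out_dir, "ff_profile.tsv"))

  results <- genotype_all(store, sites, profile, epsilon = config$epsilon,
                          mode = config$ff_mode)
  vcf_path <- file.path(config$out_dir, "fetal.vcf")
  write_fetal_vcf(results, sites, vcf_path)

  metrics <- NULL
  if (!is.null(config$truth_vcf)) {
    truth <- read_truth_vcf(config$truth_vcf)
    use <- filter_calls(results, min_depth = config$min_depth,
                        max_depth = config$max_depth, min_pp = config$min_pp)
    metrics <- evaluate_calls(use, truth)
    readr::write_tsv(metrics, file.path(config$out_dir, "metrics.tsv"))
  }

  write_provenance(config, sites, store)
  invisible(list(sites = sites, store = store, profile = profile,
                 results = results, metrics = metrics,
                 fetal_vcf = vcf_path, out_dir = config$out_dir))
}

read_truth_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- normalize_gt(vcfR::extract.gt(v, element = "GT")[, 1L])
  tibble(site_id = paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":"),
         g_fetus = unname(gt))
}

write_provenance <- function(config, sites, store) {
  inputs <- c(mother_vcf = config$mother_vcf, father_vcf = config$father_vcf,
              cfdna_bam = config$cfdna_bam, store = config$store,
              truth_vcf = config$truth_vcf)
  hashes <- vapply(inputs, function(p) {
    if (is.null(p) || !file.exists(p)) NA_character_
    else unname(tools::md5sum(p))
  }, character(1))
  prov <- list(
    package = "nipgeno",
    version = as.character(utils::packageVersion("nipgeno")),
    config = config[!vapply(config, is.null, logical(1))],
    input_md5 = as.list(hashes[!is.na(hashes)]),
    n_sites = nrow(sites),
    dropped = as.list(attr(sites, "dropped") %||% list()),
    n_observations = nrow(store)
  )
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prov)
}

#' Human-readable summary of evaluation metrics
#'
#' @param metrics Per-category metrics tibble from [evaluate_calls()] or a
#'   grid tibble from [grid_experiment()].
#' @return The input, invisibly; the summary is printed.
#' @export
report <- function(metrics) {
  if (all(c("ff", "depth") %in% names(metrics))) {
    cells <- dplyr::distinct(metrics, .data$ff, .data$depth)
    for (k in seq_len(nrow(cells))) {
      cat(sprintf("-- fetal fraction %.3f, median depth %d --\n",
                  cells$ff[k], as.integer(cells$depth[k])))
      sub <- filter(metrics, .data$ff == cells$ff[k],
                    .data$depth == cells$depth[k])
      print_metric_rows(sub)
    }
  } else {
    print_metric_rows(metrics)
  }
  total <- sum(metrics$n_sites)
  cat(sprintf("total sites: %d\n", total))
  invisible(metrics)
}

print_metric_rows <- function(df) {
  for (k in seq_len(nrow(df))) {
    cat(sprintf("  %-18s n=%-7d accuracy=%s auc=%s\n",
                df$category[k], df$n_sites[k],
                fmt_metric(df$accuracy[k]), fmt_metric(df$auc[k])))
  }
}

fmt_metric <- function(x) {
  if (length(x) == 0L || is.na(x)) "   NA " else sprintf("%.4f", x)
}
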