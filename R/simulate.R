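#' Discretized fragment-length law
#'
#' A discretized skew-normal law over a bp support, shifted so that its mode
#' lands exactly on `mode`. The defaults emulate maternal-plasma cfDNA:
#' fetal fragments peak near 140 bp and maternal fragments near 166 bp, with
#' most mass between 100 and 220 bp and a right tail.
#'
#' @param mode Modal template length in bp.
#' @param omega Scale of the underlying skew-normal (bp).
#' @param alpha Skewness (positive = right tail).
#' @param support Integer template lengths the law lives on.
#' @return Tibble (`tlen`, `prob`) with `prob` summing to 1.
#' @export
length_law <- function(mode, omega = 22, alpha = 3, support = 50:500) {
  x <- as.numeric(support)
  dens <- function(xi) {
    z <- (x - xi) / omega
    2 / omega * dnorm(z) * pnorm(alpha * z)
  }
  # place the skew-normal location so the discrete argmax sits at `mode`:
  # find the standardized mode z* off-support, then correct any rounding
  z_star <- stats::optimize(function(z) 2 * dnorm(z) * pnorm(alpha * z),
                            interval = c(-2, 5), maximum = TRUE)$maximum
  xi <- mode - omega * z_star
  d <- dens(xi)
  off <- x[which.max(d)] - mode
  if (off != 0) d <- dens(xi - off)
  tibble(tlen = as.integer(support), prob = d / sum(d))
}

#' Simulation configuration for a synthetic cfDNA trio
#'
#' Defines the generative law for a synthetic family: per-category site
#' counts, the true fetal fraction, mean depth, fetal and maternal
#' fragment-length laws, and the allele error model. With
#' `error_rate = NULL` (default) each observation carries a phred base
#' quality drawn from `N(qual_mean, qual_sd)` and is flipped with its
#' phred-implied probability, which gives call errors a feature-detectable
#' structure; a numeric `error_rate` uses a constant flip probability
#' instead.
#'
#' @param n_sites Named integer vector of site counts per category
#'   (`maternal_only_het`, `paternal_only_het`, `double_het`,
#'   `fetal_informative`, `uninformative`).
#' @param true_ff True fetal fraction in (0, 1).
#' @param depth_mean Mean fragments per site (Poisson; negative binomial when
#'   `depth_size` is finite).
#' @param depth_size Negative-binomial size parameter; `Inf` = Poisson.
#' @param fetal_length_law,maternal_length_law Tibbles from [length_law()].
#' @param error_rate Constant allele flip probability, or `NULL` for the
#'   quality-linked model.
#' @param qual_mean,qual_sd Base-quality law for the quality-linked error
#'   model.
#' @param p_indel Fraction of sites simulated as short indels.
#' @param p_improper Probability an observation is not properly paired
#'   (its template length is then unavailable).
#' @param p_noisy_sites Fraction of sites simulated as error-prone loci
#'   (mismapping-like artifacts): their observations flip alleles at
#'   `noisy_error_rate` and carry depressed mapping qualities. Off by
#'   default; used to give call errors a structure that is detectable from
#'   site features, as systematic artifacts are in real data.
#' @param noisy_error_rate Per-observation allele flip probability at
#'   error-prone loci.
#' @param seed Integer seed; mandatory for any stochastic run.
#' @return A `nipgeno_sim_config` list.
#' @export
sim_config <- function(n_sites = c(maternal_only_het = 2000L,
                                   paternal_only_het = 2000L,
                                   double_het = 2000L,
                                   fetal_informative = 2000L,
                                   uninformative = 0L),
                       true_ff = 0.15,
                       depth_mean = 100,
                       depth_size = Inf,
                       fetal_length_law = length_law(140, omega = 22, alpha = 3),
                       maternal_length_law = length_law(166, omega = 18, alpha = 3),
                       error_rate = NULL,
                       qual_mean = 33, qual_sd = 6,
                       p_indel = 0,
                       p_improper = 0.01,
                       p_noisy_sites = 0,
                       noisy_error_rate = 0.1,
                       seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  wanted <- c("maternal_only_het", "paternal_only_het", "double_het",
              "fetal_informative", "uninformative")
  full <- setNames(integer(length(wanted)), wanted)
  full[names(n_sites)] <- as.integer(n_sites)
  if (sum(full) <= 0L) stop("config yields zero sites", call. = FALSE)
  stopifnot(true_ff > 0, true_ff < 1, depth_mean > 0,
            abs(sum(fetal_length_law$prob) - 1) < 1e-9,
            abs(sum(maternal_length_law$prob) - 1) < 1e-9)
  structure(
    list(n_sites = full, true_ff = true_ff, depth_mean = depth_mean,
         depth_size = depth_size,
         fetal_length_law = fetal_length_law,
         maternal_length_law = maternal_length_law,
         error_rate = error_rate, qual_mean = qual_mean, qual_sd = qual_sd,
         p_indel = p_indel, p_improper = p_improper,
         p_noisy_sites = p_noisy_sites, noisy_error_rate = noisy_error_rate,
         seed = as.integer(seed)),
    class = "nipgeno_sim_config"
  )
}

#' Generate a synthetic trio with cfDNA evidence and known truth
#'
#' Parental genotypes are drawn to hit the requested per-category counts, the
#' fetal genotype is drawn from the Mendelian prior, and each site receives a
#' Poisson number of fragments. Every fragment is fetal with probability
#' `true_ff`; its template length comes from the matching length law, its
#' allele from the matching genotype, flipped according to the error model.
#' The same seed reproduces the output bit for bit.
#'
#' @param config A [sim_config()].
#' @return List with `sites` (tibble), `store` (evidence store) and `truth`
#'   (tibble `site_id`, `g_fetus`).
#' @export
simulate_trio <- function(config) {
  stopifnot(inherits(config, "nipgeno_sim_config"))
  withr::with_seed(config$seed, simulate_trio_impl(config))
}

simulate_trio_impl <- function(config) {
  ns <- config$n_sites
  combos <- list(
    maternal_only_het = cbind(c("0/1", "0/1"), c("0/0", "1/1")),
    paternal_only_het = cbind(c("0/0", "1/1"), c("0/1", "0/1")),
    double_het        = cbind("0/1", "0/1"),
    fetal_informative = cbind(c("0/0", "1/1"), c("1/1", "0/0")),
    uninformative     = cbind(c("0/0", "1/1"), c("0/0", "1/1"))
  )
  gm <- gf <- character(0)
  for (cat in names(ns)) {
    if (ns[[cat]] == 0L) next
    pick <- sample.int(nrow(combos[[cat]]), ns[[cat]], replace = TRUE)
    gm <- c(gm, combos[[cat]][pick, 1L])
    gf <- c(gf, combos[[cat]][pick, 2L])
  }
  n <- length(gm)
  ord <- sample.int(n)
  gm <- gm[ord]; gf <- gf[ord]

  bases <- c("A", "C", "G", "T")
  ref1 <- sample(bases, n, replace = TRUE)
  alt1 <- vapply(ref1, function(b) sample(setdiff(bases, b), 1L), character(1))
  ref <- ref1; alt <- alt1
  if (config$p_indel > 0) {
    is_indel <- runif(n) < config$p_indel
    ins <- runif(n) < 0.5
    extra <- vapply(sample(1:3, n, replace = TRUE), function(k) {
      paste(sample(bases, k, replace = TRUE), collapse = "")
    }, character(1))
    ref[is_indel & !ins] <- paste0(ref1, extra)[is_indel & !ins]  # deletion
    alt[is_indel & ins] <- paste0(ref1, extra)[is_indel & ins]    # insertion
  }
  sites <- variant_sites(chrom = "sim1", pos = seq_len(n) * 100L,
                         ref = ref, alt = alt, g_mother = gm, g_father = gf)

  # fetal genotype from the Mendelian prior
  pr <- mendelian_prior(sites$g_mother, sites$g_father)
  u <- runif(n)
  g_fetus <- ifelse(u < pr$p00, "0/0",
                    ifelse(u < pr$p00 + pr$p01, "0/1", "1/1"))
  truth <- tibble(site_id = sites$site_id, g_fetus = g_fetus)

  depth <- if (is.finite(config$depth_size)) {
    stats::rnbinom(n, size = config$depth_size, mu = config$depth_mean)
  } else {
    rpois(n, config$depth_mean)
  }
  idx <- rep.int(seq_len(n), depth)
  m <- length(idx)

  is_fetal <- runif(m) < config$true_ff
  g_src <- ifelse(is_fetal, g_fetus[idx], sites$g_mother[idx])
  alt_allele <- ifelse(g_src == "1/1", TRUE,
                       ifelse(g_src == "0/0", FALSE, runif(m) < 0.5))

  if (is.null(config$error_rate)) {
    bq <- pmin(pmax(round(rnorm(m, config$qual_mean, config$qual_sd)), 2L), 41L)
    flip_p <- 10^(-bq / 10)
  } else {
    flip_p <- rep(config$error_rate, m)
    bq <- rep.int(pmin(41L, max(2L, round(-10 * log10(max(config$error_rate,
                                                          1e-4))))), m)
  }
  # error-prone loci: elevated flip rate and depressed mapping quality
  noisy_site <- runif(n) < config$p_noisy_sites
  noisy_obs <- noisy_site[idx]
  flip_p[noisy_obs] <- config$noisy_error_rate
  flip <- runif(m) < flip_p
  alt_allele <- xor(alt_allele, flip)

  tlen <- integer(m)
  if (any(is_fetal)) {
    tlen[is_fetal] <- sample(config$fetal_length_law$tlen, sum(is_fetal),
                             replace = TRUE, prob = config$fetal_length_law$prob)
  }
  if (any(!is_fetal)) {
    tlen[!is_fetal] <- sample(config$maternal_length_law$tlen, sum(!is_fetal),
                              replace = TRUE,
                              prob = config$maternal_length_law$prob)
  }
  pp <- runif(m) >= config$p_improper
  tlen[!pp] <- 0L
  mq <- ifelse(runif(m) < 0.98, 60L, sample(20:59, m, replace = TRUE))
  if (any(noisy_obs)) {
    mq[noisy_obs] <- sample(10:40, sum(noisy_obs), replace = TRUE)
  }

  store <- evidence_store(
    tibble(
      site_id = sites$site_id[idx],
      allele = ifelse(alt_allele, "ALT", "REF"),
      tlen = tlen,
      properly_paired = pp,
      base_quality = as.integer(bq),
      map_quality = as.integer(mq),
      fragment_id = sprintf("f%08d", seq_len(m))
    ),
    metadata = list(generator = "simulate_trio", seed = config$seed,
                    true_ff = config$true_ff,
                    depth_mean = config$depth_mean)
  )
  list(sites = sites, store = store, truth = truth)
}

# sample from a vector of values (never the 1:n shorthand)
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

random_round <- function(x) {
  fl <- floor(x)
  as.integer(fl + (runif(length(x)) < (x - fl)))
}

#' Reduce the fetal fraction of an evidence store in silico
#'
#' Converts the excess fetal signal of a store from its observed fraction
#' down to a target fraction `d`, site by site. At sites where a
#' fetal-specific allele is recognizable (the mother is homozygous and the
#' father carries the other allele), a share `1 - d/f` of the fetal-allele
#' reads is discarded (`f` is the site-level observed fraction, replaced by
#' the store-wide total when `d >= f`), the same number of shared-allele
#' reads — sampled proportionally to their length's frequency in the fetal
#' length distribution — are reassigned lengths drawn from the maternal
#' distribution, and the same number of new shared-allele reads with
#' maternal-law lengths are generated (qualities copied from a random
#' template read at the site). Counts are rounded up or down at random
#' with probability equal to the fractional part. At maternal-heterozygous
#' sites no fetal-specific allele exists; a share of reads is sampled by
#' fetal-length frequency and given maternal-law lengths. The default
#' `"complement"` rule converts the excess fetal mass, a `(1 - d/f) * f`
#' share of the reads, mirroring the identifiable branch; the `"literal"`
#' rule converts a `d/f` share instead. The literal share grows with the
#' target fraction, which erases the length signal most when the least
#' reduction is requested and inverts the expected dependence of accuracy on
#' the fetal fraction, so it is not the default.
#'
#' @param store Evidence store.
#' @param sites Site tibble.
#' @param profile Estimated `nipgeno_ff_profile` supplying the empirical
#'   fetal and maternal length distributions and the total fraction.
#' @param d Target fetal fraction in (0, 1).
#' @param seed Integer seed.
#' @param maternal_het_rule `"complement"` (default) or `"literal"`
#'   (see above).
#' @return A new evidence store at the reduced fraction.
#' @export
reduce_fetal_fraction <- function(store, sites, profile, d, seed,
                                  maternal_het_rule = c("complement",
                                                        "literal")) {
  maternal_het_rule <- match.arg(maternal_het_rule)
  if (d <= 0 || d >= 1) stop("d must be in (0, 1)", call. = FALSE)
  stopifnot(inherits(profile, "nipgeno_ff_profile"))
  w_fet <- profile$table$count_fetal
  w_mat <- profile$table$count_shared
  if (sum(w_fet) == 0 || sum(w_mat) == 0) {
    stop("profile carries no empirical length distributions", call. = FALSE)
  }
  withr::with_seed(seed, reduce_ff_impl(store, sites, profile, d,
                                        maternal_het_rule, w_fet, w_mat))
}

reduce_ff_impl <- function(store, sites, profile, d, rule, w_fet, w_mat) {
  f_total <- profile$total_ff
  max_tlen <- profile$max_tlen
  obs <- as_tibble(store)
  obs <- left_join(obs, select(sites, "site_id", "g_mother", "category"),
                   by = "site_id")

  # work on plain vectors: per-site tibble assignment would copy columns
  site_v <- obs$site_id
  allele_v <- obs$allele
  tlen_v <- obs$tlen
  pp_v <- obs$properly_paired
  gm_v <- obs$g_mother
  cat_v <- obs$category

  # weight of an existing read under the fetal length distribution
  fet_weight <- function(tl) {
    w <- rep(0, length(tl))
    ok <- tl >= 1L & tl <= max_tlen
    w[ok] <- w_fet[tl[ok]]
    w
  }
  tlen_support <- profile$table$tlen
  draw_maternal <- function(k) {
    tlen_support[sample.int(length(tlen_support), k, replace = TRUE,
                            prob = w_mat)]
  }

  identifiable <- cat_v %in% c("PATERNAL_ONLY_HET", "FETAL_INFORMATIVE")
  maternal_het <- cat_v %in% c("MATERNAL_ONLY_HET", "DOUBLE_HET")

  drop <- rep(FALSE, length(site_v))
  tmpl_idx <- integer(0)   # template rows for generated reads

  # --- identifiable branch -------------------------------------------------
  id_idx <- split(which(identifiable), site_v[identifiable])
  for (ii in id_idx) {
    fa <- if (gm_v[ii[1L]] == "0/0") "ALT" else "REF"
    is_fa <- allele_v[ii] == fa
    b <- sum(is_fa); a <- length(ii) - b
    if (b == 0L) next
    f_site <- min(2 * b / (a + b), 1)
    f_use <- if (d >= f_site) f_total else f_site
    if (d >= f_use) next
    n_conv <- random_round((1 - d / f_use) * b)
    if (n_conv == 0L) next
    # (i) discard fetal-allele reads
    drop[resample(ii[is_fa], min(n_conv, b))] <- TRUE
    shared <- ii[!is_fa]
    # (ii) maternalize lengths of shared-allele reads, fetal-length weighted
    if (length(shared) > 0L) {
      w <- fet_weight(tlen_v[shared])
      k <- min(n_conv, length(shared))
      pick <- if (sum(w) > 0) sample_weighted(shared, k, w)
              else resample(shared, k)
      tlen_v[pick] <- draw_maternal(length(pick))
      pp_v[pick] <- TRUE
    }
    # (iii) generate replacement shared-allele reads with maternal lengths
    tmpl_idx <- c(tmpl_idx, resample(ii, n_conv, replace = TRUE))
  }

  # --- maternal-heterozygous branch ---------------------------------------
  p_conv <- if (rule == "literal") d / f_total else (1 - d / f_total) * f_total
  p_conv <- min(max(p_conv, 0), 1)
  mh_idx <- split(which(maternal_het), site_v[maternal_het])
  for (ii in mh_idx) {
    k <- random_round(p_conv * length(ii))
    if (k == 0L) next
    w <- fet_weight(tlen_v[ii])
    pick <- if (sum(w) > 0) sample_weighted(ii, min(k, length(ii)), w)
            else resample(ii, min(k, length(ii)))
    tlen_v[pick] <- draw_maternal(length(pick))
    pp_v[pick] <- TRUE
  }

  obs$tlen <- tlen_v
  obs$properly_paired <- pp_v
  new_rows <- NULL
  if (length(tmpl_idx) > 0L) {
    new_rows <- obs[tmpl_idx, ]
    # generated reads carry the shared (maternal) allele of their site
    new_rows$allele <- if_else(new_rows$g_mother == "0/0", "REF", "ALT")
    new_rows$tlen <- draw_maternal(length(tmpl_idx))
    new_rows$properly_paired <- TRUE
    new_rows$fragment_id <- sprintf("synth%08d", seq_along(tmpl_idx))
  }

  out <- bind_rows(obs[!drop, ], new_rows)
  out <- out[order(match(out$site_id, sites$site_id)), ]
  evidence_store(
    select(out, -"g_mother", -"category"),
    metadata = c(store_metadata(store)[setdiff(names(store_metadata(store)),
                                               "schema_version")],
                 list(reduced_to_ff = d, maternal_het_rule = rule))
  )
}

# weighted sampling without replacement tolerating zero weights
sample_weighted <- function(x, k, w) {
  pos <- w > 0
  if (sum(pos) >= k) {
    resample(x[pos], k, prob = w[pos])
  } else {
    c(resample(x[pos], sum(pos)),
      resample(x[!pos], k - sum(pos)))
  }
}

#' Downsample the sequencing depth of an evidence store
#'
#' The retention probability is the target median depth divided by the
#' measured median depth over the given sites; each observation is then kept
#' independently with that probability, so the realized median lands near the
#' target up to binomial noise.
#'
#' @param store Evidence store.
#' @param sites Site tibble defining the depth distribution.
#' @param target_median Desired median depth; must not exceed the measured
#'   median.
#' @param seed Integer seed.
#' @return A thinner evidence store.
#' @export
downsample_depth <- function(store, sites, target_median, seed) {
  depths <- site_depths(store, sites)
  med <- median(depths)
  if (target_median > med) {
    stop(sprintf(paste0("target median %s exceeds measured median %s; ",
                        "downsampling would be a no-op"),
                 target_median, med), call. = FALSE)
  }
  p <- target_median / med
  withr::with_seed(seed, {
    keep <- runif(nrow(store)) < p
    evidence_store(
      as_tibble(store)[keep, ],
      metadata = c(store_metadata(store)[setdiff(names(store_metadata(store)),
                                                 "schema_version")],
                   list(downsampled_to_median = target_median,
                        retention_probability = p))
    )
  })
}

site_depths <- function(store, sites) {
  tab <- table(factor(store$site_id, levels = sites$site_id))
  as.integer(tab)
}

#' Accuracy grid over fetal fraction and depth
#'
#' For each (fetal fraction, depth) cell: reduce the store's fetal fraction,
#' downsample its depth, re-estimate the length-dependent profile, genotype,
#' and evaluate against truth — emulating a panel of cfDNA samples spanning
#' sequencing settings from a single deeply sequenced family.
#'
#' @param store Evidence store of the base family (high fraction, high
#'   depth).
#' @param sites,truth Site and truth tibbles of the base family.
#' @param ff_values,depth_values Ascending grids of target fractions and
#'   median depths.
#' @param seed Integer seed; each cell derives its own sub-seed.
#' @param epsilon Emission error probability for genotyping.
#' @param min_count Per-length-bin fallback threshold for profile
#'   re-estimation.
#' @return Tidy tibble: `category`, `ff`, `depth`, `n_sites`, `accuracy`,
#'   `auc`.
#' @export
grid_experiment <- function(store, sites, truth, ff_values, depth_values,
                            seed, epsilon = 1e-3, min_count = 50L) {
  stopifnot(!is.unsorted(ff_values), !is.unsorted(depth_values))
  base_profile <- estimate_per_length_ff(store, sites, min_count = min_count)
  rows <- list()
  for (i in seq_along(ff_values)) {
    ffv <- ff_values[i]
    red <- reduce_fetal_fraction(store, sites, base_profile, d = ffv,
                                 seed = seed + i * 1000L)
    for (j in seq_along(depth_values)) {
      dv <- depth_values[j]
      cell <- downsample_depth(red, sites, target_median = dv,
                               seed = seed + i * 1000L + j)
      prof <- estimate_per_length_ff(cell, sites, min_count = min_count)
      res <- genotype_all(cell, sites, prof, epsilon = epsilon)
      ev <- evaluate_calls(res, truth) |>
        filter(.data$category %in% c("MATERNAL_ONLY_HET", "PATERNAL_ONLY_HET",
                                     "DOUBLE_HET")) |>
        mutate(ff = ffv, depth = dv)
      rows[[length(rows) + 1L]] <- ev
    }
  }
  bind_rows(rows) |>
    select("category", "ff", "depth", "n_sites", "accuracy", "auc")
}
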