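#' Allele emission probability given a genotype
#'
#' Probability that a fragment drawn from an individual of the given genotype
#' shows the given allele. Heterozygotes emit each allele with probability
#' 0.5; homozygotes emit the matching allele with probability `1 - epsilon`
#' and the mismatching allele with probability `epsilon`. With `epsilon = 0`
#' this reduces to the idealized 0 / 0.5 / 1 emissions of the mixture model's
#' textbook form; the nonzero default keeps a single sequencing error from
#' zeroing a genotype's likelihood.
#'
#' @param allele Character vector over `"REF"`, `"ALT"`.
#' @param genotype Character vector over `"0/0"`, `"0/1"`, `"1/1"`.
#' @param epsilon Per-observation allele error probability in `[0, 0.5)`.
#' @return Numeric vector of probabilities.
#' @export
emission_prob <- function(allele, genotype, epsilon = 1e-3) {
  stopifnot(epsilon >= 0, epsilon < 0.5)
  check_genotype(genotype)
  if (any(!allele %in% c("REF", "ALT"))) {
    stop("allele must be REF or ALT", call. = FALSE)
  }
  n <- max(length(allele), length(genotype))
  allele <- rep_len(allele, n)
  genotype <- rep_len(genotype, n)
  out <- rep(0.5, n)
  hom_ref <- genotype == "0/0"
  hom_alt <- genotype == "1/1"
  is_alt <- allele == "ALT"
  out[hom_ref] <- ifelse(is_alt[hom_ref], epsilon, 1 - epsilon)
  out[hom_alt] <- ifelse(is_alt[hom_alt], 1 - epsilon, epsilon)
  out
}

#' Log-likelihood of one observation under a fetal genotype hypothesis
#'
#' Each cfDNA fragment is modelled as a two-component mixture: fetal with
#' probability `f_r` and maternal with probability `1 - f_r`, where `f_r` is
#' the fragment's length-dependent fetal fraction. The observation likelihood
#' is `P(r | fet) f_r + P(r | mat) (1 - f_r)` with the emission model deciding
#' the per-origin allele probabilities. Returned in natural log; `-Inf` is
#' possible only at `epsilon = 0` when both emission terms vanish.
#'
#' @param allele,tlen,properly_paired Observation fields (vectors, recycled).
#' @param g_fetus Fetal genotype hypothesis.
#' @param g_mother Maternal genotype.
#' @param profile Fetal-fraction profile used via [lookup_ff()].
#' @param epsilon Emission error probability.
#' @return Numeric vector of log-probabilities.
#' @export
read_log_likelihood <- function(allele, tlen, properly_paired, g_fetus,
                                g_mother, profile, epsilon = 1e-3) {
  f_r <- lookup_ff(profile, tlen, properly_paired)
  e_fet <- emission_prob(allele, g_fetus, epsilon)
  e_mat <- emission_prob(allele, g_mother, epsilon)
  log(e_fet * f_r + e_mat * (1 - f_r))
}

#' Posterior fetal genotype probabilities at one site
#'
#' Combines the Mendelian prior with the product of per-observation mixture
#' likelihoods, normalizing in log space with a max shift. Genotypes with
#' prior 0 keep posterior 0 regardless of data; with no observations the
#' posterior equals the prior exactly.
#'
#' @param site One-row site tibble.
#' @param observations Observations for that site (tibble or store subset).
#' @param profile Fetal-fraction profile.
#' @param epsilon Emission error probability.
#' @param prior Optional one-row prior tibble (`p00`, `p01`, `p11`);
#'   defaults to [mendelian_prior()] of the site's parents.
#' @return A one-row tibble: `site_id`, `q00`, `q01`, `q11`, `ll00`, `ll01`,
#'   `ll11`, `called`, `tie`, `n_obs`, `ff_mode`.
#' @export
site_posteriors <- function(site, observations, profile, epsilon = 1e-3,
                            prior = NULL) {
  stopifnot(nrow(site) == 1L)
  if (is.null(prior)) prior <- mendelian_prior(site$g_mother, site$g_father)
  pr <- c(prior$p00, prior$p01, prior$p11)
  if (all(pr == 0)) stop("all priors are zero", call. = FALSE)
  obs <- as_tibble(observations)
  if (nrow(obs) > 0L && any(obs$site_id != site$site_id)) {
    stop("observations do not all belong to the site", call. = FALSE)
  }
  ll <- vapply(GENOTYPES, function(g) {
    if (nrow(obs) == 0L) return(0)
    sum(read_log_likelihood(obs$allele, obs$tlen, obs$properly_paired,
                            g, site$g_mother, profile, epsilon))
  }, numeric(1))
  finalize_posteriors(site$site_id, pr, ll, nrow(obs),
                      ff_mode = if (isTRUE(profile$fixed)) "FIXED"
                                else "LENGTH_DEPENDENT")
}

# Shared normalization: log prior + log likelihood, max-shift, strict prior.
finalize_posteriors <- function(site_id, pr, ll, n_obs, ff_mode) {
  lp <- ifelse(pr > 0, log(pr) + ll, -Inf)
  m <- max(lp)
  if (is.finite(m)) {
    w <- exp(lp - m)
    q <- w / sum(w)
  } else {
    # all data-supported genotypes annihilated (possible only at epsilon = 0);
    # fall back to the prior
    q <- pr / sum(pr)
  }
  cg <- call_from_posteriors(q)
  tibble(
    site_id = site_id,
    q00 = q[1L], q01 = q[2L], q11 = q[3L],
    ll00 = ll[1L], ll01 = ll[2L], ll11 = ll[3L],
    called = cg$genotype, tie = cg$tie,
    n_obs = as.integer(n_obs), ff_mode = ff_mode
  )
}

call_from_posteriors <- function(q) {
  i <- which.max(q)  # ties resolve to the earlier genotype in (0/0, 0/1, 1/1)
  list(genotype = GENOTYPES[i], tie = sum(q == q[i]) > 1L)
}

#' Call the fetal genotype from a posterior result
#'
#' The call is the genotype with the highest posterior; exact ties break
#' toward the earlier genotype in the order (0/0, 0/1, 1/1) and set the `tie`
#' flag.
#'
#' @param results Posterior tibble with columns `q00`, `q01`, `q11`.
#' @return The input with `called` and `tie` (re)computed.
#' @export
call_genotype <- function(results) {
  q <- as.matrix(results[, c("q00", "q01", "q11")])
  i <- max.col(q, ties.method = "first")
  mx <- q[cbind(seq_len(nrow(q)), i)]
  results$called <- GENOTYPES[i]
  results$tie <- rowSums(q == mx) > 1L
  results
}

#' Genotype every non-uninformative site in an evidence store
#'
#' Vectorized over sites and observations: one posterior result per site whose
#' category is not `UNINFORMATIVE` (those carry no transmission signal and are
#' skipped, counted in the `skipped_uninformative` attribute). `FIXED` mode
#' substitutes the profile's total fetal fraction for every observation,
#' giving the fixed-fraction baseline.
#'
#' @param store Evidence store.
#' @param sites Site tibble.
#' @param profile Fetal-fraction profile.
#' @param epsilon Emission error probability.
#' @param mode `"LENGTH_DEPENDENT"` (default) or `"FIXED"`.
#' @return Tibble with one row per genotyped site (site order), the posterior
#'   columns of [site_posteriors()], plus `category` and `n_obs`.
#' @export
genotype_all <- function(store, sites, profile, epsilon = 1e-3,
                         mode = c("LENGTH_DEPENDENT", "FIXED")) {
  mode <- match.arg(mode)
  if (mode == "FIXED" || isTRUE(profile$fixed)) {
    profile <- ff_profile_fixed(profile$total_ff, profile$max_tlen)
    mode <- "FIXED"
  }
  keep <- sites$category != "UNINFORMATIVE"
  n_skipped <- sum(!keep)
  sites_g <- sites[keep, ]

  obs <- as_tibble(store)
  unknown <- setdiff(unique(obs$site_id), sites$site_id)
  if (length(unknown) > 0L) {
    warning(length(unknown), " site(s) in store absent from site table, skipped",
            call. = FALSE)
  }
  obs <- inner_join(obs, select(sites_g, "site_id", "g_mother"),
                    by = "site_id")

  f_r <- lookup_ff(profile, obs$tlen, obs$properly_paired)
  ll_mat <- matrix(0, nrow = nrow(sites_g), ncol = 3L,
                   dimnames = list(sites_g$site_id, GENOTYPES))
  if (nrow(obs) > 0L) {
    e_mat <- emission_prob(obs$allele, obs$g_mother, epsilon)
    for (k in seq_along(GENOTYPES)) {
      e_fet <- emission_prob(obs$allele, GENOTYPES[k], epsilon)
      ll_obs <- log(e_fet * f_r + e_mat * (1 - f_r))
      agg <- rowsum(ll_obs, group = obs$site_id, reorder = FALSE)
      ll_mat[rownames(agg), k] <- agg[, 1L]
    }
  }
  n_obs <- integer(nrow(sites_g))
  if (nrow(obs) > 0L) {
    tab <- table(obs$site_id)
    idx <- match(names(tab), sites_g$site_id)
    n_obs[idx] <- as.integer(tab)
  }

  pr <- mendelian_prior(sites_g$g_mother, sites_g$g_father)
  pr_mat <- as.matrix(pr)
  lp <- ifelse(pr_mat > 0, log(pr_mat) + ll_mat, -Inf)
  m <- apply(lp, 1L, max)
  degenerate <- !is.finite(m)
  w <- exp(lp - ifelse(is.finite(m), m, 0))
  w[degenerate, ] <- pr_mat[degenerate, , drop = FALSE]
  q <- w / rowSums(w)

  out <- tibble(
    site_id = sites_g$site_id,
    category = sites_g$category,
    q00 = q[, 1L], q01 = q[, 2L], q11 = q[, 3L],
    ll00 = ll_mat[, 1L], ll01 = ll_mat[, 2L], ll11 = ll_mat[, 3L],
    n_obs = n_obs,
    ff_mode = mode
  )
  out <- call_genotype(out)
  attr(out, "skipped_uninformative") <- n_skipped
  attr(out, "epsilon") <- epsilon
  out
}
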