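test_that("emission probabilities reduce to the idealized mixture at eps = 0", {
  expect_equal(emission_prob("REF", "1/1", epsilon = 0), 0)
  expect_equal(emission_prob("ALT", "0/1", epsilon = 0.123), 0.5)
  expect_equal(emission_prob("REF", "0/0", epsilon = 0.001), 0.999)
  expect_equal(emission_prob("ALT", "0/0", epsilon = 0.001), 0.001)
  # emissions over {REF, ALT} sum to 1 for every genotype
  for (g in c("0/0", "0/1", "1/1")) {
    expect_equal(emission_prob("REF", g, 0.01) + emission_prob("ALT", g, 0.01),
                 1)
  }
})

test_that("the per-read likelihood reproduces the worked mixture formula", {
  prof <- ff_profile_fixed(0.2)
  # observed REF(A), fetus 1/1(aa), mother 0/1(Aa), eps 0:
  # 0*f + 0.5*(1 - f) at f = 0.2
  expect_equal(read_log_likelihood("REF", 150L, TRUE, "1/1", "0/1", prof,
                                   epsilon = 0),
               log(0.4))
  # pure-maternal limit: f ~ 0 -> depends only on the maternal genotype
  prof0 <- ff_profile_fixed(1e-6)
  l_aa <- read_log_likelihood("REF", 150L, TRUE, "1/1", "0/1", prof0, 0)
  l_AA <- read_log_likelihood("REF", 150L, TRUE, "0/0", "0/1", prof0, 0)
  expect_equal(l_aa, l_AA, tolerance = 1e-5)
  # log-space value equals a direct probability-space evaluation
  f <- 0.37
  direct <- 0.999 * f + 0.5 * (1 - f)
  expect_equal(
    read_log_likelihood("ALT", 150L, TRUE, "1/1", "0/1",
                        ff_profile_fixed(f), 1e-3),
    log(direct), tolerance = 1e-12)
})

test_that("site posteriors match a probability-space brute force", {
  # the documented 3-observation example
  site <- make_site("0/1", "0/1")
  obs <- make_store(site$site_id, c("ALT", "ALT", "REF"), tlen = 0L,
                    properly_paired = FALSE)
  prof <- ff_profile_fixed(0.2)
  res <- site_posteriors(site, obs, prof, epsilon = 0)
  expected <- brute_posteriors(c(0.25, 0.5, 0.25), "0/1",
                               c("ALT", "ALT", "REF"), rep(0.2, 3), 0)
  expect_equal(c(res$q00, res$q01, res$q11), unname(expected),
               tolerance = 1e-12)

  # randomized sites, mixed fractions and epsilon
  set.seed(402)
  prof_r <- ff_profile_fixed(0.31)
  for (k in 1:25) {
    gm <- sample(c("0/0", "0/1", "1/1"), 1)
    gf <- sample(c("0/0", "0/1", "1/1"), 1)
    site <- make_site(gm, gf, pos = 100L + k)
    n <- sample(0:10, 1)
    alleles <- sample(c("REF", "ALT"), n, replace = TRUE)
    obs <- make_store(rep(site$site_id, n), alleles,
                      tlen = sample(c(0L, 120L, 700L), n, replace = TRUE),
                      properly_paired = FALSE)
    eps <- sample(c(0, 1e-3, 0.01), 1)
    res <- site_posteriors(site, obs, prof_r, epsilon = eps)
    pr <- mendelian_prior(gm, gf)
    expected <- brute_posteriors(c(pr$p00, pr$p01, pr$p11), gm, alleles,
                                 rep(0.31, n), eps)
    if (anyNA(expected)) {
      # at eps = 0 the data can annihilate every admissible genotype; the
      # documented behaviour is a fallback to the prior
      expected <- c(pr$p00, pr$p01, pr$p11)
    }
    expect_equal(c(res$q00, res$q01, res$q11), unname(expected),
                 tolerance = 1e-12)
    expect_equal(res$q00 + res$q01 + res$q11, 1, tolerance = 1e-9)
  }
})

test_that("zero observations return the prior and permutation leaves
          posteriors bit-identical", {
  site <- make_site("0/1", "0/0")
  prof <- ff_profile_fixed(0.2)
  res0 <- site_posteriors(site, make_store(character(0), character(0)), prof)
  expect_identical(c(res0$q00, res0$q01, res0$q11), c(0.5, 0.5, 0))
  expect_identical(res0$called, "0/0")  # tie broken toward earlier genotype
  expect_true(res0$tie)

  alleles <- c("ALT", "REF", "ALT", "REF", "REF")
  obs <- make_store(rep(site$site_id, 5), alleles, tlen = 130:134)
  a <- site_posteriors(site, obs, prof)
  b <- site_posteriors(site, obs[c(4, 2, 5, 1, 3), ], prof)
  expect_identical(c(a$q00, a$q01, a$q11), c(b$q00, b$q01, b$q11))
})

test_that("strict priors never resurrect Mendelian-impossible genotypes", {
  site <- make_site("0/0", "0/0")  # fetus can only be 0/0 (no de novo)
  obs <- make_store(rep(site$site_id, 20), rep("ALT", 20))
  res <- site_posteriors(site, obs, ff_profile_fixed(0.2))
  expect_identical(c(res$q01, res$q11), c(0, 0))
  expect_identical(res$called, "0/0")
})

test_that("genotype calling breaks exact ties toward the earlier genotype", {
  r <- tibble::tibble(q00 = c(0.1, 0.5, 0), q01 = c(0.7, 0.5, 0),
                      q11 = c(0.2, 0, 1))
  out <- call_genotype(r)
  expect_identical(out$called, c("0/1", "0/0", "1/1"))
  expect_identical(out$tie, c(FALSE, TRUE, FALSE))
})

test_that("batch genotyping agrees with per-site posteriors and handles
          modes and skips", {
  fam <- small_family(seed = 8L, depth = 30,
                      n = c(maternal_only_het = 40L, double_het = 40L,
                            fetal_informative = 60L, uninformative = 10L))
  prof <- estimate_per_length_ff(fam$store, fam$sites)
  res <- genotype_all(fam$store, fam$sites, prof)
  expect_identical(attr(res, "skipped_uninformative"), 10L)
  expect_identical(nrow(res), nrow(fam$sites) - 10L)
  expect_true(all(abs(res$q00 + res$q01 + res$q11 - 1) < 1e-9))

  # agreement with the single-site path on a handful of sites
  for (sid in res$site_id[c(1, 25, 60)]) {
    site <- fam$sites[fam$sites$site_id == sid, ]
    obs <- fam$store[fam$store$site_id == sid, ]
    single <- site_posteriors(site, obs, prof)
    batch <- res[res$site_id == sid, ]
    expect_equal(c(batch$q00, batch$q01, batch$q11),
                 c(single$q00, single$q01, single$q11), tolerance = 1e-12)
  }

  # FIXED mode with a constant profile equals LENGTH_DEPENDENT
  pf <- ff_profile_fixed(0.21)
  a <- genotype_all(fam$store, fam$sites, pf, mode = "LENGTH_DEPENDENT")
  b <- genotype_all(fam$store, fam$sites, pf, mode = "FIXED")
  expect_equal(a$q01, b$q01, tolerance = 1e-15)

  # store rows at unknown sites trigger a warning, not an error
  extra <- make_store("chrX:1:A:G", "REF")
  st2 <- evidence_store(dplyr::bind_rows(tibble::as_tibble(fam$store),
                                         tibble::as_tibble(extra)))
  expect_warning(genotype_all(st2, fam$sites, prof), "absent")
})

test_that("posteriors vary continuously in the fetal fraction", {
  site <- make_site("0/1", "0/1")
  obs <- make_store(rep(site$site_id, 6), rep(c("ALT", "REF"), 3:3))
  fs <- seq(0.02, 0.98, by = 0.02)
  q01 <- vapply(fs, function(f) {
    site_posteriors(site, obs, ff_profile_fixed(f))$q01
  }, numeric(1))
  expect_true(all(abs(diff(q01)) < 0.08))
})

test_that("evaluation metrics match hand counts and null AUC is ~0.5", {
  res <- tibble::tibble(
    site_id = paste0("s", 1:6),
    category = rep("MATERNAL_ONLY_HET", 6),
    q00 = c(0.9, 0.1, 0.2, 0.8, 0.3, 0.05),
    q01 = c(0.1, 0.9, 0.8, 0.2, 0.7, 0.95),
    q11 = 0,
    called = c("0/0", "0/1", "0/1", "0/0", "0/1", "0/1"),
    n_obs = 10L
  )
  truth <- tibble::tibble(site_id = paste0("s", 1:6),
                          g_fetus = c("0/0", "0/1", "0/0", "0/1", "0/1", "0/1"))
  ev <- evaluate_calls(res, truth)
  expect_equal(ev$accuracy, 4 / 6)   # hand count of the confusion
  expect_equal(ev$n_sites, 6L)

  # all correct -> accuracy and AUC of 1
  ev2 <- evaluate_calls(res[truth$g_fetus == res$called, ],
                        truth[truth$g_fetus == res$called, ])
  expect_equal(ev2$accuracy, 1)

  # scores independent of truth -> AUC near 0.5
  set.seed(77)
  n <- 4000
  resr <- tibble::tibble(
    site_id = paste0("r", 1:n), category = "DOUBLE_HET",
    q00 = 0, q01 = runif(n), q11 = 0,
    called = sample(c("0/0", "0/1", "1/1"), n, replace = TRUE), n_obs = 10L
  )
  truthr <- tibble::tibble(site_id = paste0("r", 1:n),
                           g_fetus = sample(c("0/0", "0/1", "1/1"), n,
                                            replace = TRUE))
  evr <- evaluate_calls(resr, truthr)
  expect_lt(abs(evr$auc - 0.5), 0.05)

  # single-class truth -> AUC undefined
  ev1 <- evaluate_calls(res[c(2, 5), ], truth[c(2, 5), ])
  expect_true(is.na(ev1$auc))
})

test_that("post-hoc depth and posterior filters keep the advertised calls", {
  res <- tibble::tibble(
    site_id = paste0("s", 1:4), category = "MATERNAL_ONLY_HET",
    q00 = c(0.999, 0.6, 0.995, 0.4), q01 = c(0.001, 0.4, 0.005, 0.6),
    q11 = 0, called = c("0/0", "0/0", "0/0", "0/1"),
    n_obs = c(150L, 500L, 50L, 2000L)
  )
  kept <- filter_calls(res, min_depth = 100L, max_depth = 1000L,
                       min_pp = 0.99)
  expect_identical(kept$site_id, "s1")
  expect_identical(attr(kept, "n_removed"), 3L)
})
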