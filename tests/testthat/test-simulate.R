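test_that("length laws are normalized with the mode where requested", {
  for (mode in c(140L, 166L)) {
    law <- length_law(mode)
    expect_equal(sum(law$prob), 1, tolerance = 1e-12)
    expect_identical(law$tlen[which.max(law$prob)], mode)
  }
  # ~90% of mass between 100 and 220 bp with the default scales
  law <- length_law(140, omega = 22, alpha = 3)
  expect_gt(sum(law$prob[law$tlen >= 100 & law$tlen <= 220]), 0.85)
})

test_that("trio generation is seed-reproducible and seed-sensitive", {
  cfg <- sim_config(n_sites = c(maternal_only_het = 50L,
                                fetal_informative = 50L),
                    depth_mean = 20, seed = 123L)
  a <- simulate_trio(cfg)
  b <- simulate_trio(cfg)
  expect_identical(as.data.frame(a$store), as.data.frame(b$store))
  expect_identical(a$truth, b$truth)
  cfg2 <- sim_config(n_sites = c(maternal_only_het = 50L,
                                 fetal_informative = 50L),
                     depth_mean = 20, seed = 124L)
  c_ <- simulate_trio(cfg2)
  expect_false(identical(as.data.frame(a$store), as.data.frame(c_$store)))
  expect_error(sim_config(seed = 1L, n_sites = c(maternal_only_het = 0L)),
               "zero sites")
})

test_that("truth genotypes are always Mendelian-compatible", {
  fam <- small_family(seed = 19L, depth = 10)
  joined <- dplyr::inner_join(fam$sites, fam$truth, by = "site_id")
  pr <- mendelian_prior(joined$g_mother, joined$g_father)
  p_truth <- dplyr::case_when(joined$g_fetus == "0/0" ~ pr$p00,
                              joined$g_fetus == "0/1" ~ pr$p01,
                              .default = pr$p11)
  expect_true(all(p_truth > 0))
})

test_that("a pure fetal sample shows the heterozygous paternal-allele share", {
  cfg <- sim_config(n_sites = c(fetal_informative = 400L), true_ff = 0.999,
                    depth_mean = 100, error_rate = 0, p_improper = 0,
                    seed = 55L)
  fam <- simulate_trio(cfg)
  cc <- collect_informative_counts(fam$store, fam$sites)
  share <- cc$b / (cc$a + cc$b)
  expect_lt(abs(share - 0.5), 0.01)
})

test_that("the realized fetal fragment share converges to the target", {
  cfg <- sim_config(n_sites = c(fetal_informative = 2000L), true_ff = 0.12,
                    depth_mean = 100, error_rate = 0, seed = 77L)
  fam <- simulate_trio(cfg)  # ~2e5 fragments
  est <- estimate_total_ff(
    collect_informative_counts(fam$store, fam$sites)$a,
    collect_informative_counts(fam$store, fam$sites)$b)
  expect_lt(abs(est - 0.12), 0.01 * 1.2 + 0.005)
})

test_that("fetal-fraction reduction conserves counts site by site", {
  fam <- small_family(seed = 41L, true_ff = 0.25, depth = 100,
                      n = c(maternal_only_het = 200L,
                            paternal_only_het = 200L,
                            fetal_informative = 800L))
  prof <- estimate_per_length_ff(fam$store, fam$sites)
  red <- reduce_fetal_fraction(fam$store, fam$sites, prof, d = 0.1,
                               seed = 5L)
  # per-site totals at identifiable sites are conserved (discard N, add N)
  depths_before <- table(fam$store$site_id)
  depths_after <- table(red$site_id)
  ident <- fam$sites$site_id[fam$sites$category %in%
                               c("PATERNAL_ONLY_HET", "FETAL_INFORMATIVE")]
  common <- intersect(ident, names(depths_before))
  expect_identical(as.integer(depths_after[common]),
                   as.integer(depths_before[common]))
  # fetal-allele counts at informative sites shrink toward d/f of original
  cc0 <- collect_informative_counts(fam$store, fam$sites)
  cc1 <- collect_informative_counts(red, fam$sites)
  expect_lt(cc1$b / cc0$b, 0.55)   # ~ d/f = 0.4 plus noise
  expect_gt(cc1$b / cc0$b, 0.25)
  expect_error(reduce_fetal_fraction(fam$store, fam$sites, prof, d = 1.2,
                                     seed = 1L), "in \\(0, 1\\)")
})

test_that("reduction is a no-op when the target equals the site fraction", {
  # every site observes exactly f = 2*10/(90+10) = 0.2, matching the target
  n_sites <- 40L
  sites <- variant_sites("chr1", seq_len(n_sites) * 100L, "A", "G",
                         "0/0", "1/1")
  st <- make_store(rep(sites$site_id, each = 100L),
                   rep(rep(c("REF", "ALT"), c(90, 10)), n_sites),
                   tlen = rep_len(c(140L, 166L, 150L, 160L), 100L * n_sites))
  prof <- estimate_per_length_ff(st, sites, min_count = 10L)
  red <- reduce_fetal_fraction(st, sites, prof, d = 0.2, seed = 5L)
  expect_equal(as.data.frame(red)[order(red$fragment_id), ],
               as.data.frame(st)[order(st$fragment_id), ],
               ignore_attr = TRUE)
})

test_that("both maternal-het reduction rules run and are seeded", {
  fam <- small_family(seed = 47L, true_ff = 0.25, depth = 60,
                      n = c(maternal_only_het = 150L,
                            fetal_informative = 300L))
  prof <- estimate_per_length_ff(fam$store, fam$sites)
  lit <- reduce_fetal_fraction(fam$store, fam$sites, prof, 0.1, seed = 2L,
                               maternal_het_rule = "literal")
  lit2 <- reduce_fetal_fraction(fam$store, fam$sites, prof, 0.1, seed = 2L,
                                maternal_het_rule = "literal")
  comp <- reduce_fetal_fraction(fam$store, fam$sites, prof, 0.1, seed = 2L,
                                maternal_het_rule = "complement")
  expect_identical(as.data.frame(lit), as.data.frame(lit2))
  expect_false(identical(as.data.frame(lit), as.data.frame(comp)))
})

test_that("depth downsampling follows the median ratio rule", {
  fam <- small_family(seed = 61L, depth = 200,
                      n = c(maternal_only_het = 500L,
                            fetal_informative = 500L))
  ds <- downsample_depth(fam$store, fam$sites, target_median = 50L,
                         seed = 9L)
  depths <- table(factor(ds$site_id, levels = fam$sites$site_id))
  expect_lt(abs(median(depths) - 50), 4)
  expect_equal(attr(ds, "metadata")$retention_probability,
               50 / median(table(factor(fam$store$site_id,
                                        levels = fam$sites$site_id))))

  # target equal to the measured median keeps ~everything; above it errors
  med <- median(table(factor(fam$store$site_id, levels = fam$sites$site_id)))
  expect_error(downsample_depth(fam$store, fam$sites, med + 10, seed = 1L),
               "no-op")
})

test_that("the accuracy grid has one row per category and cell", {
  fam <- small_family(seed = 71L, true_ff = 0.25, depth = 120,
                      n = c(maternal_only_het = 150L,
                            paternal_only_het = 150L,
                            double_het = 150L,
                            fetal_informative = 400L))
  grid <- grid_experiment(fam$store, fam$sites, fam$truth,
                          ff_values = c(0.08, 0.16),
                          depth_values = c(40L, 80L), seed = 13L)
  expect_identical(nrow(grid), 12L)  # 2 x 2 cells x 3 categories
  expect_setequal(unique(grid$category),
                  c("MATERNAL_ONLY_HET", "PATERNAL_ONLY_HET", "DOUBLE_HET"))
  expect_true(all(grid$accuracy >= 0 & grid$accuracy <= 1))
})
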