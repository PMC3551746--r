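test_that("regional means aggregate uniform maps exactly", {
  st <- clean_study()
  # FA is constant over the phantom wall, so every region mean equals it
  fa_rows <- dplyr::filter(st$region_means, metric == "FA")
  expect_true(all(abs(fa_rows$value - 0.613) < 1e-9))
  expect_equal(sum(dplyr::filter(fa_rows, region_type == "wall")$n_voxels),
               dplyr::filter(fa_rows, region_type == "global")$n_voxels)
  # global equals the mean over all masked voxels
  lin <- which(st$labels$mask & st$fa$mask)
  expect_equal(dplyr::filter(fa_rows, region_type == "global")$value,
               mean(st$fa$values[lin]))
})

test_that("across-subject summaries give the textbook two-point SD", {
  cohort <- tibble::tibble(
    subject = c(1, 2), scan = "initial", metric = "FA",
    region_type = "global", region = "global", value = c(0.6, 0.62))
  s <- across_subject_stats(cohort)
  expect_equal(s$mean, 0.61)
  expect_equal(s$sd, stats::sd(c(0.6, 0.62)))
  expect_equal(s$sd, 0.0141, tolerance = 1e-2)
})

test_that("paired reproducibility reproduces the reference table arithmetic", {
  # identical studies: all zeros
  a <- tibble::tibble(subject = 1:5, region_type = "global", region = "global",
                      value = c(0.6, 0.62, 0.59, 0.61, 0.63))
  r <- paired_reproducibility(a, a)
  expect_equal(r$mean_diff, 0)
  expect_equal(r$sd_diff, 0)
  expect_equal(c(r$loa_low, r$loa_high), c(0, 0))
  expect_equal(r$cov_pct, 0)

  # published-row arithmetic: SD of difference 0.054 on a pooled mean of
  # 0.614 gives a CoV of 8.8%
  expect_equal(round(100 * 0.054 / 0.614, 1), 8.8)
  # and mean difference 0.045 with SD 0.135 brackets (-0.220, 0.310)
  expect_equal(round(0.045 - 1.96 * 0.135, 3), -0.220)
  expect_equal(round(0.045 + 1.96 * 0.135, 3), 0.310)
  # the same numbers must fall out of paired_reproducibility on synthetic
  # subject values constructed to have exactly that mean and difference SD
  set.seed(1)
  d <- scale(rnorm(10))[, 1] * 0.135 + 0.045   # differences: mean .045, sd .135
  m <- scale(rnorm(10))[, 1] * 0.05 + 0.728    # pooled structure
  ini <- tibble::tibble(subject = 1:10, region_type = "global",
                        region = "global", value = m + d / 2)
  rep_ <- tibble::tibble(subject = 1:10, region_type = "global",
                         region = "global", value = m - d / 2)
  out <- paired_reproducibility(ini, rep_)
  expect_equal(out$mean_diff, 0.045, tolerance = 1e-12)
  expect_equal(out$sd_diff, 0.135, tolerance = 1e-12)
  expect_equal(out$loa_low, 0.045 - 1.96 * 0.135, tolerance = 1e-12)
  expect_equal(out$loa_high, 0.045 + 1.96 * 0.135, tolerance = 1e-12)
  expect_equal(out$mean_value, 0.728, tolerance = 1e-12)
  expect_equal(out$cov_pct, 100 * 0.135 / 0.728, tolerance = 1e-12)

  # subject mismatch is a pairing error
  expect_error(paired_reproducibility(a, dplyr::mutate(a, subject = subject + 9)),
               "pairing")
})

test_that("reproducibility statistics are scale-equivariant with fixed CoV", {
  set.seed(2)
  ini <- tibble::tibble(subject = 1:8, region_type = "global", region = "global",
                        value = rnorm(8, 0.7, 0.05))
  rep_ <- dplyr::mutate(ini, value = value + rnorm(8, 0.01, 0.03))
  r1 <- paired_reproducibility(ini, rep_)
  k <- 3.7
  r2 <- paired_reproducibility(dplyr::mutate(ini, value = k * value),
                               dplyr::mutate(rep_, value = k * value))
  expect_equal(r2$cov_pct, r1$cov_pct, tolerance = 1e-12)
  expect_equal(r2$mean_diff, k * r1$mean_diff, tolerance = 1e-12)
  expect_equal(r2$sd_diff, k * r1$sd_diff, tolerance = 1e-12)
  expect_equal(r2$loa_low, k * r1$loa_low, tolerance = 1e-12)
  # LoA width identity
  expect_equal(r1$loa_high - r1$loa_low, 2 * 1.96 * r1$sd_diff, tolerance = 1e-14)
  # near-zero pooled mean flags the CoV rather than dividing
  z <- dplyr::mutate(ini, value = value - mean(c(ini$value, rep_$value)) / 2)
  zi <- dplyr::mutate(ini, value = 1e-12 * value)
  zr <- dplyr::mutate(rep_, value = -1e-12 * value)
  rz <- paired_reproducibility(zi, zr, cov_tol = 1e-8)
  expect_true(is.na(rz$cov_pct))
})

test_that("Bland-Altman points carry bias and limits of agreement", {
  a <- c(1, 2, 3, 4); b <- a
  p <- bland_altman_points(a, b)
  expect_equal(p$diff, rep(0, 4))
  expect_equal(attr(p, "bias"), 0)
  # constant offset: degenerate limits at the bias
  p2 <- bland_altman_points(a + 0.3, a)
  expect_equal(attr(p2, "bias"), 0.3)
  expect_equal(attr(p2, "loa_low"), 0.3)
  expect_equal(attr(p2, "loa_high"), 0.3)
  expect_error(bland_altman_points(1, 2), "insufficient")
  expect_error(bland_altman_points(1:3, 1:4), "pairing")

  # simulation oracle: recovered difference SD near truth at n = 1000
  set.seed(3)
  x <- rnorm(1000, 10, 1)
  y <- x + rnorm(1000, 0, 0.5)
  p3 <- bland_altman_points(x, y)
  expect_equal((attr(p3, "loa_high") - attr(p3, "loa_low")) / (2 * 1.96), 0.5,
               tolerance = 0.08)
  expect_s3_class(tidy(p3), "tbl_df")
  expect_s3_class(autoplot(p3), "ggplot")
})

test_that("variance-ratio test matches the F distribution", {
  set.seed(4)
  d1 <- rnorm(10, 0, 1)
  # equal normalized variances give F = 1, p = 1
  r <- variance_ratio_test(d1, d1, 2, 2)
  expect_equal(r$statistic, 1)
  expect_equal(r$p_value, 1)
  # doubling SD/mean quadruples F; p agrees with the distribution function
  d2 <- d1 * 2
  r2 <- variance_ratio_test(d2, d1, 2, 2)
  expect_equal(r2$statistic, 4)
  expect_equal(r2$df1, 9); expect_equal(r2$df2, 9)
  expect_equal(r2$p_value,
               2 * min(stats::pf(4, 9, 9), 1 - stats::pf(4, 9, 9)),
               tolerance = 1e-12)
  # swapping numerator and denominator inverts F, identical p
  r3 <- variance_ratio_test(d1, d2, 2, 2)
  expect_equal(r3$statistic, 1 / r2$statistic, tolerance = 1e-12)
  expect_equal(r3$p_value, r2$p_value, tolerance = 1e-12)
  expect_error(variance_ratio_test(d1, rep(1, 5), 2, 2), "degenerate")
})

test_that("synthetic paired cohorts recover the injected between-scan SD", {
  cfg <- phantom_config(grid_size = 24, noise_sigma = 0.1, shift_sd = 0,
                        corrupt_prob = 0, n_repetitions = 1)
  coh <- synthetic_paired_study(cfg, between_scan_sd = c(fa = 0.02, md = 0),
                                n_subjects = 12, seed = 8,
                                search_radius = 0, reject_threshold = NULL)
  # determinism
  coh2 <- synthetic_paired_study(cfg, between_scan_sd = c(fa = 0.02, md = 0),
                                 n_subjects = 12, seed = 8,
                                 search_radius = 0, reject_threshold = NULL)
  expect_identical(coh, coh2)
  tab <- cohort_reproducibility(coh)
  g <- dplyr::filter(tab, metric == "FA", region_type == "global")
  # SD of the difference of two independent perturbations is sd * sqrt(2);
  # wide sampling tolerance at n = 12
  expect_equal(g$sd_diff, 0.02 * sqrt(2), tolerance = 0.5)
  # zero perturbation and negligible noise collapse the differences
  g_md <- dplyr::filter(tab, metric == "MD", region_type == "global")
  expect_lt(g_md$sd_diff, 1e-6)
  expect_s3_class(glance(tab), "tbl_df")
  expect_error(synthetic_paired_study(cfg, n_subjects = 1), "insufficient")
})
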