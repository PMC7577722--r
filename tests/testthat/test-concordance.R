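roi1 <- roi_mask(1L, "rTPJ")

test_that("beta-series extraction averages the ROI and preserves trial order", {
  z <- matrix(rnorm(12 * 4), 12, 4,
              dimnames = list(sprintf("trial%02d", 1:12), letters[1:4]))
  # single-region ROI returns that region's column exactly
  bs <- extract_beta_series(z, roi_mask(2L, "b"))
  expect_equal(bs$values, unname(z[, 2]))
  # identical-valued regions: series equals the shared value per trial
  zc <- z; zc[, 3] <- zc[, 1]
  bs2 <- extract_beta_series(zc, roi_mask(c(1, 3)))
  expect_equal(bs2$values, unname(z[, 1]))
  expect_error(extract_beta_series(z[1:10, ], roi1), "trial11.*trial12")
  expect_error(extract_beta_series(z, roi_mask(9L)), "only 4 regions")
})

test_that("extracted beta series track the injected trial amplitudes at high SNR", {
  cfg <- unit_cfg(rho = 0)
  fits <- dyad_with_fits(cfg, "clinical_interaction", 42)
  bs <- extract_beta_series(fits$zp, roi1)
  expect_gt(cor(bs$values, fits$dyad$truth$ant_dev_patient[, 1]), 0.9)
})

test_that("self-regression gives unit slope and a capped maximal z", {
  z <- matrix(rnorm(12 * 3), 12, 3)
  partner <- z[, 1]
  res <- dyadic_concordance(z, partner, roi1)
  expect_equal(unname(res$slope[1]), 1)
  # the z saturates at the largest value the trial dof can support
  expect_gt(unname(res$z[1]), 10)
  expect_equal(which.max(res$z), 1L)
  expect_error(dyadic_concordance(z, rep(2, 12)), "constant")
})

test_that("concordance slopes are invariant to constant shifts of either side", {
  set.seed(8)
  z <- matrix(rnorm(12 * 3), 12, 3)
  s <- rnorm(12)
  base <- dyadic_concordance(z, s, roi1)
  shifted_target <- dyadic_concordance(z + 5, s, roi1)
  shifted_partner <- dyadic_concordance(z, s + 11, roi1)
  expect_equal(base$slope, shifted_target$slope)
  expect_equal(base$slope, shifted_partner$slope)
  expect_equal(base$z, shifted_partner$z)
})

test_that("the two concordance directions are exchangeable for a one-region ROI", {
  cfg <- unit_cfg(rho = 0.5)
  fwd <- rev <- numeric(100)
  for (i in 1:100) {
    fits <- dyad_with_fits(cfg, "clinical_interaction", 3000 + i)
    sp <- extract_beta_series(fits$zp, roi1)
    sc <- extract_beta_series(fits$zc, roi1)
    fwd[i] <- dyadic_concordance(fits$zc, sp, roi1)$roi_to_roi_z
    rev[i] <- dyadic_concordance(fits$zp, sc, roi1)$roi_to_roi_z
  }
  # regressing A on B and B on A give the same slope t statistic, so the
  # ROI-to-ROI values coincide and the distributions are indistinguishable
  expect_equal(fwd, rev, tolerance = 1e-8)
  expect_lt(unname(suppressWarnings(ks.test(fwd, rev))$statistic), 0.05)
})

test_that("the context contrast is antisymmetric and matches a pooled t-test", {
  set.seed(9)
  slopes <- matrix(rnorm(20 * 3), 20, 3,
                   dimnames = list(NULL, c("rTPJ", "vlPFC", "aINS")))
  ctx <- rep(c("clinical_interaction", "no_interaction"), each = 10)
  z <- context_contrast(slopes, ctx)
  z_swap <- context_contrast(slopes,
                             ifelse(ctx == "clinical_interaction",
                                    "no_interaction", "clinical_interaction"))
  expect_equal(as.numeric(z), -as.numeric(z_swap))
  # oracle: pooled-variance two-sample t
  tt <- t.test(slopes[1:10, 1], slopes[11:20, 1], var.equal = TRUE)
  expect_equal(as.numeric(z)[1],
               dyadconcord:::t_to_z(unname(tt$statistic), 18))
  expect_error(context_contrast(slopes[1:12, ],
                                rep(c("clinical_interaction",
                                      "no_interaction"), c(10, 2))),
               "at least 3")
})

test_that("concordance-behaviour correlation reduces to the Pearson test", {
  x <- c(0.2, -1, 0.5, 2, 1.1, -0.3)
  expect_equal(concordance_behavior_correlation(x, x)$r, 1)
  expect_lt(concordance_behavior_correlation(x, x)$p, 1e-10)
  y <- c(1, 2, 0.5, -1, 0.2, 0.8)
  res <- concordance_behavior_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate))
  expect_equal(res$p, ct$p.value)
  expect_equal(res$z_fisher, atanh(res$r))
  expect_error(concordance_behavior_correlation(x, rep(1, 6)), "constant")
  expect_error(concordance_behavior_correlation(x[1:3], y[1:3]), "at least 4")
})

test_that("independent behaviour keeps the correlation test at its nominal level", {
  set.seed(12)
  p <- vapply(1:1000, function(i)
    concordance_behavior_correlation(rnorm(37), rnorm(37))$p, numeric(1))
  expect_true(mean(p < 0.05) >= 0.035 && mean(p < 0.05) <= 0.065)
  expect_lt(unname(ks.test(p, "punif")$statistic), 0.05)
})

test_that("the conjunction-derived ROI falls back to the anatomical mask when empty", {
  set.seed(13)
  strong <- matrix(rnorm(10 * 4) + 3, 10, 4)
  roi <- derive_conjunction_roi(strong, strong, roi_mask(2L, "anat"))
  expect_equal(roi$indices, 2L)
  null_maps <- matrix(rnorm(10 * 4, sd = 0.1), 10, 4)
  expect_warning(fb <- derive_conjunction_roi(null_maps, -null_maps,
                                              roi_mask(3L, "anat")),
                 "anatomical")
  expect_equal(fb$indices, 3L)
})
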