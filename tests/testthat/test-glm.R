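hrf <- canonical_hrf()

make_design <- function(seed = 1) {
  sch <- generate_schedule(seed)[[1]]
  build_condition_design(sch, hrf, tr = 2)
}

test_that("noiseless signals reproduce the generating coefficients exactly", {
  des <- make_design(21)
  X <- cbind(1, des$X)
  beta <- c(2, 1.5, -0.5, 0.8, 0.3)
  y <- drop(X %*% beta)
  fit <- fit_glm_prewhitened(y, des)
  expect_equal(unname(fit$beta[, 1]), beta, tolerance = 1e-8)
})

test_that("the AR(1) coefficient is estimated without material bias on white noise", {
  des <- make_design(22)
  set.seed(1)
  Y <- matrix(rnorm(des$n_scans * 500), des$n_scans, 500)
  fit <- fit_glm_prewhitened(Y, des)
  expect_lt(abs(mean(fit$phi)), 0.05)
})

test_that("rank-deficient designs fail naming the collinear columns", {
  des <- make_design(23)
  des$X <- cbind(des$X, Dup = des$X[, "Anticipation"])
  expect_error(fit_glm_prewhitened(rnorm(des$n_scans + 0 * 1), des),
               "collinear.*Dup|Dup.*collinear")
})

test_that("degrees of freedom charge one observation for the whitening", {
  des <- make_design(24)
  fit <- fit_glm_prewhitened(rnorm(des$n_scans), des)
  expect_equal(fit$dof, des$n_scans - (ncol(des$X) + 1) - 1)
  expect_true(all(fit$sigma2 >= 0))
  expect_true(all(abs(fit$phi) < 1))
})

test_that("contrasts are linear: sign-flipping a contrast negates its z exactly", {
  des <- make_design(25)
  set.seed(2)
  fit <- fit_glm_prewhitened(matrix(rnorm(des$n_scans * 4), ncol = 4), des)
  z1 <- contrast_z(fit, c(Pain_Treat = 1, Pain_NoTreat = -1))
  z2 <- contrast_z(fit, c(Pain_Treat = -1, Pain_NoTreat = 1))
  expect_equal(as.numeric(z1), -as.numeric(z2))
  expect_error(contrast_z(fit, c(Pain_Treat = 0)), "zero")
  expect_error(contrast_z(fit, c(NotAColumn = 1)), "NotAColumn")
})

test_that("a strongly driven regressor is detected in nearly every simulation", {
  des <- make_design(26)
  X <- des$X
  hits <- vapply(1:200, function(i) {
    set.seed(i)
    y <- 5 * X[, "Pain_Treat"] + rnorm(nrow(X))
    fit <- fit_glm_prewhitened(y, des)
    as.numeric(contrast_z(fit, c(Pain_Treat = 1))) > 3
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("fixed-effects averaging follows the inverse-variance formula", {
  est <- c(a = 1.2, b = -0.4)
  # two identical maps: output equals input
  same <- fixed_effects_average(list(est, est), list(est * 0 + 2, est * 0 + 2))
  expect_equal(same$estimate, est)
  # equal variances: arithmetic mean
  other <- c(a = 0.2, b = 0.6)
  eq <- fixed_effects_average(list(est, other), list(est * 0 + 3, est * 0 + 3))
  expect_equal(eq$estimate, (est + other) / 2)
  # variances (1, 4) with estimates (0, 5): weighted estimate 1.0
  w <- fixed_effects_average(list(c(x = 0), c(x = 5)),
                             list(c(x = 1), c(x = 4)))
  expect_equal(unname(w$estimate), 1.0)
  expect_error(fixed_effects_average(list(c(a = 1), c(b = 1)),
                                     list(c(a = 1), c(a = 1))),
               "different regions|matching")
})

test_that("group model caps zero-variance degeneracies and is permutation invariant", {
  maps <- matrix(c(rep(3, 5), rnorm(5)), ncol = 2)
  z <- group_model(maps)
  expect_equal(as.numeric(z)[1], 38)
  expect_true(attr(z, "degenerate")[1])
  set.seed(4)
  maps2 <- matrix(rnorm(60), 12, 5)
  cov <- rnorm(12)
  perm <- sample(12)
  expect_equal(as.numeric(group_model(maps2, cov)),
               as.numeric(group_model(maps2[perm, ], cov[perm])))
  expect_error(group_model(maps2, rep(1, 12)), "constant")
  expect_error(group_model(maps2[1:2, ]), "at least 3")
})

test_that("minimum-statistic conjunction takes the elementwise minimum", {
  a <- dyadconcord:::stat_map(c(r1 = 2.3, r2 = -1.0, r3 = 4.0), "contrast")
  b <- dyadconcord:::stat_map(c(r1 = 3.1, r2 = 4.0, r3 = 3.9), "contrast")
  cj <- conjunction_min(a, b)
  expect_equal(as.numeric(cj), c(2.3, -1.0, 3.9))
  expect_equal(as.numeric(conjunction_min(a, a)), as.numeric(a))
  expect_true(all(as.numeric(cj) <= as.numeric(a) + 1e-12))
  expect_true(all(as.numeric(cj) <= as.numeric(b) + 1e-12))
  names(b)[1] <- "other"
  expect_error(conjunction_min(a, b), "different regions")
})

test_that("BH step-up rejections match the definitional cases", {
  expect_equal(fdr_threshold(c(0.01, 0.02, 0.03, 0.5), 0.05)$n_rejected, 3)
  expect_equal(fdr_threshold(rep(0.04, 4), 0.05)$n_rejected, 4)
  expect_equal(fdr_threshold(c(0.2, 0.9, 0.51), 0.05)$n_rejected, 0)
  expect_error(fdr_threshold(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("cluster correction detects an injected cluster and handles edge cases", {
  set.seed(10)
  maps <- matrix(rnorm(12 * 64), 12, 64)
  maps[, 20:29] <- maps[, 20:29] + 2
  res <- cluster_correct_permutation(maps, grid_dim = 64, n_perm = 199,
                                     seed = 1)
  expect_true(res$significant)
  expect_true(any(vapply(res$clusters, function(cl)
    length(intersect(cl, 20:29)) >= 8, logical(1))))
  # forming threshold above the global max yields no clusters
  empty <- cluster_correct_permutation(maps, grid_dim = 64, z_form = 50,
                                       n_perm = 199, seed = 1)
  expect_length(empty$all_clusters, 0)
  expect_false(empty$significant)
  expect_error(cluster_correct_permutation(maps, n_perm = 199),
               "fdr_threshold")
  expect_error(cluster_correct_permutation(maps, grid_dim = 64, n_perm = 10),
               "at least 100")
})

test_that("an injected 10-region cluster is detected in nearly all replicates", {
  hits <- vapply(1:100, function(i) {
    set.seed(i + 5000)
    maps <- matrix(rnorm(12 * 64), 12, 64)
    maps[, 20:29] <- maps[, 20:29] + 2
    cluster_correct_permutation(maps, grid_dim = 64, n_perm = 199,
                                seed = i)$significant
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("sign-flip cluster correction controls family-wise error on null data", {
  fwe <- vapply(1:400, function(i) {
    set.seed(i)
    maps <- matrix(rnorm(12 * 64), 12, 64)
    cluster_correct_permutation(maps, grid_dim = 64, n_perm = 199,
                                seed = i)$significant
  }, logical(1))
  expect_lte(mean(fwe), 0.075)
})

test_that("ROI intersection is a commutative set intersection with empty-case warning", {
  a <- roi_mask(c(1, 2, 3), "A")
  b <- roi_mask(c(2, 3, 9), "B")
  expect_equal(intersect_roi(a, b)$indices, c(2L, 3L))
  expect_equal(intersect_roi(b, a)$indices, intersect_roi(a, b)$indices)
  sub <- roi_mask(c(2, 3), "sub")
  expect_equal(intersect_roi(a, sub)$indices, sub$indices)
  expect_warning(em <- intersect_roi(roi_mask(1), roi_mask(5)), "empty")
  expect_true(attr(em, "empty"))
  expect_length(em$indices, 0)
})

test_that("2-D grid adjacency clusters diagonal neighbours separately", {
  maps <- matrix(rnorm(12 * 16, sd = 0.1), 12, 16)
  # nodes 1 and 6 are diagonal in a 4x4 grid: two clusters, not one
  maps[, 1] <- maps[, 1] + 5
  maps[, 6] <- maps[, 6] + 5
  res <- cluster_correct_permutation(maps, grid_dim = c(4, 4), n_perm = 100,
                                     seed = 2)
  expect_equal(length(res$all_clusters), 2)
  expect_true(all(lengths(res$all_clusters) == 1))
})
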