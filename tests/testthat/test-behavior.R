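mk_ratings <- function(pain) {
  data.frame(trial_index = 1:12,
             condition = rep(c("verum", "sham", "no_treatment"), 4),
             patient_pain = pain)
}

test_that("analgesia is the treated-minus-untreated mean pain difference", {
  expect_equal(analgesia_score(mk_ratings(rep(25, 12))), 0)
  pain <- ifelse(rep(c(TRUE, TRUE, FALSE), 4), 20, 30)
  expect_equal(analgesia_score(mk_ratings(pain)), -10)
  only_treated <- mk_ratings(rep(20, 12))
  only_treated$condition <- "verum"
  expect_error(analgesia_score(only_treated), "treated and untreated")
})

test_that("TOST matches the closed-form t oracle and its boundary case", {
  # n = 16, zero mean difference: t = 2.0 on 15 df one-sided
  x <- scale(rnorm(16))[, 1]  # exactly mean 0, sd 1
  res <- tost_equivalence(x, rep(0, 16), bound_dz = 0.5)
  expect_equal(res$p, pt(2, 15, lower.tail = FALSE), tolerance = 1e-4)
  expect_equal(res$df, 15)
  # observed dz exactly at the bound: p = 0.5
  y <- scale(rnorm(16))[, 1] * 2 + 1  # mean 1, sd 2 -> dz = 0.5
  expect_equal(tost_equivalence(y, rep(0, 16), bound_dz = 0.5)$p, 0.5)
  # degenerate all-zero differences declare equivalence trivially
  res0 <- tost_equivalence(rep(3, 5), rep(3, 5))
  expect_true(res0$equivalent && res0$degenerate)
  expect_error(tost_equivalence(1:2, 2:3), "at least 3")
})

test_that("simulated equivalence rate at true dz = 0 matches the analytic power", {
  n <- 16; bound <- 0.5; alpha <- 0.05
  tcrit <- qt(1 - alpha, n - 1)
  # reject iff |sqrt(n) * dz_hat| < bound * sqrt(n) - tcrit, dz_hat*sqrt(n) ~ t
  analytic <- 2 * pt(bound * sqrt(n) - tcrit, n - 1) - 1
  set.seed(20)
  rej <- vapply(1:2000, function(i)
    tost_equivalence(rnorm(n), rep(0, n), bound, alpha)$equivalent,
    logical(1))
  expect_lt(abs(mean(rej) - analytic), 0.03)
})

test_that("TOST p-values are approximately uniform at the equivalence boundary", {
  set.seed(21)
  p <- vapply(1:2000, function(i)
    tost_equivalence(rnorm(16, 0.5, 1), rep(0, 16))$p, numeric(1))
  expect_lt(unname(ks.test(p, "punif")$statistic), 0.05)
})

test_that("the Fisher transform is odd, strictly increasing, and clamped", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_true(is.finite(fisher_z(1)))
  expect_error(fisher_z(1.1), "\\[-1, 1\\]")
})

test_that("correspondence is the Fisher-transformed trial correlation", {
  p <- c(30, 45, 22, 60, 38, 52, 20, 41, 33, 57, 29, 48)
  self <- correspondence_score(p, p)
  expect_equal(self$r, 1)
  expect_equal(self$z, atanh(1 - 1e-7))
  v <- rev(p) * 0.7 + 3
  res <- correspondence_score(p, v)
  expect_equal(res$r, cor(p, v))
  # invariance under positive affine rescaling of either member
  expect_equal(correspondence_score(p * 2 + 5, v)$z, res$z)
  expect_equal(correspondence_score(p, v / 3 - 1)$z, res$z)
  expect_error(correspondence_score(p, rep(10, 12)), "clinician")
  expect_error(correspondence_score(rep(10, 12), v), "patient")
})

test_that("permuting one member's trials destroys correspondence on average", {
  set.seed(22)
  p <- rnorm(12, 35, 10)
  v <- 0.8 * p + rnorm(12, 0, 4)
  z <- vapply(1:2000, function(i) correspondence_score(p, sample(v))$z,
              numeric(1))
  expect_lt(abs(mean(z)), 0.05)
})

test_that("facial mirroring correlates the members' treatment change vectors", {
  conds <- rep(c("verum", "sham", "no_treatment"), 4)
  treated <- conds %in% c("verum", "sham")
  delta <- seq(-8, 8, length.out = 9)
  base <- matrix(40, 9, 12)
  vp <- base + outer(delta, as.numeric(treated))
  identical_score <- facial_mirroring_score(vp, vp, conds)
  expect_equal(identical_score$r, 1)
  expect_equal(identical_score$z, atanh(1 - 1e-7))
  vn <- base + outer(-delta, as.numeric(treated))
  negated <- facial_mirroring_score(vp, vn, conds)
  expect_equal(negated$r, -1)
  expect_equal(negated$z, -identical_score$z)
  # positive affine rescaling of one member leaves the score unchanged
  expect_equal(facial_mirroring_score(vp * 1.5 + 2, vn, conds)$z, negated$z)
  expect_error(facial_mirroring_score(base, vp, conds), "constant")
  expect_error(facial_mirroring_score(vp[1:7, ], vp[1:7, ], conds),
               "9 channels")
})
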