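# Percentile-bootstrap mediation with the product-of-coefficients indirect
# effect and the joint significance rule: mediation is declared when the
# indirect CI excludes zero, the total effect c was significant, and the
# direct effect c' is no longer significant after adjusting for the
# mediator.

# closed-form paths for many bootstrap resamples at once; rows of idx are
# resample index vectors
boot_paths <- function(x, m, y, idx) {
  n <- ncol(idx)
  X <- matrix(x[idx], nrow(idx), n)
  M <- matrix(m[idx], nrow(idx), n)
  Y <- matrix(y[idx], nrow(idx), n)
  sx <- rowMeans(X); sm <- rowMeans(M); sy <- rowMeans(Y)
  cxx <- rowMeans(X * X) - sx^2
  cxm <- rowMeans(X * M) - sx * sm
  cmm <- rowMeans(M * M) - sm^2
  cxy <- rowMeans(X * Y) - sx * sy
  cmy <- rowMeans(M * Y) - sm * sy
  a <- cxm / cxx
  det <- cxx * cmm - cxm^2
  b <- (cmy * cxx - cxy * cxm) / det
  bad <- cxx <= 0 | det <= .Machine$double.eps * cxx * cmm
  ind <- a * b
  ind[bad] <- NA_real_
  ind
}

ols_path <- function(formula, data, term) {
  fit <- stats::lm(formula, data = data)
  s <- summary(fit)$coefficients
  list(est = s[term, "Estimate"], p = s[term, "Pr(>|t|)"])
}

#' Percentile-bootstrap mediation analysis
#'
#' Estimates the mediation paths by least squares — `a` (mediator on
#' exposure), `b` (outcome on mediator, exposure-adjusted), `c` (total
#' effect), `c'` (direct effect) — with the indirect effect `a * b`, and a
#' case-resampling bootstrap (dyads resampled whole) for its confidence
#' interval. `p_indirect` is twice the smaller tail proportion of bootstrap
#' indirect estimates crossing zero. Mediation is flagged significant when
#' the CI excludes zero, `c` is significant at `alpha`, and `c'` is not.
#'
#' @param exposure,mediator,outcome Equal-length numeric vectors
#'   (n >= 10), non-constant.
#' @param n_boot Bootstrap draws (warning below 100).
#' @param alpha Significance/CI level (CI is `1 - alpha`).
#' @param seed RNG seed for the bootstrap.
#' @param ci_type `"percentile"` (default) or `"bca"`
#'   (bias-corrected and accelerated).
#' @return Object of class `mediation_result` with fields `a`, `b`, `c`,
#'   `c_prime`, `indirect`, `ci`, `p_indirect`, `p_c`, `p_c_prime`,
#'   `n_boot`, `seed`, `significant_mediation`.
#' @export
mediate_bootstrap <- function(exposure, mediator, outcome, n_boot = 1000,
                              alpha = 0.05, seed = 1,
                              ci_type = c("percentile", "bca")) {
  ci_type <- match.arg(ci_type)
  n <- length(exposure)
  if (length(mediator) != n || length(outcome) != n)
    stopf("exposure, mediator and outcome must have equal length")
  if (n < 10) stopf("mediation needs at least 10 observations, got %d", n)
  for (nm in c("exposure", "mediator", "outcome"))
    if (stats::sd(get(nm)) == 0) stopf("'%s' is constant", nm)
  if (abs(stats::cor(exposure, mediator)) > 1 - 1e-10)
    stopf("exposure and mediator are collinear; b and c' are inestimable")
  if (n_boot < 100) warnf("n_boot = %d is very small; intervals will be unstable", n_boot)
  dat <- data.frame(x = exposure, m = mediator, y = outcome)
  a_fit <- ols_path(m ~ x, dat, "x")
  c_fit <- ols_path(y ~ x, dat, "x")
  ym <- stats::lm(y ~ x + m, data = dat)
  ys <- summary(ym)$coefficients
  a <- a_fit$est
  b <- ys["m", "Estimate"]
  c_total <- c_fit$est
  c_prime <- ys["x", "Estimate"]
  indirect <- a * b
  boot <- with_seed(seed, {
    idx <- matrix(sample.int(n, n_boot * n, replace = TRUE), n_boot, n)
    boot_paths(dat$x, dat$m, dat$y, idx)
  })
  boot_ok <- boot[is.finite(boot)]
  probs <- c(alpha / 2, 1 - alpha / 2)
  ci <- if (ci_type == "percentile") {
    unname(stats::quantile(boot_ok, probs))
  } else {
    z0 <- stats::qnorm(mean(boot_ok < indirect))
    jk <- vapply(seq_len(n), function(i) {
      d <- dat[-i, ]
      aj <- stats::coef(stats::lm(m ~ x, d))["x"]
      bj <- stats::coef(stats::lm(y ~ x + m, d))["m"]
      unname(aj * bj)
    }, numeric(1))
    u <- mean(jk) - jk
    acc <- sum(u^3) / (6 * sum(u^2)^1.5)
    zq <- stats::qnorm(probs)
    adj <- stats::pnorm(z0 + (z0 + zq) / (1 - acc * (z0 + zq)))
    unname(stats::quantile(boot_ok, adj))
  }
  p_indirect <- 2 * min(mean(boot_ok <= 0), mean(boot_ok >= 0))
  p_indirect <- min(1, max(p_indirect, 1 / length(boot_ok)))
  significant <- (ci[1] > 0 || ci[2] < 0) && c_fit$p < alpha &&
    ys["x", "Pr(>|t|)"] >= alpha
  structure(list(a = a, b = b, c = c_total, c_prime = c_prime,
                 indirect = indirect, ci = ci, p_indirect = p_indirect,
                 p_c = c_fit$p, p_c_prime = ys["x", "Pr(>|t|)"],
                 p_a = a_fit$p, p_b = ys["m", "Pr(>|t|)"],
                 n = n, n_boot = n_boot, seed = seed, alpha = alpha,
                 ci_type = ci_type, significant_mediation = significant,
                 boot = boot),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> n = %d, %d bootstrap draws (%s CI)\n",
              x$n, x$n_boot, x$ci_type))
  cat(sprintf("  a = %.4f  b = %.4f  c = %.4f  c' = %.4f\n",
              x$a, x$b, x$c, x$c_prime))
  cat(sprintf("  indirect a*b = %.4f, %d%% CI [%.4f, %.4f], p = %.4g\n",
              x$indirect, round(100 * (1 - x$alpha)), x$ci[1], x$ci[2],
              x$p_indirect))
  cat(sprintf("  significant mediation: %s\n", x$significant_mediation))
  invisible(x)
}
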