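# Shared fixtures and independent oracles used across test files.

# small cohort configuration for fast end-to-end runs
small_cfg <- function(n_ci = 5, n_ni = 5, rho_ci = 0.6, rho_ni = 0, ...) {
  sim_config(n_dyads = n_ci + n_ni,
             context_split = c(clinical_interaction = n_ci,
                               no_interaction = n_ni),
             coupling_rho = c(clinical_interaction = rho_ci,
                              no_interaction = rho_ni),
             ...)
}

# a single-dyad config used when dyads are simulated one at a time
unit_cfg <- function(rho = 0, ...) small_cfg(1, 1, rho_ci = rho, rho_ni = 0, ...)

# direct generalized-least-squares solve under a known AR(1) correlation
gls_oracle <- function(X, y, phi) {
  n <- nrow(X)
  R <- phi^abs(outer(seq_len(n), seq_len(n), "-"))
  Ri <- solve(R)
  solve(t(X) %*% Ri %*% X, t(X) %*% Ri %*% y)
}

# brute-force Benjamini-Hochberg: largest k with p_(k) <= k * alpha / m,
# rejecting everything at or below that order statistic
bh_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * alpha / m)
  if (!length(ok)) return(integer(0))
  sort(o[seq_len(max(ok))])
}

# linear mediation chain x -> m -> y with known path coefficients
set_chain <- function(n, a = 0.5, b = 0.4, cp = 0, sd_m = 1, sd_y = 1,
                      seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  m <- a * x + rnorm(n, sd = sd_m)
  y <- cp * x + b * m + rnorm(n, sd = sd_y)
  list(x = x, m = m, y = y)
}

# simulate one dyad and return the dyad plus both members' trial-wise z maps
dyad_with_fits <- function(cfg, context, seed, hrf = canonical_hrf()) {
  d <- simulate_dyad(cfg, "dyad", context, seed)
  list(dyad = d,
       zp = fit_trialwise_session(d$patient_signals, d$schedules, hrf,
                                  cfg$tr_seconds),
       zc = fit_trialwise_session(d$clinician_signals, d$schedules, hrf,
                                  cfg$tr_seconds))
}
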