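# Internal helpers shared across modules.

# Largest z-statistic reported for degenerate (zero-variance) inputs; finite
# so downstream arithmetic stays well defined.
Z_CAP <- 38

#' Evaluate an expression under a fixed RNG seed, restoring the caller's RNG
#' @noRd
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

#' Derive a reproducible child seed from a parent seed and an index
#'
#' Linear-congruential mix kept below 2^31 so the result is a valid integer
#' seed on 32-bit R integers.
#' @noRd
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + as.numeric(i) * 9973 + 7) %%
               2147483629) + 1L
}

#' Convert t statistics to z by matched tail probability
#'
#' Works in log-probability space so |t| far in the tail maps to a finite,
#' accurate z instead of saturating at qnorm(1) = Inf.
#' @noRd
t_to_z <- function(t, df) {
  z <- sign(t) * qnorm(pt(abs(t), df, lower.tail = FALSE, log.p = TRUE),
                       lower.tail = FALSE, log.p = TRUE)
  z[t == 0] <- 0
  z
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_correlation <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(abs(x) > 1))
    stopf("'%s' must be a correlation in [-1, 1], got %s", name,
          paste(format(x), collapse = ", "))
  invisible(x)
}
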