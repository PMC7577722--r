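#' Canonical double-gamma hemodynamic response function
#'
#' Builds the impulse response linking a neural event to the BOLD signal as
#' the difference of two gamma densities: a positive lobe peaking at
#' `peak_delay` seconds and an undershoot peaking at `undershoot_delay`
#' seconds, scaled by `peak_undershoot_ratio`. The gamma shapes are
#' parameterised so that the mode of each lobe falls exactly at its stated
#' delay (shape = delay/dispersion + 1, scale = dispersion). The kernel is
#' truncated at `length_s` seconds and normalised to unit peak.
#'
#' @param dt Sampling interval of the kernel in seconds (> 0).
#' @param peak_delay Time to peak of the positive lobe, seconds.
#' @param undershoot_delay Time to peak of the undershoot, seconds.
#' @param peak_dispersion,undershoot_dispersion Dispersion (gamma scale) of
#'   each lobe, seconds; larger values widen the lobe.
#' @param peak_undershoot_ratio Ratio of undershoot to peak amplitude;
#'   0 gives a single-gamma (everywhere non-negative) response.
#' @param length_s Support of the kernel in seconds; values beyond this are
#'   truncated to zero.
#' @return An object of class `hrf`: a list with `dt`, `kernel` (sampled
#'   values at `seq(0, length_s, by = dt)`) and `params`.
#' @examples
#' h <- canonical_hrf(dt = 0.1)
#' h$dt * which.max(h$kernel)  # ~ 6 s
#' @export
canonical_hrf <- function(dt = 0.1, peak_delay = 6, undershoot_delay = 16,
                          peak_dispersion = 1, undershoot_dispersion = 1,
                          peak_undershoot_ratio = 1 / 6, length_s = 32) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stopf("'dt' must be a positive sampling interval in seconds")
  if (peak_dispersion <= 0 || undershoot_dispersion <= 0)
    stopf("HRF dispersions must be positive")
  if (peak_delay <= 0 || undershoot_delay <= 0)
    stopf("HRF delays must be positive")
  if (peak_undershoot_ratio < 0)
    stopf("'peak_undershoot_ratio' must be non-negative")
  t <- seq(0, length_s, by = dt)
  pos <- dgamma(t, shape = peak_delay / peak_dispersion + 1,
                scale = peak_dispersion)
  und <- dgamma(t, shape = undershoot_delay / undershoot_dispersion + 1,
                scale = undershoot_dispersion)
  kernel <- pos - peak_undershoot_ratio * und
  kernel <- kernel / max(kernel)
  structure(list(dt = dt, kernel = kernel,
                 params = list(peak_delay = peak_delay,
                               undershoot_delay = undershoot_delay,
                               peak_dispersion = peak_dispersion,
                               undershoot_dispersion = undershoot_dispersion,
                               peak_undershoot_ratio = peak_undershoot_ratio,
                               length_s = length_s)),
            class = "hrf")
}

#' @export
print.hrf <- function(x, ...) {
  cat(sprintf("<hrf> double-gamma, dt = %g s, peak %g s, undershoot %g s, ratio %g, length %g s\n",
              x$dt, x$params$peak_delay, x$params$undershoot_delay,
              x$params$peak_undershoot_ratio, x$params$length_s))
  invisible(x)
}
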