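# Behavioural and facial statistics: analgesia scores, TOST equivalence,
# Fisher transform, rating correspondence and overall facial mirroring.

#' Analgesia score of one dyad
#'
#' Mean patient pain over treated trials (verum and sham pooled) minus the
#' mean over untreated trials; negative values mean treatment-related pain
#' relief.
#'
#' @param ratings A ratings data.frame with columns `condition` and
#'   `patient_pain` ([generate_ratings()] output or equivalent).
#' @return Numeric scalar (VAS points).
#' @export
analgesia_score <- function(ratings) {
  treated <- ratings$condition %in% c("verum", "sham")
  untreated <- ratings$condition == "no_treatment"
  if (!any(treated) || !any(untreated))
    stopf("ratings must contain both treated and untreated trials")
  mean(ratings$patient_pain[treated]) - mean(ratings$patient_pain[untreated])
}

#' Paired TOST equivalence test
#'
#' Two one-sided paired t-tests of the standardized mean difference against
#' symmetric equivalence bounds expressed as Cohen's dz. Following the
#' conventional formulation, each one-sided statistic is
#' `t = (dz_hat -/+ bound) * sqrt(n)` referred to a central t distribution
#' with n-1 df; the reported p is the larger of the two one-sided p-values
#' and equivalence is declared when it falls below `alpha`.
#'
#' @param x,y Paired numeric vectors (n >= 3).
#' @param bound_dz Equivalence bound on Cohen's dz (symmetric).
#' @param alpha Significance level.
#' @return List with `t` (statistic of the binding one-sided test), `p`,
#'   `df`, `dz` (observed standardized difference), `equivalent`, and
#'   `degenerate` (TRUE when all differences are exactly zero, in which
#'   case equivalence is declared trivially).
#' @export
tost_equivalence <- function(x, y, bound_dz = 0.5, alpha = 0.05) {
  if (length(x) != length(y)) stopf("paired series differ in length")
  n <- length(x)
  if (n < 3) stopf("TOST needs at least 3 pairs, got %d", n)
  if (bound_dz <= 0) stopf("'bound_dz' must be positive")
  d <- x - y
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (mean(d) == 0)
      return(list(t = Inf, p = 0, df = n - 1, dz = 0, equivalent = TRUE,
                  degenerate = TRUE))
    stopf("differences have zero variance but nonzero mean; dz is undefined")
  }
  dz <- mean(d) / sdd
  df <- n - 1
  t_upper <- (dz - bound_dz) * sqrt(n)   # H0: dz >= bound
  t_lower <- (dz + bound_dz) * sqrt(n)   # H0: dz <= -bound
  p_upper <- stats::pt(t_upper, df)
  p_lower <- stats::pt(t_lower, df, lower.tail = FALSE)
  if (p_upper >= p_lower) {
    t <- t_upper; p <- p_upper
  } else {
    t <- t_lower; p <- p_lower
  }
  list(t = t, p = p, df = df, dz = dz, equivalent = p < alpha,
       degenerate = FALSE)
}

#' Fisher r-to-z transform
#'
#' `atanh(r)` with |r| clamped to 1 - 1e-7 so perfect correlations map to a
#' large finite value.
#'
#' @param r Correlation in \[-1, 1\].
#' @return Numeric.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) > 1))
    stopf("'r' must lie in [-1, 1]")
  atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
}

#' Pain / vicarious-pain correspondence of one dyad
#'
#' Pearson correlation across trials between the patient's pain ratings and
#' the clinician's vicarious pain ratings, Fisher r-to-z transformed — a
#' proxy for the clinician's accuracy in evaluating the patient's pain.
#'
#' @param patient_pain,clinician_vicarious Equal-length per-trial series.
#' @return List with `r`, `z` and `n`.
#' @export
correspondence_score <- function(patient_pain, clinician_vicarious) {
  if (length(patient_pain) != length(clinician_vicarious))
    stopf("series differ in length")
  if (stats::sd(patient_pain) == 0)
    stopf("patient series is constant; correspondence undefined")
  if (stats::sd(clinician_vicarious) == 0)
    stopf("clinician series is constant; correspondence undefined")
  r <- stats::cor(patient_pain, clinician_vicarious)
  list(r = r, z = fisher_z(r), n = length(patient_pain))
}

facial_values <- function(x) {
  v <- if (inherits(x, "facial_features")) x$values else as.matrix(x)
  if (nrow(v) != 9L)
    stopf("facial features must have exactly 9 channels, got %d", nrow(v))
  v
}

#' Overall facial mirroring score of one dyad
#'
#' For each member, computes the treatment-related change vector across the
#' nine expression channels (mean over treated trials minus mean over
#' untreated trials, per channel), then the Pearson correlation between the
#' two members' change vectors across channels, Fisher r-to-z transformed.
#'
#' @param patient,clinician `facial_features` objects (or 9 x 12 matrices).
#' @param conditions Length-12 condition vector aligning trials to
#'   treatment.
#' @return List with `r`, `z`, and the two `change` vectors.
#' @export
facial_mirroring_score <- function(patient, clinician, conditions) {
  vp <- facial_values(patient); vc <- facial_values(clinician)
  treated <- conditions %in% c("verum", "sham")
  if (!any(treated) || all(treated))
    stopf("need both treated and untreated trials to form change vectors")
  chg <- function(v, who) {
    out <- rowMeans(v[, treated, drop = FALSE]) -
      rowMeans(v[, !treated, drop = FALSE])
    if (stats::sd(out) == 0)
      stopf("%s change vector is constant; mirroring undefined", who)
    out
  }
  cp <- chg(vp, "patient"); cc <- chg(vc, "clinician")
  r <- stats::cor(cp, cc)
  list(r = r, z = fisher_z(r), change = list(patient = cp, clinician = cc))
}
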