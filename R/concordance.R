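# Trial-wise beta-series extraction and dyadic brain-to-brain concordance.

#' Trial-wise z maps for one subject's session
#'
#' Fits the one-regressor-per-trial prewhitened GLM to each of the two runs
#' and assembles the 12 per-trial z statistics per region, ordered by
#' global trial index.
#'
#' @param signals List of two `n_scans x regions` matrices (runs 1 and 2).
#' @param schedules List of two `event_schedule`s shared by the dyad.
#' @param hrf An [canonical_hrf()].
#' @param tr Repetition time, seconds.
#' @param phase `"anticipation"` or `"pain"`.
#' @param motion Optional list of per-run motion matrices.
#' @return 12 x regions matrix of z values, rownames `trial01..trial12`.
#' @export
fit_trialwise_session <- function(signals, schedules, hrf, tr = 2,
                                  phase = "anticipation", motion = NULL) {
  stopifnot(length(signals) == length(schedules))
  pieces <- lapply(seq_along(schedules), function(r) {
    design <- build_trialwise_design(schedules[[r]], hrf, tr, phase,
                                     motion = if (is.null(motion)) NULL
                                              else motion[[r]])
    fit <- fit_glm_prewhitened(signals[[r]], design)
    z <- regressor_z(fit, design$of_interest)
    rownames(z) <- sprintf("trial%02d", schedules[[r]]$trials$trial_index)
    z
  })
  out <- do.call(rbind, pieces)
  out[order(rownames(out)), , drop = FALSE]
}

#' Extract an ROI beta series from trial-wise z maps
#'
#' Averages the per-trial z values over the ROI's regions, yielding the
#' 12-point dynamic signal used as the unit of concordance.
#'
#' @param trial_z 12 x regions matrix from [fit_trialwise_session()], or a
#'   list of per-run matrices stacked to 12 rows.
#' @param roi An [roi_mask()].
#' @param subject_id,phase Labels stored with the series.
#' @return Object of class `beta_series` with `values` (length 12, ordered
#'   by global trial index).
#' @export
extract_beta_series <- function(trial_z, roi, subject_id = "subject",
                                phase = "anticipation") {
  if (is.list(trial_z)) trial_z <- do.call(rbind, trial_z)
  if (nrow(trial_z) != 12L) {
    have <- rownames(trial_z) %||% as.character(seq_len(nrow(trial_z)))
    want <- sprintf("trial%02d", 1:12)
    stopf("expected 12 trial maps, got %d; missing: %s", nrow(trial_z),
          paste(setdiff(want, have), collapse = ", "))
  }
  if (max(roi$indices) > ncol(trial_z))
    stopf("ROI indexes region %d but only %d regions are present",
          max(roi$indices), ncol(trial_z))
  values <- rowMeans(trial_z[, roi$indices, drop = FALSE])
  structure(list(subject_id = subject_id, roi_label = roi$label,
                 phase = phase, values = unname(values)),
            class = "beta_series")
}

#' @export
print.beta_series <- function(x, ...) {
  cat(sprintf("<beta_series> %s / %s (%s):\n", x$subject_id, x$roi_label,
              x$phase))
  print(round(x$values, 3))
  invisible(x)
}

#' Dyadic concordance regression
#'
#' For every target-brain region, regresses the region's 12 per-trial z
#' values on the partner's ROI beta series (mean-centred, with intercept)
#' across trials, and converts the slope t statistic (10 residual df) to z.
#' The mean z over the designated target ROI is exported as the dyad's
#' ROI-to-ROI concordance.
#'
#' @param target_trial_z 12 x regions z matrix of the target brain
#'   ([fit_trialwise_session()]).
#' @param partner_series [extract_beta_series()] of the partner's ROI (or a
#'   plain numeric vector of length 12).
#' @param roi [roi_mask()] of the target region whose mean z becomes
#'   `roi_to_roi_z`; defaults to region 1.
#' @param dyad_id,direction Labels stored in the result.
#' @return Object of class `concordance_result` with `slope`, `z` (per
#'   region), `roi_to_roi_z`, `roi_to_roi_slope`.
#' @export
dyadic_concordance <- function(target_trial_z, partner_series,
                               roi = roi_mask(1L),
                               dyad_id = "dyad",
                               direction = "patient_roi_to_clinician_brain") {
  s <- if (inherits(partner_series, "beta_series")) partner_series$values
       else as.numeric(partner_series)
  Y <- as.matrix(target_trial_z)
  n <- nrow(Y)
  if (length(s) != n)
    stopf("partner series has %d trials but the target has %d maps",
          length(s), n)
  if (stats::sd(s) == 0)
    stopf("partner series is constant; the concordance regressor is degenerate")
  sc <- s - mean(s)
  X <- cbind(1, sc)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  B <- xtx_inv %*% crossprod(X, Y)
  res <- Y - X %*% B
  dof <- n - 2L
  sigma2 <- colSums(res^2) / dof
  se <- sqrt(pmax(sigma2 * xtx_inv[2, 2], .Machine$double.eps))
  z <- t_to_z(B[2, ] / se, dof)
  z <- pmin(pmax(z, -Z_CAP), Z_CAP)
  names(z) <- colnames(Y)
  slope <- stats::setNames(B[2, ], colnames(Y))
  structure(list(dyad_id = dyad_id, direction = direction, slope = slope,
                 z = z, roi_to_roi_z = mean(z[roi$indices]),
                 roi_to_roi_slope = mean(slope[roi$indices]),
                 roi_label = roi$label, dof = dof),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance_result> %s (%s): %s-to-%s z = %.3f\n",
              x$dyad_id, x$direction, x$roi_label, x$roi_label,
              x$roi_to_roi_z))
  invisible(x)
}

#' Clinical-context contrast of concordance
#'
#' Two-sample comparison per target region of the dyadic concordance
#' slopes, clinical-interaction minus no-interaction, pooled-variance t
#' converted to z.
#'
#' @param slopes n_dyads x regions matrix of concordance slopes (one row
#'   per dyad, e.g. `result$slope`).
#' @param context Character/factor vector per dyad with levels
#'   `clinical_interaction` and `no_interaction`; at least 3 dyads each.
#' @return A `stat_map` of z values per region.
#' @export
context_contrast <- function(slopes, context) {
  slopes <- rbind(slopes)
  context <- as.character(context)
  g1 <- slopes[context == "clinical_interaction", , drop = FALSE]
  g2 <- slopes[context == "no_interaction", , drop = FALSE]
  n1 <- nrow(g1); n2 <- nrow(g2)
  if (n1 < 3 || n2 < 3)
    stopf("each context needs at least 3 dyads (got %d clinical_interaction, %d no_interaction)",
          n1, n2)
  v1 <- apply(g1, 2, stats::var); v2 <- apply(g2, 2, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  t <- (colMeans(g1) - colMeans(g2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  stat_map(stats::setNames(t_to_z(t, n1 + n2 - 2), colnames(slopes)),
           "group", "clinical_interaction - no_interaction")
}

#' Correlation between dyadic concordance and behaviour
#'
#' Pearson correlation between the per-dyad ROI-to-ROI concordance values
#' and a per-dyad behavioural measure (e.g. analgesia), with two-sided p
#' and Fisher r-to-z.
#'
#' @param concordance Numeric vector, one value per dyad.
#' @param behavior Matching numeric vector.
#' @return List with `r`, `p`, `z_fisher`, `n`.
#' @export
concordance_behavior_correlation <- function(concordance, behavior) {
  if (length(concordance) != length(behavior))
    stopf("concordance and behavior differ in length")
  if (length(concordance) < 4)
    stopf("need at least 4 dyads, got %d", length(concordance))
  if (stats::sd(concordance) == 0 || stats::sd(behavior) == 0)
    stopf("constant input; correlation undefined")
  ct <- stats::cor.test(concordance, behavior, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       z_fisher = fisher_z(unname(ct$estimate)), n = length(concordance))
}

#' Derive the functional concordance ROI by group conjunction
#'
#' Mirrors the map-level ROI derivation: one-sample group z maps of the
#' anticipation response for patients and clinicians, minimum-statistic
#' conjunction, Benjamini-Hochberg FDR over regions (two-sided p), and
#' intersection with an a priori anatomical mask. If no region survives
#' FDR, the anatomical mask is returned with a warning so downstream
#' analyses remain defined.
#'
#' @param patient_maps,clinician_maps n_subjects x regions matrices of
#'   anticipation contrast statistics.
#' @param anatomical [roi_mask()] of the structural region.
#' @param alpha FDR level.
#' @return An [roi_mask()].
#' @export
derive_conjunction_roi <- function(patient_maps, clinician_maps, anatomical,
                                   alpha = 0.05) {
  conj <- conjunction_min(group_model(patient_maps),
                          group_model(clinician_maps))
  p <- 2 * stats::pnorm(abs(as.numeric(conj)), lower.tail = FALSE)
  fdr <- fdr_threshold(p, alpha)
  if (!fdr$n_rejected) {
    warnf("no region survives the conjunction FDR; falling back to the anatomical mask")
    return(anatomical)
  }
  out <- intersect_roi(fdr$rejected, anatomical)
  if (isTRUE(attr(out, "empty"))) anatomical else out
}
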