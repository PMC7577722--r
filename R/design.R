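# Design-matrix construction: HRF-convolved regressors sampled at the TR.
#
# Boxcars are built on a fine grid (the HRF's dt, default 0.1 s), convolved
# with the kernel, and read out at TR midpoints. Building at fine resolution
# before downsampling avoids onset-quantisation bias for jittered onsets.

#' Convolve a set of timed events into scan-resolution regressors
#'
#' @param events data.frame with columns onset, duration (seconds).
#' @param hrf An [canonical_hrf()] object.
#' @param total_duration Run length, seconds.
#' @param tr Repetition time, seconds.
#' @return matrix n_scans x nrow(events); each column is the HRF-convolved
#'   boxcar of one event, scaled so a sustained boxcar plateaus at the
#'   kernel's time integral.
#' @noRd
convolve_events <- function(events, hrf, total_duration, tr) {
  dt <- hrf$dt
  n_scans <- round(total_duration / tr)
  if (max(events$onset + events$duration) > total_duration)
    stopf("events extend to %g s but the run lasts only %g s",
          max(events$onset + events$duration), total_duration)
  n_hi <- length(seq(0, total_duration, by = dt))
  mid_idx <- pmin(n_hi, round(((seq_len(n_scans)) - 0.5) * tr / dt) + 1L)
  # boxcar * kernel convolution via the kernel's running integral:
  # conv[i] = K(i - onset_idx) - K(i - offset_idx), K = cumsum(kernel) * dt
  nk <- length(hrf$kernel)
  K <- c(0, cumsum(hrf$kernel) * dt)
  lookup <- function(lag) K[pmin(pmax(lag, 0L), nk) + 1L]
  out <- matrix(0, n_scans, nrow(events))
  for (j in seq_len(nrow(events))) {
    i_on <- round(events$onset[j] / dt)
    i_off <- round((events$onset[j] + events$duration[j]) / dt)
    out[, j] <- lookup(mid_idx - i_on) - lookup(mid_idx - i_off)
  }
  out
}

new_design_matrix <- function(X, tr, of_interest, schedule) {
  structure(list(X = X, tr = tr, n_scans = nrow(X),
                 times = (seq_len(nrow(X)) - 0.5) * tr,
                 column_names = colnames(X),
                 of_interest = of_interest,
                 run_index = schedule$run_index),
            class = "design_matrix")
}

check_motion <- function(motion, n_scans) {
  if (is.null(motion)) return(NULL)
  motion <- as.matrix(motion)
  if (nrow(motion) != n_scans)
    stopf("motion nuisance series have %d rows but the run has %d scans",
          nrow(motion), n_scans)
  if (ncol(motion) != 6L)
    stopf("expected the six motion parameter series, got %d columns",
          ncol(motion))
  if (all(abs(motion) < 1e-12)) {
    warnf("all-zero motion regressors supplied; dropping them from the design")
    return(NULL)
  }
  colnames(motion) <- paste0("Motion", 1:6)
  motion
}

#' Condition-wise first-level design matrix
#'
#' Task regressors: `Anticipation` (all trials pooled), `Pain_Treat`
#' (verum and sham pain blocks), `Pain_NoTreat` (untreated pain blocks).
#' Nuisance regressors: `Ratings` (all rating blocks) and, when supplied,
#' the six motion parameter series. Rest is the implicit baseline. All task
#' and rating columns are boxcars convolved with `hrf`.
#'
#' @param schedule An `event_schedule`.
#' @param hrf An [canonical_hrf()] object.
#' @param tr Repetition time, seconds.
#' @param motion Optional n_scans x 6 matrix of motion parameters; all-zero
#'   input is dropped with a warning.
#' @return A `design_matrix`; `of_interest` lists the three task columns.
#' @export
build_condition_design <- function(schedule, hrf, tr = 2, motion = NULL) {
  validate_event_schedule(schedule)
  trl <- schedule$trials
  treated <- trl$condition %in% c("verum", "sham")
  if (!any(treated) || all(treated))
    stopf("run contains no %s trials; cannot form both pain condition regressors",
          if (all(treated)) "untreated" else "treated")
  blocks <- list(
    Anticipation = data.frame(onset = trl$anticipation_onset,
                              duration = trl$anticipation_duration),
    Pain_Treat = data.frame(onset = trl$pain_onset[treated],
                            duration = trl$pain_duration[treated]),
    Pain_NoTreat = data.frame(onset = trl$pain_onset[!treated],
                              duration = trl$pain_duration[!treated]),
    Ratings = data.frame(onset = trl$rating_onset,
                         duration = trl$rating_duration))
  cols <- lapply(blocks, function(ev)
    rowSums(convolve_events(ev, hrf, schedule$total_duration, tr)))
  X <- do.call(cbind, cols)
  colnames(X) <- names(blocks)
  motion <- check_motion(motion, nrow(X))
  if (!is.null(motion)) X <- cbind(X, motion)
  new_design_matrix(X, tr, c("Anticipation", "Pain_Treat", "Pain_NoTreat"),
                    schedule)
}

#' Trial-wise (beta-series) first-level design matrix
#'
#' One regressor per trial for the phase of interest, with per-trial
#' regressors of the other phase, the pooled ratings blocks, and optional
#' motion series as nuisance. Column names carry the global trial index
#' (e.g. `Anticipation_t07`), so the 12 per-trial estimates of a session can
#' be assembled across the two runs.
#'
#' @inheritParams build_condition_design
#' @param phase `"anticipation"` or `"pain"`: which phase gets the
#'   of-interest per-trial regressors.
#' @return A `design_matrix`; `of_interest` names the six per-trial columns
#'   of the chosen phase for this run.
#' @export
build_trialwise_design <- function(schedule, hrf, tr = 2,
                                   phase = c("anticipation", "pain"),
                                   motion = NULL) {
  phase <- match.arg(phase)
  validate_event_schedule(schedule)
  trl <- schedule$trials
  ant <- convolve_events(data.frame(onset = trl$anticipation_onset,
                                    duration = trl$anticipation_duration),
                         hrf, schedule$total_duration, tr)
  pai <- convolve_events(data.frame(onset = trl$pain_onset,
                                    duration = trl$pain_duration),
                         hrf, schedule$total_duration, tr)
  colnames(ant) <- sprintf("Anticipation_t%02d", trl$trial_index)
  colnames(pai) <- sprintf("Pain_t%02d", trl$trial_index)
  ratings <- rowSums(convolve_events(data.frame(onset = trl$rating_onset,
                                                duration = trl$rating_duration),
                                     hrf, schedule$total_duration, tr))
  X <- cbind(ant, pai, Ratings = ratings)
  motion <- check_motion(motion, nrow(X))
  if (!is.null(motion)) X <- cbind(X, motion)
  of_interest <- if (phase == "anticipation") colnames(ant) else colnames(pai)
  new_design_matrix(X, tr, of_interest, schedule)
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d scans x %d regressors (TR %g s); of interest: %s\n",
              x$n_scans, length(x$column_names), x$tr,
              paste(x$of_interest, collapse = ", ")))
  invisible(x)
}
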