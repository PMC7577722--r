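# Formats: BIDS-style events TSV, wide CSV (and optional NIfTI) signal
# tables, ratings/facial CSV.

#' Write one run's event schedule as a BIDS-style events TSV
#'
#' One row per event with columns `onset`, `duration`, `trial_type`
#' (phase and condition joined as e.g. `anticipation_verum`) and
#' `trial_index` (global).
#'
#' @param schedule An `event_schedule`.
#' @param path Output file.
#' @export
write_events <- function(schedule, path) {
  validate_event_schedule(schedule)
  tr <- schedule$trials
  rows <- do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
    data.frame(
      onset = c(tr$anticipation_onset[i], tr$pain_onset[i], tr$rating_onset[i]),
      duration = c(tr$anticipation_duration[i], tr$pain_duration[i],
                   tr$rating_duration[i]),
      trial_type = paste(c("anticipation", "pain", "rating"),
                         tr$condition[i], sep = "_"),
      trial_index = tr$trial_index[i])
  }))
  utils::write.table(cbind(rows, run = schedule$run_index,
                           total_duration = schedule$total_duration),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events TSV into an event schedule
#'
#' Expects the dialect written by [write_events()]: tab-separated with
#' columns `onset`, `duration`, `trial_type` (phase_condition) and
#' `trial_index`; condition vocabulary is mapped to
#' verum / sham / no_treatment.
#'
#' @param path Events file for one run.
#' @return A validated `event_schedule`.
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type", "trial_index")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stopf("events file %s is missing columns: %s", path,
          paste(miss, collapse = ", "))
  phase <- sub("_(verum|sham|no_treatment)$", "", ev$trial_type)
  condition <- sub("^(anticipation|pain|rating)_", "", ev$trial_type)
  if (!all(condition %in% CONDITIONS))
    stopf("unknown condition labels in %s: %s", path,
          paste(unique(setdiff(condition, CONDITIONS)), collapse = ", "))
  if (!all(phase %in% c("anticipation", "pain", "rating")))
    stopf("unknown event phases in %s: %s", path,
          paste(unique(setdiff(phase, c("anticipation", "pain", "rating"))),
                collapse = ", "))
  ids <- sort(unique(ev$trial_index))
  if (length(ids) != 6L)
    stopf("expected 6 trials per run in %s, got %d", path, length(ids))
  grab <- function(ph, col) {
    sub <- ev[phase == ph, ]
    sub <- sub[order(sub$trial_index), ]
    if (nrow(sub) != 6L)
      stopf("expected one %s event per trial in %s", ph, path)
    sub[[col]]
  }
  trials <- data.frame(
    trial_index = ids,
    condition = {
      sub <- ev[phase == "anticipation", ]
      sub[order(sub$trial_index), "trial_type"] |>
        sub(pattern = "^anticipation_", replacement = "")
    },
    anticipation_onset = grab("anticipation", "onset"),
    anticipation_duration = grab("anticipation", "duration"),
    pain_onset = grab("pain", "onset"),
    pain_duration = grab("pain", "duration"),
    rating_onset = grab("rating", "onset"),
    rating_duration = grab("rating", "duration"),
    stringsAsFactors = FALSE)
  run <- if ("run" %in% names(ev)) ev$run[1] else 1L
  total <- if ("total_duration" %in% names(ev)) ev$total_duration[1]
           else max(trials$rating_onset + trials$rating_duration) + 16
  event_schedule(run, trials, total)
}

#' Read a region-by-time signal table
#'
#' Accepts either a wide CSV (rows = scans, columns = regions) or a 4D
#' NIfTI volume plus a label-mask NIfTI, in which case voxel values are
#' averaged within each positive integer mask label (requires the RNifti
#' package).
#'
#' @param path CSV or NIfTI (.nii/.nii.gz) file.
#' @param tr Declared repetition time; stored as attribute `"tr"`.
#' @param mask Path to an integer-labelled NIfTI mask (NIfTI input only).
#' @return `n_scans x regions` numeric matrix with region names, attribute
#'   `"tr"`.
#' @export
read_signals <- function(path, tr = 2, mask = NULL) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stopf("reading NIfTI input requires the RNifti package")
    if (is.null(mask)) stopf("NIfTI input requires a label mask")
    vol <- RNifti::readNifti(path)
    msk <- round(as.array(RNifti::readNifti(mask)))
    labels <- sort(unique(msk[msk > 0]))
    if (!length(labels)) stopf("mask %s contains no positive labels", mask)
    d <- dim(vol)
    nt <- d[length(d)]
    flat <- matrix(as.array(vol), ncol = nt)
    out <- vapply(labels, function(l) colMeans(flat[as.vector(msk == l), ,
                                                    drop = FALSE]),
                  numeric(nt))
    colnames(out) <- paste0("region", labels)
  } else {
    out <- as.matrix(utils::read.csv(path, check.names = FALSE))
  }
  if (anyNA(out)) stopf("signals in %s contain missing values", path)
  storage.mode(out) <- "double"
  attr(out, "tr") <- tr
  out
}

#' Write a signal matrix as a wide CSV
#' @param signals `n_scans x regions` matrix.
#' @param path Output file.
#' @export
write_signals <- function(signals, path) {
  utils::write.csv(as.data.frame(signals), path, row.names = FALSE)
  invisible(path)
}

#' Read a trial ratings CSV
#' @param path CSV with the [generate_ratings()] columns.
#' @return A validated ratings data.frame.
#' @export
read_ratings <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_index", "condition", "patient_pain",
            "clinician_vicarious_pain")
  miss <- setdiff(need, names(r))
  if (length(miss))
    stopf("ratings file %s is missing columns: %s", path,
          paste(miss, collapse = ", "))
  vas <- intersect(c("patient_pain", "clinician_vicarious_pain",
                     "patient_affect", "clinician_affect"), names(r))
  for (col in vas)
    if (any(r[[col]] < 0 | r[[col]] > 100))
      stopf("column %s in %s has values outside the VAS range [0, 100]",
            col, path)
  if (!all(r$condition %in% CONDITIONS))
    stopf("unknown condition labels in %s", path)
  r
}
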