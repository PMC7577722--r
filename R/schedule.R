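#' Event schedule for one hyperscanning run
#'
#' An `event_schedule` describes the timed trial structure of a single fMRI
#' run: six trials, each consisting of a jittered anticipation cue, a 15 s
#' pain/treatment block and a 16 s rating block (two consecutive 8 s
#' ratings), separated by rest. Trial indices are global (1..12 across the
#' two runs of a session).
#'
#' @param run_index 1 or 2.
#' @param trials A data.frame with one row per trial and columns
#'   `trial_index`, `condition` (one of `"verum"`, `"sham"`,
#'   `"no_treatment"`), `anticipation_onset`, `anticipation_duration`,
#'   `pain_onset`, `pain_duration`, `rating_onset`, `rating_duration`
#'   (all seconds from run start).
#' @param total_duration Run length in seconds.
#' @return A validated object of class `event_schedule`.
#' @export
event_schedule <- function(run_index, trials, total_duration) {
  x <- structure(list(run_index = as.integer(run_index),
                      trials = as.data.frame(trials),
                      total_duration = total_duration),
                 class = "event_schedule")
  validate_event_schedule(x)
  x
}

CONDITIONS <- c("verum", "sham", "no_treatment")

#' Validate an event schedule
#'
#' Checks the structural invariants of a run schedule: six trials, valid
#' condition labels, anticipation durations within \[6, 12\] s, 15 s pain
#' blocks, 16 s rating blocks, strictly ordered non-overlapping intervals,
#' and a total duration covering the last event.
#'
#' @param x An `event_schedule`.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_event_schedule <- function(x) {
  tr <- x$trials
  need <- c("trial_index", "condition", "anticipation_onset",
            "anticipation_duration", "pain_onset", "pain_duration",
            "rating_onset", "rating_duration")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stopf("schedule is missing columns: %s", paste(miss, collapse = ", "))
  if (nrow(tr) != 6L)
    stopf("a run schedule must contain exactly 6 trials, got %d", nrow(tr))
  if (!all(tr$condition %in% CONDITIONS))
    stopf("unknown condition labels: %s",
          paste(setdiff(tr$condition, CONDITIONS), collapse = ", "))
  if (any(tr$anticipation_duration < 6 - 1e-9 | tr$anticipation_duration > 12 + 1e-9))
    stopf("anticipation durations must lie in [6, 12] s")
  if (any(abs(tr$pain_duration - 15) > 1e-9))
    stopf("pain blocks must last 15 s")
  if (any(abs(tr$rating_duration - 16) > 1e-9))
    stopf("rating blocks must last 16 s (two 8 s ratings)")
  # flatten to an interval list and require strict ordering without overlap
  on <- c(rbind(tr$anticipation_onset, tr$pain_onset, tr$rating_onset))
  du <- c(rbind(tr$anticipation_duration, tr$pain_duration, tr$rating_duration))
  if (any(diff(on) <= 0))
    stopf("events within a run must be strictly ordered in time")
  if (any(on[-1] < (on + du)[-length(on)] - 1e-9))
    stopf("events within a run must not overlap")
  if (x$total_duration < max(on + du))
    stopf("total_duration (%g s) ends before the last event (%g s)",
          x$total_duration, max(on + du))
  invisible(x)
}

#' Generate the two-run trial schedule of one hyperscanning session
#'
#' Emits the paradigm used throughout the package: 12 trials split into two
#' runs of six, with four verum, four sham and four no-treatment trials in a
#' pseudo-randomised order (two of each condition per run, order shuffled
#' within run). Each trial is anticipation (uniform 6-12 s in 0.5 s steps),
#' a 15 s pain/treatment block, a post-stimulus rest gap (uniform 4-10 s in
#' 0.5 s steps), a 16 s rating block and an inter-trial rest gap (uniform
#' 4-10 s). Runs start with 8 s of rest and end with 16 s of rest so the
#' final response has room to evolve; the run length is rounded up to a
#' whole number of TRs.
#'
#' @param seed Integer seed; the same seed always yields byte-identical
#'   schedules.
#' @param tr_seconds Repetition time used to round the run length, seconds.
#' @return A list of two `event_schedule` objects (runs 1 and 2).
#' @examples
#' sch <- generate_schedule(seed = 1)
#' table(c(sch[[1]]$trials$condition, sch[[2]]$trials$condition))
#' @export
generate_schedule <- function(seed, tr_seconds = 2) {
  if (tr_seconds <= 0) stopf("'tr_seconds' must be positive")
  with_seed(seed, {
    per_run <- lapply(1:2, function(r) sample(rep(CONDITIONS, 2L)))
    lapply(1:2, function(r) {
      cond <- per_run[[r]]
      t <- 8
      rows <- vector("list", 6L)
      for (k in 1:6) {
        ant_dur <- sample(seq(6, 12, by = 0.5), 1L)
        post_gap <- sample(seq(4, 10, by = 0.5), 1L)
        iti <- sample(seq(4, 10, by = 0.5), 1L)
        ant_on <- t
        pain_on <- ant_on + ant_dur
        rate_on <- pain_on + 15 + post_gap
        rows[[k]] <- data.frame(trial_index = (r - 1L) * 6L + k,
                                condition = cond[k],
                                anticipation_onset = ant_on,
                                anticipation_duration = ant_dur,
                                pain_onset = pain_on, pain_duration = 15,
                                rating_onset = rate_on, rating_duration = 16,
                                stringsAsFactors = FALSE)
        t <- rate_on + 16 + iti
      }
      total <- ceiling((t + 16) / tr_seconds) * tr_seconds
      event_schedule(r, do.call(rbind, rows), total)
    })
  })
}

#' Condition labels of a two-run schedule, ordered by global trial index
#' @param schedules List of two `event_schedule` objects.
#' @return Character vector of length 12.
#' @export
schedule_conditions <- function(schedules) {
  tr <- do.call(rbind, lapply(schedules, function(s) s$trials))
  tr$condition[order(tr$trial_index)]
}

#' @export
print.event_schedule <- function(x, ...) {
  cat(sprintf("<event_schedule> run %d, %d trials, %g s\n",
              x$run_index, nrow(x$trials), x$total_duration))
  print(x$trials, row.names = FALSE)
  invisible(x)
}
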