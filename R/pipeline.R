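# End-to-end orchestration: simulate (or accept) a cohort of dyads, run
# first-level models, derive the conjunction ROI, compute dyadic
# concordance and its clinical-context contrast, behavioural statistics,
# and the concordance -> mediator -> analgesia mediation.

#' Pipeline configuration
#'
#' @param sim A [sim_config()] describing the synthetic cohort, or `NULL`
#'   when `dyads` supplies pre-assembled datasets.
#' @param dyads Optional list of `dyad_dataset` objects (real or simulated
#'   input assembled via the reading functions); exactly one of `sim` /
#'   `dyads` must be given.
#' @param seed Integer seed recorded in all outputs and driving every
#'   stochastic stage.
#' @param phase Phase used for the concordance beta series
#'   (`"anticipation"` or `"pain"`).
#' @param direction Reported concordance direction;
#'   `"patient_roi_to_clinician_brain"` (default) or
#'   `"clinician_roi_to_patient_brain"`.
#' @param roi Optional [roi_mask()] for the concordance ROI; by default it
#'   is derived from the group conjunction intersected with the anatomical
#'   coupled-region mask.
#' @param mediator_roi [roi_mask()] for the mediator region; defaults to
#'   the registry's vlPFC-like region.
#' @param n_boot Bootstrap draws for the mediation stage.
#' @param out_dir Optional directory; when set, [run_pipeline()] writes the
#'   result tables there as CSV plus a JSON provenance record.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), dyads = NULL, seed = 1,
                            phase = c("anticipation", "pain"),
                            direction = c("patient_roi_to_clinician_brain",
                                          "clinician_roi_to_patient_brain"),
                            roi = NULL, mediator_roi = NULL, n_boot = 1000,
                            out_dir = NULL) {
  phase <- match.arg(phase)
  direction <- match.arg(direction)
  if (is.null(sim) == is.null(dyads))
    stopf("exactly one of 'sim' (simulation block) or 'dyads' (input data) must be given")
  structure(list(sim = sim, dyads = dyads, seed = seed, phase = phase,
                 direction = direction, roi = roi,
                 mediator_roi = mediator_roi, n_boot = n_boot,
                 out_dir = out_dir),
            class = "pipeline_config")
}

# per-subject condition-wise session fit: fixed-effects average across the
# two runs of one contrast's estimate/variance; returns estimate, variance, z
session_contrast <- function(signals, schedules, hrf, tr, contrast) {
  est <- vector("list", length(schedules))
  v <- vector("list", length(schedules))
  for (r in seq_along(schedules)) {
    design <- build_condition_design(schedules[[r]], hrf, tr)
    fit <- fit_glm_prewhitened(signals[[r]], design)
    zmap <- contrast_z(fit, contrast)
    est[[r]] <- attr(zmap, "estimate")
    v[[r]] <- attr(zmap, "variance")
  }
  fixed_effects_average(est, v)
}

#' Run the full dyadic concordance pipeline
#'
#' Stages: (1) simulate or accept the dyad cohort; (2) condition-wise
#' prewhitened GLMs per member and run, fixed-effects averaged, feeding the
#' group conjunction that derives the functional concordance ROI and the
#' patients' treatment-contrast mediator values; (3) trial-wise GLMs and
#' ROI beta series per member; (4) dyadic concordance regressions in the
#' configured direction (the reverse direction's ROI-to-ROI value is also
#' recorded) and the clinical-context contrast of concordance slopes;
#' (5) behavioural statistics per dyad (analgesia, rating correspondence,
#' facial mirroring) and the verum/sham paired equivalence test;
#' (6) concordance-analgesia correlation and the bootstrap mediation
#' through the patients' mediator-region treatment response.
#'
#' All stages are deterministic given the configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_bundle`: `concordance` (per-dyad table),
#'   `context_contrast` (`stat_map`), `behavior` (per-dyad table),
#'   `equivalence` (TOST result), `concordance_analgesia`
#'   (correlation result), `mediation` (`mediation_result`), `roi`,
#'   `slopes` (dyads x regions), and `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    stopf("'config' must be a pipeline_config()")
  cohort <- if (!is.null(config$sim))
    simulate_cohort(config$sim, config$seed)
  else list(dyads = config$dyads,
            regions = config$dyads[[1]]$regions,
            cfg = NULL, seed = config$seed)
  dyads <- cohort$dyads
  regions <- cohort$regions
  cfg <- cohort$cfg
  tr <- if (!is.null(cfg)) cfg$tr_seconds else 2
  hrf <- do.call(canonical_hrf, if (!is.null(cfg)) cfg$hrf_params else list())
  coupled <- roi_mask(1L, regions[1])
  mediator_roi <- config$mediator_roi %||% roi_mask(2L, regions[2])

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # --- condition-wise fits: anticipation maps (ROI derivation) and the
  #     patients' treatment contrast (mediator) --------------------------
  cond <- stage("first_level_condition", {
    ant_p <- ant_c <- med_z <- NULL
    ant_p <- t(vapply(dyads, function(d)
      session_contrast(d$patient_signals, d$schedules, hrf, tr,
                       c(Anticipation = 1))$z, numeric(length(regions))))
    ant_c <- t(vapply(dyads, function(d)
      session_contrast(d$clinician_signals, d$schedules, hrf, tr,
                       c(Anticipation = 1))$z, numeric(length(regions))))
    med_z <- t(vapply(dyads, function(d)
      session_contrast(d$patient_signals, d$schedules, hrf, tr,
                       c(Pain_Treat = 1, Pain_NoTreat = -1))$z,
      numeric(length(regions))))
    colnames(ant_p) <- colnames(ant_c) <- colnames(med_z) <- regions
    list(ant_p = ant_p, ant_c = ant_c, med_z = med_z)
  })

  roi <- config$roi %||% stage("conjunction_roi",
    derive_conjunction_roi(cond$ant_p, cond$ant_c, coupled))

  # --- trial-wise fits and dyadic concordance --------------------------
  conc <- stage("concordance", lapply(dyads, function(d) {
    zp <- fit_trialwise_session(d$patient_signals, d$schedules, hrf, tr,
                                config$phase)
    zc <- fit_trialwise_session(d$clinician_signals, d$schedules, hrf, tr,
                                config$phase)
    sp <- extract_beta_series(zp, roi, paste0(d$dyad_id, "_patient"),
                              config$phase)
    sc <- extract_beta_series(zc, roi, paste0(d$dyad_id, "_clinician"),
                              config$phase)
    fwd <- dyadic_concordance(zc, sp, roi, d$dyad_id,
                              "patient_roi_to_clinician_brain")
    rev <- dyadic_concordance(zp, sc, roi, d$dyad_id,
                              "clinician_roi_to_patient_brain")
    if (config$direction == "patient_roi_to_clinician_brain")
      list(main = fwd, other = rev)
    else list(main = rev, other = fwd)
  }))
  slopes <- t(vapply(conc, function(x) x$main$slope, numeric(length(regions))))
  rownames(slopes) <- vapply(dyads, `[[`, "", "dyad_id")
  contexts <- vapply(dyads, `[[`, "", "context")
  ctx_map <- stage("context_contrast", context_contrast(slopes, contexts))

  concordance_tab <- data.frame(
    dyad_id = rownames(slopes), context = contexts,
    roi_to_roi_z = vapply(conc, function(x) x$main$roi_to_roi_z, 0),
    roi_to_roi_z_reverse = vapply(conc, function(x) x$other$roi_to_roi_z, 0),
    roi_to_roi_slope = vapply(conc, function(x) x$main$roi_to_roi_slope, 0),
    direction = config$direction, seed = config$seed,
    stringsAsFactors = FALSE)

  # --- behavioural statistics ------------------------------------------
  behavior <- stage("behavior", {
    med_val <- cond$med_z[, mediator_roi$indices, drop = FALSE]
    data.frame(
      dyad_id = rownames(slopes), context = contexts,
      analgesia = vapply(dyads, function(d) analgesia_score(d$ratings), 0),
      correspondence_r = vapply(dyads, function(d)
        correspondence_score(d$ratings$patient_pain,
                             d$ratings$clinician_vicarious_pain)$r, 0),
      correspondence_z = vapply(dyads, function(d)
        correspondence_score(d$ratings$patient_pain,
                             d$ratings$clinician_vicarious_pain)$z, 0),
      mirroring_r = vapply(dyads, function(d)
        facial_mirroring_score(d$facial$patient, d$facial$clinician,
                               d$conditions)$r, 0),
      mirroring_z = vapply(dyads, function(d)
        facial_mirroring_score(d$facial$patient, d$facial$clinician,
                               d$conditions)$z, 0),
      mediator_z = rowMeans(med_val),
      pain_treated = vapply(dyads, function(d)
        mean(d$ratings$patient_pain[d$ratings$condition %in%
                                      c("verum", "sham")]), 0),
      pain_untreated = vapply(dyads, function(d)
        mean(d$ratings$patient_pain[d$ratings$condition == "no_treatment"]), 0),
      seed = config$seed, stringsAsFactors = FALSE)
  })

  equivalence <- stage("equivalence", {
    verum <- vapply(dyads, function(d)
      mean(d$ratings$patient_pain[d$ratings$condition == "verum"]), 0)
    sham <- vapply(dyads, function(d)
      mean(d$ratings$patient_pain[d$ratings$condition == "sham"]), 0)
    tost_equivalence(verum, sham)
  })

  conc_beh <- stage("concordance_behavior",
    concordance_behavior_correlation(concordance_tab$roi_to_roi_z,
                                     behavior$analgesia))

  mediation <- stage("mediation",
    mediate_bootstrap(concordance_tab$roi_to_roi_z, behavior$mediator_z,
                      behavior$analgesia, n_boot = config$n_boot,
                      seed = derive_seed(config$seed, 7777)))

  bundle <- structure(list(
    concordance = concordance_tab,
    context_contrast = ctx_map,
    behavior = behavior,
    equivalence = equivalence,
    concordance_analgesia = conc_beh,
    mediation = mediation,
    roi = roi, slopes = slopes,
    anticipation_maps = cond[c("ant_p", "ant_c")],
    mediator_maps = cond$med_z,
    provenance = list(
      package = "dyadconcord",
      version = as.character(utils::packageVersion("dyadconcord")),
      seed = config$seed, phase = config$phase,
      direction = config$direction, n_dyads = length(dyads),
      contexts = c(sum(contexts == "clinical_interaction"),
                   sum(contexts == "no_interaction")),
      roi = list(label = roi$label, indices = roi$indices),
      simulated = !is.null(config$sim))),
    class = "pipeline_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' Write a pipeline bundle to disk
#'
#' CSV tables for the concordance, context-contrast and behaviour results,
#' a JSON summary of the equivalence / correlation / mediation statistics,
#' and a JSON provenance record (configuration echo and seed).
#'
#' @param bundle A `pipeline_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$concordance,
                   file.path(dir, "concordance.csv"), row.names = FALSE)
  utils::write.csv(bundle$behavior,
                   file.path(dir, "behavior.csv"), row.names = FALSE)
  utils::write.csv(data.frame(region = names(bundle$context_contrast),
                              z = as.numeric(bundle$context_contrast),
                              seed = bundle$provenance$seed),
                   file.path(dir, "context_contrast.csv"), row.names = FALSE)
  med <- bundle$mediation
  stats <- list(
    equivalence = bundle$equivalence[c("t", "p", "df", "dz", "equivalent")],
    concordance_analgesia = bundle$concordance_analgesia,
    mediation = med[c("a", "b", "c", "c_prime", "indirect", "ci",
                      "p_indirect", "p_c", "p_c_prime", "n_boot",
                      "significant_mediation")])
  jsonlite::write_json(stats, file.path(dir, "statistics.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  pr <- x$provenance
  cat(sprintf("<pipeline_bundle> %d dyads (%s), phase %s, seed %d\n",
              pr$n_dyads, paste(pr$contexts, collapse = "/"), pr$phase,
              pr$seed))
  cat(sprintf("  ROI '%s' context contrast z = %.3f\n", x$roi$label,
              as.numeric(x$context_contrast)[x$roi$indices[1]]))
  cat(sprintf("  concordance-analgesia r = %.3f (p = %.4g)\n",
              x$concordance_analgesia$r, x$concordance_analgesia$p))
  cat(sprintf("  mediation indirect = %.3f [%.3f, %.3f]\n",
              x$mediation$indirect, x$mediation$ci[1], x$mediation$ci[2]))
  invisible(x)
}
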