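# Synthetic dyad generator: schedules, coupled latent trial amplitudes,
# AR(1)-noise BOLD forward model, ratings and facial-expression features
# with known ground truth.

REGION_NAMES <- c("rTPJ", "vlPFC", "aINS", "lSTS", "mPFC", "dlPFC", "SMG",
                  "precuneus")
FACIAL_CHANNELS <- c("joy", "fear", "disgust", "sadness", "anger",
                     "surprise", "contempt", "valence", "engagement")

#' Simulation configuration for synthetic hyperscanning dyads
#'
#' Collects every latent parameter of the generator. Defaults emulate the
#' study conditions the pipeline targets: 37 dyads (19 scanned after a
#' clinical intake, 18 without), a 12-trial two-run session of 4 verum /
#' 4 sham / 4 no-treatment trials, inter-brain trial-amplitude coupling in
#' the coupled region only when clinical rapport exists, a 6.6 VAS-point
#' mean treatment-related pain reduction, and moderate rating
#' correspondence and facial mirroring.
#'
#' @param n_dyads Number of dyads.
#' @param context_split Named counts per context
#'   (`clinical_interaction`, `no_interaction`); must sum to `n_dyads`.
#' @param coupling_rho Named per-context correlation in \[-1, 1\] of the
#'   patient and clinician per-trial amplitude deviations in the coupled
#'   region.
#' @param treatment_effect Mean reduction of patient pain ratings on
#'   treated trials, VAS points.
#' @param correspondence_rho Correlation in \[-1, 1\] between the patient's
#'   trial-by-trial pain and the clinician's vicarious pain.
#' @param mirroring_rho Correlation in \[-1, 1\] between the members'
#'   facial treatment-related change vectors across the 9 channels.
#' @param ar_phi AR(1) coefficient of the BOLD noise, in (-1, 1).
#' @param noise_sd Innovation standard deviation of the BOLD noise (> 0).
#' @param tr_seconds Repetition time, seconds.
#' @param hrf_params List of arguments passed to [canonical_hrf()].
#' @param n_regions Number of synthetic regions; region 1 ("rTPJ") carries
#'   the inter-brain coupling, region 2 ("vlPFC") carries the mediation
#'   chain, the rest are independent.
#' @param amp_sd Trial-to-trial standard deviation of latent amplitude
#'   deviations around `base_amp`.
#' @param base_amp Named mean amplitudes of the anticipation and pain
#'   responses (arbitrary BOLD units).
#' @param rating_amp Amplitude of the rating-period response.
#' @param rating_noise_sd Trial-level rating noise, VAS points.
#' @param patient_pain_mean,vicarious_pain_mean,affect_mean Baseline VAS
#'   means of the rating channels.
#' @param rating_sd Population standard deviation used to scale the
#'   clinician channels.
#' @param affect_effect Mean affect increase on treated trials, VAS points.
#' @param facial_change_sd Standard deviation across channels of the latent
#'   treatment-related facial change.
#' @param facial_noise_sd Per-trial measurement noise of facial channels.
#' @param mediation List describing the planted mediation chain:
#'   `enabled`, `a` (coupled-region slope: vlPFC treatment contrast per
#'   unit of realized coupling, centred at the context's nominal rho),
#'   `b` (VAS rating reduction per unit of vlPFC contrast),
#'   `mediator_noise_sd`, `analgesia_noise_sd` (dyad-level VAS noise).
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_dyads = 37,
                       context_split = c(clinical_interaction = 19,
                                         no_interaction = 18),
                       coupling_rho = c(clinical_interaction = 0.6,
                                        no_interaction = 0),
                       treatment_effect = 6.6,
                       correspondence_rho = 0.4,
                       mirroring_rho = 0.5,
                       ar_phi = 0.3,
                       noise_sd = 0.5,
                       tr_seconds = 2,
                       hrf_params = list(),
                       n_regions = 8,
                       amp_sd = 0.5,
                       base_amp = c(anticipation = 1, pain = 1.5),
                       rating_amp = 0.5,
                       rating_noise_sd = 10,
                       patient_pain_mean = 33,
                       vicarious_pain_mean = 26,
                       affect_mean = 50,
                       rating_sd = 10,
                       affect_effect = 15,
                       facial_change_sd = 15,
                       facial_noise_sd = 2,
                       mediation = list(enabled = TRUE, a = 1, b = 12,
                                        mediator_noise_sd = 0.3,
                                        analgesia_noise_sd = 4)) {
  cfg <- as.list(environment())
  check_correlation(coupling_rho, "coupling_rho")
  check_correlation(correspondence_rho, "correspondence_rho")
  check_correlation(mirroring_rho, "mirroring_rho")
  if (abs(ar_phi) >= 1) stopf("'ar_phi' must lie in (-1, 1)")
  if (noise_sd <= 0) stopf("'noise_sd' must be positive")
  if (tr_seconds <= 0) stopf("'tr_seconds' must be positive")
  if (sum(context_split) != n_dyads)
    stopf("context_split sums to %d but n_dyads is %d",
          sum(context_split), n_dyads)
  if (!all(c("clinical_interaction", "no_interaction") %in%
           names(context_split)))
    stopf("context_split must name clinical_interaction and no_interaction")
  if (n_regions < 2) stopf("need at least 2 regions (coupled + mediator)")
  cfg$region_names <- if (n_regions <= length(REGION_NAMES))
    REGION_NAMES[seq_len(n_regions)]
  else c(REGION_NAMES, sprintf("region%02d",
                               seq_len(n_regions - length(REGION_NAMES))))
  cfg$coupled_region <- 1L
  cfg$mediator_region <- 2L
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d dyads (%d CI / %d NI), coupling rho CI %.2f / NI %.2f,\n",
                     "  treatment effect %.1f VAS, correspondence rho %.2f, mirroring rho %.2f,\n",
                     "  AR(1) phi %.2f, noise sd %.2f, TR %g s, %d regions\n"),
              x$n_dyads, x$context_split[["clinical_interaction"]],
              x$context_split[["no_interaction"]],
              x$coupling_rho[["clinical_interaction"]],
              x$coupling_rho[["no_interaction"]], x$treatment_effect,
              x$correspondence_rho, x$mirroring_rho, x$ar_phi, x$noise_sd,
              x$tr_seconds, x$n_regions))
  invisible(x)
}

# draws a pair of length-n vectors with correlation rho
bivariate_pair <- function(n, rho, sd = 1) {
  z1 <- rnorm(n); z2 <- rnorm(n)
  list(x = z1 * sd, y = (rho * z1 + sqrt(1 - rho^2) * z2) * sd)
}

#' Latent paired trial amplitudes for one dyad
#'
#' Draws the per-trial amplitude deviations for every region and both dyad
#' members. In the coupled region the patient and clinician anticipation
#' deviations are bivariate normal with correlation `coupling_rho` for the
#' dyad's context; all other regions (and all pain-phase deviations) are
#' independent between members. When the mediation chain is enabled, the
#' patient's mediator-region pain amplitude is shifted on treated trials by
#' a contrast that is a linear function of the dyad's realized coupling
#' (centred at the context's nominal rho) plus noise.
#'
#' @param cfg A [sim_config()].
#' @param conditions Length-12 condition vector from
#'   [schedule_conditions()].
#' @param context `"clinical_interaction"` or `"no_interaction"`.
#' @param seed Integer seed.
#' @return List with per-member lists of `anticipation` and `pain`
#'   amplitude matrices (12 x regions) and a `truth` record holding the
#'   deviations, the realized coupling and the planted mediator contrast.
#' @export
generate_latent_amplitudes <- function(cfg, conditions, context, seed) {
  if (!context %in% names(cfg$coupling_rho))
    stopf("no coupling_rho defined for context '%s'", context)
  rho <- check_correlation(cfg$coupling_rho[[context]], "coupling_rho")
  R <- cfg$n_regions
  with_seed(seed, {
    ant_p <- matrix(rnorm(12 * R, sd = cfg$amp_sd), 12, R)
    ant_c <- matrix(rnorm(12 * R, sd = cfg$amp_sd), 12, R)
    cp <- bivariate_pair(12, rho, cfg$amp_sd)
    ant_p[, cfg$coupled_region] <- cp$x
    ant_c[, cfg$coupled_region] <- cp$y
    pain_p <- matrix(rnorm(12 * R, sd = cfg$amp_sd), 12, R)
    pain_c <- matrix(rnorm(12 * R, sd = cfg$amp_sd), 12, R)
    realized <- stats::cor(ant_p[, cfg$coupled_region],
                           ant_c[, cfg$coupled_region])
    delta_vlpfc <- if (isTRUE(cfg$mediation$enabled))
      cfg$mediation$a * (realized - rho) +
        rnorm(1, sd = cfg$mediation$mediator_noise_sd)
    else 0
    treated <- conditions %in% c("verum", "sham")
    amp <- function(dev, phase) dev + cfg$base_amp[[phase]]
    pain_amp_p <- amp(pain_p, "pain")
    pain_amp_p[treated, cfg$mediator_region] <-
      pain_amp_p[treated, cfg$mediator_region] + delta_vlpfc
    colnames(ant_p) <- colnames(ant_c) <- cfg$region_names
    list(patient = list(anticipation = amp(ant_p, "anticipation"),
                        pain = pain_amp_p),
         clinician = list(anticipation = amp(ant_c, "anticipation"),
                          pain = amp(pain_c, "pain")),
         truth = list(ant_dev_patient = ant_p, ant_dev_clinician = ant_c,
                      realized_coupling = realized,
                      delta_vlpfc = delta_vlpfc, context = context,
                      coupling_rho = rho))
  })
}

# stationary AR(1) noise matrix, n x R
ar1_noise <- function(n, R, phi, sd) {
  innov <- matrix(rnorm(n * R, sd = sd), n, R)
  if (phi == 0) return(innov)
  innov[1, ] <- innov[1, ] / sqrt(1 - phi^2)
  apply(innov, 2, function(e) stats::filter(e, phi, method = "recursive"))
}

#' Forward BOLD model for one subject and one session
#'
#' Each region's time series is the sum over events of the event's latent
#' amplitude times the HRF-convolved boxcar, plus stationary AR(1) Gaussian
#' noise (coefficient `ar_phi`, innovation sd `noise_sd`). Rating periods
#' contribute a fixed-amplitude response in every region.
#'
#' @param amplitudes Per-member element of
#'   [generate_latent_amplitudes()]: list with `anticipation` and `pain`
#'   12 x regions amplitude matrices.
#' @param schedules List of two `event_schedule`s.
#' @param cfg A [sim_config()].
#' @param hrf An [canonical_hrf()]; defaults to the config's HRF.
#' @param seed Integer seed (noise only; the signal part is deterministic).
#' @return List of two `n_scans x regions` matrices, one per run.
#' @export
synthesize_bold <- function(amplitudes, schedules, cfg, hrf = NULL, seed = 1) {
  hrf <- hrf %||% do.call(canonical_hrf, cfg$hrf_params)
  if (abs(cfg$ar_phi) >= 1) stopf("'ar_phi' must lie in (-1, 1)")
  with_seed(seed, lapply(seq_along(schedules), function(r) {
    sch <- schedules[[r]]
    trl <- sch$trials
    rows <- trl$trial_index  # global indices of this run's trials
    ev <- data.frame(
      onset = c(trl$anticipation_onset, trl$pain_onset, trl$rating_onset),
      duration = c(trl$anticipation_duration, trl$pain_duration,
                   trl$rating_duration))
    E <- convolve_events(ev, hrf, sch$total_duration, cfg$tr_seconds)
    A <- rbind(amplitudes$anticipation[rows, , drop = FALSE],
               amplitudes$pain[rows, , drop = FALSE],
               matrix(cfg$rating_amp, 6, cfg$n_regions))
    Y <- E %*% A + ar1_noise(nrow(E), cfg$n_regions, cfg$ar_phi, cfg$noise_sd)
    colnames(Y) <- cfg$region_names
    Y
  }))
}

#' Trial ratings for one dyad
#'
#' Patient pain is `patient_pain_mean` minus the dyad's treatment-related
#' reduction on treated trials plus Gaussian trial noise; the reduction is
#' `treatment_effect` plus the mediation-chain contribution
#' (`b * delta_vlpfc`) plus dyad-level noise, so analgesia has known ground
#' truth. The clinician's vicarious pain is built from the patient's
#' standardized full-series deviation so its population Pearson correlation
#' with patient pain equals `correspondence_rho` exactly. Affect channels
#' are generated analogously with the treatment sign inverted (treated
#' trials more positive). All values are clipped to \[0, 100\].
#'
#' @param cfg A [sim_config()].
#' @param truth Truth record from [generate_latent_amplitudes()] (used for
#'   the planted mediator contrast); may be `NULL` for a chain-free dyad.
#' @param conditions Length-12 condition vector.
#' @param seed Integer seed.
#' @return A ratings data.frame (class `ratings_table`) with columns
#'   `trial_index`, `condition`, `patient_pain`,
#'   `clinician_vicarious_pain`, `patient_affect`, `clinician_affect`, and
#'   the realized `rating_reduction` in attribute `"truth"`.
#' @export
generate_ratings <- function(cfg, truth = NULL, conditions, seed) {
  rho <- check_correlation(cfg$correspondence_rho, "correspondence_rho")
  treated <- conditions %in% c("verum", "sham")
  f <- mean(treated)
  with_seed(seed, {
    delta <- if (is.null(truth)) 0 else truth$delta_vlpfc
    reduction <- cfg$treatment_effect +
      (if (isTRUE(cfg$mediation$enabled)) cfg$mediation$b * delta else 0) +
      rnorm(1, sd = cfg$mediation$analgesia_noise_sd %||% 0)
    noise_p <- rnorm(12, sd = cfg$rating_noise_sd)
    pain_mu <- cfg$patient_pain_mean - reduction * treated
    pain_raw <- pain_mu + noise_p
    # population moments of the patient's series, for exact-rho construction
    overall_mean <- cfg$patient_pain_mean - reduction * f
    overall_sd <- sqrt(f * (1 - f) * reduction^2 + cfg$rating_noise_sd^2)
    zdev <- (pain_raw - overall_mean) / overall_sd
    vic_raw <- cfg$vicarious_pain_mean + cfg$rating_sd *
      (rho * zdev + sqrt(1 - rho^2) * rnorm(12))
    aff_mu <- cfg$affect_mean + cfg$affect_effect * treated
    aff_raw <- aff_mu + rnorm(12, sd = cfg$rating_noise_sd)
    aff_sd <- sqrt(f * (1 - f) * cfg$affect_effect^2 + cfg$rating_noise_sd^2)
    zdev_a <- (aff_raw - (cfg$affect_mean + cfg$affect_effect * f)) / aff_sd
    caff_raw <- cfg$affect_mean + cfg$rating_sd *
      (rho * zdev_a + sqrt(1 - rho^2) * rnorm(12))
    clip <- function(x) pmin(100, pmax(0, x))
    out <- data.frame(trial_index = 1:12, condition = conditions,
                      patient_pain = clip(pain_raw),
                      clinician_vicarious_pain = clip(vic_raw),
                      patient_affect = clip(aff_raw),
                      clinician_affect = clip(caff_raw),
                      stringsAsFactors = FALSE)
    class(out) <- c("ratings_table", class(out))
    attr(out, "truth") <- list(rating_reduction = reduction)
    out
  })
}

#' Facial-expression trial features for one dyad
#'
#' Nine expression channels (seven basic emotions plus valence and
#' engagement) by 12 trials per member. Each member's latent
#' treatment-related change vector across channels is drawn so the
#' inter-member correlation of the change vectors is `mirroring_rho` in
#' expectation; treated trials are shifted by the change, untreated trials
#' sit at the channel baseline, and small per-trial measurement noise is
#' added before clipping to \[0, 100\].
#'
#' @inheritParams generate_ratings
#' @param phase Phase label stored with the features.
#' @return List with `patient` and `clinician` feature objects (class
#'   `facial_features`: `member`, `phase`, `values` 9 x 12 matrix) and a
#'   `truth` record with the latent change vectors.
#' @export
generate_facial <- function(cfg, conditions, seed, phase = "anticipation") {
  rho <- check_correlation(cfg$mirroring_rho, "mirroring_rho")
  treated <- conditions %in% c("verum", "sham")
  baseline <- c(40, 30, 30, 30, 30, 35, 30, 50, 55)
  with_seed(seed, {
    ch <- bivariate_pair(9, rho, cfg$facial_change_sd)
    mk <- function(delta, member) {
      vals <- baseline + outer(delta, as.numeric(treated)) +
        matrix(rnorm(9 * 12, sd = cfg$facial_noise_sd), 9, 12)
      vals <- pmin(pmax(vals, 0), 100)
      dimnames(vals) <- list(FACIAL_CHANNELS, sprintf("trial%02d", 1:12))
      structure(list(member = member, phase = phase, values = vals),
                class = "facial_features")
    }
    list(patient = mk(ch$x, "patient"), clinician = mk(ch$y, "clinician"),
         truth = list(delta_patient = ch$x, delta_clinician = ch$y))
  })
}

#' Simulate one complete hyperscanning dyad
#'
#' Draws a schedule, coupled latent amplitudes, BOLD for both members (who
#' share the schedule, as in simultaneous scanning), ratings and facial
#' features, and stores the full ground truth.
#'
#' @param cfg A [sim_config()].
#' @param dyad_id Identifier.
#' @param context `"clinical_interaction"` or `"no_interaction"`.
#' @param seed Integer seed; every component draws from a seed derived
#'   from it.
#' @param order Counterbalancing label (`"ci_first"`/`"ni_first"`),
#'   recorded but not otherwise used by the generator.
#' @return An object of class `dyad_dataset`.
#' @export
simulate_dyad <- function(cfg, dyad_id, context, seed,
                          order = c("ci_first", "ni_first")) {
  order <- match.arg(order)
  hrf <- do.call(canonical_hrf, cfg$hrf_params)
  schedules <- generate_schedule(derive_seed(seed, 1), cfg$tr_seconds)
  conditions <- schedule_conditions(schedules)
  lat <- generate_latent_amplitudes(cfg, conditions, context,
                                    derive_seed(seed, 2))
  patient <- synthesize_bold(lat$patient, schedules, cfg, hrf,
                             derive_seed(seed, 3))
  clinician <- synthesize_bold(lat$clinician, schedules, cfg, hrf,
                               derive_seed(seed, 4))
  ratings <- generate_ratings(cfg, lat$truth, conditions,
                              derive_seed(seed, 5))
  facial <- generate_facial(cfg, conditions, derive_seed(seed, 6))
  truth <- c(lat$truth, attr(ratings, "truth"),
             list(facial = facial$truth, seed = seed))
  structure(list(dyad_id = dyad_id, context = context, order = order,
                 schedules = schedules, conditions = conditions,
                 patient_signals = patient, clinician_signals = clinician,
                 ratings = ratings,
                 facial = facial[c("patient", "clinician")],
                 regions = cfg$region_names, truth = truth),
            class = "dyad_dataset")
}

#' @export
print.dyad_dataset <- function(x, ...) {
  cat(sprintf("<dyad_dataset> %s (%s), %d regions, runs of %d/%d scans\n",
              x$dyad_id, x$context, length(x$regions),
              nrow(x$patient_signals[[1]]), nrow(x$patient_signals[[2]])))
  invisible(x)
}

#' Simulate a cohort of dyads
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; dyad `i` uses a seed derived from it.
#' @return List with `dyads` (list of [simulate_dyad()] results, contexts
#'   interleaved per `cfg$context_split`), `regions`, `cfg` and `seed`.
#' @export
simulate_cohort <- function(cfg, seed = 1) {
  contexts <- rep(names(cfg$context_split), cfg$context_split)
  dyads <- lapply(seq_along(contexts), function(i)
    simulate_dyad(cfg, sprintf("dyad%03d", i), contexts[i],
                  derive_seed(seed, 100 + i),
                  order = if (i %% 2L == 0L) "ni_first" else "ci_first"))
  list(dyads = dyads, regions = cfg$region_names, cfg = cfg, seed = seed)
}
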