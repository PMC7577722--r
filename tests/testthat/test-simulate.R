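conds <- rep(c("verum", "sham", "no_treatment"), 4)

test_that("simulation configuration enforces its invariants", {
  expect_error(sim_config(coupling_rho = c(clinical_interaction = 1.2,
                                           no_interaction = 0)),
               "\\[-1, 1\\]")
  expect_error(sim_config(noise_sd = 0), "positive")
  expect_error(sim_config(ar_phi = 1), "\\(-1, 1\\)")
  expect_error(sim_config(n_dyads = 5,
                          context_split = c(clinical_interaction = 3,
                                            no_interaction = 3)),
               "sums to")
})

test_that("perfect coupling yields identical amplitude deviations in the coupled region", {
  cfg <- unit_cfg(rho = 1)
  lat <- generate_latent_amplitudes(cfg, conds, "clinical_interaction", 5)
  expect_equal(lat$truth$ant_dev_patient[, 1], lat$truth$ant_dev_clinician[, 1])
  expect_equal(lat$truth$realized_coupling, 1)
  expect_error(generate_latent_amplitudes(cfg, conds, "unknown_context", 5),
               "unknown_context")
})

test_that("latent coupling matches its nominal value in expectation", {
  cfg <- unit_cfg(rho = 0.6)
  rc <- vapply(1:800, function(i)
    generate_latent_amplitudes(cfg, conds, "clinical_interaction",
                               i)$truth$realized_coupling, numeric(1))
  expect_lt(abs(mean(rc) - 0.6), 0.05)
})

test_that("BOLD synthesis is the amplitude-scaled convolved response plus AR noise", {
  cfg <- unit_cfg(noise_sd = 1e-7, rating_amp = 0)
  sch <- generate_schedule(3, cfg$tr_seconds)
  hrf <- canonical_hrf()
  zero <- list(anticipation = matrix(0, 12, cfg$n_regions),
               pain = matrix(0, 12, cfg$n_regions))
  flat <- synthesize_bold(zero, sch, cfg, hrf, seed = 1)
  expect_lt(max(abs(flat[[1]])), 1e-5)  # null signal, near-null noise
  # single unit-amplitude anticipation event reproduces the convolved kernel
  one <- zero
  one$anticipation[1, 1] <- 1
  y <- synthesize_bold(one, sch, cfg, hrf, seed = 1)[[1]][, 1]
  trl <- sch[[1]]$trials[1, ]
  oracle <- dyadconcord:::convolve_events(
    data.frame(onset = trl$anticipation_onset,
               duration = trl$anticipation_duration),
    hrf, sch[[1]]$total_duration, cfg$tr_seconds)[, 1]
  expect_equal(y, oracle, tolerance = 1e-4)
  peak_time <- (which.max(y) - 0.5) * cfg$tr_seconds
  expect_gt(peak_time, trl$anticipation_onset + hrf$params$peak_delay - 2)
})

test_that("identical seeds give bit-identical dyads", {
  cfg <- small_cfg(2, 2)
  expect_identical(simulate_dyad(cfg, "d", "clinical_interaction", 9),
                   simulate_dyad(cfg, "d", "clinical_interaction", 9))
  expect_false(identical(simulate_dyad(cfg, "d", "clinical_interaction", 9),
                         simulate_dyad(cfg, "d", "clinical_interaction", 10)))
})

test_that("ratings carry the planted treatment effect and stay on the VAS scale", {
  cfg <- unit_cfg(mediation = list(enabled = FALSE, analgesia_noise_sd = 0))
  r <- generate_ratings(cfg, NULL, conds, 2)
  expect_s3_class(r, "ratings_table")
  expect_equal(nrow(r), 12)
  expect_true(all(r$patient_pain >= 0 & r$patient_pain <= 100))
  expect_true(all(r$clinician_vicarious_pain >= 0 &
                    r$clinician_vicarious_pain <= 100))
  # with the treatment effect switched off the mean difference is null
  cfg0 <- unit_cfg(treatment_effect = 0,
                   mediation = list(enabled = FALSE, analgesia_noise_sd = 0))
  d <- vapply(1:1000, function(i)
    analgesia_score(generate_ratings(cfg0, NULL, conds, i)), numeric(1))
  expect_lt(abs(mean(d)), 0.5)
})

test_that("perfect correspondence makes the clinician series affine in the patient's", {
  cfg <- unit_cfg(correspondence_rho = 1, rating_noise_sd = 5,
                  mediation = list(enabled = FALSE, analgesia_noise_sd = 0))
  r <- generate_ratings(cfg, NULL, conds, 3)
  expect_gt(cor(r$clinician_vicarious_pain, r$patient_pain)^2, 0.999)
})

test_that("facial features have nine channels and obey the mirroring limits", {
  cfg <- unit_cfg()
  f <- generate_facial(cfg, conds, 4)
  expect_equal(nrow(f$patient$values), 9)
  expect_equal(ncol(f$patient$values), 12)
  expect_true(all(f$patient$values >= 0 & f$patient$values <= 100))
  # perfect mirroring with no measurement noise: identical change vectors
  cfg1 <- unit_cfg(mirroring_rho = 1, facial_noise_sd = 0)
  f1 <- generate_facial(cfg1, conds, 4)
  s <- facial_mirroring_score(f1$patient, f1$clinician, conds)
  expect_equal(s$change$patient, s$change$clinician)
  expect_equal(s$r, 1)
})

test_that("a simulated cohort respects the context split and shares schedules in-dyad", {
  cfg <- small_cfg(3, 2)
  cohort <- simulate_cohort(cfg, 1)
  ctx <- vapply(cohort$dyads, `[[`, "", "context")
  expect_equal(sum(ctx == "clinical_interaction"), 3)
  expect_equal(sum(ctx == "no_interaction"), 2)
  d <- cohort$dyads[[1]]
  # both members share identical schedules and consistent signal lengths
  expect_equal(nrow(d$patient_signals[[1]]), nrow(d$clinician_signals[[1]]))
  expect_equal(nrow(d$patient_signals[[1]]),
               round(d$schedules[[1]]$total_duration / cfg$tr_seconds))
})
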