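---
title: "Trial-wise brain-to-brain concordance for hyperscanning dyads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-wise brain-to-brain concordance for hyperscanning dyads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadconcord)
```

## The scientific problem

In hyperscanning experiments two interacting people — here a patient with
chronic pain and a clinician treating that pain — are scanned
simultaneously while sharing a common experimental timeline. The question
this package addresses is whether the two brains *co-fluctuate* beyond
what the shared timeline imposes: does a trial on which the patient's
right temporoparietal junction (rTPJ) responds unusually strongly also
show an unusually strong response in the clinician's brain, and is that
coupling (a) specific to dyads with an established clinical relationship
and (b) relevant to the patient's treatment analgesia?

The central methodological hazard is **pseudo-concordance**: any two
people receiving the same stimulus sequence will show correlated raw BOLD
series simply because both respond to the same events. A model-free
volume-by-volume correlation therefore overstates coupling. The approach
implemented here first removes the shared task structure with a
first-level GLM per person — one regressor per trial — and only then asks
whether the *residual trial-to-trial deviations* of one person's ROI
co-vary with the partner's. Concordance is defined on per-trial effect
estimates (a "beta series" of z statistics), not on raw time courses.

## The generative model behind the simulator

The synthetic dyad generator (`sim_config()`, `simulate_dyad()`)
produces complete sessions with known ground truth so every stage can be
tested for calibration and recovery:

* **Schedule.** Two runs of six trials; four verum, four sham and four
  no-treatment trials per session, pseudo-randomised as two of each
  condition per run. Each trial is a jittered anticipation cue (uniform
  6–12 s in 0.5 s steps), a 15 s pain/treatment block, a 4–10 s rest gap,
  a 16 s rating block (two consecutive 8 s ratings) and a 4–10 s
  inter-trial rest. Balancing two trials of each condition into each run
  guarantees that every condition regressor is estimable in every run;
  the order within a run is fully randomised.
* **Latent amplitudes.** Each region's per-trial response amplitude is a
  base amplitude (1.0 for anticipation, 1.5 for pain, arbitrary BOLD
  units) plus a Gaussian deviation with sd 0.5. In the coupled region
  (the "rTPJ" of the registry) the patient and clinician anticipation
  deviations are bivariate normal with correlation `coupling_rho`, set
  per clinical context (defaults: 0.6 with clinical interaction, 0
  without). All other regions, and all pain-phase deviations, are
  independent between members.
* **Forward BOLD model.** Amplitude-scaled boxcars convolved with a
  double-gamma HRF, plus stationary AR(1) Gaussian noise
  (`ar_phi = 0.3`, innovation sd 0.5). AR(1) was chosen to match the
  prewhitening model in the estimator, so estimator correctness can be
  tested under a correctly specified noise model; real FMRI noise is
  longer-tailed and the estimator's single-lag whitening is a documented
  simplification of tapered full-autocorrelation schemes.
* **Ratings.** Patient pain is `patient_pain_mean` (33 VAS) minus a
  dyad-level treatment reduction on treated trials plus trial noise
  (sd 10 VAS), clipped to [0, 100]. The default reduction of 6.6 VAS
  points reproduces the scale of treated vs untreated group means
  (about 26 vs 33). The clinician's vicarious pain is constructed from
  the patient's *standardized full-series deviation* so that the
  population Pearson correlation across the 12 trials equals
  `correspondence_rho` exactly; building it from condition means plus
  correlated noise instead would inflate the realized correlation above
  its nominal value and make calibration unverifiable. A consequence,
  documented deliberately: the clinician's treatment-related vicarious
  reduction arises through the correlation rather than as an independent
  parameter. Affect channels are generated analogously with the
  treatment sign inverted.
* **Facial features.** Nine channels (seven basic expressions plus
  valence and engagement) by 12 trials per member. Each member carries a
  latent treatment-related change vector across channels (sd 15);
  the two members' vectors are correlated at `mirroring_rho`
  (default 0.5). Per-trial measurement noise is small (sd 2) so that the
  estimated change vectors attenuate the latent correlation by under 2%;
  large trial noise would make the 9-point channel correlation an
  unusably noisy estimate of the latent mirroring.
* **Mediation chain.** The patient's mediator-region ("vlPFC")
  treated-trial pain amplitude is shifted by
  `a * (realized coupling − nominal coupling) + noise`, and the dyad's
  rating reduction by `b ×` that shift, so coupling → vlPFC → analgesia
  has known ground truth. The realized coupling is centred at the
  context's nominal value so that the *mean* rating reduction stays at
  `treatment_effect` — an uncentred chain would confound the treatment
  calibration with the mediation strength. Defaults `a = 1` (amplitude
  units per unit correlation) and `b = 12` (VAS per amplitude unit)
  produce a moderate, realistic negative concordance–analgesia
  correlation (about −0.3 in expectation at 37 dyads).

What the generator does **not** emulate: spatially correlated noise and
smoothing, physiological confounds, motion (the motion regressors exist
in the designs but the simulator produces none), registration error
between subjects, individual HRF variability, and missing data. Passing
tests therefore demonstrate the estimator's statistical correctness under
its stated model, not robustness to every property of real data.

## Estimation

**Design matrices.** Boxcars are built on the HRF's 0.1 s grid, convolved
analytically (running-integral form of the boxcar ⊛ kernel convolution),
and sampled at TR midpoints (TR default 2 s) — fine-grid construction
avoids onset quantisation bias for jittered onsets. The condition-wise
design has Anticipation, Pain_Treat, Pain_NoTreat and Ratings columns
(plus optional motion nuisance); rest is the implicit baseline. The
trial-wise design carries one regressor per trial of the phase of
interest and per-trial nuisance regressors for the other phase. No
high-pass filtering is applied at this scale; the simulator produces no
drift, and drift columns can be added to a design by hand if needed.

**HRF.** Double-gamma, parameterised so each lobe's mode sits exactly at
its stated delay (peak 6 s, undershoot 16 s, dispersions 1 s, undershoot
ratio 1/6, 32 s support, unit peak). All parameters are configurable
because acquisition software defaults vary.

**Prewhitened GLM.** OLS residuals give a lag-1 autocorrelation estimate
per region; data and design are then whitened with the exact
Prais–Winsten AR(1) transform (first row scaled by `sqrt(1 − phi²)`),
which reproduces generalized least squares exactly when `phi` is known.
One residual degree of freedom is charged for estimating `phi`
(`dof = n − rank − 1`). Contrast t statistics are converted to z by
matched tail probability, computed in log space so extreme statistics
stay finite and accurate.

**Group level and maps.** Fixed-effects (inverse-variance) averaging
across runs; unweighted OLS one-sample or covariate-slope models across
subjects — a deliberate simplification of Bayesian mixed-effects
weighting, adequate at this scale. Minimum-statistic conjunction,
Benjamini–Hochberg FDR over regions, and, for spatial grids, a sign-flip
permutation test on maximum supra-threshold cluster extent (forming
threshold z = 2.3, 5% family-wise level by default) replace
Gaussian-random-field cluster inference; sign flipping is exact under
symmetric subject-level nulls. Zero-variance group inputs produce a
capped, flagged z (|z| = 38) rather than infinities.

**Concordance.** Per member, the 12 per-trial anticipation z values are
averaged over the functional ROI (the group conjunction map intersected
with the anatomical coupled-region mask; single region in the synthetic
registry). Each target region's 12 trial values are regressed on the
partner's ROI series (mean-centred, intercept included, OLS across the
12 pooled trials; 10 residual df), slope t converted to z. Trials are
treated as exchangeable draws — no autocorrelation model across trials —
matching the second-level treatment of beta series as dynamic signals.
Both directions are computed; patient-ROI → clinician-brain is the
reported default. The context effect is a pooled-variance two-sample
comparison of concordance slopes between dyads scanned with and without
a prior clinical interaction.

**Behaviour.** Analgesia is the treated-minus-untreated mean patient
pain (negative = relief). Verum/sham equivalence uses the paired TOST
with Cohen's dz bounds (±0.5): each one-sided statistic is
`(dz_hat ∓ bound)·sqrt(n)` referred to central t with n−1 df — the
conventional formulation, which the closed-form reference values in the
tests pin down; it is only approximately pivotal at the bound, an
approximation shared by standard equivalence software. Correspondence
and facial mirroring are Pearson correlations (across trials and across
the nine channels respectively), Fisher r-to-z transformed with |r|
clamped at 1 − 1e-7.

**Mediation.** Least-squares paths a, b, c, c′; indirect effect a·b;
percentile bootstrap over whole resampled dyads (1000 draws by default;
BCa available via `ci_type = "bca"`). The percentile interval is the
plainest defensible bootstrap for this design; case resampling matches
the dyad-level observational structure. `p_indirect` is twice the
smaller tail proportion of bootstrap draws crossing zero, floored at
1/n_boot. Mediation is declared when the indirect CI excludes zero, the
total effect c is significant at α, and the direct effect c′ is not —
the joint rule under which "full" mediation is reported.

## Numerical choices and degenerate inputs

* AR(1) estimates are clamped to ±0.99; series shorter than
  rank + 3 scans are rejected.
* Rank-deficient designs fail naming the collinear columns; zero
  contrast vectors, constant covariates, constant partner series,
  constant rating series and collinear exposure/mediator pairs are all
  explicit errors rather than NaNs.
* All-zero motion input is dropped with a warning rather than fitted.
* Empty ROI intersections return a flagged empty mask with a warning;
  the pipeline falls back to the anatomical mask if the conjunction
  yields nothing.
* Every stochastic function takes a seed and restores the caller's RNG
  state; the same configuration and seed reproduce bit-identical
  outputs, including bootstrap draws.

## Problem sizes used in validation

The test suite validates, among others: exact GLS equivalence on
200-timepoint, 8-regressor instances; N(0,1) calibration of contrast and
group z on 2000 null simulations (Kolmogorov–Smirnov D < 0.05);
pseudo-concordance type-I rate over 500 zero-coupling dyads (≤ 0.075 at
the 1.96 threshold); strict monotone recovery of mean concordance over
coupling 0/0.3/0.6/0.9 (200 dyads per level); ≥ 80% context-contrast
power at 19 vs 18 dyads with coupling 0.8 vs 0; BH-FDR against a
brute-force oracle on 1000 random p-vectors; closed-form TOST reference
values; exact mediation decomposition and 92–97% percentile-CI coverage
of a null indirect effect over 500 replicates at n = 37; and ±0.05
calibration of the three generator correlations over 2000 dyads. These
sizes were chosen to make Monte-Carlo error small relative to each
tolerance while keeping the full suite runnable on a laptop in a few
minutes.

## Known limitations

* The whitening model is single-lag AR(1); heavier autocorrelation in
  real data would leave residual correlation and mildly optimistic
  first-level dof.
* Group models are unweighted: subjects with noisier first-level
  estimates are not down-weighted.
* Trial z statistics inherit a small shared sensitivity to the trial's
  anticipation duration (the per-trial standard error varies with the
  jitter, identically for both members). With realistic amplitude
  variability this inflates the null concordance rate by well under the
  tested ceiling, but it is the reason the type-I bound is verified by
  simulation rather than assumed.
* The region registry stands in for standard-space registration; real
  data must arrive as aligned region series (or NIfTI + label mask).
* The facial module starts from per-trial channel tables; video
  processing is out of scope.
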