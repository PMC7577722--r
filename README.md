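# dyadconcord

Trial-wise brain-to-brain concordance analysis for fMRI **hyperscanning**
dyads — two people (a patient with chronic pain and a treating clinician)
scanned simultaneously during a block-design pain-treatment protocol.

For researchers studying the patient–clinician interaction (or any
two-person neuroimaging design), the package answers three questions:

1. **Concordance.** Do the two brains co-fluctuate trial to trial beyond
   the shared experimental timeline? The statistic is a *beta-series
   regression*: fit each person a first-level GLM with one regressor per
   trial, extract the 12 per-trial z values of a region of interest
   (ROI), and regress each region of the partner's trial series on it:

   `z_target(t) = β₀ + β₁ · z_partnerROI(t) + ε(t)`, t = 1…12 trials,

   with the slope t statistic (10 df) converted to z. Modelling trials
   first and correlating after removes *pseudo-concordance* — apparent
   coupling induced by the shared stimulus schedule.
2. **Context.** Is concordance stronger in dyads that established
   clinical rapport beforehand? A two-sample contrast of concordance
   slopes between the clinical-interaction and no-interaction groups.
3. **Mechanism.** Does the patient's treatment-related prefrontal (vlPFC)
   response mediate the association between rTPJ-to-rTPJ concordance and
   analgesia? Percentile-bootstrap mediation: paths a, b, c, c′, indirect
   effect a·b with a case-resampling CI.

Supporting machinery: a synthetic dyad generator with known ground truth
(coupling, treatment effect, rating correspondence, facial mirroring,
mediation chain), double-gamma HRF design matrices, AR(1)-prewhitened
(Prais–Winsten) GLM with contrast z maps, fixed-effects averaging, group
models, minimum-statistic conjunction, Benjamini–Hochberg FDR, sign-flip
permutation cluster correction, analgesia scores, paired TOST
equivalence tests, Fisher-transformed rating correspondence and
facial-mirroring scores. See the vignette
(`vignettes/dyadic-concordance-methods.Rmd`) for the models and their
assumptions.

## Worked example

Simulate a 12-dyad cohort (6 scanned after a clinical intake, 6 without;
coupling 0.6 vs 0) and run the full pipeline:

```r
library(dyadconcord)
cfg <- sim_config(n_dyads = 12,
                  context_split = c(clinical_interaction = 6,
                                    no_interaction = 6))
bundle <- run_pipeline(pipeline_config(sim = cfg, seed = 42))
bundle
#> <pipeline_bundle> 12 dyads (6/6), phase anticipation, seed 42
#>   ROI 'rTPJ' context contrast z = 2.589
#>   concordance-analgesia r = -0.556 (p = 0.06042)
#>   mediation indirect = 0.601 [-0.759, 2.111]
```

The context-contrast map shows which regions' concordance with the
partner's rTPJ series is enhanced by prior clinical interaction — the
coupled rTPJ region tops the list (z = 2.59), the independent regions
hover around zero:

```r
round(as.numeric(bundle$context_contrast), 2)
#> [1]  2.59  1.78  0.84 -0.12 -0.19 -0.93  1.65 -0.51   # rTPJ first
head(bundle$concordance[, 1:3], 4)
#>   dyad_id              context roi_to_roi_z
#> 1 dyad001 clinical_interaction     3.758971
#> 2 dyad002 clinical_interaction     2.188051
#> 3 dyad003 clinical_interaction     3.139274
#> 4 dyad004 clinical_interaction     1.914360
```

Per-dyad `roi_to_roi_z` is the rTPJ-to-rTPJ concordance (z of the
trial-wise regression); negative correlation with the analgesia score
(treated-minus-untreated pain, negative = relief) means stronger
coupling goes with stronger pain relief. At 12 dyads the mediation
stage runs but is underpowered (`significant_mediation: FALSE` above);
37 dyads is the intended scale.

Individual stages are exported (`fit_glm_prewhitened()`, `contrast_z()`,
`conjunction_min()`, `fdr_threshold()`, `cluster_correct_permutation()`,
`fit_trialwise_session()`, `extract_beta_series()`,
`dyadic_concordance()`, `context_contrast()`, `analgesia_score()`,
`tost_equivalence()`, `correspondence_score()`,
`facial_mirroring_score()`, `mediate_bootstrap()` …), as are the
readers/writers for BIDS-style events TSV, wide signal CSV / NIfTI +
label mask, and ratings CSV. A thin CLI
(`inst/cli/dyadconcord.R`, subcommands `simulate` and `report`) wraps
the simulator and the pipeline.

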