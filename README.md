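# drprofile

Tools for public-health dementia-prevention cohort studies built around a
nine-domain traffic-light **Dementia Risk Profile (DRP)**.

Large observational prevention programs give participants personalised
feedback on modifiable dementia-risk behaviours — alcohol use, body-mass
index, blood-pressure/cholesterol/diabetes management, smoking, cognitive
and physical activity, and diet — each classified low/medium/high against
published cut points, and summarised as a continuous risk total

```
DRP total = sum over the 9 domains of w(level),   w(low) = 0, w(medium) = 0.5, w(high) = 1,
```

with range 0–9 (undefined whenever a domain cannot be scored). The package
implements, for analysts of such cohorts:

- **Scoring** — the nine domain classifiers (`score_alcohol()`,
  `score_bmi()`, `score_cardiometabolic()`, `score_smoking()`,
  `score_physical_activity()` on `compute_met_minutes()` with the 3.3/4/8
  MET weighting, `score_cognitive_activity()`, `score_mind_diet()`),
  profile assembly (`assemble_drp()`) and whole-table scoring
  (`score_waves()`).
- **Instruments** — knowledge subscales scored as correct-answer counts
  (`score_koderr()`: general 0–22, strategy 0–20, misconception discernment
  0–12) and seven Health-Beliefs-Model motivation dimensions scored as item
  sums (`score_mchlb()`).
- **Panel assembly** — report-exposure counting and `log(months + 1)` study
  time for a rolling-baseline design (`derive_exposures()`), and the
  analysis-sample filters with an exclusion report
  (`apply_analysis_filters()`).
- **Models** — REML random-intercept trajectory models with standardized
  coefficients `b_s = b·SD(x)/SD(y)`, Satterthwaite inference, Nakagawa
  marginal/conditional R² (`fit_trajectory()`, `marginal_r2()`), estimated
  marginal means with Tukey-adjusted pairwise contrasts
  (`marginal_means()`), and multinomial baseline-to-final risk-transition
  models reporting odds ratios (`fit_transitions()`).
- **Mediation** — baseline-adjusted product-of-coefficients path models:
  `a` from `M_fu ~ X + M_bl`, `b` and `c'` from `Y_fu ~ X + M_fu + Y_bl`,
  indirect effect `a·b`, proportion mediated `a·b/(a·b + c')`, case-resampling
  bootstrap CIs, EM-under-normality handling of missing data, and
  χ²/CFI/RMSEA fit indices (`fit_mediation()`, `em_normal_estimates()`,
  `fit_indices()`).
- **Synthetic cohorts** — a seed-reproducible generator
  (`simulate_cohort()`, `inject_missingness()`) whose raw responses score
  back exactly to its latent ground truth, for parameter-recovery testing.
- **Reporting & pipeline** — the traffic-light participant report
  (`render_report()`) and a deterministic end-to-end pipeline with a
  hash manifest (`run_pipeline()`).

## Worked example

```r
library(drprofile)

cfg    <- sim_config(n_participants = 600L)        # study-like conditions
sim    <- simulate_cohort(cfg, seed = 11)
waves  <- inject_missingness(sim$waves, cfg, seed = 12)
scored <- score_waves(waves)                       # adds risk_*, drp_total
panel  <- apply_analysis_filters(derive_exposures(scored))

fit <- fit_trajectory(panel$model_panel, pdmooc = TRUE, interaction = TRUE)
fit
#> Random-intercept trajectory model (REML): drp_total ~ n_drp_exposures +
#>     log_time + pdmooc + n_drp_exposures:pdmooc + (1 | id)
#> Observations: 1730  Participants: 597
#>                    term estimate     se   df   ci_lo   ci_hi         p      b_s ...
#>         n_drp_exposures  0.04685 0.0469 1301 -0.0451  0.1388  3.18e-01  0.04061
#>                log_time -0.10496 0.0277 1285 -0.1593 -0.0506  1.58e-04 -0.13299
#>                  pdmooc  0.00258 0.0927  950 -0.1792  0.1844  9.78e-01  0.00224
#>  n_drp_exposures:pdmooc -0.09096 0.0379 1218 -0.1652 -0.0167  1.64e-02 -0.07631
#> Variance components: id 0.7703, residual 0.5281
#> Marginal R2 = 0.022, conditional R2 = 0.602

med <- fit_mediation(mediation_dataset(panel$panel),
                     x = "pdmooc", m = "m_fu", y = "y_fu",
                     m_baseline = "m_bl", y_baseline = "y_bl",
                     n_boot = 1000, seed = 13)
med
#> Baseline-adjusted mediation model (complete_case, model_specific covariates)
#>   n used: 462
#>   a (X -> M)         0.4891  [0.3357, 0.6355]  (boot SE 0.0791)
#>   b (M -> Y)        -0.0620  [-0.1349, 0.0092]  (boot SE 0.0366)
#>   c' (direct)       -0.1232  [-0.2771, 0.0252]  (boot SE 0.0791)
#>   indirect (a*b)    -0.0303  [-0.0674, 0.0038]  (boot SE 0.0186)
#>   % mediated        19.7654  ...
#>   fit: chisq(2) = 3.076, CFI = 0.997, RMSEA = 0.034 [0.000, 0.105]
```

Reading the output: the significant negative exposure-by-course interaction
(`b_s = -0.076`) says risk totals fall faster per report exposure among
online-course participants, on top of the overall time trend; the mediation
model attributes about a fifth of the course's total effect on the risk
total to its effect on misconception-discernment knowledge (`a = 0.49` SD),
with a small negative indirect path (`a·b = -0.03`). At this small n (600
participants) the course main effect is indistinguishable from zero; the
generating effects used here are recovered without bias at scale (see the
parameter-recovery tests).

A full pipeline run — simulate → score → assemble → fit → transitions →
mediate → report, with a manifest of md5-hashed artifacts — is one call:

```r
run_pipeline("all", sim_config(), seed = 1, out_dir = "drp-run")
```

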