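---
title: "Methods: risk-profile scoring, longitudinal models and mediation in drprofile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk-profile scoring, longitudinal models and mediation in drprofile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical content: the
traffic-light risk score and its conventions, the longitudinal and mediation
models, the synthetic cohort generator, and the design decisions taken where
the published material left the design open.

## The nine-domain risk score

Each behaviour domain is classified **low / medium / high** against
established cut points; the continuous **DRP total** is the weighted count
of elevated domains (medium = 0.5, high = 1), range 0–9, lower is better.
Conventions worth stating explicitly:

* **BMI** is computed as weight(kg)/height(m)²; bands are half-open —
  [18, 25) low, [25, 30) or < 18 medium, [30, ∞) high — so values such as
  24.95, which fall between printed band labels like "24.9" and "25", have
  a defined level.
* **MIND-diet adherence** sums 14 scoreable components (wine excluded),
  each 0/0.5/1, giving the 0–14 range; bands are [12, ∞) low, [7.5, 12)
  medium, [0, 7.5) high.
* **Physical activity** uses weekly MET-minutes, 3.3·light + 4·moderate +
  8·vigorous, with a single 600 threshold (150 moderate minutes); there is
  no medium level. **Cognitive activity** likewise is two-level: the sum of
  eleven 0–5 frequency codes against a threshold of 33 ("several times a
  month", code 3, on every item). Only code 3 is anchored externally; the
  rest of the 0–5 scale is a package convention and configurable.
* **Alcohol**: > 14 standard drinks/week is high; ≤ 14/week with > 2 per
  occasion is medium; abstaining or ≤ 2 per occasion is low. The "either"
  in the published medium-risk wording is read as a conjunction of the
  weekly and per-occasion conditions. On the contradictory input
  "abstainer reporting > 2 drinks per occasion" the abstention clause wins
  (a reported weekly total > 14 still scores high).
* **Cardiometabolic domains** (hypertension, cholesterol, diabetes) share
  one classifier over (diagnosis, regular check-ups, management).
  Combinations not named by the rule table (e.g. diagnosed, with check-ups,
  but unmanaged) are returned as `unknown` rather than guessed.
* **Unknown propagation**: any unknown domain makes `drp_total` undefined
  for that observation; domain-level categorical analyses still use the
  known domains. Continuous-outcome models drop such rows.

A single degraded domain changes the total by exactly its weight step; this
monotonicity, band boundaries on both sides of every printed cut point, and
agreement with an independently coded brute-force rule table on 10,000
random response vectors are asserted in the test suite.

## Instruments

The knowledge instrument is scored as correct-answer counts on three
subscales (general 0–22, strategy 0–20, misconception discernment 0–12);
the motivation instrument as item sums on seven Health-Beliefs-Model
dimensions. Published score ranges, not item lists, are available, so item
structure is configuration with defaults that attain exactly the printed
ranges: most dimensions are 5 items on 1–4; self-efficacy is 2 items on
1–5. The printed severity range (6–25) is inconsistent with six 1–4 items
(max 24) and the printed minima sum to 33 items against a described
28-item instrument; the defaults honour the printed *ranges* (severity: six
items, one on 1–5) and the discrepancy is simply flagged here. Dimensions
with any missing item are reported missing rather than prorated — no
prorating rule is published, and silent proration would bias sums low or
high depending on the missing item's scale.

## Panel assembly

The personalised report is released immediately *after* each completed
survey, so the exposure count attached to an observation is the number of
completed waves strictly before it: baseline rows have 0 exposures; a
participant with baseline plus only the final annual survey has 1 exposure
at that final row. A skipped intermediate wave contributes no exposure
(count of completed prior waves). Study time is whole months since
baseline, entered as `log(months + 1)` (natural log) to reflect the
fast-then-slow change pattern; months are integer calendar-month
differences. The analysis sample keeps participants with an in-window
baseline and at least one follow-up, excludes (by default) those exposed to
the online course before enrolment, and reports exclusion counts by reason;
filtering is idempotent and every excluded row lands in exactly one bucket.

## Trajectory and transition models

The trajectory model is a random-intercept linear mixed model fitted by
REML: outcome ~ exposures + log-time [+ course dummy] [+ exposures×course]
[+ covariates] + (1 | participant). Random slopes are deliberately not
offered — with at most four waves per person they are weakly identified and
the scientific targets are population-level trends. Exposure count and
log-time enter jointly by default (they are correlated but separately
interpretable: per-report effect adjusted for elapsed time). Inference uses
Satterthwaite degrees of freedom, falling back to a normal approximation
when unavailable. Standardized coefficients are `b_s = b·SD(x)/SD(y)` for
continuous predictors and `b/SD(y)` for binary (0/1) ones, with SDs from
the estimation sample; this equals refitting on z-scored data and is tested
as such. R² follows the Nakagawa decomposition: marginal = fixed-effect
variance over (fixed + random-intercept + residual); conditional adds the
random-intercept variance to the numerator.

Estimated marginal means are computed at covariate means over a user grid,
with all pairwise contrasts Tukey-adjusted within one model's family; no
across-model correction is applied. Risk-level transitions (baseline vs the
final wave, configurable to last-available) are modelled per domain by
multinomial logistic regression with reference outcome "low", adjusted for
gender, age, socioeconomic decile and education; odds ratios carry Wald
CIs. A single-level baseline predictor is dropped (giving the intercept-only
model whose fitted probabilities are the observed proportions), and sparse
outcome categories under covariate adjustment raise an error suggesting
category collapse instead of fitting an unstable model.

## Mediation

The mediation model is the three-variable baseline-adjusted path system

* a-path: `M_fu ~ X + M_bl`
* outcome: `Y_fu ~ X + M_fu + Y_bl` (gives `b` and the direct effect `c'`)
* total: `Y_fu ~ X + Y_bl`

estimated by least squares on (possibly EM-estimated) first and second
moments. The indirect effect is the product `a·b`; the proportion mediated
is `100·a·b/(a·b + c')`, flagged as *inconsistent mediation* when the
indirect and direct effects oppose in sign with `|a·b| > |a·b + c'|` — the
ratio is then not interpretable as a share and is not silently reported as
one. Continuous variables are z-scored on the analysis sample (effects in
SD units); binary exposures are left on the 0/1 scale so their coefficients
are group differences in outcome SDs.

**Additivity.** `a·b + c' = c` is an exact algebraic identity only when all
three regressions condition on the same set; with model-specific baselines
(each equation adjusting only for its own variable's baseline, the default
here) the identity holds only approximately. `covariate_set = "shared"`
conditions every equation on both baselines and restores the exact
identity; the test suite asserts it there at 1e-8. The shared model is also
saturated in the path-model sense (df = 0), while the default
model-specific system leaves two over-identifying restrictions (the omitted
M_bl→Y_fu path and the M/Y residual covariance), so its χ², CFI and RMSEA
are informative.

**Inference** is by nonparametric case-resampling bootstrap (default 5000
replications; percentile 95% CIs; SE = SD of the bootstrap distribution),
deterministic given a seed; a resample on which the statistic fails is
redrawn and counted. A single replication yields an undefined SE and is
flagged rather than reported as 0. Under the `em_normal` missing-data
policy, EM is re-run on every resample.

**Missing data.** `em_normal_estimates()` runs EM for the mean and
covariance of a multivariate normal under arbitrary ignorable missingness,
sweeping by missingness pattern; with no missing data it returns the sample
moments (ML, denominator n) exactly — and complete-case moments use the
same denominator so the two policies coincide bit-for-bit at 0%
missingness. A variable with no observed values is an error, not an
imputation. Convergence is max-absolute parameter change below 1e-7 within
1000 iterations; non-convergence errors with the tail of the change trace.

**Fit indices.** From model/saturated/baseline log-likelihoods:
χ² = 2(llₛ − llₘ), CFI = 1 − max(χ²ₘ − dfₘ, 0)/max(χ²_b − df_b, χ²ₘ − dfₘ, 0),
RMSEA = √(max(χ²ₘ − dfₘ, 0)/(dfₘ·n)), with the 90% RMSEA interval from
noncentral-χ² inversion (noncentrality solving P(χ²_{df,λ} ≤ χ²ₘ) = 0.95
and 0.05). A saturated model reports RMSEA 0 with a flag; a noiseless path
system (zero residual variance) reports fit indices as unavailable rather
than a degenerate likelihood.

## The synthetic cohort generator

`simulate_cohort()` generates each participant-wave in three steps:

1. a **latent risk total** from the linear mixed model
   η = β₀ + bᵢ + β_exp·exposures + β_time·log(months+1) + β_mooc·course +
   β_int·exposures·course + covariates + b·knowledge, with bᵢ ~ N(0, σ_id)
   and configured effects in outcome-SD units (reference SD 1.24);
2. a **discretised total** on the 0.5 grid of [0, 9]. Plain
   rounding-and-clamping attenuates effects near the floor, so the linear
   predictor is first pushed through the inverse of the exact
   censored-grid mean function: the conditional expectation of the
   discretised total equals the linear predictor wherever that predictor
   lies inside (0, 9). Conditional means outside the scale are clamped —
   the unavoidable floor of a bounded score — which leaves a residual
   attenuation of roughly 5–8% of an effect under study-like baseline
   means (≈ 2.2 of 9);
3. **nine domain levels** drawn from baseline-calibrated marginal
   propensities and nudged one step at a time (half steps for three-level
   domains) until their weights sum to the target total, then **raw survey
   responses** sampled strictly inside each assigned level's scoring band
   (boundary-safe margins cover rounding of heights/weights), so scoring
   the generated data returns the generated totals exactly — asserted
   wave-for-wave in the tests.

The course indicator is a participant-level trait effect (present at every
wave, including baseline): engaged participants differ at baseline as in
self-selecting cohorts, and the generating model then coincides with the
fitted model term. The knowledge channel raises the misconception score at
follow-ups by `a` SD for course participants (baseline knowledge stays
independent of the exposure — applying the a-path at baseline would change
the baseline-adjusted estimand to a(1−ρ)) and feeds the outcome with
weight `b` SD, so the configured (a, b, c′) are the generating mediation
truth. Enrolment months are exponentially front-loaded (mean ≈ 4 months
into the window), giving realistic intermediate-wave sample sizes under a
rolling baseline; attrition is Bernoulli completion of eligible waves
(five-month invitation lead), and `inject_missingness()` blanks each
domain's raw inputs at configured per-domain rates (scaled down at
follow-ups). Generation is vectorised over participants on a single seeded
stream: identical (config, seed) pairs reproduce the tables exactly. (A
per-participant substream scheme — adding participants without perturbing
earlier ones — was considered and dropped; it conflicts with vectorised
generation, and the determinism contract the pipeline relies on does not
need it.)

What the generator does **not** emulate: item-level instrument responses
(subscale scores are generated directly), outcome-dependent attrition or
missingness (both are MCAR), pandemic-era shocks, and demographic
confounding of course uptake. Passing recovery tests therefore show the
estimators are correct under ignorable missingness and trait-like
self-selection — not that they would remain unbiased under informative
dropout.

## Recovery-harness design and problem sizes

Two dedicated configurations drive the parameter-recovery tests; both are
simulation-design choices, distinct from the shipped study-like defaults:

* **Trajectory recovery** (200 cohorts, n = 2000): intercept 4.5
  (mid-scale, away from both bounds so boundary censoring does not
  confound estimator validation), nuisance time trend and knowledge
  channel zeroed, target effects β_exp = −0.10 SD, β_mooc = −0.11 SD,
  β_int = −0.03 SD. Checks: mean standardized-estimate bias below 10% of
  each effect, and 95% CI coverage within [91%, 99%].
* **Mediation recovery** (100 cohorts, n = 3000, bootstrap 500):
  participant-level outcome heterogeneity and covariate effects zeroed, so
  the configured (a, b, c′) are the exact estimands of the baseline-
  adjusted regressions. With heterogeneity present, baseline adjustment
  provably shifts the b-estimand away from the structural coefficient
  (the baseline outcome then proxies the stable person effect); that bias
  is a property of the design, not of the estimator, so the harness
  removes its source. Checks: mean indirect-effect estimate within
  Monte-Carlo error of a·b, percentile-CI coverage within [91%, 99%],
  additivity at 1e-8 under the shared conditioning set.

The remaining checks run at small, fixed sizes: 10,000 response vectors
for oracle equivalence, 20 random tuples for fit-index agreement, and two
full pipeline runs on the shipped configuration (n = 3038, bootstrap 5000)
for byte-reproducibility.

## Numerical choices and known limitations

Half-open scoring bands; natural log for study time; Tukey adjustment only
within a model's contrast family; multinomial fits tightened to reltol
1e-12 so closed-form checks hold at 1e-6; EM tolerance 1e-7; RMSEA CI roots
bracketed adaptively. Degenerate inputs error loudly: fewer than two
participants or no repeated waves, rank-deficient fixed-effect designs
(naming the collinear columns), zero-variance predictors or exposures,
wrong item counts, out-of-scale responses, template gaps (naming the
domain/level), and fully missing variables in EM.

Limitations: the DRP total is a bounded, discrete score — near its floor,
linear-model effects attenuate and model-based standard errors are only
approximate (the recovery harness quantifies this away from the floor;
under study-like means expect mild conservatism in small effects). The
proportion mediated is unstable whenever the total effect is near zero
(its bootstrap distribution is heavy-tailed; the CI, not the point value,
is the interpretable summary). The EM route assumes multivariate normality
of jointly analysed variables; with a binary exposure it is best read as a
conditional-linear approximation, which is why complete-case estimation is
the default.
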