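---
title: "Models and methods behind tonebattery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tonebattery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonebattery)
```

## The analysis problem

A phonetic-training battery produces binary accuracy records: one row per
trial, annotated with subject, training condition (LV / HV / HVB), task,
session, item and voice novelty, and — for the oddity task — a trial-type
difficulty factor. Two questions dominate: does high-variability (multi-talker)
input produce better *generalisation* than single-talker input, and does
that benefit interact with individual pitch aptitude? Both tend to yield
non-significant frequentist results, which are uninterpretable on their own:
`p > 0.05` does not distinguish "evidence for no effect" from "no evidence
for anything". The package therefore pairs logistic mixed-effects estimation
with informed Bayes factors that can positively support the null.

## Logistic mixed models and contrast coding

All accuracy outcomes are modelled on the log-odds scale with subject random
effects (`fit_glmm`, backed by `lme4::glmer` with BOBYQA). Categorical
predictors are entered as *centred* dummies (`build_contrasts`): a 0/1 dummy
minus its observed mean. On balanced data the three-level condition factor
with baseline LV gives codes {−1/3, 2/3, −1/3}, a two-level test-session
factor gives {−1/2, +1/2}, and the pooled LV-vs-(HV∪HVB) contrast used for
the Bayes-factor models gives {−2/3, 1/3, 1/3}. Centring makes the intercept
the grand mean and evaluates each effect averaged over the levels of the
others; on balanced data it leaves the highest-order interaction untouched
(a property the test suite checks against `glm`). Centring constants use
*observed* frequencies, so derived columns are exactly mean-zero even after
trial exclusions unbalance the cells — the alternative (design frequencies)
was rejected because it breaks the mean-zero invariant on filtered data.

Random-effects structure starts maximal (per-subject intercepts plus slopes
for within-subject factors). Non-convergence triggers a deterministic
fallback ladder: correlations between random terms removed
(`(a | g)` → `(a || g)`), then random intercepts only, with the rung
recorded in `fallback_level`. A boundary ("singular") fit — a variance
estimated at exactly zero — counts as converged and is flagged separately;
treating it as failure would re-fit an identical model. Convergence follows
`lme4`'s own criteria; the optimiser is BOBYQA throughout. Wald statistics
use the normal approximation (`z = β̂/SE`, `p = 2Φ(−|z|)`) with no
degrees-of-freedom correction and no multiple-testing adjustment, matching
the reporting conventions of the designs this package targets.

Likelihood integration is adaptive Gauss–Hermite with 9 nodes when the
random part is a single scalar intercept, and the Laplace approximation for
multivariate random effects. The test suite bounds the approximation error
against an independent 51-node quadrature oracle written from first
principles (Golub–Welsch nodes, no `lme4` code), agreeing to below 10⁻³ in
log-likelihood on random-intercept fixtures.

## Informed Bayes factors

`bf_halfnormal(beta, se, x)` compares a point null to a half-normal H1 with
mode 0 and scale `x`, supported only on the predicted direction. With the
summary-statistic likelihood `β̂ ~ N(θ, SE²)` the marginal likelihood under
H1 has a conjugate closed form,

$$ m_1 = 2\,N(\hat\beta;\,0,\,SE^2+x^2)\,\Phi\!\left(\mu_p/\sigma_p\right), $$

with $\mu_p, \sigma_p$ the posterior mean and SD of $\theta$ under the full
normal prior; `B = m1 / N(β̂; 0, SE²)`. A quadrature route
(`method = "integration"`, integrated over the likelihood's effective
support) agrees to 10⁻⁶ and guards the algebra. Two limits anchor the
implementation: `B → 1` as `x → 0⁺` (H1 collapses onto H0), and at `β̂ = 0`,
`B` strictly decreases in `x` (a more diffuse alternative is penalised).
Effects opposite to prediction drive `B` toward the null because the prior
places no mass there; the observed sign is kept, never folded.

### Prior-scale derivation

Default prior scales are deliberately avoided. Each contrast's `x` comes
from the scale or from other estimates in the same data:

* **Predicted main effect** (`scale_main_effect`): the maximal group
  difference arises if the LV group sits at task baseline `b` and the pooled
  group mirrors it above the grand mean `p̄`, i.e. `2(p̄ − b)`; treating the
  maximum as ≈ 2 SD gives `x = p̄ − b`. Baselines (`chance_logodds`) are
  logit(1/2) = 0 for 2AFC, logit(1/4) = −1.099 for four-way tone
  identification, logit(1/72) = −4.263 for open transcription (minimal
  performance: one correct of 72; the log-odds of 0 cannot be used), and
  logit(1/3) = −0.693 for three-interval oddity. Chance values are stored
  *signed* (negative): magnitudes printed without signs in some sources are
  interpreted as negative log-odds for internal consistency.
* **Session-by-condition interaction** (`scale_session_interaction`):
  `x = t̄`, the mean pre-to-post improvement across conditions.
* **Aptitude-by-condition interaction** (`scale_aptitude_interaction`):
  `x = ā`, the mean aptitude effect across conditions.
* **Three-way interaction** (`scale_threeway`): `x = (maxa − ba)/2`, where
  `maxa` is the maximal aptitude effect per aptitude unit —
  (ceiling − chance) log-odds divided by the length of the aptitude
  predictor (`max_aptitude_effect`; ceiling is 71/72 correct, log-odds
  4.263) — and `ba` the fitted baseline aptitude effect. The "length" of the
  aptitude predictor is taken as the observed range (max − min) of the
  ×10-scaled score; the theoretical range (0–10) is not used because
  observed samples never span it.

Conclusions use `B < 1/3` / `B > 3` with the boundaries themselves assigned
to "ambiguous" (open intervals). `robustness_region` scans scales on a 0.01
grid up to 50 log-odds units and reports the maximal contiguous interval
sharing the reference conclusion; because `B → 1` as `x → 0⁺`, an ambiguous
run touching the origin starts at 0, and null-evidence regions always end at
∞. Endpoints are reported to 2 decimals; comparisons against published
endpoints use ±0.05 because printed inputs are themselves rounded to 2–3
decimals.

`required_sample_size` projects evidence to larger samples holding `β̂`
fixed and shrinking the standard error as `SE(n) = SE·√(n₀/n)` — the
standard error-scaling assumption — and returns the smallest `n` with
`B ≤ 1/3` by exhaustive scan (checked against an independent brute-force
scan in tests). When `β̂` is genuinely in the predicted direction, shrinking
`SE` strengthens H1 instead and the projection honestly reports
non-attainability.

## The synthetic-data generator

`generate_design` lays out the full battery (one row per planned trial,
balanced cells by construction); `simulate_responses` draws
`correct ~ Bernoulli(plogis(η))` with `η` = task fixed effects (over centred
design columns, the same coding the analysis uses) + per-subject
multivariate-normal random effects. Default effect sizes are the reported
coefficient magnitudes of the design the package mirrors: training-session
slope 0.5, pre-to-post gains 0.31–0.40, LV's training advantage ≈ −0.8,
oddity trial-type offsets +0.40/−0.14 (easy/hard vs neutral), aptitude
slopes 0.07–0.15 — with every condition-by-session and condition-by-aptitude
interaction defaulting to 0, the no-variability-benefit world the evidence
supported. One reported aptitude row ("β = 1.48, SE = 0.08, z = 1.96") is
internally inconsistent (β/SE ≠ z); it was read as β ≈ 0.148, hence the 0.15
default.

A latent true aptitude (proportion scale, Normal(0.55, 0.15) truncated to
[0.05, 0.95] — a realistic spread for naive listeners on a four-way pitch
task) plays two roles: it *is* the pitch-contour test's intercept in
log-odds, and, ×10-scaled and centred, it modulates the other tasks through
their `aptitude` coefficient. This mirrors treating the pre-test score as a
proxy for latent aptitude, and is why an explicit `aptitude` coefficient is
rejected for the pitch-contour task (it would double-count).

`simulate_continuum` draws Tone 2/Tone 3 choices from
`P(Tone 3 | step t) = 1/(1 + b1^(t − midpoint))` — exactly the response
curve implied by the logistic growth parameterisation that
`fit_categorization_slope` fits, so round-trip recovery is a meaningful
check (`b1 = 0.5` recovered within ±0.05 at 200 trials/step; rank
correlation ≥ 0.95 across 50 subjects spanning `b1` 0.3–1.5).
`simulate_ratings` gives two raters a *shared* latent production (tone
correct with a stated probability, or tied to trial outcomes simulated
elsewhere) plus independent coding noise, unusable-trial zeros, 1–7 ratings
and pinyin transcriptions.

What the generator does **not** emulate: acoustic stimulus properties,
counterbalancing versions (voice identity reduces to the novelty flag, since
no analysis conditions on version), reaction times, item-level crossed
random effects, learning *within* a session, and serial dependence between
trials. Passing tests therefore show that the pipeline recovers what it
assumes — a logistic world with subject random effects — not that real
participants satisfy those assumptions.

## Aptitude scoring and reliability

The pitch-contour score is proportion correct at pre-test, ×10, centred
(`pitch_contour_aptitude`). The categorisation slope uses the log-linearised
logistic growth fit described above on *per-step proportions* (the raw
binary alternative is statistically equivalent here and the per-step form
makes the continuity correction explicit: proportions of 0 or 1 become
`1/(2n_step)` from the boundary). Flat responders get `b1 = 1` and a `flat`
flag; `b1 > 1.2` excludes a subject, and exclusion counts are monotone
non-increasing in the threshold.

Cohen's kappa is the unweighted `(p_o − p_e)/(1 − p_e)` with Landis–Koch
bands; the two-way mixed, average-measures, *consistency* ICC is
`(MS_items − MS_error)/MS_items` with Cicchetti bands. The consistency
variant was chosen because the reliability question here is about rater
ordering, not absolute agreement on the 1–7 scale; tests cross-check kappa
against `e1071::classAgreement` and the ICC against `stats::aov` mean
squares. Unusable-trial filtering defaults to "either rater coded 0"
(restrictable by flag), and removal percentages are `round(·, 2)` of
count/denominator × 100. Band edges are rounded at 10⁻¹⁰ before labelling so
that exact boundary values (e.g. κ = 0.6 computed in floating point) land in
their intended band. Analyses of production accuracy default to the naive
rater's codings; the 1–7 rating feeds only the ICC.

## The battery pipeline

`run_battery` runs: simulation → dual-rater coding and reliability →
aptitude scoring → per-task GLMM presets → the two Bayes-factor batteries
(pooled-variability generalisation contrasts; aptitude-interaction
contrasts), each row carrying its own (β̂, SE, x, B, category, robustness
region) so every reported `B` is reproducible from its own row. A failed
row (e.g. a non-positive fitted aptitude effect making its prior scale
underivable) is retained with a note, never silently dropped. Reports are
deterministic given the seed and serialisable with `write_battery_report`.
The package's exported functions are its interface; there is no shell
wrapper beyond `scripts/acceptance.R`.

## Numerical choices and problem sizes

* Closed-form BF everywhere; quadrature only as a cross-check, over
  `[0, max(β̂, 0) + 15·SE]` with `rel.tol = 1e-12`.
* Robustness grid 0.01, ceiling 50 log-odds units (far beyond any plausible
  effect); sample-size scan to 10⁵.
* Test problem sizes were chosen as the smallest that make each property
  sharp: quadrature oracle on 5 subjects × 50 trials; parameter recovery on
  the picture-identification task at its design size (60 subjects × 72
  trials, 20 replicates, coverage of true values by β̂ ± 2SE ≥ 90%);
  null-world evidence on 30 subjects × 24 trials, 50 replicates (B < 1 in
  ≥ 70%); Monte-Carlo accuracy checks at 3 binomial SEs.

## Known limitations

* The generator's random-effects vocabulary covers intercepts and the main
  within-subject slopes, not random interaction slopes or item effects.
* `fit_glmm`'s fallback ladder handles non-convergence, not quasi-complete
  separation; separated coefficients are only flagged (|β̂| > 10 by
  default).
* The SPSS-style categorisation slope is a summary of per-step proportions,
  not a full psychometric model with lapse rates.
* One published robustness endpoint (picture-naming pinyin, lower endpoint
  0.101) cannot be derived from its own printed inputs, whose Bayes factor
  is ≈ 1.09 at that scale; `verify_printed_tables` reports the
  inconsistency instead of matching it, and the anomalous word-repetition
  pinyin row (negative printed SE) is excluded from verification outright.
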