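---
title: "Scoring and validating a preference-weighted composite endpoint for older persons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and validating a preference-weighted composite endpoint for older persons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topicscep)
```

## The composite endpoint

TOPICS-CEP summarizes the health-related quality of life of an older person
as a single preference-weighted index on 0 (worst) to 10 (best). It combines
42 data points from eight domains: 17 morbidity indicators, 15
functional-limitation items (Katz-index derived), 5 emotional-wellbeing items
(RAND-36 mental-health subscale), the EQ-5D pain dimension, the EQ-5D+C
cognition dimension, the RAND-36 social-functioning item, self-perceived
health and self-perceived quality of life. Scoring proceeds in four steps:

1. **Reverse coding.** Every item is oriented so that 0 is the best state.
   The reversal map reflects levels within each item's range and is an
   involution; orientation then shifts items to a 0-based scale.
2. **Aggregation.** The 17 morbidity items sum to a morbidity count (0–17),
   the 15 functional items to a limitation count (0–15), and the 5 emotional
   items to a raw wellbeing score (0–25); the remaining five domains are
   single items.
3. **Preference weighting.** The raw score applies weights elicited from
   older persons and informal caregivers:

   raw = 9.00 − 0.18·morbidities − 0.12·functional − 0.03·emotional
   − 0.03·pain − 0.14·cognition − 0.01·social − 0.17·health − 0.02·qol

4. **Index transformation.** raw is mapped affinely onto 0–10 using the
   minimum raw score and raw range implied by the component maxima. Under
   the default coding scheme the raw minimum is 2.25 and the range 6.75;
   both are always *derived* from the active scheme, never hard-coded, so
   overriding item codings keeps the index internally consistent.

**Missing items.** Only the three multi-item components tolerate missingness:
fewer than 5 missing morbidity or functional items and fewer than 2 missing
emotional items. Gaps are pro-rated as
`answered_sum / n_answered * n_items` (12 of 15 functional items summing to
6 gives (6/12) × 15 = 7.5). Pro-rated morbidity counts are left fractional
(no rounding). A respondent breaching any threshold, or missing any
single-item domain, receives no score and is excluded from downstream
analyses; the pipeline log reconciles these exclusions against input counts.

**Item codings are a declared default, not an assertion.** The per-item
level ranges and reverse directions used here (morbidity and functional
items 0/1, emotional items on the native 1–6 RAND-36 scale giving a
component maximum of 25, the 3- and 5-level single items as documented in
`default_coding_scheme()`) reproduce the published component ranges, but the
instrument's source documentation defines the canonical codings; the scheme
is therefore a versioned configuration that users can override via
`coding_scheme()` or the YAML config.

## Companion measures

The EQ-5D utility applies the Dutch time-trade-off value set to the five
3-level dimensions: a constant decrement of 0.071 for any departure from
full health, per-dimension decrements for levels 2 and 3, and an extra
0.234 when any dimension is extreme. Full health scores exactly 1.00 and the
worst state −0.329, reported as −0.33 at the tariff's two-decimal precision;
full precision is kept internally and rounding happens only at the reporting
layer (including floor/ceiling counting). The Cantril ladder is passed
through after validating it is an integer in 0–10.

## Convergent validity: random-effects meta-correlation

Because the cohort pools many research projects, correlations are estimated
within project and pooled rather than computed naively on the stacked data.
For each project with at least 4 complete pairs and non-degenerate variance,
a pairwise-complete Pearson r is computed; each r is Fisher-z transformed
with sampling variance 1/(n−3); between-project variance τ² comes from the
DerSimonian–Laird moment estimator; the pooled z uses weights
1/(1/(n−3) + τ²) and is back-transformed with its Wald 95% interval. The
original analysis names neither the transform nor the τ² estimator; Fisher-z
with DerSimonian–Laird is the standard default of the meta-analysis tooling
it relied on, and the test suite verifies exact agreement with `metafor`'s
DL estimator as an independent cross-check. Pooled correlations below 0.3
in magnitude are labelled weak, 0.3–0.5 (inclusive at both boundaries,
following the "between 0.3 and 0.5" phrasing) moderate, and above 0.5 strong.

## Known-group validity: random-intercept mixed models

For each characteristic (marital status, living arrangement, education,
dementia, depression, dizziness with falls) one model is fitted per
characteristic — never a joint model — of the indexed score on the factor,
with a random intercept per project (`lme4::lmer`, REML) and Wald 95%
intervals. Age enters the adjusted models centered at the sample mean so the
intercept is the reference-group mean at average age. A singular fit or a
single project downgrades to a plain linear model with a warning. The
change-in-estimate rule compares unadjusted and age/gender-adjusted
contrasts: percent change |unadj − adj| / |unadj| × 100, with changes above
15% flagged (a change of exactly 15% is acceptable; a 1e-8 numeric tolerance
protects the boundary from floating-point noise, and a zero unadjusted
estimate yields an undefined change flagged for review).

## Floor and ceiling effects

`summarize_outcome()` counts respondents at the *theoretical* instrument
bounds (composite endpoint and Cantril 0–10; EQ-5D −0.33 to 1.00), after
rounding to the tariff's two-decimal precision, as a percentage of the
non-missing sample. Percentages strictly above 15% are flagged.

## The synthetic multi-project generator

No public extract of the pooled dataset exists at desk scale, so the package
ships a generator that emulates its statistical structure and makes every
downstream stage testable. Defaults are the study conditions: 28 projects
with right-skewed log-normal sizes totalling about 17,600 respondents; age
79 (SD 7); 61.5% women; covariate prevalences 5.6% dementia, 9.1%
depression, 14.6% dizziness with falls; project random-intercept SD 0.5 and
residual SD 1.1 points; outcome means/SDs 7.37/1.23 (composite), 7.12/1.40
(Cantril), 0.63/0.29 (EQ-5D); and within-project correlations 0.43
(CEP–Cantril), 0.63 (CEP–EQ-5D), 0.34 (Cantril–EQ-5D). True group effects
default to the unadjusted known-group contrasts (e.g. depression −1.16
points). All randomness flows through one explicitly passed seed, scoped so
the caller's RNG state is untouched; a fixed seed reproduces the dataset
byte for byte.

Two modes serve different layers. **Outcome mode** draws ready-scored
outcomes: the composite score is grand mean + project intercept + covariate
effects + residual, and the three outcomes' residuals share the target
correlation matrix (applied via its Cholesky factor). Covariate effects
enter the composite's mean only, so configs with non-zero effects attenuate
the realized marginal correlations slightly; correlation-recovery runs use a
covariate-free config. By default outcomes are bounded to their instruments
(composite clamped to 0–10, Cantril rounded to an integer in 0–10, EQ-5D
clamped to the tariff range), which reproduces realistic ceiling behaviour —
about 10% of utilities at 1.00 under the defaults — at the measured cost of
under 0.01 of correlation attenuation. Recovery simulations that check an
estimator against a configured ground truth set `truncate_outcomes = FALSE`
so the generating process is exactly the assumed linear mixed model.
**Item mode** draws the 42 raw items, the EQ-5D dimensions and the Cantril
score from a one-factor graded-threshold model: a standard-normal severity
variable per item loads 0.7 on the respondent's standardized latent
wellbeing and is cut at fixed marginal thresholds skewed toward healthy
states; raw codings are then emitted per the active scheme and items masked
completely at random at the configured rate. Scoring the generated items
reproduces the latent ordering (Spearman ρ > 0.9 at default noise).

What the generator does *not* emulate: the real projects' sampling frames,
informative non-response or any missingness mechanism beyond
missing-completely-at-random masking, project-specific instrument variants,
and correlations between covariates. Passing tests therefore demonstrate
that the scoring rules are exact and that the estimators recover known
ground truth under the assumed model — not that the original cohort's
numerical tables are reproduced, which would require the restricted extract.

## Problem sizes and numerical choices

The test suite runs its recovery simulations at deliberately modest sizes —
28 projects × 500 for meta-correlation recovery (pooled r within ±0.03 of
the generating 0.63 and 0.43), 28 × 357 (≈10,000 respondents) for the
depression contrast (±0.08 of −1.16), and 100 replicates of 28 × 100 for
interval coverage (expected within 90–99%) — sizes at which Monte-Carlo
error is comfortably inside those bands. The DerSimonian–Laird pooling is
checked against a frozen hand-computed spreadsheet oracle to 1e-12 and
against `metafor` on random inputs. Degenerate inputs are handled
explicitly: zero-variance or tiny projects are excluded from pooling with a
warning, single-project or singular mixed fits fall back to ordinary least
squares, and respondents breaching the pro-rating policy are excluded rather
than imputed.

## Known limitations

The preference weights themselves are taken as printed and are not
re-derived; non-Dutch EQ-5D tariffs and caregiver instruments are out of
scope; τ² estimators other than DerSimonian–Laird (REML, Paule–Mandel) are a
documented extension point, not implemented. One documented oddity of the
source tables: the general-population stratum is labelled N = 3,331 in the
descriptive table but N = 2,221 in the correlation table; the discrepancy is
unexplained there and is surfaced here rather than resolved.
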