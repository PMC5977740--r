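---
title: "FoodMATS: scoring model, reliability and validity methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FoodMATS: scoring model, reliability and validity methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodmats)
```

# The instrument and its data model

FoodMATS audits food and beverage marketing in recreation and sport
facilities. The unit of observation is the *marketing occasion*: any
commercial advertising, promotion or messaging of a food or beverage
product, brand or retailer, recorded against one of 37 audit items — 26
location items grouped into three facility areas (food/concession, sports,
other) and 11 pricing indicators (four covering overeating or repeat-visit
rewards, seven comparing prices of healthier versus less healthy options).
Product packaging is never an occasion. A *site* is one building; two
geographically separate buildings are two sites, and no merge operation is
offered.

Each occasion carries the marketed entity (name plus kind: product, brand
or retailer — the pair is the identity used for repetition counting), an
ordered healthfulness class, two boolean design flags (child-targeted,
sports-related), an ordered size class where size applies, and the
indoor/outdoor setting. A site audit bundles the occasions with the
pricing-indicator records and two facility-size covariates (number of
concessions, number of sports areas).

# Classification rules

Products and brands are ranked on three ordered classes: Most Healthy
(unprocessed, no added fat, sugar or salt), Less Healthy (some added fat,
sugar or salt), Least Healthy (processed, energy-dense, nutrient-poor).
Because full nutrient profiles are rarely available for items seen in the
field, the default implementation is keyword-driven: an ordered rule list
where the first matching pattern decides, with energy-dense keywords
deliberately ordered ahead of whole-food keywords ("fruit punch" must
resolve before "fruit"). An optional added-fat/sugar/salt argument maps
directly onto the three classes and bypasses the keywords, providing a
nutrient-override hook for users who do have composition data. Brands rank
as the product they most closely represent via an editable brand map;
retailers rank by category (grocery/farmers-market/salad/sandwich/smoothie
→ Most; sit-down/cafeteria/coffee/prepared-grocery/supplement → Less;
pizza/burger/taco/fried-chicken/Asian/ice-cream/pub → Least) with a
most-prominent-product fallback. All rules ship as a versioned, editable
JSON document (`inst/extdata/foodmats_rules.json`) rather than code
constants, since real deployments extend the rankings case by case.

Size classes use letter-sheet equivalents (8.5 × 11 in): indoors small
< 1, medium 1–3, large > 3; outdoors small < 1, medium 1–10, large > 10.
The medium intervals are closed — exactly 1, 3 or 10 sheets is medium —
because the instrument's strict inequalities apply only to the small and
large ends. Below one sheet the two settings agree by construction.
Non-positive areas are rejected.

# The scoring model

Per area $a$, with $E_a$ the occasion count (triggered pricing indicators
enter the food area as Least-Healthy pseudo-occasions),

$$A_a = E_a\left(1 + w_c\,(p_{least} + f\,p_{less}) + w_{ch}\,p_{child}
      + w_{sp}\,p_{sport}\right) + w_{sz} \sum_{i \in sized(a)} size_i$$

and the site score is $S = \sum_a A_a + w_{rep}\,R$, where $R$ counts
distinct entities recorded at least 3 times site-wide.

Defaults: $w_c = w_{ch} = w_{sp} = w_{sz} = 1$, $f = 0.5$, $w_{rep} = 2$,
threshold 3. The published instrument's verbatim point values are not in
the public record, so this multiplicative frequency-times-power form is
the package's own documented default, chosen to satisfy the qualitative
requirements the instrument states: the score strictly increases with
exposure, with each powerful characteristic (unhealthiness, child
targeting, sports theming, physical size), and with repetition; it is zero
exactly for an empty audit; and with all power and repetition weights set
to zero it degenerates to the plain occasion count. Every constant lives
in `scoring_config()`, so an alternative point scheme — including an
additive frequency-plus-power variant — can be expressed without touching
code. The repetition threshold of 3 follows the instrument's definition
verbatim; the repetition weight of 2 is a tunable default.

Three deliberate choices deserve note:

- **Less Healthy counts half of Least Healthy** ($f = 0.5$): the content
  scale is ordered Most < Less < Least and the ordering must be visible in
  the score; one half is the simplest weight that achieves it.
- **Size points accrue only from occasions that carry a size.** Size is
  excluded for some pricing and place occasions, so the area's size factor
  could be written either as $E_a \times$ (mean size over sized occasions)
  or as the plain sum of size points. The first form extrapolates the mean
  to unsized occasions and, as a consequence, is *not* monotone under
  exposure: appending a small occasion to an area with many unsized
  occasions can lower the product faster than the +1 exposure gain. Since
  monotone ordering is the entire semantic content of the score, the
  package uses the additive form. The two coincide whenever every occasion
  in the area has a size. The reported power profile still carries
  `mean_size` averaged over sized occasions only.
- **Triggered pricing indicators are pseudo-occasions in the food area**:
  they enter $E_{food}$ and the content proportions (each contributing a
  Least-Healthy observation) but carry no design flags and no size, and
  they never enter repetition counting, which is entity-based. Whether
  pricing should affect only the count or also the power mix is genuinely
  open; counting it in both keeps "pricing that pushes unhealthy choices"
  score-visible even in sites with little other food-area marketing.

# Reliability statistics

Two trained raters audit the same site on the same day. The report has six
components: (a) presence of marketing per item, (b) occasion counts per
area, and — restricted to occasions both raters identified — (c) the
entity marketed, (d) the child-targeted flag, (e) the sports-related flag,
(f) the physical size. Co-identification is resolved on the
(area, item, entity) key, with occasions sharing a key paired in recording
order up to the smaller count; unmatched occasions contribute only to (a)
and (b). No matching key is canonical here — this one makes "both raters
saw this ad" concrete while keeping (c) interpretable as a consistency
check of the matching itself.

Agreement is quantified by percent agreement, Cohen's κ for nominal data,
weighted κ_w for ordinal data, and the two-way random-effects intraclass
correlation for counts. Implementation choices:

- κ = (p_o − p_e)/(1 − p_e); confidence intervals use the
  Fleiss–Cohen–Everitt large-sample variance (the weighted expression,
  which reduces to the unweighted one under identity weights), and the
  test of κ = 0 uses the null-hypothesis variance with marginals fixed.
- κ_w defaults to **linear** disagreement weights — the conservative
  convention for short ordered scales like small/medium/large — with
  quadratic weights available by flag; identity weights recover the
  unweighted statistic exactly (asserted in tests to 1e-12).
- Perfect agreement on a single observed category makes p_e = 1; the
  package returns κ = 1 with a warning rather than failing, because a
  complete audit pair can legitimately agree perfectly on a one-category
  component.
- The ICC is the Shrout–Fleiss two-way random, absolute-agreement form,
  computed from the ANOVA mean squares, on square-root-transformed counts
  (counts are right-skewed; the transform improves normality). Both the
  single-rater ICC(2,1) and the average-rater ICC(2,k) are reported — the
  instrument's documentation is ambiguous about which of the two headline
  numbers refers to which form, so the report always carries both.
  Confidence bounds are the McGraw–Wong F-distribution bounds, with the
  average-rater bounds obtained by the Spearman–Brown step-up. Zero
  between-subject variance is an error (the statistic is undefined);
  negative variance components can push the point estimate outside [0, 1],
  in which case it is reported as computed but left without a band label.
- Interpretation bands are reproduced exactly as published with the
  instrument: for κ, 0.0–0.2 "fair", 0.21–0.40 "poor", 0.41–0.60
  "moderate", 0.61–0.80 "good", 0.81–1.00 "very good". The first two
  labels are swapped relative to the usual convention; the package
  reproduces the published ordering by default (fidelity over correction)
  and offers `bands = "conventional"` to restore poor-then-fair. ICC
  bands: < 0.40 poor, 0.40–0.59 fair, 0.60–0.74 good, 0.75–1.00
  excellent.

# The validity pipeline

The pipeline mirrors the instrument's validation analyses on a per-site
outcomes table (score, sponsorship dollars, weekly Least-Healthy sales by
channel, facility-size covariates):

1. **Transforms.** Scores, sponsorship dollars and sales are square-root
   transformed; the transform stage is isolated so raw and transformed
   paths differ only where specified.
2. **Truncation.** Values beyond mean ± 3 SD are replaced by one point
   above (below) the most extreme value inside the threshold. "One point"
   is one unit on the variable's measured scale (configurable), and the SD
   is the sample (n − 1) estimator computed *including* the outlier —
   both conventions are under-determined by the source procedure and are
   fixed here for reproducibility. The rule is applied once, as in the
   analysis it implements; a second application is a no-op on all
   realistic tables (asserted in tests), though a contrived bimodal table
   could cascade under repeated application. Note a structural
   consequence of the include-outlier SD: with n points the largest
   achievable z-score is (n − 1)/√n, so no value can sit beyond 3 SD in
   samples of 9 or fewer — truncation only ever fires at moderate n.
3. **Sponsorship correlations.** Pearson and Spearman correlations of
   √score with √food-sponsorship, and the partial Pearson correlation
   controlling for facility size. Both size covariates enter separately
   (the composite-versus-separate question is ambiguous in the source;
   separate covariates are the less lossy choice). The partial correlation
   residualizes both variables on the controls and correlates the
   residuals, with the t test on n − 2 − q degrees of freedom; the
   residual identity is asserted in tests to 1e-10. Total sponsorship is
   screened with a plain Pearson correlation first and analysed no
   further when non-significant.
4. **Missing-data check.** Welch two-sample t-tests (the variance
   assumption is the safer default for an unspecified "independent
   t-test") compare mean scores of sites that did and did not provide
   each outcome.
5. **Collinearity screen.** Predictor pairs with |r| > 0.7 are flagged;
   the member not itself associated with the outcome (two-sided p ≥ 0.05)
   is recommended for dropping, mirroring the exclusion of concession
   count from the original models. Ties drop the weaker associate. Size
   covariates that are constant in a channel's subsample are dropped
   before screening (a constant column is inestimable).
6. **Sequential regression** per channel (concession, vending, total):
   Model 1 regresses √sales on facility size, Model 2 adds √score.
   Reported per model: standardized β with confidence intervals
   (obtained by refitting on z-scored variables), R², adjusted R², ΔR²
   against the previous model, and the F-change test
   $F = (\Delta R^2/\Delta k) / ((1 - R^2_{full})/(n - k_{full} - 1))$,
   verified in tests against the direct nested-model sum-of-squares
   computation. Rank-deficient designs fail with the collinear columns
   named. Significance is two-sided p < 0.05 throughout with no
   multiple-testing correction, matching the source analysis.

Sites missing a variable are excluded from that analysis only, with
counts logged; a section with no usable data is skipped with a log entry.
Two weeks of itemized sales convert to weekly Least-Healthy dollars by
classifying every row with the product rules and halving the
Least-Healthy total; a channel containing any unclassifiable row is
flagged excluded, as poorly itemized data cannot be classified by
healthfulness.

# The synthetic-data generator

`generator_params()` documents the study conditions the generator
emulates: 50 sites; concession counts mostly 1 (1 + Binomial(2, 0.15));
sports areas 1 + Poisson(2.5), median 3; per-area occasion counts Poisson
with the food rate proportional to concessions (5 per concession), the
sport rate proportional to sports areas (1.2 per area) and a flat rate of
4 elsewhere — tying exposure to facility size, as observed in real
facilities; a health mix of 0.15/0.25/0.60 (most recorded marketing is
Least Healthy); child-targeting probability 0.20, sports-theming 0.25;
size mix 0.3/0.5/0.2 with 10% of occasions unsized; entities drawn from a
20-name pool with Zipf(1) reuse so that the 3-recording repetition
threshold fires at a realistic rate; and 11 pricing indicators each
triggered with probability 0.3. Poisson is the minimal count model given
no distributional information; the parameters were fixed once, before the
acceptance suite existed, and not revisited. Under these defaults the
median synthetic site score is in the mid-40s.

Outcomes couple to the score on the square-root scale — the scale on
which the analyses transform both scores and dollars:
√sponsorship = 2 + 5·√S + N(0, 4.5) floored at zero, with total
sponsorship adding an independent component (√ ~ N(100, 30)) so its
correlation with the score is attenuated; √weekly-sales =
5 + 2·n_sports + 4·√S + N(0, 5) for concessions and a deliberately
weaker 3 + 1.5·n_sports + 1.5·√S + N(0, 4) for vending. Outcomes are
masked missing with probabilities 0.3/0.4/0.5
(sponsorship/concession/vending), near real provision rates. The noise
scales were chosen so the noiseless design-time effect sizes sit in the
range the instrument's validation reports (partial r near 0.85, sales
ΔR² between roughly 0.15 and 0.25).

Rater pairs perturb each categorical or boolean attribute of each
occasion independently with probability `flip` (booleans toggle;
categories move to a uniformly chosen alternative). For a binary
attribute with truth marginal p this gives the closed-form expected
kappa implemented in `expected_flip_kappa()`: observed agreement 1 − f
against the chance agreement of the two resulting marginals (zero at
f = 0.5 with balanced marginals).

What the generator does *not* emulate — and hence what passing tests do
not establish about field data: rater omissions and false detections
(only attribute disagreement is modelled, so synthetic presence/count
agreement is perfect by construction), entity-consistent healthfulness
(attributes are drawn independently per occasion), spatial or seasonal
structure in occasion placement, non-Poisson overdispersion of occasion
counts, and informative missingness (outcomes are masked completely at
random, which is why the pipeline's missing-data t-tests are expected to
be null on synthetic data).

# Problem sizes and numerical tolerances used in the tests

The test suite checks the scoring properties exhaustively on all audits
of up to 4 occasions over a 16-type attribute grid (2 entities × 2 health
classes × 2 child flags × 2 areas, about 4.8k audits) plus seeded random
audits over the full attribute space; agreement statistics against
brute-force contingency/ANOVA oracles on 100 random tables at 1e-12; the
rater-noise closed form over 1,000 occasions within ±0.05; and the
pipeline's operating characteristics over 200 seeded replicates of the
50-site design for the positive-coupling and null-coupling cases
(recovery in at least 80% of positive replicates; null false-positive
rate within 5% ± 3%). These sizes were chosen as the smallest at which
each property is sharp: exhaustiveness makes the monotonicity claims
proofs over the grid rather than spot checks, and 200 replicates bound
the binomial error on an operating-characteristic estimate to about ±3
percentage points.

# Known limitations

- The default point scheme is the package's own; absolute score values
  are not comparable to scores produced with the original unpublished
  point tables, although orderings induced by any monotone configuration
  agree on the qualitative properties above.
- Keyword-based healthfulness classification is a coarse stand-in for
  nutrient-threshold guidelines; the rule file is meant to be edited per
  jurisdiction, and the added-fat/sugar/salt override should be preferred
  when composition data exist.
- The reliability report supports exactly two raters; multi-rater
  generalizations (e.g. Fleiss' kappa) are out of scope.
- The asymptotic kappa interval is a Wald interval and degenerates at the
  boundary (κ = 1 yields a zero-width interval); exact or bootstrap
  intervals are not provided.
- Placement-height child-targeting assessment and content analysis of
  promotional imagery are explicitly outside the instrument's scope and
  therefore outside the package's.
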