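# foodmats

**FoodMATS — the Food and beverage Marketing Assessment Tool for Settings, as
a reusable R package.**

Children encounter heavy food and beverage marketing in the places they play
sport. FoodMATS is an observational audit instrument for quantifying that
marketing in recreation and sport facilities: trained raters walk a site and
record every *marketing occasion* — any commercial advertising, promotion or
messaging of a food or beverage product, brand or retailer (product
packaging excluded) — across three facility areas (food/concession, sports,
other), together with 11 pricing indicators, and the instrument condenses
the audit into a single site score. This package implements the complete
toolchain for researchers and public-health practitioners using the
instrument: the audit data model and file formats, the classification
rules, the scoring algorithm, the inter-rater reliability statistics, the
validity-analysis pipeline, and a seeded synthetic-data generator so every
component can be exercised without access to field data.

## The score

The instrument operationalizes the *exposure* and *power* of marketing
messages. Per area *a* ∈ {food, sport, other}:

- **Exposure** — the occasion count `E_a`; triggered pricing indicators
  (pricing that encourages overeating, repeat visits, or prices unhealthy
  options below healthy ones) count as Least-Healthy occasions in the food
  area.
- **Power** — the proportions of occasions that are Least/Less Healthy
  (`p_least`, `p_less`; content is ranked on the ordered classes
  Most < Less < Least Healthy), child-targeted (`p_child`), sports-related
  (`p_sport`), and the physical size of each promotion in letter-sheet
  units (small 0, medium 0.5, large 1).

With default weights the area score is

```
A_a = E_a · (1 + p_least + ½·p_less + p_child + p_sport) + Σ size_i
```

(the size sum runs over occasions that carry a size; when all do, it equals
`E_a · mean_size`, the familiar frequency × power product), and the site
score adds a repetition factor counting distinct marketed entities recorded
three or more times site-wide:

```
S = A_food + A_sport + A_other + 2·R
```

Higher scores mean more, and more powerful (unhealthy, child-targeted,
sports-themed, large) food marketing. Every constant is configurable via
`scoring_config()`.

Around the score the package provides the instrument's two analysis
pipelines:

- **Reliability** (`reliability_report()`, `cohens_kappa()`,
  `weighted_kappa()`, `icc_two_way_random()`): percent agreement, Cohen's κ
  with Fleiss–Cohen–Everitt confidence intervals, linear/quadratic weighted
  κ_w for ordinal scales, and Shrout–Fleiss two-way random ICC(2,1)/(2,k)
  on square-root-transformed counts, each labelled with its interpretation
  band.
- **Validity** (`run_validity_pipeline()`, `sequential_regression()`,
  `correlations()`, `truncate_outliers()`): square-root transforms, ±3 SD
  outlier truncation, Pearson/Spearman/partial correlations of scores with
  sponsorship dollars controlling for facility size, collinearity
  screening, and sequential regression of weekly Least-Healthy sales
  (Model 1 = facility size; Model 2 adds the score) with ΔR² and F-change
  tests.

## Worked example

Score a small audit — two cola-brand posters in the concession area, two
sport-area banners, a retailer ad in a hallway, and two triggered pricing
indicators:

```r
library(foodmats)

occ <- rbind(
  marketing_occasions("arena_1", "food",  1L, "Fizz Cola", "brand",
                      "least_healthy", TRUE,  FALSE, "large"),
  marketing_occasions("arena_1", "food",  3L, "Fizz Cola", "brand",
                      "least_healthy", FALSE, FALSE, "medium"),
  marketing_occasions("arena_1", "sport", 12L, "Fizz Cola", "brand",
                      "least_healthy", FALSE, TRUE,  "large"),
  marketing_occasions("arena_1", "sport", 14L, "Aqua Pura", "brand",
                      "most_healthy",  FALSE, FALSE, "small"),
  marketing_occasions("arena_1", "other", 20L, "Burger Barn", "retailer",
                      "least_healthy", TRUE,  FALSE, NA_character_)
)
audit <- site_audit("arena_1", occ,
                    pricing = pricing_records(1:11, c(TRUE, TRUE, rep(FALSE, 9))),
                    n_concessions = 1L, n_sports_areas = 3L)
summary(foodmats_score(audit))
#> FoodMATS score breakdown, site 'arena_1'
#>   area frequency p_least p_less p_child p_sport mean_size area_score
#>   food         4     1.0      0    0.25     0.0      0.75       10.5
#>  sport         2     0.5      0    0.00     0.5      0.50        5.0
#>  other         1     1.0      0    1.00     0.0      0.00        3.0
#> repetition count: 1; total: 20.50
```

The food area holds 4 occasions (2 posters + 2 triggered pricing
indicators, all Least Healthy, one child-targeted, sizes large + medium),
giving `4·(1 + 1 + 0.25) + 1.5 = 10.5` points; "Fizz Cola" appears three
times site-wide, adding the repetition factor `2·1`, for 20.5 points total.

Reliability and validity analyses work the same way on real or synthetic
data:

```r
p      <- generator_params()                 # documented study-like defaults
audits <- generate_audits(p, seed = 42)      # 50 synthetic site audits
oc     <- generate_outcomes(audits, p, seed = 43)
run_validity_pipeline(oc)
#> FoodMATS validity report (50 sites)
#> Food sponsorship (n = 27): r = 0.826 (p = <1e-04), rho = 0.810 (p = <1e-04),
#>   partial r = 0.759 (p = <1e-04)
#> concession sales (n = 30): Model 2 R2 = 0.580, dR2 = 0.317,
#>   F(1, 26) = 19.606, p = 0.000152
#> ...
```

Here the generator couples sponsorship dollars and Least-Healthy sales to
the score on the square-root scale, and the pipeline recovers those
couplings: a strong positive partial correlation with food sponsorship
after controlling for facility size, and a significant R² increment when
the score joins facility size in the sales regressions.

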