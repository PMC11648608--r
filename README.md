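# foodswap

Multicriteria assessment of meat and milk alternatives in R.

Plant-based alternatives to meat and milk are usually evaluated one
dimension at a time — a nutrient comparison here, a life-cycle footprint
there, a price survey elsewhere — which hides the trade-offs between
domains. `foodswap` runs the four assessments in one consistent pipeline
and folds them into a single score, for researchers and analysts studying
diet change:

* **Nutrition** — a diet-level *nutritional imbalance indicator*: the mean
  percentage violation across recommended nutrients,
  `NI = (100/N) [ Σ shortfalls below minimum limits + Σ excesses above
  maximum limits ]`, with diet-dependent zinc (phytate-banded) and iron
  (absorption-blended) requirements re-resolved per scenario, and an exact
  per-nutrient decomposition of changes.
* **Health** — a comparative risk assessment on six nutrient risk factors
  (PUFAs, fiber, potassium protective; cholesterol, sodium, heme iron
  harmful) with log-linear dose-response `RR(Δ) = RR_unit^(Δ/u)`,
  population impact fractions `PIF = (RR_base − RR_scen)/RR_base` applied
  to cause-specific mortality, and a 3,500 mg/day cap on potassium
  benefits.
* **Environment** — GHG/land/water footprints per serving, calorie, or kg,
  expressed relative to a high-impact benchmark (beef; mean of whole and
  low-fat milk) and weighted 0.65/0.17/0.18 by planetary-boundary
  contributions.
* **Cost** — CPI deflation to a common year, PPP conversion to
  international dollars, diet costs and replacement cost changes.
* **Replacement & synthesis** — calorie-conserving (or serving-conserving)
  replacement of all meat and/or dairy, then min-max normalization of each
  domain across the candidate pool and a weighted 0–100 score:
  `100 [ ⅓(½·nutrition + ½·mortality) + ⅓(0.65·GHG + 0.17·land +
  0.18·water) + ⅓·cost ]`.

A seeded synthetic-data generator produces complete, internally consistent
input bundles (foods, diets, recommendations, relative risks, mortality,
CPI/PPP), so the whole pipeline runs and is tested without any downloads.

## Worked example

```r
library(foodswap)

bundle <- generate_bundle(generator_spec(seed = 1))

# baseline diet: high-income-style imbalance profile
diet_imbalance(bundle$diets, bundle$foods, bundle$recommendations,
               bundle$zinc_reference, bundle$iron_model)
#> Nutritional imbalance indicator: 6.70% (over 20 recommended nutrients)
#> Violated recommendations:
#>   energy_kcal     maximum limit, deviation +7.6%
#>   fiber_g         minimum limit, deviation -35.9%
#>   satfat_g        maximum limit, deviation +33.8%
#>   ...

# one replacement scenario: all meat calories -> soybeans
s <- replacement_scenario("meat_to_soybeans", replace = "meat",
                          with = "soybeans", basis = "calorie")
run_scenario(s, bundle)$domain_changes[, c("domain", "value")]
#>          domain  value
#> 1  nutrition_pp  -1.92
#> 2 mortality_pct -16.81
#> 3       ghg_pct -55.38
#> 4      land_pct -62.83
#> 5     water_pct -19.33
#> 6      cost_pct -17.00
```

Negative is favorable in every domain: this synthetic scenario cuts the
imbalance indicator by 1.9 percentage points, diet-attributable mortality
by 17%, GHG by 55%, land by 63%, water by 19%, and diet cost by 17%
(magnitudes reflect the generator's illustrative risk and price tables,
not real-world estimates). Scoring the full scenario matrix:

```r
scores <- synthesize_scores(run_scenarios(default_scenarios(bundle), bundle))
scores[scores$replaced == "meat", c("food_id", "score", "rank")]
#>    food_id score rank
#> 1     peas  92.3    1
#> 2    beans  90.5    2
#> 3 soybeans  88.7    3
#> ...
#> 20 beef_burger  38.9   20
#> 21        beef  32.6   21
```

Per-product benchmark comparisons work the same way:

```r
milk <- benchmark_food(bundle$foods, "dairy")
soy  <- bundle$foods[bundle$foods$id == "soybeans", ]
relative_impact(soy, milk, basis = "serving")
#> soybeans vs whole_milk+lowfat_milk (serving basis):
#>   GHG 6%, land 5%, water 1% -> weighted 5%
```

A thin command-line front end mirrors the pipeline:

```sh
Rscript inst/cli/foodswap.R synth      --out bundle --seed 1
Rscript inst/cli/foodswap.R run-all    --bundle bundle --out results
Rscript inst/cli/foodswap.R synthesize --changes results/domain_changes.csv --out results
```

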