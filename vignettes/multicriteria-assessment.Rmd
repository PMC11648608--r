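---
title: "Methods: multicriteria assessment of meat and milk alternatives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multicriteria assessment of meat and milk alternatives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodswap)
```

# Scope and data model

`foodswap` compares candidate replacement foods (tofu, tempeh, veggie
burgers and sausages, plant milks, and the unprocessed legumes, nuts, and
grains they are made from) with the animal-source foods they are meant to
replace, across four assessment domains: nutrition, long-term health,
environment, and cost. Everything runs off one input *bundle*: a food
table (30 nutrient columns per 100 g, serving size, per-kg footprints, a
price observation), regional diets in g/person/day (assumed waste-
adjusted), a nutrient recommendation table, relative risks for six
nutrient risk factors, cause-specific mortality, and CPI/PPP series. All
per-mass quantities are held per 100 g internally — the composition-table
convention — with footprints converted from per-kg at load and back at
write, so files round-trip losslessly. Milliliter servings of liquids are
treated as grams at unit density, which is what standard serving tables
assume for milk. The food table's column dictionary is closed: an
unrecognized nutrient column is an error rather than being ignored,
because a silently mismatched nutrient name would corrupt the imbalance
indicator downstream.

# Nutritional imbalance

For a diet with intakes $I_n$ and recommendations $R_n$ over $N$
recommended nutrients, the imbalance indicator is the mean magnitude of
violations, in percent:

$$\mathrm{NI} = \frac{100}{N}\left[
  \sum_{n \in \min,\; I_n < R_n} \frac{R_n - I_n}{R_n} +
  \sum_{n \in \max,\; I_n > R_n} \frac{I_n - R_n}{R_n}\right]$$

Compliant nutrients contribute zero; shortfalls below minimum limits and
excesses above maximum limits both count positively, so the indicator is
nonnegative and vanishes exactly when every recommendation is met. This
magnitude convention is the only reading of "subtracting excesses from
shortfalls" under which reported imbalance levels are positive and
improvements appear as reductions in percentage points. Per-nutrient
deviations are deliberately uncapped (a saturated-fat intake 60% above its
limit contributes 60 points), and energy participates as a maximum-limit
nutrient, so chronic calorie excess registers as imbalance.

The packaged default recommendation set has $N = 20$ nutrients and is
labeled illustrative: authoritative harmonized requirement tables are not
redistributable here, so the defaults are plausible adult population
averages and every function accepts a user table instead. Two exclusions
are principled rather than data-driven: calcium carries no recommendation
(its reference values derive from balance studies of prevailing intakes,
so deviations from them are not interpretable as imbalance), and total
sugars carry none (quantitative limits address *free* sugars, which a
total-sugar composition column — lactose, intrinsic fruit sugar — does not
measure). Copper fills the twentieth slot.

Two requirements are diet-dependent and re-resolved for every scenario
diet before the indicator is computed. The zinc requirement is linearly
interpolated in dietary phytate between tabulated reference points and
clamped at the table ends. The iron requirement divides a target absorbed
amount (default 1.5 mg/day) by a blended absorption fraction: heme iron
absorbs at a constant rate (default 0.25) while nonheme absorption is
log-linear in dietary mediators — phytate and calcium inhibit, vitamin C
and meat tissue (indexed by heme iron intake) enhance — truncated to
(0, 1]. The published nonheme-absorption regression is not reproduced in
the source we implement from, so the packaged coefficients are synthetic
values carrying the established signs; they are a labeled, editable table,
and tests exercise the model with synthetic coefficients only.

Changes in the indicator decompose exactly: each nutrient's contribution
is the change in its own violation term over $N$, contributions sum to the
total change, and shares are reported sign-aware so they total 100%.

# Comparative risk assessment

Six nutrient exposures drive the health model: PUFAs, fiber, and potassium
(protective) and cholesterol, sodium, and heme iron (harmful). Dose
response is log-linear — a relative risk $RR_u$ per increment $u$ compounds
as $RR(\Delta) = RR_u^{\Delta/u}$ — which is the standard form in
comparative risk assessment and the only one under which per-unit risks
compose multiplicatively. Multi-factor risks multiply across factors, the
usual independence assumption, and we flag it as such. Protective
potassium benefits saturate: exposure is capped at 3,500 mg/day inside
risk computations (the cap is a risk-factor attribute and can be
overridden per scenario), while raw intake is reported everywhere else.

The population impact fraction for an endpoint is
$\mathrm{PIF} = (RR_{\mathrm{base}} - RR_{\mathrm{scen}})/RR_{\mathrm{base}}$.
The reference exposure used to anchor the RRs cancels in this ratio; the
implementation normalizes to the baseline exposure so that
$RR_{\mathrm{base}} = 1$ exactly, which is numerically stable for large
exposure shifts. PIFs are applied to cause-specific deaths (coronary heart
disease, stroke, cancer), summed, and expressed as a share of all-cause
deaths. The mortality domain change carries a negative sign when deaths
are averted so that all six assessment domains share one convention:
negative = favorable.

Per-serving risk comparisons need one overall number per food. The
endpoint RRs are combined with weights equal to each endpoint's share of
cause-specific deaths in the analysis region — an explicit, configurable
choice, recorded in the output, since no single combiner is canonical.
Both comparison modes are implemented: a food swapped against a benchmark
serving, or added on top of the current diet; the mode is recorded in the
result. The default endpoint map (all six factors to CHD and stroke, heme
iron and fiber additionally to cancer) and the default RR magnitudes are
packaged as illustrative, editable tables.

# Environment

Footprints enter per kg of food for GHG (kg CO2eq), land (m2), and water
(L), and convert to serving or calorie bases through serving size and
energy density. Comparisons are benchmark-relative: each domain is
expressed as a percent of a high-impact benchmark — beef for meats, and
for dairy the mean footprint of whole and low-fat milk (both benchmarks
configurable) — and the three domains fold into one score with
planetary-boundary weights 0.65/0.17/0.18 (GHG/land/water), reflecting
the larger contribution dietary change must make to the climate boundary
than to land or water limits. The weighted score is a convex combination
(bounded by the domain extremes), scale-invariant to multiplying all
footprints by a constant, and exactly 100% for the benchmark itself.
Replacement scenarios report per-domain percentage changes of absolute
diet totals plus the same weighted average. A per-kg processing GHG
increment (e.g. cooking emissions for dry legumes) can be switched on as
a sensitivity; it is additive and touches GHG only. Reported percentages
are rounded half-away-from-zero to integers for presentation, matching
how such results are printed; machine outputs keep full precision.

# Cost

Price observations carry currency and year. Harmonization deflates to a
common base year (default 2020) with the food CPI series of the
observation's currency, then converts to international dollars with the
base-year PPP rate; the two operations commute. Multiple observations per
food average after harmonization, and full provenance (source year,
currency, CPI factor, PPP rate) is retained. Diet cost is linear in
quantities and invariant to rescaling local prices and the PPP rate
together.

# Replacement scenarios

A scenario replaces *all* intake of a category (meat, dairy, or both) with
one alternative per category. On the calorie basis the alternative
supplies exactly the pooled calories removed, so total diet energy is
conserved — asserted to 1e-6 relative on every run. On the serving basis
it supplies the pooled number of servings removed; energy is then not
conserved, which is the point of that sensitivity. Replaced-category
intake is exactly zero afterwards. Category membership is data-driven via
the food table's category column, and the replaced pool is aggregated
before conversion (one calorie pool, not food-by-food mapping), matching
an "all meat" replacement. The dairy category defaults to milk only.

One deliberate relaxation: an alternative belonging to the replaced
category is normally an error (it almost always signals a typo), but
within-category comparator runs — replacing all meat with only poultry, or
scoring beef itself alongside the alternatives — are part of the
assessment design, so they are allowed behind an explicit
`comparator = TRUE` flag, and `default_scenarios()` uses it to place the
animal comparators in the synthesis pool. Cultivated-meat-style variants
need no special machinery: they are ordinary food rows (optionally tagged
via the `variant` field) with user-supplied footprint and cost ranges.

# Synthesis

Within a pool of scenarios sharing a replaced category, basis, and region,
each domain's changes are min-max normalized,
$s = 1 - (x - \mathrm{best})/(\mathrm{worst} - \mathrm{best})$, so the
most favorable change (the largest reduction) scores 1 and the least
favorable 0; the mapping is affine-invariant. If a pool has zero spread in
some domain there is no information to discriminate and every food scores
1, with a warning. The summary score is

$$100\left[\tfrac13\left(\tfrac12 s_{\mathrm{nut}} + \tfrac12 s_{\mathrm{mort}}\right)
 + \tfrac13\left(0.65\, s_{\mathrm{ghg}} + 0.17\, s_{\mathrm{land}} + 0.18\, s_{\mathrm{water}}\right)
 + \tfrac13 s_{\mathrm{cost}}\right]$$

bounded in [0, 100]. Every weight level must sum to one to 1e-9. Two
alternative schemes ship alongside the main one: equal environmental
subweights, and equal weights across all six subdomains; the rank
correlation between schemes is computed and reported, not asserted.
Ranking is descending by score with exact ties broken lexicographically by
food id, so output order is deterministic.

The normalization pool includes the animal comparators, which is why an
animal product can score above zero overall even when it anchors the worst
end of several subdomains; the pool is explicit in the scenario list, so
either reading (comparators in or out) is runnable.

# The synthetic-data generator

`generate_bundle()` emits a complete bundle from a fixed roster of
template foods. What it emulates is the *structure* real inputs have:
animal-source foods elevated in saturated fat, heme iron, cholesterol, and
sodium; legumes, nuts, and whole grains elevated in fiber, potassium, and
PUFAs; processed alternatives fortified (vitamin B12, riboflavin, vitamin
A, additive and toggleable) and priced above their unprocessed
ingredients (markup 1.6x by default); and a GHG hierarchy of
beef : pork : poultry : plant at 60 : 7 : 6 : 1. The baseline diet is
scaled so meat contributes 15% and dairy 8% of a 2,260 kcal/day total —
energy deliberately ~8% above the packaged 2,100 kcal limit — and its
violation profile is high-income-like: saturated fat above its cap, fiber
and potassium short, vitamin B12 marginal. Noise is one lognormal factor
per food (sd 0.05) multiplying all nutrients, which preserves composition
invariants (fatty-acid closure, heme within total iron) at any noise
level; footprints and prices get independent factors from separate
sub-streams of the same seed. Identical specs give byte-identical bundles.

What it does not emulate: real covariance between nutrients beyond the
category templates, country-level heterogeneity, seasonal or within-food
price variation, and the absolute calibration of any real composition
database. Passing tests on synthetic bundles therefore demonstrate that
the machinery is correct and the orderings forced by construction are
recovered — not that real-data results would take particular values. The
synthetic baseline imbalance lands near 5%: structurally high-income-like
but milder than real estimates, which depend on requirement tables not
shipped here.

`generate_known_answer_diet()` is the exact-recovery scaffold: it builds a
one-food diet whose intake of every recommended nutrient sits at a
requested signed deviation from its recommendation, computes the implied
indicator from the targets alone, and the nutrition module must reproduce
both to 1e-9 relative. Special handlers are disabled in its
recommendation set, since diet-dependent requirements would move the
targets.

# Numerical choices and degenerate inputs

* Violation magnitudes are uncapped; no nutrient's contribution is
  truncated.
* Fatty-acid closure tolerates 5% relative slack over total fat
  (glycerol backbone and table rounding).
* Dose-response RRs must be positive; a protective factor with RR > 1
  per positive increment warns but loads (the table may be intentionally
  contrarian in a sensitivity).
* Zero benchmark footprints, zero baseline domain totals, zero-energy
  foods on a calorie basis, empty reference tables, and all-zero exposure
  deltas are errors, not NaNs.
* Presentation rounding is half-away-from-zero; machine output is full
  precision.
* Test and acceptance runs use the full 30-food roster, 38-scenario
  matrix, and 20 random known-answer vectors; these sizes were chosen as
  comfortably representative for a per-region analysis of this kind.

# Limitations

Population-average intakes are compared with average requirements; there
is no distributional adequacy modelling, no age/sex stratification of
relative risks, and no uncertainty propagation of RR confidence intervals.
Footprints are inputs, not computed LCAs, and carry their sources'
harmonization limits. The packaged recommendation, RR, and iron-model
tables are illustrative defaults intended to be replaced for substantive
work; published food-level results are reproducible only with the original
deposited tables, which users can stage for the optional integration
tests (see `find_replication_data()`).
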