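ENV_DOMAINS <- c("ghg", "land", "water")

env_cols_100g <- c(ghg = "ghg_kg_per_100g", land = "land_m2_per_100g",
                   water = "water_l_per_100g")

# Per-100g footprint vector for one food row, optionally with the
# processing (e.g. cooking) GHG add-on.
footprint_100g <- function(food, include_processing = FALSE) {
  fp <- setNames(vapply(env_cols_100g, function(cl) food[[cl]], numeric(1)),
                 ENV_DOMAINS)
  if (include_processing)
    fp[["ghg"]] <- fp[["ghg"]] + food$ghg_processing_kg_per_100g
  fp
}

#' Footprint of a food on a chosen basis
#'
#' Converts per-mass footprints to the comparison basis: per serving
#' (`per_kg * serving_g / 1000`), per calorie (`per_kg / kcal_per_kg`,
#' i.e. per kcal), or per kg (`"weight"`).
#'
#' @param food Single-row food table.
#' @param basis `"serving"`, `"calorie"`, or `"weight"`.
#' @param include_processing Add the processing GHG increment (sensitivity
#'   for cooking emissions on flagged unprocessed foods).
#' @return Named numeric `c(ghg=, land=, water=)` on the requested basis.
#' @export
footprint_per_basis <- function(food, basis = c("serving", "calorie", "weight"),
                                include_processing = FALSE) {
  basis <- match.arg(basis)
  fp100 <- footprint_100g(food, include_processing)
  switch(basis,
    weight = fp100 * 10,
    serving = fp100 * food$serving_g / 100,
    calorie = {
      if (food$energy_kcal <= 0)
        abort_table("food '%s' has zero energy density: calorie basis undefined",
                    food$id)
      fp100 / food$energy_kcal
    })
}

#' Benchmark-relative environmental impact of a food
#'
#' Expresses each footprint domain as a percent of a high-impact benchmark
#' food (beef for meats, milk for dairy) on a common basis, and folds the
#' three domains into one score with the planetary-boundary environment
#' weights. The benchmark scores exactly 100% in every domain and overall.
#'
#' @param food,benchmark Single-row food tables on the same basis.
#' @param basis Comparison basis, see [footprint_per_basis()].
#' @param weights A [synthesis_weights()] object (its environment level is
#'   used).
#' @param include_processing Passed to [footprint_per_basis()] for `food`.
#' @return List of class `relative_impact`: `food_id`, `benchmark_id`,
#'   `basis`, `per_domain_pct` (named ghg/land/water), `weighted_pct`.
#' @export
relative_impact <- function(food, benchmark,
                            basis = c("serving", "calorie", "weight"),
                            weights = synthesis_weights(),
                            include_processing = FALSE) {
  basis <- match.arg(basis)
  fp <- footprint_per_basis(food, basis, include_processing)
  bm <- footprint_per_basis(benchmark, basis)
  if (any(bm <= 0))
    abort_table("benchmark '%s' has a zero footprint in domain(s): %s",
                benchmark$id, paste(ENV_DOMAINS[bm <= 0], collapse = ", "))
  pct <- 100 * fp / bm
  w <- weights$environment[ENV_DOMAINS]
  structure(list(
    food_id = food$id, benchmark_id = benchmark$id, basis = basis,
    per_domain_pct = pct,
    weighted_pct = sum(w * pct)
  ), class = "relative_impact")
}

#' Benchmark food for a replaced category
#'
#' The meat benchmark is beef (the highest-impact meat); the dairy
#' benchmark is a virtual food whose footprints are the mean of whole and
#' low-fat milk. Both are configurable by id.
#'
#' @param foods A `food_table`.
#' @param category `"meat"` or `"dairy"`.
#' @param ids Benchmark food id(s); footprints are averaged when more than
#'   one id is given.
#' @return A single-row food table (averaged footprints when needed).
#' @export
benchmark_food <- function(foods, category = c("meat", "dairy"),
                           ids = NULL) {
  category <- match.arg(category)
  if (is.null(ids)) {
    ids <- if (category == "meat") "beef" else
      intersect(c("whole_milk", "lowfat_milk"), foods$id)
    if (length(ids) == 0)
      abort_table("no default benchmark food present for category '%s'",
                  category)
  }
  rows <- lookup_food(foods, ids)
  out <- rows[1, , drop = FALSE]
  if (nrow(rows) > 1) {
    for (cl in c(env_cols_100g, "ghg_processing_kg_per_100g", "serving_g",
                 "energy_kcal"))
      out[[cl]] <- mean(rows[[cl]])
    out$id <- paste(ids, collapse = "+")
  }
  out
}

#' Absolute environmental totals of a diet
#'
#' `total_d = sum_f grams_f / 1000 * footprint_d(f)` per person per day
#' (kg CO2eq, m2, L). Totals are linear in intake.
#'
#' @inheritParams nutrient_intake
#' @param include_processing Include per-food processing GHG add-ons.
#' @return Named numeric `c(ghg=, land=, water=)`.
#' @export
diet_environmental_totals <- function(diet, foods,
                                      include_processing = FALSE) {
  if (nrow(diet) == 0) return(setNames(rep(0, 3), ENV_DOMAINS))
  rows <- lookup_food(foods, diet$food_id)
  fp <- vapply(seq_len(nrow(rows)), function(i)
    footprint_100g(rows[i, ], include_processing), numeric(3))
  setNames(as.numeric(fp %*% (diet$intake_g_day / 100)), ENV_DOMAINS)
}

#' Environmental change of a replacement diet
#'
#' Per-domain percentage change of scenario totals against baseline totals
#' plus the planetary-boundary-weighted average change.
#'
#' @param baseline_totals,scenario_totals Named totals from
#'   [diet_environmental_totals()]; baseline must be positive per domain.
#' @param weights A [synthesis_weights()] object.
#' @return List: `per_domain_pct` (named ghg/land/water, signed),
#'   `weighted_pct`.
#' @export
replacement_environment_change <- function(baseline_totals, scenario_totals,
                                           weights = synthesis_weights()) {
  b <- baseline_totals[ENV_DOMAINS]
  s <- scenario_totals[ENV_DOMAINS]
  if (any(!is.finite(b)) || any(b <= 0))
    abort_table("baseline environmental totals must be > 0 in every domain")
  pct <- 100 * (s - b) / b
  w <- weights$environment[ENV_DOMAINS]
  list(per_domain_pct = pct, weighted_pct = sum(w * pct))
}

#' Round half away from zero
#'
#' Presentation rounding for reported percentages (so 9.88 prints as 10 and
#' -14.5 as -15); machine outputs keep full precision.
#'
#' @param x Numeric.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10 ^ digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' @export
print.relative_impact <- function(x, ...) {
  cat(sprintf(
    "%s vs %s (%s basis): GHG %.0f%%, land %.0f%%, water %.0f%% -> weighted %.0f%%\n",
    x$food_id, x$benchmark_id, x$basis,
    round_half_away(x$per_domain_pct[["ghg"]]),
    round_half_away(x$per_domain_pct[["land"]]),
    round_half_away(x$per_domain_pct[["water"]]),
    round_half_away(x$weighted_pct)))
  invisible(x)
}
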