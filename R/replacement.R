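#' Define a replacement scenario
#'
#' One scenario replaces all of a category's intake (all meat, all dairy,
#' or both) with one alternative food per replaced category, on a calorie
#' or serving basis, optionally with sensitivity switches: extra sodium on
#' the alternative, processing (cooking) emissions, or an overridden
#' potassium cap.
#'
#' @param id Scenario id.
#' @param region Region whose baseline diet is modified.
#' @param replace `"meat"`, `"dairy"`, or `"both"`.
#' @param with Alternative food id; for `"both"` a named list/vector
#'   `c(meat = ..., dairy = ...)`.
#' @param basis `"calorie"` (energy-conserving) or `"serving"`
#'   (serving-count-conserving; energy not necessarily conserved).
#' @param sodium_addon_mg_per_100g Extra sodium added to the alternative's
#'   exposure, mg per 100 g of alternative consumed.
#' @param processing_emissions Include per-food processing GHG add-ons in
#'   the environmental accounting.
#' @param potassium_cap Override for the potassium exposure cap (mg/day);
#'   `NULL` keeps the default.
#' @param comparator Allow the alternative to belong to the replaced
#'   category itself. By default this is an error (it usually signals a
#'   mis-specified scenario), but comparator runs -- replacing all meat
#'   with only poultry, or scoring beef within the meat pool -- are part of
#'   the assessment design and require it.
#' @return A list of class `replacement_scenario`.
#' @export
replacement_scenario <- function(id, region = "HIC",
                                 replace = c("meat", "dairy", "both"),
                                 with, basis = c("calorie", "serving"),
                                 sodium_addon_mg_per_100g = 0,
                                 processing_emissions = FALSE,
                                 potassium_cap = NULL,
                                 comparator = FALSE) {
  replace <- match.arg(replace)
  basis <- match.arg(basis)
  with <- unlist(with)
  if (replace == "both") {
    if (is.null(names(with)) || !setequal(names(with), c("meat", "dairy")))
      abort_table("scenario '%s': 'both' needs alternatives named meat and dairy",
                  id)
    with <- with[c("meat", "dairy")]
  } else {
    if (length(with) != 1)
      abort_table("scenario '%s': exactly one alternative food expected", id)
    with <- setNames(with, replace)
  }
  structure(list(
    id = id, region = region, replace = replace, with = with, basis = basis,
    sodium_addon_mg_per_100g = sodium_addon_mg_per_100g,
    processing_emissions = isTRUE(processing_emissions),
    potassium_cap = potassium_cap,
    comparator = isTRUE(comparator)
  ), class = "replacement_scenario")
}

diet_energy_kcal <- function(diet, foods) {
  unname(nutrient_intake(diet, foods)[["energy_kcal"]])
}

#' Build a replacement diet
#'
#' Removes all intake of the replaced category (or categories) from the
#' baseline diet and adds the alternative food. On the calorie basis the
#' alternative supplies exactly the calories removed (pooled across the
#' replaced category), so total diet energy is conserved; this is asserted
#' to 1e-6 relative. On the serving basis the alternative supplies as many
#' servings as were removed; energy is generally not conserved.
#'
#' @param baseline Single-region `diet_table`.
#' @param scenario A [replacement_scenario()].
#' @param foods A `food_table`.
#' @return The scenario `diet_table`; replaced-category intake is exactly
#'   zero. Attribute `alternative_grams` records the grams of each
#'   alternative added.
#' @export
build_replacement_diet <- function(baseline, scenario, foods) {
  stopifnot(inherits(scenario, "replacement_scenario"))
  diet <- tibble::as_tibble(baseline)
  cats <- names(scenario$with)
  added <- numeric(0)
  for (cat in cats) {
    alt_id <- scenario$with[[cat]]
    alt <- lookup_food(foods, alt_id)
    if (alt$category == cat && !scenario$comparator)
      abort_table("scenario '%s': alternative '%s' is itself in the replaced category '%s' (set comparator = TRUE for a within-category comparator run)",
                  scenario$id, alt_id, cat)
    cat_foods <- foods$id[foods$category == cat]
    rows <- diet$food_id %in% cat_foods & diet$intake_g_day > 0
    if (!any(rows))
      abort_table("scenario '%s': baseline diet has no positive intake of category '%s'",
                  scenario$id, cat)
    replaced <- lookup_food(foods, diet$food_id[rows])
    grams <- diet$intake_g_day[rows]
    alt_grams <- if (scenario$basis == "calorie") {
      removed_kcal <- sum(grams / 100 * replaced$energy_kcal)
      if (alt$energy_kcal <= 0)
        abort_table("scenario '%s': alternative '%s' has zero energy density on calorie basis",
                    scenario$id, alt_id)
      removed_kcal / (alt$energy_kcal / 100)
    } else {
      servings <- sum(grams / replaced$serving_g)
      servings * alt$serving_g
    }
    diet$intake_g_day[diet$food_id %in% cat_foods] <- 0
    if (alt_id %in% diet$food_id) {
      diet$intake_g_day[diet$food_id == alt_id] <-
        diet$intake_g_day[diet$food_id == alt_id] + alt_grams
    } else {
      diet <- dplyr::bind_rows(diet, tibble::tibble(
        region = diet$region[1], food_id = alt_id,
        intake_g_day = alt_grams,
        waste_adjusted = diet$waste_adjusted[1]))
    }
    added[alt_id] <- alt_grams
  }
  out <- diet_table(diet, foods = foods)
  if (scenario$basis == "calorie") {
    e0 <- diet_energy_kcal(diet_table(tibble::as_tibble(baseline)), foods)
    e1 <- diet_energy_kcal(out, foods)
    if (abs(e1 - e0) > 1e-6 * max(e0, 1))
      abort_table("scenario '%s': calorie accounting failed (%.6f vs %.6f kcal)",
                  scenario$id, e0, e1)
  }
  attr(out, "alternative_grams") <- added
  out
}

scenario_risk_factors <- function(bundle, scenario) {
  rf <- bundle$risk_factors
  if (!is.null(scenario$potassium_cap))
    rf$cap[rf$factor == "potassium_mg"] <- scenario$potassium_cap
  rf
}

#' Run one replacement scenario through all four analyses
#'
#' Builds the replacement diet and evaluates, against the region's baseline
#' diet: the change in the nutritional imbalance indicator (percentage
#' points, with zinc/iron requirements re-resolved per diet), the all-cause
#' mortality change from the comparative risk assessment (percent,
#' negative = deaths averted), the per-domain and weighted environmental
#' changes, and the diet cost change. All outputs are deterministic given
#' the bundle.
#'
#' @param scenario A [replacement_scenario()].
#' @param bundle A [swap_bundle()].
#' @param verbose Print the scenario's energy accounting.
#' @param prices Optional precomputed [harmonize_prices()] table for the
#'   bundle's foods; computed on the fly when `NULL`.
#' @return List of class `scenario_result`: `domain_changes` (tidy tibble
#'   `scenario_id`, `food_id`, `replaced`, `basis`, `region`, `domain`,
#'   `value` over domains `nutrition_pp`, `mortality_pct`, `ghg_pct`,
#'   `land_pct`, `water_pct`, `cost_pct`) plus `details` (imbalance
#'   results, PIFs, deaths averted, environmental and cost levels).
#' @export
run_scenario <- function(scenario, bundle, verbose = FALSE, prices = NULL) {
  stopifnot(inherits(scenario, "replacement_scenario"),
            inherits(bundle, "swap_bundle"))
  foods <- bundle$foods
  baseline <- diet_for_region(bundle$diets, scenario$region)
  scen_diet <- build_replacement_diet(baseline, scenario, foods)
  rf <- scenario_risk_factors(bundle, scenario)

  # nutrition: handler-adjusted requirements are diet-dependent, so each
  # diet resolves its own recommendation set
  imb_base <- diet_imbalance(baseline, foods, bundle$recommendations,
                             bundle$zinc_reference, bundle$iron_model)
  imb_scen <- diet_imbalance(scen_diet, foods, bundle$recommendations,
                             bundle$zinc_reference, bundle$iron_model)

  # health: sodium add-on applies to the grams of alternative consumed
  added <- attr(scen_diet, "alternative_grams")
  sodium_addon <- scenario$sodium_addon_mg_per_100g * sum(added) / 100
  exp_base <- exposure_from_diet(baseline, foods, rf)
  exp_scen <- exposure_from_diet(scen_diet, foods, rf,
                                 sodium_addon_mg = sodium_addon)
  endpoints <- intersect(ENDPOINTS, unique(bundle$rr_table$endpoint))
  pifs <- setNames(vapply(endpoints, function(e)
    pif(exp_base, exp_scen, bundle$rr_table, e, rf), numeric(1)), endpoints)
  mort_row <- bundle$mortality[bundle$mortality$region == scenario$region, ]
  if (nrow(mort_row) != 1)
    abort_table("scenario '%s': no mortality row for region '%s'",
                scenario$id, scenario$region)
  deaths <- attributable_deaths(pifs, mort_row)

  env_base <- diet_environmental_totals(baseline, foods,
                                        scenario$processing_emissions)
  env_scen <- diet_environmental_totals(scen_diet, foods,
                                        scenario$processing_emissions)
  env <- replacement_environment_change(env_base, env_scen, bundle$weights)

  if (is.null(prices))
    prices <- harmonize_prices(foods, bundle$cpi, bundle$ppp)
  cost_base <- diet_cost(baseline, prices)
  cost_scen <- diet_cost(scen_diet, prices)
  cost_pct <- replacement_cost_change(cost_base, cost_scen)

  if (verbose)
    message(sprintf(
      "[%s] %s -> %s (%s basis): %.0f kcal baseline, %.0f kcal scenario",
      scenario$id, scenario$replace, paste(scenario$with, collapse = "+"),
      scenario$basis,
      diet_energy_kcal(baseline, foods), diet_energy_kcal(scen_diet, foods)))

  values <- c(
    nutrition_pp = imb_scen$indicator - imb_base$indicator,
    mortality_pct = deaths$mortality_change_pct,
    ghg_pct = unname(env$per_domain_pct[["ghg"]]),
    land_pct = unname(env$per_domain_pct[["land"]]),
    water_pct = unname(env$per_domain_pct[["water"]]),
    cost_pct = cost_pct
  )
  structure(list(
    domain_changes = tibble::tibble(
      scenario_id = scenario$id,
      food_id = paste(scenario$with, collapse = "+"),
      replaced = scenario$replace, basis = scenario$basis,
      region = scenario$region,
      domain = names(values), value = as.numeric(values)),
    details = list(
      imbalance_baseline = imb_base, imbalance_scenario = imb_scen,
      pifs = pifs, deaths = deaths,
      env_baseline = env_base, env_scenario = env_scen,
      env_weighted_pct = env$weighted_pct,
      cost_baseline = cost_base, cost_scenario = cost_scen,
      scenario_diet = scen_diet)
  ), class = "scenario_result")
}

#' Run a list of scenarios
#'
#' @param scenarios List of [replacement_scenario()] objects (for example
#'   from a [load_config()] result).
#' @param bundle A [swap_bundle()].
#' @param verbose Print per-scenario energy accounting.
#' @return Tidy tibble of all scenarios' domain changes (see
#'   [run_scenario()]).
#' @export
run_scenarios <- function(scenarios, bundle, verbose = FALSE) {
  prices <- harmonize_prices(bundle$foods, bundle$cpi, bundle$ppp)
  dplyr::bind_rows(lapply(scenarios, function(s)
    run_scenario(s, bundle, verbose = verbose,
                 prices = prices)$domain_changes))
}

#' Default scenario matrix for a bundle
#'
#' One scenario per candidate replacement food and replaced category:
#' every alternative-category food with positive energy density, plus the
#' animal comparators themselves (meat products for the meat pool, milks
#' for the dairy pool, as within-category comparator runs), so the
#' synthesis normalization pool contains both the candidate alternatives
#' and the animal products they are judged against.
#'
#' @param bundle A [swap_bundle()].
#' @param region Region id.
#' @param basis `"calorie"` or `"serving"`.
#' @param categories Food categories eligible as alternatives.
#' @return List of [replacement_scenario()] objects.
#' @export
default_scenarios <- function(bundle, region = "HIC", basis = "calorie",
                              categories = c("meat", "dairy",
                                             "processed_alternative",
                                             "unprocessed_alternative")) {
  foods <- bundle$foods
  cand <- foods[foods$category %in% categories & foods$energy_kcal > 0, ]
  out <- list()
  for (replaced in c("meat", "dairy")) {
    for (i in seq_len(nrow(cand))) {
      same_cat <- cand$category[i] == replaced
      other_animal <- cand$category[i] %in% c("meat", "dairy") && !same_cat
      if (other_animal) next  # milk is not a meat candidate and vice versa
      id <- sprintf("%s_to_%s_%s", replaced, cand$id[i], basis)
      out[[id]] <- replacement_scenario(
        id = id, region = region, replace = replaced, with = cand$id[i],
        basis = basis, comparator = same_cat)
    }
  }
  out
}
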