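#' Specification for the synthetic input generator
#'
#' Controls the seeded generator that emits a complete, internally
#' consistent input bundle (foods, diets, recommendations, relative risks,
#' footprints, prices, mortality, CPI/PPP). Defaults encode the structure
#' the assessment assumes: animal-source foods elevated in saturated fat,
#' heme iron, cholesterol, and sodium; legumes, nuts, and whole grains
#' elevated in fiber, potassium, and PUFAs; processed alternatives
#' fortified (vitamin B12, riboflavin, vitamin A) and priced above their
#' unprocessed ingredients; and a footprint hierarchy with beef far above
#' pork and poultry, which sit far above plant foods.
#'
#' @param seed Integer seed; identical specs produce identical bundles.
#' @param regions Character vector of region ids to emit diets for.
#' @param foods_per_category Optional named integer vector limiting how
#'   many foods of each category to keep (first n of the roster).
#' @param animal_elevation Multipliers on saturated fat, heme iron,
#'   cholesterol, and sodium of meat and dairy foods.
#' @param plant_elevation Multipliers on fiber, potassium, and PUFA of the
#'   plant-based alternatives.
#' @param fortification Add fortificant nutrients to processed
#'   alternatives.
#' @param footprint_ratio Named GHG ratio `c(beef=, pork=, poultry=,
#'   plant=)` relative to the plant tier.
#' @param price_markup Multiplier on processed-alternative prices relative
#'   to their template (ingredient-level) prices.
#' @param baseline_shares Calorie shares of meat and dairy in the baseline
#'   diet.
#' @param energy_target_kcal Total baseline diet energy (kcal/person/day).
#' @param noise_sd Standard deviation of the per-food lognormal noise
#'   factor. One factor multiplies all of a food's nutrients, so
#'   composition invariants (fatty-acid closure, heme within total iron)
#'   survive any noise level; independent noise of the same spread is
#'   applied to footprints and prices.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L,
                           regions = "HIC",
                           foods_per_category = NULL,
                           animal_elevation = c(satfat = 1, heme_iron = 1,
                                                cholesterol = 1, sodium = 1),
                           plant_elevation = c(fiber = 1, potassium = 1,
                                               pufa = 1),
                           fortification = TRUE,
                           footprint_ratio = c(beef = 60, pork = 7,
                                               poultry = 6, plant = 1),
                           price_markup = 1.6,
                           baseline_shares = c(meat = 0.15, dairy = 0.08),
                           energy_target_kcal = 2260,
                           noise_sd = 0.05) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (any(footprint_ratio <= 0)) abort_table("footprint ratios must be > 0")
  if (sum(baseline_shares) >= 1)
    abort_table("meat and dairy calorie shares must sum to < 1")
  structure(list(
    seed = as.integer(seed), regions = regions,
    foods_per_category = foods_per_category,
    animal_elevation = animal_elevation,
    plant_elevation = plant_elevation,
    fortification = isTRUE(fortification),
    footprint_ratio = footprint_ratio,
    price_markup = price_markup,
    baseline_shares = baseline_shares,
    energy_target_kcal = energy_target_kcal,
    noise_sd = noise_sd
  ), class = "generator_spec")
}

# Generic per-100g profile for a category; distinguishing nutrients are
# overridden per food in food_roster().
category_profile <- function(category) {
  base <- setNames(rep(0, length(nutrient_ids())), nutrient_ids())
  common <- switch(category,
    meat = c(energy_kcal = 220, protein_g = 25, fat_g = 13, satfat_g = 5,
             mufa_g = 5.5, pufa_g = 1, transfat_g = 0.3, cholesterol_mg = 80,
             iron_mg = 2, heme_iron_mg = 1.2, sodium_mg = 75,
             potassium_mg = 320, zinc_mg = 4.5, calcium_mg = 15,
             magnesium_mg = 22, phosphorus_mg = 200, copper_mg = 0.08,
             thiamine_mg = 0.07, riboflavin_mg = 0.18, niacin_mg = 5,
             pantothenate_mg = 0.6, vitamin_b6_mg = 0.4, folate_ug = 8,
             vitamin_b12_ug = 2.2, vitamin_a_ug = 5),
    dairy = c(energy_kcal = 61, protein_g = 3.2, fat_g = 3.3, satfat_g = 1.9,
              mufa_g = 0.8, pufa_g = 0.2, transfat_g = 0.1,
              cholesterol_mg = 10, carbohydrate_g = 4.8, sugar_g = 5,
              iron_mg = 0.03, sodium_mg = 44, potassium_mg = 140,
              zinc_mg = 0.4, calcium_mg = 120, magnesium_mg = 11,
              phosphorus_mg = 95, copper_mg = 0.01, thiamine_mg = 0.04,
              riboflavin_mg = 0.17, niacin_mg = 0.1, pantothenate_mg = 0.37,
              vitamin_b6_mg = 0.04, folate_ug = 5, vitamin_b12_ug = 0.5,
              vitamin_a_ug = 46),
    processed_alternative = c(energy_kcal = 160, protein_g = 14, fat_g = 7,
                              satfat_g = 1, mufa_g = 2, pufa_g = 3.2,
                              carbohydrate_g = 8, sugar_g = 1, fiber_g = 4,
                              iron_mg = 2.2, sodium_mg = 350,
                              potassium_mg = 300, zinc_mg = 1.2,
                              phytate_mg = 250, calcium_mg = 80,
                              magnesium_mg = 55, phosphorus_mg = 180,
                              copper_mg = 0.3, thiamine_mg = 0.12,
                              riboflavin_mg = 0.1, niacin_mg = 1.5,
                              pantothenate_mg = 0.4, vitamin_b6_mg = 0.15,
                              folate_ug = 50, vitamin_a_ug = 2),
    unprocessed_alternative = c(energy_kcal = 140, protein_g = 9, fat_g = 3,
                                satfat_g = 0.4, mufa_g = 0.8, pufa_g = 1.4,
                                carbohydrate_g = 20, sugar_g = 2,
                                fiber_g = 7, iron_mg = 2.5, sodium_mg = 5,
                                potassium_mg = 450, zinc_mg = 1.3,
                                phytate_mg = 450, calcium_mg = 60,
                                magnesium_mg = 70, phosphorus_mg = 180,
                                copper_mg = 0.35, thiamine_mg = 0.2,
                                riboflavin_mg = 0.1, niacin_mg = 1.2,
                                pantothenate_mg = 0.5, vitamin_b6_mg = 0.2,
                                folate_ug = 120, vitamin_c_mg = 1.5,
                                vitamin_a_ug = 1),
    other_diet_component = c(energy_kcal = 120, protein_g = 4, fat_g = 2,
                             satfat_g = 0.5, mufa_g = 0.7, pufa_g = 0.6,
                             carbohydrate_g = 22, sugar_g = 4, fiber_g = 2,
                             iron_mg = 1, sodium_mg = 120,
                             potassium_mg = 180, zinc_mg = 0.7,
                             phytate_mg = 80, calcium_mg = 30,
                             magnesium_mg = 25, phosphorus_mg = 90,
                             copper_mg = 0.1, thiamine_mg = 0.1,
                             riboflavin_mg = 0.08, niacin_mg = 1.2,
                             pantothenate_mg = 0.3, vitamin_b6_mg = 0.1,
                             folate_ug = 30, vitamin_c_mg = 5,
                             vitamin_a_ug = 15))
  base[names(common)] <- common
  base
}

# Roster of template foods: category, serving size, footprint tier, per-kg
# footprints, price observation, processing GHG add-on (cooking-emissions
# sensitivity on unprocessed foods), and overrides of the distinguishing
# nutrients per 100 g.
food_roster <- function() {
  list(
    beef = list(category = "meat", serving_g = 110, tier = "beef",
      fp = c(60, 160, 1450), price = c(11, 2020), currency = "USD",
      over = c(energy_kcal = 250, fat_g = 17, satfat_g = 7, mufa_g = 7.5,
               pufa_g = 0.6, cholesterol_mg = 88, iron_mg = 2.6,
               heme_iron_mg = 1.8, zinc_mg = 6.2, sodium_mg = 66,
               vitamin_b12_ug = 2.6)),
    beef_burger = list(category = "meat", serving_g = 110, tier = "beef",
      fp = c(54, 144, 1310), price = c(9.5, 2020), currency = "USD",
      over = c(energy_kcal = 260, fat_g = 18, satfat_g = 7.2, mufa_g = 7.8,
               pufa_g = 0.7, cholesterol_mg = 85, iron_mg = 2.5,
               heme_iron_mg = 1.7, zinc_mg = 5.8, sodium_mg = 330,
               vitamin_b12_ug = 2.4)),
    pork = list(category = "meat", serving_g = 110, tier = "pork",
      fp = c(7.2, 11, 590), price = c(8, 2020), currency = "USD",
      over = c(energy_kcal = 240, fat_g = 14, satfat_g = 5, mufa_g = 6.2,
               pufa_g = 1.5, cholesterol_mg = 80, iron_mg = 0.9,
               heme_iron_mg = 0.4, zinc_mg = 2.4, sodium_mg = 62,
               riboflavin_mg = 0.3, thiamine_mg = 0.6, vitamin_b12_ug = 0.7)),
    pork_sausages = list(category = "meat", serving_g = 75, tier = "pork",
      fp = c(7.8, 12, 620), price = c(7.5, 2020), currency = "USD",
      over = c(energy_kcal = 300, fat_g = 26, satfat_g = 9, mufa_g = 12,
               pufa_g = 3.2, cholesterol_mg = 72, iron_mg = 1.1,
               heme_iron_mg = 0.5, zinc_mg = 2.0, sodium_mg = 750,
               vitamin_b12_ug = 1.0)),
    pork_bacon = list(category = "meat", serving_g = 35, tier = "pork",
      fp = c(8.1, 12.5, 640), price = c(9, 2020), currency = "USD",
      over = c(energy_kcal = 420, fat_g = 38, satfat_g = 13, mufa_g = 17,
               pufa_g = 4.5, cholesterol_mg = 95, iron_mg = 1.2,
               heme_iron_mg = 0.5, zinc_mg = 2.6, sodium_mg = 1700,
               vitamin_b12_ug = 1.1)),
    poultry = list(category = "meat", serving_g = 110, tier = "poultry",
      fp = c(6.1, 7.5, 480), price = c(6.5, 2020), currency = "USD",
      over = c(energy_kcal = 190, fat_g = 7.5, satfat_g = 2.1, mufa_g = 2.7,
               pufa_g = 1.6, cholesterol_mg = 89, iron_mg = 1.0,
               heme_iron_mg = 0.3, zinc_mg = 1.9, sodium_mg = 82,
               niacin_mg = 9, vitamin_b12_ug = 0.3)),
    whole_milk = list(category = "dairy", serving_g = 240, tier = "none",
      fp = c(3.2, 9.0, 630), price = c(1.1, 2020), currency = "USD",
      over = c()),
    lowfat_milk = list(category = "dairy", serving_g = 240, tier = "none",
      fp = c(2.6, 7.4, 560), price = c(1.0, 2020), currency = "USD",
      over = c(energy_kcal = 42, fat_g = 1.0, satfat_g = 0.6, mufa_g = 0.25,
               pufa_g = 0.05, transfat_g = 0.03, cholesterol_mg = 5,
               vitamin_a_ug = 14)),
    veggie_burger = list(category = "processed_alternative",
      serving_g = 110, tier = "plant",
      fp = c(3.1, 3.0, 160), price = c(12.5, 2020), currency = "USD",
      over = c(energy_kcal = 180, protein_g = 18, fat_g = 9, satfat_g = 1.6,
               mufa_g = 2.4, pufa_g = 4.2, fiber_g = 5, iron_mg = 3.2,
               sodium_mg = 390, zinc_mg = 1.5)),
    veggie_sausage = list(category = "processed_alternative",
      serving_g = 75, tier = "plant",
      fp = c(2.3, 2.1, 120), price = c(10.5, 2020), currency = "USD",
      over = c(energy_kcal = 170, protein_g = 16, fat_g = 8, satfat_g = 1.2,
               mufa_g = 2.2, pufa_g = 3.8, fiber_g = 4.5, iron_mg = 2.6,
               sodium_mg = 560)),
    veggie_bacon = list(category = "processed_alternative",
      serving_g = 35, tier = "plant",
      fp = c(2.5, 2.3, 130), price = c(14, 2019), currency = "GBP",
      over = c(energy_kcal = 210, protein_g = 20, fat_g = 10, satfat_g = 1.4,
               mufa_g = 2.8, pufa_g = 4.6, fiber_g = 3.5, iron_mg = 2.4,
               sodium_mg = 1150)),
    tofu = list(category = "processed_alternative", serving_g = 85,
      tier = "plant",
      fp = c(3.0, 2.2, 150), price = c(5.5, 2020), currency = "USD",
      over = c(energy_kcal = 95, protein_g = 10, fat_g = 5.3, satfat_g = 0.8,
               mufa_g = 1.2, pufa_g = 3.0, fiber_g = 1.2, iron_mg = 2.7,
               sodium_mg = 9, calcium_mg = 200, phytate_mg = 300,
               zinc_mg = 1.0)),
    tempeh = list(category = "processed_alternative", serving_g = 85,
      tier = "plant",
      fp = c(3.3, 2.6, 170), price = c(7.5, 2018), currency = "GBP",
      over = c(energy_kcal = 190, protein_g = 19, fat_g = 11, satfat_g = 2.2,
               mufa_g = 3.0, pufa_g = 4.3, fiber_g = 6, iron_mg = 2.7,
               sodium_mg = 9, phytate_mg = 400, zinc_mg = 1.1,
               riboflavin_mg = 0.36)),
    soy_milk = list(category = "processed_alternative", serving_g = 240,
      tier = "plant",
      fp = c(1.0, 0.7, 30), price = c(1.9, 2020), currency = "USD",
      over = c(energy_kcal = 43, protein_g = 3.0, fat_g = 1.8, satfat_g = 0.2,
               mufa_g = 0.4, pufa_g = 1.0, carbohydrate_g = 2.5,
               sugar_g = 2, fiber_g = 0.5, iron_mg = 0.5, sodium_mg = 40,
               potassium_mg = 120, phytate_mg = 60, calcium_mg = 120,
               zinc_mg = 0.25)),
    oat_milk = list(category = "processed_alternative", serving_g = 240,
      tier = "plant",
      fp = c(0.9, 0.8, 45), price = c(2.0, 2020), currency = "USD",
      over = c(energy_kcal = 47, protein_g = 1.0, fat_g = 1.5, satfat_g = 0.2,
               mufa_g = 0.5, pufa_g = 0.6, carbohydrate_g = 7, sugar_g = 4,
               fiber_g = 0.8, iron_mg = 0.3, sodium_mg = 42,
               potassium_mg = 120, phytate_mg = 40, calcium_mg = 120,
               zinc_mg = 0.2)),
    almond_milk = list(category = "processed_alternative", serving_g = 240,
      tier = "plant",
      fp = c(0.7, 0.5, 180), price = c(2.0, 2020), currency = "USD",
      over = c(energy_kcal = 17, protein_g = 0.6, fat_g = 1.1, satfat_g = 0.1,
               mufa_g = 0.7, pufa_g = 0.25, carbohydrate_g = 1.4,
               sugar_g = 0.8, fiber_g = 0.3, iron_mg = 0.3, sodium_mg = 60,
               potassium_mg = 67, phytate_mg = 20, calcium_mg = 120,
               zinc_mg = 0.1, riboflavin_mg = 0.01)),
    rice_milk = list(category = "processed_alternative", serving_g = 240,
      tier = "plant",
      fp = c(1.2, 0.3, 270), price = c(2.2, 2020), currency = "USD",
      over = c(energy_kcal = 47, protein_g = 0.3, fat_g = 1.0, satfat_g = 0.1,
               mufa_g = 0.6, pufa_g = 0.3, carbohydrate_g = 9.2, sugar_g = 5,
               fiber_g = 0.3, iron_mg = 0.2, sodium_mg = 39,
               potassium_mg = 27, phytate_mg = 10, calcium_mg = 118,
               zinc_mg = 0.13, riboflavin_mg = 0.01)),
    soybeans = list(category = "unprocessed_alternative", serving_g = 45,
      tier = "plant", processing = 0.6,
      fp = c(0.9, 2.2, 39), price = c(3.2, 2020), currency = "USD",
      over = c(energy_kcal = 170, protein_g = 18, fat_g = 9, satfat_g = 1.3,
               mufa_g = 2.0, pufa_g = 5.1, carbohydrate_g = 10, fiber_g = 6,
               iron_mg = 5.1, sodium_mg = 1, potassium_mg = 520,
               zinc_mg = 1.2, phytate_mg = 600, riboflavin_mg = 0.29,
               folate_ug = 110)),
    peas = list(category = "unprocessed_alternative", serving_g = 45,
      tier = "plant", processing = 0.5,
      fp = c(0.8, 3.4, 35), price = c(2.4, 2020), currency = "USD",
      over = c(energy_kcal = 118, protein_g = 8.3, fat_g = 0.4,
               satfat_g = 0.05, mufa_g = 0.08, pufa_g = 0.17,
               carbohydrate_g = 21, fiber_g = 8.3, iron_mg = 1.3,
               sodium_mg = 2, potassium_mg = 360, zinc_mg = 1.0,
               phytate_mg = 380, folate_ug = 65)),
    beans = list(category = "unprocessed_alternative", serving_g = 45,
      tier = "plant", processing = 0.5,
      fp = c(1.0, 3.9, 44), price = c(2.5, 2020), currency = "USD",
      over = c(energy_kcal = 127, protein_g = 8.7, fat_g = 0.5,
               satfat_g = 0.07, mufa_g = 0.06, pufa_g = 0.23,
               carbohydrate_g = 22.8, fiber_g = 6.4, iron_mg = 2.9,
               sodium_mg = 1, potassium_mg = 405, zinc_mg = 1.0,
               phytate_mg = 420, folate_ug = 130)),
    almonds = list(category = "unprocessed_alternative", serving_g = 30,
      tier = "plant", processing = 0.2,
      fp = c(0.9, 2.9, 370), price = c(9.5, 2020), currency = "USD",
      over = c(energy_kcal = 579, protein_g = 21, fat_g = 50, satfat_g = 3.8,
               mufa_g = 31.5, pufa_g = 12.3, carbohydrate_g = 21.5,
               sugar_g = 4.3, fiber_g = 12.5, iron_mg = 3.7, sodium_mg = 1,
               potassium_mg = 733, zinc_mg = 3.1, phytate_mg = 1200,
               calcium_mg = 269, magnesium_mg = 270, riboflavin_mg = 1.1,
               vitamin_a_ug = 0)),
    oats = list(category = "unprocessed_alternative", serving_g = 40,
      tier = "plant", processing = 0.3,
      fp = c(1.0, 2.6, 180), price = c(1.8, 2020), currency = "USD",
      over = c(energy_kcal = 379, protein_g = 13.2, fat_g = 6.5,
               satfat_g = 1.1, mufa_g = 2.0, pufa_g = 2.4,
               carbohydrate_g = 67.7, sugar_g = 1, fiber_g = 10.1,
               iron_mg = 4.2, sodium_mg = 6, potassium_mg = 362,
               zinc_mg = 3.6, phytate_mg = 900, magnesium_mg = 138,
               thiamine_mg = 0.46)),
    rice = list(category = "unprocessed_alternative", serving_g = 45,
      tier = "plant", processing = 0.4,
      fp = c(3.6, 1.0, 650), price = c(1.6, 2020), currency = "USD",
      over = c(energy_kcal = 360, protein_g = 6.6, fat_g = 0.6,
               satfat_g = 0.16, mufa_g = 0.2, pufa_g = 0.16,
               carbohydrate_g = 79, sugar_g = 0.1, fiber_g = 1.3,
               iron_mg = 0.8, sodium_mg = 1, potassium_mg = 86,
               zinc_mg = 1.1, phytate_mg = 300, folate_ug = 9,
               vitamin_c_mg = 0)),
    refined_grains = list(category = "other_diet_component", serving_g = 60,
      tier = "plant",
      fp = c(1.4, 1.6, 450), price = c(1.5, 2020), currency = "USD",
      over = c(energy_kcal = 270, protein_g = 8, fat_g = 2, satfat_g = 0.4,
               mufa_g = 0.4, pufa_g = 0.8, carbohydrate_g = 53, sugar_g = 3,
               fiber_g = 2.5, iron_mg = 2.5, sodium_mg = 380,
               potassium_mg = 120, phytate_mg = 150)),
    vegetables = list(category = "other_diet_component", serving_g = 85,
      tier = "plant",
      fp = c(0.5, 0.4, 50), price = c(2.2, 2020), currency = "USD",
      over = c(energy_kcal = 35, protein_g = 1.8, fat_g = 0.3,
               satfat_g = 0.05, mufa_g = 0.02, pufa_g = 0.1,
               carbohydrate_g = 6.5, sugar_g = 3, fiber_g = 2.5,
               iron_mg = 0.8, sodium_mg = 30, potassium_mg = 260,
               zinc_mg = 0.3, phytate_mg = 30, vitamin_c_mg = 25,
               folate_ug = 45, vitamin_a_ug = 150)),
    fruits = list(category = "other_diet_component", serving_g = 120,
      tier = "plant",
      fp = c(0.6, 0.5, 110), price = c(2.0, 2020), currency = "USD",
      over = c(energy_kcal = 55, protein_g = 0.7, fat_g = 0.2,
               satfat_g = 0.04, mufa_g = 0.02, pufa_g = 0.06,
               carbohydrate_g = 13.5, sugar_g = 10.5, fiber_g = 2.2,
               iron_mg = 0.3, sodium_mg = 2, potassium_mg = 180,
               zinc_mg = 0.1, phytate_mg = 10, vitamin_c_mg = 30,
               folate_ug = 15, vitamin_a_ug = 25)),
    potatoes = list(category = "other_diet_component", serving_g = 110,
      tier = "plant",
      fp = c(0.5, 0.9, 60), price = c(1.1, 2020), currency = "USD",
      over = c(energy_kcal = 87, protein_g = 1.9, fat_g = 0.1,
               satfat_g = 0.03, mufa_g = 0.01, pufa_g = 0.04,
               carbohydrate_g = 20, sugar_g = 0.9, fiber_g = 1.8,
               iron_mg = 0.3, sodium_mg = 4, potassium_mg = 380,
               zinc_mg = 0.3, phytate_mg = 20, vitamin_c_mg = 13)),
    vegetable_oil = list(category = "other_diet_component", serving_g = 14,
      tier = "plant",
      fp = c(3.0, 5.0, 300), price = c(2.8, 2020), currency = "USD",
      over = c(energy_kcal = 884, protein_g = 0, fat_g = 100, satfat_g = 12,
               mufa_g = 40, pufa_g = 42, transfat_g = 0.5,
               carbohydrate_g = 0, sugar_g = 0, fiber_g = 0, iron_mg = 0,
               sodium_mg = 0, potassium_mg = 0, zinc_mg = 0, phytate_mg = 0,
               calcium_mg = 0, magnesium_mg = 0, phosphorus_mg = 0,
               copper_mg = 0, thiamine_mg = 0, riboflavin_mg = 0,
               niacin_mg = 0, pantothenate_mg = 0, vitamin_b6_mg = 0,
               folate_ug = 0, vitamin_c_mg = 0, vitamin_a_ug = 0)),
    sugar_sweets = list(category = "other_diet_component", serving_g = 30,
      tier = "plant",
      fp = c(1.8, 2.0, 200), price = c(3.5, 2020), currency = "USD",
      over = c(energy_kcal = 400, protein_g = 2, fat_g = 8, satfat_g = 4.5,
               mufa_g = 2.5, pufa_g = 0.5, carbohydrate_g = 78,
               sugar_g = 62, fiber_g = 1, iron_mg = 0.5, sodium_mg = 150,
               potassium_mg = 100, zinc_mg = 0.3, phytate_mg = 10)),
    animal_fats = list(category = "other_diet_component", serving_g = 14,
      tier = "beef",
      fp = c(9.0, 5.6, 700), price = c(8.5, 2020), currency = "USD",
      over = c(energy_kcal = 717, protein_g = 0.9, fat_g = 81, satfat_g = 51,
               mufa_g = 21, pufa_g = 3, transfat_g = 3.3,
               cholesterol_mg = 215, carbohydrate_g = 0.1, sugar_g = 0.1,
               fiber_g = 0, iron_mg = 0.02, heme_iron_mg = 0,
               sodium_mg = 11, potassium_mg = 24, zinc_mg = 0.09,
               phytate_mg = 0, calcium_mg = 24, magnesium_mg = 2,
               phosphorus_mg = 24, copper_mg = 0, thiamine_mg = 0,
               riboflavin_mg = 0.03, niacin_mg = 0.04,
               pantothenate_mg = 0.1, vitamin_b6_mg = 0, folate_ug = 3,
               vitamin_b12_ug = 0.2, vitamin_c_mg = 0, vitamin_a_ug = 684)),
    eggs = list(category = "other_diet_component", serving_g = 50,
      tier = "poultry",
      fp = c(4.2, 5.7, 580), price = c(3.2, 2020), currency = "USD",
      over = c(energy_kcal = 155, protein_g = 12.6, fat_g = 10.6,
               satfat_g = 3.3, mufa_g = 4.1, pufa_g = 1.4,
               carbohydrate_g = 1.1, sugar_g = 1.1, fiber_g = 0,
               cholesterol_mg = 373, iron_mg = 1.2, heme_iron_mg = 0,
               sodium_mg = 124, potassium_mg = 126, zinc_mg = 1.0,
               phytate_mg = 0, riboflavin_mg = 0.46, vitamin_b12_ug = 1.1,
               vitamin_a_ug = 149)))
}

GENERATOR_DEFAULT_RATIO <- c(beef = 60, pork = 7, poultry = 6, plant = 1)

# Template grams/day of each food in the pre-scaling baseline diet.
baseline_diet_template <- function() {
  c(beef = 40, beef_burger = 15, pork = 35, pork_sausages = 12,
    pork_bacon = 8, poultry = 70,
    whole_milk = 120, lowfat_milk = 130,
    refined_grains = 230, vegetables = 150, fruits = 120, potatoes = 130,
    vegetable_oil = 22, sugar_sweets = 45, animal_fats = 16, eggs = 25)
}

#' Generate a complete synthetic input bundle
#'
#' Builds every table an analysis run needs from the roster of template
#' foods, applying the spec's elevation factors, fortification,
#' footprint-ratio and price-markup knobs, and a single per-food lognormal
#' noise factor per random stream. The same spec always yields the same
#' bundle; sub-streams for foods, footprints, and prices are derived
#' deterministically from the one seed. The emitted bundle passes all
#' core-table validation, and two structural assertions are checked at
#' generation time: beef's GHG footprint strictly exceeds every
#' plant-based alternative's, and every meat's per-serving saturated fat
#' exceeds every legume's.
#'
#' @param spec A [generator_spec()].
#' @return A [swap_bundle()].
#' @export
generate_bundle <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  roster <- food_roster()
  if (!is.null(spec$foods_per_category)) {
    fpc <- as.list(spec$foods_per_category)
    keep <- unlist(lapply(names(roster), function(id) {
      cat <- roster[[id]]$category
      n <- fpc[[cat]] %||% Inf
      sum(vapply(roster[seq_len(match(id, names(roster)))], function(x)
        x$category == cat, logical(1))) <= n
    }))
    roster <- roster[keep]
    for (cat in c("meat", "dairy")) {
      if (!any(vapply(roster, function(x) x$category == cat, logical(1))))
        abort_table("degenerate spec: no foods left in required category '%s'",
                    cat)
    }
  }
  ids <- names(roster)
  n <- length(ids)

  # sub-streams: one seed, deterministic offsets per table
  set.seed(spec$seed)
  noise_food <- exp(rnorm(n, 0, spec$noise_sd))
  set.seed(spec$seed + 1L)
  noise_fp <- matrix(exp(rnorm(3 * n, 0, spec$noise_sd)), nrow = n)
  set.seed(spec$seed + 2L)
  noise_price <- exp(rnorm(n, 0, spec$noise_sd))

  rows <- lapply(seq_along(roster), function(i) {
    f <- roster[[i]]
    prof <- category_profile(f$category)
    prof[names(f$over)] <- f$over
    if (f$category %in% c("meat", "dairy")) {
      el <- spec$animal_elevation
      prof["satfat_g"] <- prof["satfat_g"] * el[["satfat"]]
      prof["heme_iron_mg"] <- prof["heme_iron_mg"] * el[["heme_iron"]]
      prof["cholesterol_mg"] <- prof["cholesterol_mg"] * el[["cholesterol"]]
      prof["sodium_mg"] <- prof["sodium_mg"] * el[["sodium"]]
    }
    if (f$category %in% c("processed_alternative",
                          "unprocessed_alternative")) {
      el <- spec$plant_elevation
      prof["fiber_g"] <- prof["fiber_g"] * el[["fiber"]]
      prof["potassium_mg"] <- prof["potassium_mg"] * el[["potassium"]]
      prof["pufa_g"] <- prof["pufa_g"] * el[["pufa"]]
    }
    prof <- prof * noise_food[i]
    if (spec$fortification && f$category == "processed_alternative") {
      prof["vitamin_b12_ug"] <- prof["vitamin_b12_ug"] + 1.0
      prof["riboflavin_mg"] <- prof["riboflavin_mg"] + 0.2
      prof["vitamin_a_ug"] <- prof["vitamin_a_ug"] + 80
    }
    # re-close composition invariants after elevation/fortification
    prof["iron_mg"] <- max(prof["iron_mg"], prof["heme_iron_mg"])
    fat_sum <- sum(prof[c("satfat_g", "mufa_g", "pufa_g", "transfat_g")])
    prof["fat_g"] <- max(prof["fat_g"], fat_sum)

    ratio_scale <- if (f$tier == "none") 1 else
      spec$footprint_ratio[[f$tier]] / GENERATOR_DEFAULT_RATIO[[f$tier]]
    fp <- f$fp * c(ratio_scale, 1, 1) * noise_fp[i, ]
    price <- f$price[1] * noise_price[i] *
      if (f$category == "processed_alternative")
        spec$price_markup / 1.6 else 1

    c(list(id = ids[i], name = gsub("_", " ", ids[i]),
           category = f$category, serving_g = f$serving_g,
           variant = NA_character_,
           ghg_kg_per_kg = unname(fp[1]), land_m2_per_kg = unname(fp[2]),
           water_l_per_kg = unname(fp[3]),
           ghg_processing_kg_per_kg = f$processing %||% 0,
           price = unname(price), currency = f$currency,
           year = f$price[2]),
      as.list(prof))
  })
  foods <- food_table(dplyr::bind_rows(lapply(rows, tibble::as_tibble)))

  # structural assertions forced by construction
  plant <- foods[foods$category %in% c("processed_alternative",
                                       "unprocessed_alternative"), ]
  if ("beef" %in% foods$id &&
      !all(foods$ghg_kg_per_100g[foods$id == "beef"] >
           plant$ghg_kg_per_100g))
    abort_table("generator postcondition failed: beef GHG must exceed plant GHG")
  meat <- foods[foods$category == "meat", ]
  legumes <- foods[foods$id %in% c("soybeans", "peas", "beans"), ]
  if (nrow(meat) > 0 && nrow(legumes) > 0 &&
      !(min(meat$satfat_g * meat$serving_g) >
          max(legumes$satfat_g * legumes$serving_g)))
    abort_table("generator postcondition failed: meat per-serving saturated fat must exceed legumes'")

  # baseline diets: scale food groups so calorie shares match the spec
  tmpl <- baseline_diet_template()
  tmpl <- tmpl[names(tmpl) %in% foods$id]
  prof <- lookup_food(foods, names(tmpl))
  kcal <- tmpl / 100 * prof$energy_kcal
  grp <- ifelse(prof$category == "meat", "meat",
                ifelse(prof$category == "dairy", "dairy", "other"))
  shares <- c(spec$baseline_shares,
              other = 1 - sum(spec$baseline_shares))
  scale_by_grp <- vapply(c("meat", "dairy", "other"), function(g)
    spec$energy_target_kcal * shares[[g]] / sum(kcal[grp == g]), numeric(1))
  intake <- tmpl * scale_by_grp[match(grp, c("meat", "dairy", "other"))]
  diets <- dplyr::bind_rows(lapply(spec$regions, function(r)
    tibble::tibble(region = r, food_id = names(tmpl),
                   intake_g_day = unname(intake), waste_adjusted = TRUE)))

  mortality <- tibble::tibble(
    region = spec$regions, population = 1e8,
    deaths_CHD = 150000, deaths_stroke = 80000, deaths_cancer = 250000,
    deaths_all = 900000)

  years <- 2015:2023
  cpi <- dplyr::bind_rows(
    tibble::tibble(entity = "USD", year = years,
                   value = 100 * 1.02 ^ (years - 2020)),
    tibble::tibble(entity = "GBP", year = years,
                   value = 100 * 1.025 ^ (years - 2020)))
  ppp <- dplyr::bind_rows(
    tibble::tibble(entity = "USD", year = years, value = 1),
    tibble::tibble(entity = "GBP", year = years, value = 0.7))

  swap_bundle(
    foods = foods, diets = diets,
    recommendations = default_recommendations(),
    rr_table = default_rr_table(),
    mortality = mortality, cpi = cpi, ppp = ppp,
    zinc_reference = default_zinc_reference(),
    iron_model = default_iron_model(),
    risk_factors = risk_factor_definitions(),
    weights = synthesis_weights())
}

#' Construct a diet realizing exact nutrient deviations
#'
#' Testing scaffold for the imbalance indicator: builds a one-food diet
#' (100 g/day of a synthetic composite food) whose intake of every
#' recommended nutrient sits at exactly the requested signed percentage
#' deviation from its recommendation, so the nutrition module must recover
#' the targets to numerical precision. Special handlers are disabled in the
#' returned recommendation set (diet-dependent requirements would otherwise
#' move the targets). The expected indicator is computed here from the
#' targets alone: the mean over recommended nutrients of each target's
#' violating magnitude (shortfall below a minimum, excess above a maximum).
#'
#' @param target_deviations Named numeric, one signed percent per
#'   recommended nutrient (name = nutrient id). Must cover every nutrient
#'   in `recommendations`; a deviation below -100% implies negative intake
#'   and errors.
#' @param recommendations Recommendation tibble defining the targets.
#' @param region Region id of the emitted diet.
#' @return List: `diet` (`diet_table`), `foods` (`food_table` with the one
#'   composite food), `recommendations` (handlers disabled),
#'   `expected_indicator` (%), `expected_deviation_pct` (the targets).
#' @export
generate_known_answer_diet <- function(target_deviations,
                                       recommendations = default_recommendations(),
                                       region = "KA") {
  rec <- validate_recommendations(recommendations)
  rec$special_handler <- "none"
  missing <- setdiff(rec$nutrient, names(target_deviations))
  if (length(missing) > 0)
    abort_table("target deviation missing for recommended nutrient(s): %s",
                paste(missing, collapse = ", "))
  dev <- target_deviations[rec$nutrient]
  if (any(dev < -100))
    abort_table("infeasible target(s): deviation below -100%% implies negative intake")

  prof <- setNames(rep(0, length(nutrient_ids())), nutrient_ids())
  # 100 g/day of the food makes per-100g amounts equal daily intakes
  prof[rec$nutrient] <- rec$daily_value * (1 + dev / 100)
  # close composition invariants on non-targeted structural nutrients
  fat_sum <- sum(prof[c("satfat_g", "mufa_g", "pufa_g", "transfat_g")])
  prof["fat_g"] <- max(prof["fat_g"], fat_sum)
  prof["iron_mg"] <- max(prof["iron_mg"], prof["heme_iron_mg"])
  if (!("energy_kcal" %in% rec$nutrient))
    prof["energy_kcal"] <- 100  # untargeted; any positive density works

  foods <- food_table(tibble::as_tibble(c(list(
    id = "ka_food", name = "known-answer composite (synthetic)",
    category = "other_diet_component", serving_g = 100,
    variant = NA_character_,
    ghg_kg_per_kg = 1, land_m2_per_kg = 1, water_l_per_kg = 1,
    ghg_processing_kg_per_kg = 0,
    price = 1, currency = "USD", year = 2020), as.list(prof))))
  diet <- diet_table(tibble::tibble(
    region = region, food_id = "ka_food", intake_g_day = 100,
    waste_adjusted = TRUE), foods = foods)

  violation <- ifelse(rec$direction == "minimum", pmax(0, -dev),
                      pmax(0, dev))
  list(diet = diet, foods = foods, recommendations = rec,
       expected_indicator = sum(violation) / nrow(rec),
       expected_deviation_pct = setNames(as.numeric(dev), rec$nutrient))
}
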