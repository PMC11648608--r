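# Shared fixtures, built in code. The default bundle is generated once per
# test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

test_bundle <- function(seed = 1) {
  key <- paste0("bundle_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_bundle(generator_spec(seed = seed))
  .fixture_env[[key]]
}

# Minimal hand-built food table: a meat-like, a legume-like, and a
# milk-like food with simple round numbers, convenient for arithmetic
# oracles.
mini_food_df <- function() {
  nut <- setNames(rep(0, length(nutrient_ids())), nutrient_ids())
  row <- function(id, category, serving_g, over, ghg, land, water,
                  price = 5, currency = "USD", year = 2020) {
    p <- nut
    p[names(over)] <- over
    tibble::as_tibble(c(list(id = id, name = id, category = category,
                             serving_g = serving_g,
                             ghg_kg_per_kg = ghg, land_m2_per_kg = land,
                             water_l_per_kg = water,
                             price = price, currency = currency,
                             year = year), as.list(p)))
  }
  dplyr::bind_rows(
    row("meaty", "meat", 110,
        c(energy_kcal = 250, protein_g = 26, fat_g = 17, satfat_g = 7,
          mufa_g = 7, pufa_g = 0.6, cholesterol_mg = 80, iron_mg = 2.6,
          heme_iron_mg = 1.8, sodium_mg = 70, potassium_mg = 320,
          zinc_mg = 6),
        ghg = 60, land = 160, water = 1500, price = 10),
    row("beany", "unprocessed_alternative", 45,
        c(energy_kcal = 125, protein_g = 9, fat_g = 0.5, satfat_g = 0.1,
          pufa_g = 0.2, fiber_g = 5, iron_mg = 2.9, sodium_mg = 1,
          potassium_mg = 400, zinc_mg = 1, phytate_mg = 400),
        ghg = 1, land = 4, water = 40, price = 2.5),
    row("milky", "dairy", 240,
        c(energy_kcal = 60, protein_g = 3.2, fat_g = 3.3, satfat_g = 1.9,
          mufa_g = 0.8, pufa_g = 0.2, cholesterol_mg = 10,
          sodium_mg = 44, potassium_mg = 140, calcium_mg = 120,
          zinc_mg = 0.4, iron_mg = 0.05),
        ghg = 3, land = 9, water = 600, price = 1.2)
  )
}

mini_foods <- function() food_table(mini_food_df())

mini_mortality <- function() {
  tibble::tibble(region = "HIC", population = 1e8,
                 deaths_CHD = 150000, deaths_stroke = 80000,
                 deaths_cancer = 250000, deaths_all = 900000)
}

# Single-factor RR table for closed-form checks.
single_factor_rr <- function(rr = 1.2, increment = 50,
                             factor = "sodium_mg", endpoint = "CHD") {
  tibble::tibble(factor = factor, endpoint = endpoint, rr = rr,
                 increment = increment)
}
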