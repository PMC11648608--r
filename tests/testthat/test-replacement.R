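test_that("calorie-basis replacement converts removed calories to grams", {
  foods <- mini_foods()
  # 200 g/day meaty at 250 kcal/100 g = 500 kcal; beany has 1.25 kcal/g
  d <- diet_table(tibble::tibble(
    region = "HIC", food_id = c("meaty", "milky"),
    intake_g_day = c(200, 100)), foods = foods)
  s <- replacement_scenario("s", replace = "meat", with = "beany",
                            basis = "calorie")
  out <- build_replacement_diet(d, s, foods)
  expect_equal(out$intake_g_day[out$food_id == "meaty"], 0)
  expect_equal(out$intake_g_day[out$food_id == "beany"], 500 / 1.25)
  expect_equal(attr(out, "alternative_grams")[["beany"]], 400)
  # energy conserved
  e_out <- sum(lookup_food(foods, out$food_id)$energy_kcal *
                 out$intake_g_day / 100)
  e_in <- sum(lookup_food(foods, d$food_id)$energy_kcal *
                d$intake_g_day / 100)
  expect_equal(e_out, e_in)
})

test_that("serving-basis replacement conserves serving counts", {
  foods <- mini_foods()
  # 220 g meaty = 2 servings of 110 g
  d <- diet_table(tibble::tibble(
    region = "HIC", food_id = c("meaty", "milky"),
    intake_g_day = c(220, 100)), foods = foods)
  s <- replacement_scenario("s", replace = "meat", with = "beany",
                            basis = "serving")
  out <- build_replacement_diet(d, s, foods)
  expect_equal(out$intake_g_day[out$food_id == "beany"], 2 * 45)
})

test_that("replacement guards category membership and energy density", {
  foods <- mini_foods()
  d <- diet_table(tibble::tibble(region = "HIC", food_id = "meaty",
                                 intake_g_day = 200), foods = foods)
  same_cat <- replacement_scenario("bad", replace = "meat", with = "meaty")
  expect_error(build_replacement_diet(d, same_cat, foods),
               "itself in the replaced category")
  # ... unless explicitly a comparator run
  comp <- replacement_scenario("cmp", replace = "meat", with = "meaty",
                               comparator = TRUE)
  out <- build_replacement_diet(d, comp, foods)
  expect_equal(out$intake_g_day[out$food_id == "meaty"], 200)

  d2 <- diet_table(tibble::tibble(region = "HIC", food_id = "beany",
                                  intake_g_day = 200), foods = foods)
  s <- replacement_scenario("s", replace = "meat", with = "beany")
  expect_error(build_replacement_diet(d2, s, foods),
               "no positive intake of category 'meat'")
})

test_that("calorie conservation holds across the generated scenario matrix", {
  b <- test_bundle()
  base <- diet_for_region(b$diets, "HIC")
  e0 <- unname(nutrient_intake(base, b$foods)[["energy_kcal"]])
  scen <- default_scenarios(b, basis = "calorie")
  for (s in scen[seq(1, length(scen), by = 5)]) {
    out <- build_replacement_diet(base, s, b$foods)
    e1 <- unname(nutrient_intake(out, b$foods)[["energy_kcal"]])
    expect_equal(e1, e0, tolerance = 1e-9)
    replaced_ids <- b$foods$id[b$foods$category %in% names(s$with)]
    expect_true(all(out$intake_g_day[out$food_id %in%
                                       setdiff(replaced_ids,
                                               unlist(s$with))] == 0))
  }
})

test_that("scenario runs are deterministic and null changes vanish", {
  b <- test_bundle()
  s <- replacement_scenario("soy", replace = "meat", with = "soybeans")
  r1 <- run_scenario(s, b)
  r2 <- run_scenario(s, b)
  expect_identical(r1$domain_changes, r2$domain_changes)
  expect_setequal(r1$domain_changes$domain,
                  c("nutrition_pp", "mortality_pct", "ghg_pct", "land_pct",
                    "water_pct", "cost_pct"))

  # a comparator scenario replacing the category with a clone of itself
  # leaves every domain unchanged
  foods <- mini_foods()
  clone <- mini_food_df()[1, ]
  clone$id <- "meaty2"
  clone$category <- "other_diet_component"
  foods2 <- food_table(dplyr::bind_rows(mini_food_df(), clone))
  diets <- tibble::tibble(region = "HIC",
                          food_id = c("meaty", "beany", "milky"),
                          intake_g_day = c(150, 100, 200))
  bundle <- swap_bundle(foods2, diets, mortality = mini_mortality(),
                        cpi = tibble::tibble(entity = "USD", year = 2020,
                                             value = 100),
                        ppp = tibble::tibble(entity = "USD", year = 2020,
                                             value = 1))
  null_s <- replacement_scenario("null", replace = "meat", with = "meaty2")
  r <- run_scenario(null_s, bundle)
  expect_true(all(abs(r$domain_changes$value) < 1e-9))
})

test_that("joint meat+dairy replacement adds up in diet totals", {
  b <- test_bundle()
  base <- diet_for_region(b$diets, "HIC")
  s_meat <- replacement_scenario("m", replace = "meat", with = "soybeans")
  s_dairy <- replacement_scenario("d", replace = "dairy", with = "oat_milk")
  s_both <- replacement_scenario("b", replace = "both",
                                 with = c(meat = "soybeans",
                                          dairy = "oat_milk"))
  t_base <- diet_environmental_totals(base, b$foods)
  t_m <- diet_environmental_totals(
    build_replacement_diet(base, s_meat, b$foods), b$foods)
  t_d <- diet_environmental_totals(
    build_replacement_diet(base, s_dairy, b$foods), b$foods)
  t_b <- diet_environmental_totals(
    build_replacement_diet(base, s_both, b$foods), b$foods)
  expect_equal(t_b - t_base, (t_m - t_base) + (t_d - t_base),
               tolerance = 1e-9)
})

test_that("a dominating alternative gets the weaker environmental outcome", {
  b <- test_bundle()
  foods <- b$foods
  # soybeans' footprints are dominated by beef burger's in every domain
  soy <- lookup_food(foods, "soybeans")
  burger <- lookup_food(foods, "beef_burger")
  stopifnot(all(footprint_per_basis(soy, "calorie") <
                  footprint_per_basis(burger, "calorie")))
  r_soy <- run_scenario(
    replacement_scenario("s", replace = "meat", with = "soybeans"), b)
  r_bur <- run_scenario(
    replacement_scenario("b", replace = "meat", with = "beef_burger",
                         comparator = TRUE), b)
  env_w <- function(r) r$details$env_weighted_pct
  expect_lt(env_w(r_soy), env_w(r_bur))
})

test_that("sensitivity switches shift the intended margins only", {
  b <- test_bundle()
  s0 <- replacement_scenario("s0", replace = "meat", with = "soybeans")
  s_na <- replacement_scenario("sna", replace = "meat", with = "soybeans",
                               sodium_addon_mg_per_100g = 400)
  r0 <- run_scenario(s0, b)
  r_na <- run_scenario(s_na, b)
  val <- function(r, d) r$domain_changes$value[r$domain_changes$domain == d]
  # added sodium worsens (raises) the mortality change, nothing else
  expect_gt(val(r_na, "mortality_pct"), val(r0, "mortality_pct"))
  expect_equal(val(r_na, "ghg_pct"), val(r0, "ghg_pct"))

  s_pe <- replacement_scenario("spe", replace = "meat", with = "soybeans",
                               processing_emissions = TRUE)
  r_pe <- run_scenario(s_pe, b)
  # soybeans carry a processing add-on, so their GHG benefit shrinks
  expect_gt(val(r_pe, "ghg_pct"), val(r0, "ghg_pct"))
  expect_equal(val(r_pe, "water_pct"), val(r0, "water_pct"))
})
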