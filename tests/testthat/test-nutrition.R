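test_that("nutrient intake sums grams x density / 100", {
  foods <- mini_foods()
  d <- diet_table(tibble::tibble(region = "HIC", food_id = "beany",
                                 intake_g_day = 100), foods = foods)
  intake <- nutrient_intake(d, foods)
  expect_equal(unname(intake[["fiber_g"]]), 5)

  empty <- diet_table(tibble::tibble(region = character(),
                                     food_id = character(),
                                     intake_g_day = numeric()))
  expect_true(all(nutrient_intake(empty, foods) == 0))

  # brute-force two-food oracle
  d2 <- diet_table(tibble::tibble(
    region = "HIC", food_id = c("meaty", "beany"),
    intake_g_day = c(80, 120)), foods = foods)
  got <- nutrient_intake(d2, foods)
  for (n in c("protein_g", "iron_mg", "potassium_mg")) {
    manual <- 80 / 100 * foods[[n]][foods$id == "meaty"] +
      120 / 100 * foods[[n]][foods$id == "beany"]
    expect_equal(unname(got[[n]]), manual)
  }
})

test_that("source classification uses the 10% and 20% density cuts", {
  expect_equal(as.character(classify_source(0.25)), "high")
  expect_equal(as.character(classify_source(0.15)), "good")
  expect_equal(as.character(classify_source(0)), "none")
  expect_equal(as.character(classify_source(c(0.10, 0.199, 0.20))),
               c("good", "good", "high"))
  expect_error(classify_source(-0.1), ">= 0")
})

test_that("nutrient densities are per-serving fractions of recommendations", {
  foods <- mini_foods()
  dens <- nutrient_density(foods)
  beany_fiber <- dens[dens$food_id == "beany" & dens$nutrient == "fiber_g", ]
  expect_equal(beany_fiber$density, 5 * 45 / 100 / 30)
  expect_false("calcium_mg" %in% dens$nutrient)
})

test_that("zinc requirement interpolates the phytate reference linearly", {
  tab <- default_zinc_reference()
  expect_equal(zinc_requirement(600, tab), 7.6)
  expect_equal(zinc_requirement(750, tab), (7.6 + 8.9) / 2)
  expect_equal(zinc_requirement(5000, tab), 10.2)  # clamped above
  expect_equal(zinc_requirement(0, tab), 6.2)      # clamped below
  bad <- tibble::tibble(phytate_mg = c(300, 600), zinc_mg = c(8, 7))
  expect_error(zinc_requirement(400, bad), "nondecreasing")
  expect_error(zinc_requirement(400, tab[0, ]), "empty")
})

test_that("iron requirement follows the blended absorption model", {
  model <- default_iron_model()
  # all-heme diet: requirement = target / heme absorption
  intakes <- setNames(rep(0, length(nutrient_ids())), nutrient_ids())
  intakes["iron_mg"] <- 10
  intakes["heme_iron_mg"] <- 10
  model0 <- model
  model0$nonheme_coefficients[] <- 0  # silence the heme-as-mediator term
  expect_equal(iron_requirement(intakes, model0),
               model$target_absorbed_mg / model$heme_absorption)

  # mediator-free all-nonheme diet: absorption = exp(intercept)
  intakes2 <- intakes
  intakes2["heme_iron_mg"] <- 0
  expect_equal(iron_requirement(intakes2, model),
               model$target_absorbed_mg / exp(model$nonheme_intercept))

  # more vitamin C (positive coefficient) never raises the requirement
  reqs <- vapply(c(0, 20, 80, 200), function(vc) {
    x <- intakes2
    x["vitamin_c_mg"] <- vc
    iron_requirement(x, model)
  }, numeric(1))
  expect_true(all(diff(reqs) <= 1e-12))

  bad <- model
  bad$heme_absorption <- 1.5
  expect_error(iron_requirement(intakes, bad), "\\(0, 1\\]")
})

test_that("imbalance indicator averages violation magnitudes", {
  rec <- tibble::tibble(
    nutrient = c("fiber_g", "satfat_g", "protein_g", "sodium_mg"),
    direction = c("minimum", "maximum", "minimum", "maximum"),
    daily_value = c(30, 20, 50, 2000),
    source = "t", special_handler = "none")
  ok <- c(fiber_g = 35, satfat_g = 15, protein_g = 60, sodium_mg = 1500)
  expect_equal(imbalance_indicator(ok, rec)$indicator, 0)

  v <- c(fiber_g = 15, satfat_g = 30, protein_g = 60, sodium_mg = 1500)
  r <- imbalance_indicator(v, rec)
  expect_equal(r$indicator, 25)  # (50 + 50 + 0 + 0) / 4

  # invariant to non-recommended nutrients
  v2 <- c(v, calcium_mg = 1, vitamin_c_mg = 500)
  expect_equal(imbalance_indicator(v2, rec)$indicator, 25)

  # doubling every violation magnitude doubles the indicator
  v3 <- c(fiber_g = 0, satfat_g = 40, protein_g = 60, sodium_mg = 1500)
  expect_equal(imbalance_indicator(v3, rec)$indicator,
               2 * r$indicator)

  # zero iff no violation
  expect_true(all(imbalance_indicator(ok, rec)$table$violation_pct == 0))
  expect_gt(sum(r$table$violation_pct), 0)
})

test_that("handler-resolved requirements respond to the diet", {
  b <- test_bundle()
  d <- diet_for_region(b$diets, "HIC")
  intakes <- nutrient_intake(d, b$foods)
  rec <- resolve_recommendations(b$recommendations, intakes,
                                 b$zinc_reference, b$iron_model)
  zinc <- rec$daily_value[rec$nutrient == "zinc_mg"]
  expect_equal(zinc,
               zinc_requirement(intakes[["phytate_mg"]], b$zinc_reference))
  iron <- rec$daily_value[rec$nutrient == "iron_mg"]
  expect_equal(iron, iron_requirement(intakes, b$iron_model))
  # a higher-phytate diet cannot lower the zinc requirement
  intakes_hi <- intakes
  intakes_hi["phytate_mg"] <- intakes[["phytate_mg"]] * 3
  rec_hi <- resolve_recommendations(b$recommendations, intakes_hi,
                                    b$zinc_reference, b$iron_model)
  expect_gte(rec_hi$daily_value[rec_hi$nutrient == "zinc_mg"], zinc)
})

test_that("imbalance change decomposes into per-nutrient contributions", {
  rec <- tibble::tibble(
    nutrient = c("fiber_g", "satfat_g", "sodium_mg"),
    direction = c("minimum", "maximum", "maximum"),
    daily_value = c(30, 20, 2000),
    source = "t", special_handler = "none")
  base <- imbalance_indicator(
    c(fiber_g = 15, satfat_g = 30, sodium_mg = 3000), rec)
  scen <- imbalance_indicator(
    c(fiber_g = 24, satfat_g = 22, sodium_mg = 3000), rec)

  dec <- imbalance_change_decomposition(base, scen)
  expect_equal(sum(dec$contribution_pp), scen$indicator - base$indicator,
               tolerance = 1e-9)
  expect_equal(sum(dec$share_pct), 100)

  # leave-one-out oracle: each contribution equals the indicator change
  # when only that nutrient moves
  base_int <- c(fiber_g = 15, satfat_g = 30, sodium_mg = 3000)
  scen_int <- c(fiber_g = 24, satfat_g = 22, sodium_mg = 3000)
  for (n in rec$nutrient) {
    hybrid <- base_int
    hybrid[n] <- scen_int[n]
    oracle <- imbalance_indicator(hybrid, rec)$indicator - base$indicator
    expect_equal(dec$contribution_pp[dec$nutrient == n], oracle,
                 tolerance = 1e-9)
  }

  # identical scenarios: all contributions zero
  dec0 <- imbalance_change_decomposition(base, base)
  expect_true(all(dec0$contribution_pp == 0))

  # single-nutrient change takes a 100% share
  scen1 <- imbalance_indicator(
    c(fiber_g = 24, satfat_g = 30, sodium_mg = 3000), rec)
  dec1 <- imbalance_change_decomposition(base, scen1)
  expect_equal(dec1$share_pct[dec1$nutrient == "fiber_g"], 100)
})
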