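make_fp_food <- function(id, ghg, land, water, serving_g = 100,
                         energy_kcal = 200) {
  df <- mini_food_df()[1, ]
  df$id <- id
  df$ghg_kg_per_kg <- ghg
  df$land_m2_per_kg <- land
  df$water_l_per_kg <- water
  df$serving_g <- serving_g
  df$energy_kcal <- energy_kcal
  lookup_food(food_table(df), id)
}

test_that("footprints convert between weight, serving, and calorie bases", {
  f <- make_fp_food("x", ghg = 10, land = 20, water = 500,
                    serving_g = 110, energy_kcal = 250)
  per_serving <- footprint_per_basis(f, "serving")
  expect_equal(unname(per_serving[["ghg"]]), 10 * 110 / 1000)  # 1.1 kg

  per_kg <- footprint_per_basis(f, "weight")
  expect_equal(unname(per_kg), c(10, 20, 500))

  # dimensional consistency: per-calorie x kcal/serving = per-serving
  per_cal <- footprint_per_basis(f, "calorie")
  kcal_per_serving <- f$energy_kcal * f$serving_g / 100
  expect_equal(per_cal * kcal_per_serving, per_serving, tolerance = 1e-12)

  f0 <- make_fp_food("zero", 1, 1, 1, energy_kcal = 0)
  expect_error(footprint_per_basis(f0, "calorie"), "zero energy")
})

test_that("relative impacts reproduce the printed worked examples", {
  bench <- make_fp_food("bench", ghg = 100, land = 100, water = 100)
  # soy-vs-milk: per-domain 7/25/6 -> weighted 9.88 -> 10
  soy <- make_fp_food("soy", 7, 25, 6)
  ri <- relative_impact(soy, bench, basis = "weight")
  expect_equal(unname(ri$per_domain_pct), c(7, 25, 6))
  expect_equal(ri$weighted_pct, 9.88, tolerance = 1e-12)
  expect_equal(round_half_away(ri$weighted_pct), 10)
  # almond milk: 27/16/70 -> 32.87 -> 33
  am <- make_fp_food("am", 27, 16, 70)
  expect_equal(relative_impact(am, bench, basis = "weight")$weighted_pct,
               32.87, tolerance = 1e-12)
  # identity: benchmark scores 100 everywhere
  self <- relative_impact(bench, bench, basis = "weight")
  expect_equal(unname(self$per_domain_pct), c(100, 100, 100))
  expect_equal(self$weighted_pct, 100)
  # a composite at a uniform 90% of the benchmark scores 90 under any
  # weights summing to 1
  comp <- make_fp_food("comp", 90, 90, 90)
  for (w in list(synthesis_weights(), weight_scheme("equal_env")))
    expect_equal(relative_impact(comp, bench, basis = "weight",
                                 weights = w)$weighted_pct, 90)
})

test_that("relative impact is a convex combination and scale-invariant", {
  bench <- make_fp_food("bench", 40, 10, 800)
  f <- make_fp_food("f", 12, 7, 300)
  ri <- relative_impact(f, bench, basis = "weight")
  expect_gte(ri$weighted_pct, min(ri$per_domain_pct))
  expect_lte(ri$weighted_pct, max(ri$per_domain_pct))
  # multiplying all footprints by a constant changes nothing
  bench2 <- make_fp_food("bench2", 40 * 3, 10 * 3, 800 * 3)
  f2 <- make_fp_food("f2", 12 * 3, 7 * 3, 300 * 3)
  ri2 <- relative_impact(f2, bench2, basis = "weight")
  expect_equal(unname(ri2$per_domain_pct), unname(ri$per_domain_pct),
               tolerance = 1e-12)
  zero <- make_fp_food("z", 1, 0, 1)
  expect_error(relative_impact(f, zero, basis = "weight"), "zero footprint")
})

test_that("diet environmental totals are linear in intake", {
  foods <- mini_foods()
  empty <- diet_table(tibble::tibble(region = character(),
                                     food_id = character(),
                                     intake_g_day = numeric()))
  expect_true(all(diet_environmental_totals(empty, foods) == 0))

  dA <- diet_table(tibble::tibble(region = "HIC", food_id = "meaty",
                                  intake_g_day = 200), foods = foods)
  tA <- diet_environmental_totals(dA, foods)
  expect_equal(unname(tA[["ghg"]]), 200 / 1000 * 60)

  dB <- diet_table(tibble::tibble(region = "HIC", food_id = "beany",
                                  intake_g_day = 150), foods = foods)
  dAB <- diet_table(tibble::tibble(
    region = "HIC", food_id = c("meaty", "beany"),
    intake_g_day = c(200, 150)), foods = foods)
  expect_equal(diet_environmental_totals(dAB, foods),
               tA + diet_environmental_totals(dB, foods),
               tolerance = 1e-12)
})

test_that("replacement environmental change reproduces the almond-milk example", {
  base <- c(ghg = 100, land = 100, water = 100)
  scen <- c(ghg = 103, land = 100, water = 167)
  ch <- replacement_environment_change(base, scen)
  expect_equal(unname(ch$per_domain_pct), c(3, 0, 67))
  expect_equal(ch$weighted_pct, 14.01, tolerance = 1e-12)
  expect_equal(round_half_away(ch$weighted_pct), 14)

  same <- replacement_environment_change(base, base)
  expect_true(all(same$per_domain_pct == 0))
  expect_equal(same$weighted_pct, 0)

  half <- replacement_environment_change(base, base / 2)
  expect_true(all(half$per_domain_pct == -50))
  expect_equal(half$weighted_pct, -50)

  expect_error(replacement_environment_change(c(ghg = 0, land = 1,
                                                water = 1), base),
               "> 0")
})

test_that("processing add-ons enter GHG only when requested", {
  df <- mini_food_df()[2, ]
  df$ghg_processing_kg_per_kg <- 2
  f <- food_table(df)
  d <- diet_table(tibble::tibble(region = "HIC", food_id = df$id,
                                 intake_g_day = 500), foods = f)
  off <- diet_environmental_totals(d, f)
  on <- diet_environmental_totals(d, f, include_processing = TRUE)
  expect_equal(unname(on[["ghg"]] - off[["ghg"]]), 0.5 * 2)
  expect_equal(on[["land"]], off[["land"]])
})

test_that("presentation rounding is half-away-from-zero", {
  expect_equal(round_half_away(9.88), 10)
  expect_equal(round_half_away(0.5), 1)
  expect_equal(round_half_away(-14.5), -15)
  expect_equal(round_half_away(2.5), 3)
  expect_equal(round_half_away(32.87), 33)
})
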