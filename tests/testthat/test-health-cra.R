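test_that("diet exposures cover the six factors and keep raw potassium", {
  foods <- mini_foods()
  empty <- diet_table(tibble::tibble(region = character(),
                                     food_id = character(),
                                     intake_g_day = numeric()))
  expect_true(all(exposure_from_diet(empty, foods) == 0))

  d <- diet_table(tibble::tibble(region = "HIC", food_id = "beany",
                                 intake_g_day = 1000), foods = foods)
  exp <- exposure_from_diet(d, foods)
  expect_equal(unname(exp[["potassium_mg"]]), 4000)  # raw, uncapped
  capped <- apply_exposure_caps(exp)
  expect_equal(unname(capped[["potassium_mg"]]), 3500)

  d2 <- diet_table(tibble::tibble(region = "HIC", food_id = "beany",
                                  intake_g_day = 750), foods = foods)
  exp2 <- apply_exposure_caps(exposure_from_diet(d2, foods))
  expect_equal(unname(exp2[["potassium_mg"]]), 3000)  # below the cap

  # sodium add-on enters the exposure
  exp3 <- exposure_from_diet(d2, foods, sodium_addon_mg = 250)
  expect_equal(unname(exp3[["sodium_mg"]]),
               unname(exposure_from_diet(d2, foods)[["sodium_mg"]]) + 250)
})

test_that("dose-response relative risks compound log-linearly", {
  rr <- single_factor_rr(rr = 1.2, increment = 50)
  expect_equal(relative_risk_for_shift("sodium_mg", "CHD", 0, rr), 1)
  expect_equal(relative_risk_for_shift("sodium_mg", "CHD", 50, rr), 1.2)
  expect_equal(relative_risk_for_shift("sodium_mg", "CHD", 25, rr),
               1.2 ^ 0.5)
  expect_error(relative_risk_for_shift("sodium_mg", "stroke", 10, rr),
               "no relative risk")
})

test_that("population impact fractions follow the closed form", {
  rr <- single_factor_rr(rr = 1.2, increment = 50)
  base <- c(sodium_mg = 2050)
  ref <- c(sodium_mg = 2000)
  # identical exposures
  expect_equal(pif(base, base, rr, "CHD"), 0)
  # single factor returned to reference: PIF = (RR - 1) / RR
  expect_equal(pif(base, ref, rr, "CHD"), 0.2 / 1.2, tolerance = 1e-12)
  # protective increase gives positive PIF
  rr_f <- single_factor_rr(rr = 0.8, increment = 10, factor = "fiber_g")
  expect_gt(pif(c(fiber_g = 15), c(fiber_g = 25), rr_f, "CHD"), 0)
})

test_that("multi-factor PIF matches an independent fixed-reference oracle", {
  rr <- dplyr::bind_rows(
    single_factor_rr(rr = 1.2, increment = 50, factor = "sodium_mg"),
    single_factor_rr(rr = 0.85, increment = 10, factor = "fiber_g"),
    single_factor_rr(rr = 1.1, increment = 1, factor = "heme_iron_mg"))
  oracle_pif <- function(base, scen) {
    # explicit product of per-unit RRs against a zero reference
    rr_at <- function(x) {
      1.2 ^ (x[["sodium_mg"]] / 50) * 0.85 ^ (x[["fiber_g"]] / 10) *
        1.1 ^ (x[["heme_iron_mg"]] / 1)
    }
    (rr_at(base) - rr_at(scen)) / rr_at(base)
  }
  grid <- expand.grid(sodium = c(1500, 2500), fiber = c(10, 30),
                      heme = c(0.5, 2))
  for (i in seq_len(nrow(grid))) {
    base <- c(sodium_mg = grid$sodium[i], fiber_g = grid$fiber[i],
              heme_iron_mg = grid$heme[i])
    scen <- c(sodium_mg = 1800, fiber_g = 22, heme_iron_mg = 1)
    expect_equal(pif(base, scen, rr, "CHD"), oracle_pif(base, scen),
                 tolerance = 1e-12)
  }
})

test_that("potassium benefits saturate at the cap", {
  rr <- single_factor_rr(rr = 0.87, increment = 1000,
                         factor = "potassium_mg")
  base <- c(potassium_mg = 2500)
  expect_equal(pif(base, c(potassium_mg = 3500), rr, "CHD"),
               pif(base, c(potassium_mg = 5000), rr, "CHD"))
  # but movement below the cap still matters
  expect_gt(pif(base, c(potassium_mg = 3500), rr, "CHD"),
            pif(base, c(potassium_mg = 3000), rr, "CHD"))
})

test_that("attributable deaths scale PIFs by cause-specific mortality", {
  m <- mini_mortality()
  res <- attributable_deaths(c(CHD = 0.1), m)
  expect_equal(res$total_averted, 0.1 * 150000)

  res0 <- attributable_deaths(c(CHD = 0, stroke = 0, cancer = 0), m)
  expect_equal(res0$pct_of_all_cause_averted, 0)

  # two-cause hand computation
  res2 <- attributable_deaths(c(CHD = 0.05, stroke = -0.02), m)
  manual <- 0.05 * 150000 - 0.02 * 80000
  expect_equal(res2$total_averted, manual)
  expect_equal(res2$pct_of_all_cause_averted, 100 * manual / 900000)
  expect_equal(res2$mortality_change_pct, -100 * manual / 900000)

  expect_error(attributable_deaths(c(dementia = 0.1), m),
               "unknown endpoint")
})

test_that("deaths averted conserve against fixed-reference attribution", {
  rr <- dplyr::bind_rows(
    single_factor_rr(rr = 1.15, increment = 500, factor = "sodium_mg"),
    single_factor_rr(rr = 0.9, increment = 10, factor = "fiber_g"))
  m <- mini_mortality()
  ref <- c(sodium_mg = 1500, fiber_g = 30)
  base <- c(sodium_mg = 2600, fiber_g = 18)
  scen <- c(sodium_mg = 2100, fiber_g = 26)
  attrib <- function(x) {
    p <- pif(x, ref, rr, "CHD")
    p * m$deaths_CHD
  }
  averted_direct <- pif(base, scen, rr, "CHD") * m$deaths_CHD
  # attributable burden at baseline minus at scenario, both vs the same
  # reference, scaled to the baseline RR
  rr_at <- function(x) 1.15 ^ ((x[["sodium_mg"]] - 1500) / 500) *
    0.9 ^ ((x[["fiber_g"]] - 30) / 10)
  averted_conserve <- (rr_at(base) - rr_at(scen)) / rr_at(base) *
    m$deaths_CHD
  expect_equal(averted_direct, averted_conserve, tolerance = 1e-12)
})

test_that("per-serving risk changes weight endpoints by death shares", {
  foods <- mini_foods()
  m <- mini_mortality()
  rr <- default_rr_table()
  meaty <- lookup_food(foods, "meaty")
  beany <- lookup_food(foods, "beany")

  same <- per_serving_risk_change(meaty, meaty, rr, m)
  expect_equal(same$risk_change_pct, 0)

  # a pure-fiber food added to the diet lowers risk
  df <- mini_food_df()[2, ]
  nut <- nutrient_ids()
  df[, setdiff(nut, c("fiber_g", "energy_kcal"))] <- 0
  df$id <- "fiber_only"
  fiber_food <- lookup_food(food_table(df), "fiber_only")
  add <- per_serving_risk_change(fiber_food, NULL, rr, m, mode = "add")
  expect_lt(add$risk_change_pct, 0)

  # with a single endpoint the change reduces to RR - 1
  rr1 <- single_factor_rr(rr = 0.85, increment = 10, factor = "fiber_g")
  one <- per_serving_risk_change(fiber_food, NULL, rr1, m, mode = "add")
  delta <- fiber_food$fiber_g * fiber_food$serving_g / 100
  expect_equal(one$risk_change_pct, 100 * (0.85 ^ (delta / 10) - 1),
               tolerance = 1e-12)

  # swapping beans in for meat reduces risk in the default tables
  swap <- per_serving_risk_change(beany, meaty, rr, m)
  expect_lt(swap$risk_change_pct, 0)
})

test_that("risk-change decomposition shares sum to 100%", {
  rr <- dplyr::bind_rows(
    single_factor_rr(rr = 1.2, increment = 50, factor = "sodium_mg"),
    single_factor_rr(rr = 0.85, increment = 10, factor = "fiber_g"),
    single_factor_rr(rr = 1.1, increment = 1, factor = "heme_iron_mg"))

  one <- risk_change_decomposition(c(sodium_mg = 100, fiber_g = 0,
                                     heme_iron_mg = 0), rr)
  expect_equal(one$share_pct[one$factor == "sodium_mg"], 100)

  # two factors with equal |delta log RR| split 50/50
  d_f <- 10 * log(1.2) / log(1 / 0.85) * (50 / 50)
  two <- risk_change_decomposition(
    c(sodium_mg = 50, fiber_g = d_f, heme_iron_mg = 0), rr)
  expect_equal(two$share_pct[two$factor != "heme_iron_mg"], c(50, 50),
               tolerance = 1e-9)

  # three-factor arithmetic oracle
  deltas <- c(sodium_mg = 120, fiber_g = -8, heme_iron_mg = 0.7)
  dec <- risk_change_decomposition(deltas, rr)
  dlog <- c(log(1.2) * 120 / 50, log(0.85) * (-8) / 10, log(1.1) * 0.7)
  expect_equal(dec$share_pct, 100 * abs(dlog) / sum(abs(dlog)),
               tolerance = 1e-9)
  expect_equal(sum(dec$share_pct), 100)

  expect_error(risk_change_decomposition(
    c(sodium_mg = 0, fiber_g = 0, heme_iron_mg = 0), rr), "zero")
})
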