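#' Nutrient dictionary
#'
#' The fixed set of nutrients tracked per 100 g edible food. The dictionary
#' follows the conventional composition-table grouping: six proximates, five
#' lipids, the mineral block (with heme iron counted as a subcomponent of
#' total iron and phytate tracked alongside phosphorus as the absorption
#' antinutrient), and nine vitamins. Column names in food tables must match
#' the `id` column exactly; unknown nutrient columns are a load-time error.
#'
#' @return A tibble with columns `id`, `group`
#'   (proximate/lipid/mineral/vitamin), `label`, and `unit` (amount per 100 g).
#' @export
#' @examples
#' nutrient_dictionary()
nutrient_dictionary <- function() {
  tibble::tribble(
    ~id,              ~group,      ~label,                    ~unit,
    "energy_kcal",    "proximate", "Energy",                  "kcal",
    "protein_g",      "proximate", "Protein",                 "g",
    "fat_g",          "proximate", "Total fat",               "g",
    "carbohydrate_g", "proximate", "Carbohydrate",            "g",
    "sugar_g",        "proximate", "Sugars",                  "g",
    "fiber_g",        "proximate", "Dietary fiber",           "g",
    "satfat_g",       "lipid",     "Saturated fat",           "g",
    "mufa_g",         "lipid",     "Monounsaturated fat",     "g",
    "pufa_g",         "lipid",     "Polyunsaturated fat",     "g",
    "transfat_g",     "lipid",     "Trans fat",               "g",
    "cholesterol_mg", "lipid",     "Cholesterol",             "mg",
    "calcium_mg",     "mineral",   "Calcium",                 "mg",
    "iron_mg",        "mineral",   "Iron (total)",            "mg",
    "heme_iron_mg",   "mineral",   "Heme iron",               "mg",
    "magnesium_mg",   "mineral",   "Magnesium",               "mg",
    "phosphorus_mg",  "mineral",   "Phosphorus",              "mg",
    "phytate_mg",     "mineral",   "Phytate",                 "mg",
    "potassium_mg",   "mineral",   "Potassium",               "mg",
    "sodium_mg",      "mineral",   "Sodium",                  "mg",
    "zinc_mg",        "mineral",   "Zinc",                    "mg",
    "copper_mg",      "mineral",   "Copper",                  "mg",
    "vitamin_c_mg",   "vitamin",   "Vitamin C",               "mg",
    "thiamine_mg",    "vitamin",   "Thiamine (B1)",           "mg",
    "riboflavin_mg",  "vitamin",   "Riboflavin (B2)",         "mg",
    "niacin_mg",      "vitamin",   "Niacin (B3)",             "mg",
    "pantothenate_mg","vitamin",   "Pantothenic acid (B5)",   "mg",
    "vitamin_b6_mg",  "vitamin",   "Vitamin B6",              "mg",
    "folate_ug",      "vitamin",   "Folate",                  "ug",
    "vitamin_b12_ug", "vitamin",   "Vitamin B12",             "ug",
    "vitamin_a_ug",   "vitamin",   "Vitamin A",               "ug RAE"
  )
}

#' Nutrient column ids
#' @return Character vector of nutrient ids in canonical order.
#' @export
nutrient_ids <- function() nutrient_dictionary()$id

#' Default nutrient recommendations
#'
#' An illustrative harmonized set of population-level average daily
#' requirements (minimum limits for protective nutrients, maximum limits for
#' energy, saturated fat, sugar, sodium, and cholesterol). The set is a
#' plausible adult population average assembled for testing and
#' demonstration; users with access to authoritative requirement tables
#' should load their own via [read_recommendation_table()]. Calcium carries
#' no recommendation and must not appear here: current reference values are
#' based on balance studies of prevailing intakes, so shortfalls against
#' them are not interpretable as imbalance. Sugars likewise carry no
#' default: quantitative limits target free sugars, which the composition
#' dictionary's total-sugar column (lactose, intrinsic fruit sugars) does
#' not measure.
#'
#' Zinc and iron carry special handlers: the zinc requirement depends on
#' dietary phytate ([zinc_requirement()]) and the iron requirement on the
#' absorption-adjusting composition of the diet ([iron_requirement()]); the
#' `daily_value` stored here is the fallback used when a handler is
#' disabled.
#'
#' @return A tibble with columns `nutrient`, `direction` ("minimum" or
#'   "maximum"), `daily_value`, `source`, `special_handler`
#'   ("zinc_phytate", "iron_absorption", or "none").
#' @export
default_recommendations <- function() {
  rec <- tibble::tribble(
    ~nutrient,        ~direction, ~daily_value, ~special_handler,
    "energy_kcal",    "maximum",  2100,         "none",
    "protein_g",      "minimum",  50,           "none",
    "fiber_g",        "minimum",  30,           "none",
    "satfat_g",       "maximum",  23.3,         "none",
    "copper_mg",      "minimum",  1.1,          "none",
    "pufa_g",         "minimum",  11.7,         "none",
    "cholesterol_mg", "maximum",  300,          "none",
    "sodium_mg",      "maximum",  2000,         "none",
    "potassium_mg",   "minimum",  3500,         "none",
    "iron_mg",        "minimum",  11,           "iron_absorption",
    "magnesium_mg",   "minimum",  350,          "none",
    "zinc_mg",        "minimum",  9.4,          "zinc_phytate",
    "vitamin_c_mg",   "minimum",  80,           "none",
    "thiamine_mg",    "minimum",  1.1,          "none",
    "riboflavin_mg",  "minimum",  1.2,          "none",
    "niacin_mg",      "minimum",  14,           "none",
    "vitamin_b6_mg",  "minimum",  1.4,          "none",
    "folate_ug",      "minimum",  330,          "none",
    "vitamin_b12_ug", "minimum",  4,            "none",
    "vitamin_a_ug",   "minimum",  700,          "none"
  )
  rec$source <- "packaged illustrative default"
  validate_recommendations(rec)
}

#' Default phytate-dependent zinc requirement reference table
#'
#' Monotone (phytate intake, zinc requirement) pairs in the style of
#' phytate-banded average requirements; intermediate phytate levels are
#' linearly interpolated and the table is clamped at its ends. Values are
#' an illustrative adult population average.
#'
#' @return Tibble with columns `phytate_mg`, `zinc_mg` (both per day).
#' @export
default_zinc_reference <- function() {
  tibble::tibble(
    phytate_mg = c(300, 600, 900, 1200),
    zinc_mg    = c(6.2, 7.6, 8.9, 10.2)
  )
}

#' Default iron absorption model
#'
#' Parameters for the diet-dependent iron requirement. Heme iron is absorbed
#' at a constant fraction; nonheme absorption is log-linear in dietary
#' mediators (phytate and calcium inhibit, vitamin C and meat tissue --
#' indexed by heme iron intake -- enhance):
#' `a_nonheme = exp(intercept + sum(coef * log1p(mediator intake)))`,
#' truncated to (0, 1]. The daily requirement is the target absorbed iron
#' divided by the absorption fraction blended over the heme/nonheme shares
#' of dietary iron. Coefficients are packaged as a labeled, editable set of
#' synthetic defaults with the qualitative signs established for each
#' mediator; substitute fitted coefficients for quantitative work.
#'
#' @return A list with elements `target_absorbed_mg`, `heme_absorption`,
#'   `nonheme_intercept` (log absorption at zero mediator intake), and
#'   `nonheme_coefficients` (named vector over nutrient ids).
#' @export
default_iron_model <- function() {
  list(
    target_absorbed_mg = 1.5,
    heme_absorption = 0.25,
    nonheme_intercept = log(0.25),
    nonheme_coefficients = c(
      phytate_mg   = -0.12,
      calcium_mg   = -0.05,
      vitamin_c_mg =  0.10,
      heme_iron_mg =  0.05
    )
  )
}

#' The six nutritional risk factors of the comparative risk assessment
#'
#' Low intake of polyunsaturated fat, fiber, and potassium and high intake
#' of cholesterol, sodium, and heme iron. Potassium benefits saturate: its
#' exposure is capped (default 3,500 mg/day) inside risk computations while
#' raw intake is retained everywhere else.
#'
#' @return Tibble with columns `factor` (id, equal to the nutrient id),
#'   `direction` ("protective"/"harmful"), `cap` (exposure cap in intake
#'   units, `NA` if none).
#' @export
risk_factor_definitions <- function() {
  tibble::tribble(
    ~factor,          ~direction,   ~cap,
    "pufa_g",         "protective", NA_real_,
    "fiber_g",        "protective", NA_real_,
    "potassium_mg",   "protective", 3500,
    "cholesterol_mg", "harmful",    NA_real_,
    "sodium_mg",      "harmful",    NA_real_,
    "heme_iron_mg",   "harmful",    NA_real_
  )
}

#' Default relative-risk table
#'
#' Illustrative log-linear dose-response relative risks per stated exposure
#' increment, one row per (risk factor, endpoint) pair. The default mapping
#' sends all six factors to coronary heart disease and stroke, with heme
#' iron and fiber additionally linked to cancer. Magnitudes are plausible
#' for meta-analytic estimates but are packaged defaults: load study-grade
#' values with [read_rr_table()] for substantive use.
#'
#' @return Tibble with columns `factor`, `endpoint` ("CHD"/"stroke"/
#'   "cancer"), `rr` (relative risk per increment), `increment` (exposure
#'   units of the factor's nutrient).
#' @export
default_rr_table <- function() {
  rr <- tibble::tribble(
    ~factor,          ~endpoint, ~rr,  ~increment,
    "pufa_g",         "CHD",     0.88, 10,
    "pufa_g",         "stroke",  0.98, 10,
    "fiber_g",        "CHD",     0.81, 10,
    "fiber_g",        "stroke",  0.88, 10,
    "fiber_g",        "cancer",  0.87, 10,
    "potassium_mg",   "CHD",     0.93, 1000,
    "potassium_mg",   "stroke",  0.87, 1000,
    "cholesterol_mg", "CHD",     1.13, 200,
    "cholesterol_mg", "stroke",  1.05, 200,
    "sodium_mg",      "CHD",     1.12, 1000,
    "sodium_mg",      "stroke",  1.17, 1000,
    "heme_iron_mg",   "CHD",     1.15, 1,
    "heme_iron_mg",   "cancer",  1.08, 1
  )
  validate_rr_table(rr)
}
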