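#' @importFrom stats setNames approx weighted.mean
#' @importFrom utils modifyList
NULL

# Fat-component closure tolerance: saturated + MUFA + PUFA + trans may exceed
# total fat by at most this relative amount (glycerol backbone and rounding
# slack in composition tables).
FAT_SUM_TOLERANCE <- 0.05

FOOD_CATEGORIES <- c(
  "meat", "dairy", "processed_alternative",
  "unprocessed_alternative", "other_diet_component"
)

ENDPOINTS <- c("CHD", "stroke", "cancer")

# Non-nutrient columns of the food table, in canonical on-disk order.
food_meta_columns <- function() {
  c("id", "name", "category", "serving_g", "variant",
    "ghg_kg_per_kg", "land_m2_per_kg", "water_l_per_kg",
    "ghg_processing_kg_per_kg",
    "price", "currency", "year")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_table <- function(...) stop(sprintf(...), call. = FALSE)

#' Construct and validate a food table
#'
#' The central product table: one row per food with identity, category,
#' serving size, full nutrient profile per 100 g, environmental footprints,
#' and a price observation. Footprints are accepted per kg of food (the unit
#' LCA sources report) and held per 100 g internally so every per-mass
#' quantity in the package shares the composition-table convention; the
#' writer converts back, so a write/read cycle is lossless. Serving sizes in
#' ml (liquids) are treated as g at unit density.
#'
#' @param df A data frame with columns `id`, `name`, `category`,
#'   `serving_g`, footprint columns `ghg_kg_per_kg`, `land_m2_per_kg`,
#'   `water_l_per_kg` (optional `ghg_processing_kg_per_kg`, default 0),
#'   price columns `price`, `currency`, `year`, optional `variant`, and one
#'   column per nutrient id in [nutrient_dictionary()]. No other columns are
#'   permitted.
#' @return A validated `food_table` tibble with footprints per 100 g
#'   (`ghg_kg_per_100g`, `land_m2_per_100g`, `water_l_per_100g`,
#'   `ghg_processing_kg_per_100g`).
#' @export
food_table <- function(df) {
  df <- tibble::as_tibble(df)
  nut <- nutrient_ids()
  mandatory <- setdiff(food_meta_columns(),
                       c("variant", "ghg_processing_kg_per_kg"))
  missing <- setdiff(c(mandatory, nut), names(df))
  if (length(missing) > 0)
    abort_table("food table is missing mandatory column(s): %s",
                paste(missing, collapse = ", "))
  extra <- setdiff(names(df), c(food_meta_columns(), nut))
  if (length(extra) > 0)
    abort_table(paste0(
      "food table has unknown column(s): %s. The nutrient column dictionary ",
      "is fixed; a misspelled nutrient would silently corrupt the imbalance ",
      "indicator, so extra columns are rejected."),
      paste(extra, collapse = ", "))
  if (!("variant" %in% names(df))) df$variant <- NA_character_
  df$variant <- as.character(df$variant)
  if (!("ghg_processing_kg_per_kg" %in% names(df)))
    df$ghg_processing_kg_per_kg <- 0
  df$ghg_processing_kg_per_kg[is.na(df$ghg_processing_kg_per_kg)] <- 0

  if (anyDuplicated(df$id))
    abort_table("duplicate food id(s): %s",
                paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  bad_cat <- setdiff(unique(df$category), FOOD_CATEGORIES)
  if (length(bad_cat) > 0)
    abort_table("unknown food category: %s (expected one of %s)",
                paste(bad_cat, collapse = ", "),
                paste(FOOD_CATEGORIES, collapse = ", "))
  if (any(!is.finite(df$serving_g) | df$serving_g <= 0))
    abort_table("serving size must be > 0 for: %s",
                paste(df$id[!is.finite(df$serving_g) | df$serving_g <= 0],
                      collapse = ", "))

  for (col in nut) {
    bad <- !is.finite(df[[col]]) | df[[col]] < 0
    if (any(bad))
      abort_table("negative or missing %s for food(s): %s",
                  col, paste(df$id[bad], collapse = ", "))
  }
  bad_heme <- df$heme_iron_mg > df$iron_mg + 1e-9
  if (any(bad_heme))
    abort_table("heme iron exceeds total iron for food(s): %s",
                paste(df$id[bad_heme], collapse = ", "))
  fat_sum <- df$satfat_g + df$mufa_g + df$pufa_g + df$transfat_g
  bad_fat <- fat_sum > df$fat_g * (1 + FAT_SUM_TOLERANCE) + 1e-9
  if (any(bad_fat))
    abort_table("fatty-acid components exceed total fat for food(s): %s",
                paste(df$id[bad_fat], collapse = ", "))
  for (col in c("ghg_kg_per_kg", "land_m2_per_kg", "water_l_per_kg",
                "ghg_processing_kg_per_kg")) {
    bad <- !is.finite(df[[col]]) | df[[col]] < 0
    if (any(bad))
      abort_table("footprint column %s must be >= 0 (food(s): %s)",
                  col, paste(df$id[bad], collapse = ", "))
  }
  if (any(!is.finite(df$price) | df$price < 0))
    abort_table("price must be >= 0 for: %s",
                paste(df$id[!is.finite(df$price) | df$price < 0],
                      collapse = ", "))

  out <- df
  out$ghg_kg_per_100g <- out$ghg_kg_per_kg / 10
  out$land_m2_per_100g <- out$land_m2_per_kg / 10
  out$water_l_per_100g <- out$water_l_per_kg / 10
  out$ghg_processing_kg_per_100g <- out$ghg_processing_kg_per_kg / 10
  out <- out[, c(food_meta_columns(),
                 c("ghg_kg_per_100g", "land_m2_per_100g", "water_l_per_100g",
                   "ghg_processing_kg_per_100g"),
                 nut)]
  class(out) <- c("food_table", class(tibble::tibble()))
  out
}

#' Read a food table from CSV
#'
#' @param path Path to a UTF-8 CSV with "." decimal separator and the column
#'   dictionary documented in [food_table()].
#' @return A validated `food_table`.
#' @export
read_food_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  food_table(df)
}

#' Write a food table to CSV
#'
#' Inverse of [read_food_table()]: footprints are emitted per kg, so
#' `write_food_table()` then [read_food_table()] reproduces the table to
#' full double precision.
#'
#' @param foods A `food_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_food_table <- function(foods, path) {
  stopifnot(inherits(foods, "food_table"))
  out <- tibble::as_tibble(foods)
  out$ghg_kg_per_kg <- out$ghg_kg_per_100g * 10
  out$land_m2_per_kg <- out$land_m2_per_100g * 10
  out$water_l_per_kg <- out$water_l_per_100g * 10
  out$ghg_processing_kg_per_kg <- out$ghg_processing_kg_per_100g * 10
  out <- out[, c(food_meta_columns(), nutrient_ids())]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

lookup_food <- function(foods, id) {
  i <- match(id, foods$id)
  if (any(is.na(i)))
    abort_table("food id(s) not found in food table: %s",
                paste(id[is.na(i)], collapse = ", "))
  foods[i, , drop = FALSE]
}

#' Construct a dietary intake table
#'
#' Region-level consumption in g/person/day per food group, assumed already
#' adjusted for household-level food waste (set `waste_adjusted = FALSE` to
#' record that the adjustment has not been applied; the flag is carried, not
#' acted on).
#'
#' @param df Data frame with columns `region`, `food_id`, `intake_g_day`,
#'   optional logical `waste_adjusted` (default `TRUE`).
#' @param foods Optional `food_table` for referential-integrity checking.
#' @return A validated `diet_table` tibble.
#' @export
diet_table <- function(df, foods = NULL) {
  df <- tibble::as_tibble(df)
  missing <- setdiff(c("region", "food_id", "intake_g_day"), names(df))
  if (length(missing) > 0)
    abort_table("diet table missing column(s): %s",
                paste(missing, collapse = ", "))
  if (!("waste_adjusted" %in% names(df))) df$waste_adjusted <- TRUE
  if (any(!is.finite(df$intake_g_day) | df$intake_g_day < 0))
    abort_table("diet intakes must be finite and >= 0")
  if (anyDuplicated(df[, c("region", "food_id")]))
    abort_table("duplicate (region, food_id) rows in diet table")
  if (!is.null(foods)) {
    unknown <- setdiff(unique(df$food_id), foods$id)
    if (length(unknown) > 0)
      abort_table("diet references unknown food id(s): %s",
                  paste(unknown, collapse = ", "))
  }
  class(df) <- c("diet_table", class(tibble::tibble()))
  df
}

#' @rdname diet_table
#' @param path CSV path.
#' @export
read_diet_table <- function(path, foods = NULL) {
  diet_table(readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
             foods = foods)
}

#' @rdname diet_table
#' @export
write_diet_table <- function(df, path) {
  readr::write_csv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}

diet_for_region <- function(diets, region) {
  out <- diets[diets$region == region, , drop = FALSE]
  if (nrow(out) == 0)
    abort_table("no dietary intake rows for region '%s'", region)
  out
}

validate_recommendations <- function(rec) {
  rec <- tibble::as_tibble(rec)
  missing <- setdiff(c("nutrient", "direction", "daily_value"), names(rec))
  if (length(missing) > 0)
    abort_table("recommendation table missing column(s): %s",
                paste(missing, collapse = ", "))
  if (!("source" %in% names(rec))) rec$source <- NA_character_
  if (!("special_handler" %in% names(rec))) rec$special_handler <- "none"
  unknown <- setdiff(rec$nutrient, nutrient_ids())
  if (length(unknown) > 0)
    abort_table("recommendation for unknown nutrient(s): %s",
                paste(unknown, collapse = ", "))
  if ("calcium_mg" %in% rec$nutrient)
    abort_table(paste0(
      "calcium must not carry a recommendation: reference values based on ",
      "balance studies of current intake are excluded from the imbalance ",
      "comparison"))
  if (anyDuplicated(rec$nutrient))
    abort_table("duplicate recommendation for nutrient(s): %s",
                paste(unique(rec$nutrient[duplicated(rec$nutrient)]),
                      collapse = ", "))
  if (!all(rec$direction %in% c("minimum", "maximum")))
    abort_table("recommendation direction must be 'minimum' or 'maximum'")
  if (any(!is.finite(rec$daily_value) | rec$daily_value <= 0))
    abort_table("recommendation daily_value must be > 0 (nutrient(s): %s)",
                paste(rec$nutrient[!is.finite(rec$daily_value) |
                                     rec$daily_value <= 0], collapse = ", "))
  if (!all(rec$special_handler %in% c("none", "zinc_phytate",
                                      "iron_absorption")))
    abort_table("unknown special_handler value in recommendation table")
  rec[, c("nutrient", "direction", "daily_value", "source",
          "special_handler")]
}

#' Read / write a nutrient recommendation table
#'
#' @param path CSV with columns `nutrient`, `direction`, `daily_value`,
#'   optional `source` and `special_handler`.
#' @return Validated tibble (see [default_recommendations()]).
#' @export
read_recommendation_table <- function(path) {
  validate_recommendations(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname read_recommendation_table
#' @param rec Recommendation tibble.
#' @export
write_recommendation_table <- function(rec, path) {
  readr::write_csv(tibble::as_tibble(rec), path, progress = FALSE)
  invisible(path)
}

validate_rr_table <- function(rr, risk_factors = risk_factor_definitions()) {
  rr <- tibble::as_tibble(rr)
  missing <- setdiff(c("factor", "endpoint", "rr", "increment"), names(rr))
  if (length(missing) > 0)
    abort_table("relative-risk table missing column(s): %s",
                paste(missing, collapse = ", "))
  unknown <- setdiff(rr$factor, risk_factors$factor)
  if (length(unknown) > 0)
    abort_table("relative risk for unknown risk factor(s): %s",
                paste(unknown, collapse = ", "))
  if (!all(rr$endpoint %in% ENDPOINTS))
    abort_table("relative-risk endpoint must be one of %s",
                paste(ENDPOINTS, collapse = ", "))
  if (anyDuplicated(rr[, c("factor", "endpoint")]))
    abort_table("duplicate (factor, endpoint) rows in relative-risk table")
  if (any(!is.finite(rr$rr) | rr$rr <= 0))
    abort_table("relative risks must be > 0")
  if (any(!is.finite(rr$increment) | rr$increment == 0))
    abort_table("relative-risk increments must be nonzero")
  dir <- risk_factors$direction[match(rr$factor, risk_factors$factor)]
  inconsistent <- (dir == "protective" & rr$rr >= 1 & rr$increment > 0) |
    (dir == "harmful" & rr$rr <= 1 & rr$increment > 0)
  if (any(inconsistent))
    warning(sprintf(
      "relative risk inconsistent with factor direction for: %s",
      paste(sprintf("%s/%s", rr$factor[inconsistent],
                    rr$endpoint[inconsistent]), collapse = ", ")),
      call. = FALSE)
  rr
}

#' Read a relative-risk table
#' @param path CSV with columns `factor`, `endpoint`, `rr`, `increment`.
#' @param risk_factors Risk-factor definitions used for validation.
#' @return Validated tibble (see [default_rr_table()]).
#' @export
read_rr_table <- function(path, risk_factors = risk_factor_definitions()) {
  validate_rr_table(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    risk_factors)
}

validate_mortality <- function(m) {
  m <- tibble::as_tibble(m)
  needed <- c("region", "population", "deaths_CHD", "deaths_stroke",
              "deaths_cancer", "deaths_all")
  missing <- setdiff(needed, names(m))
  if (length(missing) > 0)
    abort_table("mortality table missing column(s): %s",
                paste(missing, collapse = ", "))
  num <- setdiff(needed, "region")
  for (col in num)
    if (any(!is.finite(m[[col]]) | m[[col]] < 0))
      abort_table("mortality column %s must be finite and >= 0", col)
  cause_sum <- m$deaths_CHD + m$deaths_stroke + m$deaths_cancer
  if (any(cause_sum > m$deaths_all + 1e-6))
    abort_table("cause-specific deaths exceed all-cause deaths for region: %s",
                paste(m$region[cause_sum > m$deaths_all + 1e-6],
                      collapse = ", "))
  m[, needed]
}

#' Read a mortality table
#'
#' One row per region with population and cause-specific death counts for
#' coronary heart disease, stroke, cancer, and all causes.
#'
#' @param path CSV with columns `region`, `population`, `deaths_CHD`,
#'   `deaths_stroke`, `deaths_cancer`, `deaths_all`.
#' @return Validated tibble.
#' @export
read_mortality_table <- function(path) {
  validate_mortality(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

validate_series <- function(s, what) {
  s <- tibble::as_tibble(s)
  missing <- setdiff(c("entity", "year", "value"), names(s))
  if (length(missing) > 0)
    abort_table("%s series missing column(s): %s", what,
                paste(missing, collapse = ", "))
  if (any(!is.finite(s$value) | s$value <= 0))
    abort_table("%s series values must be > 0", what)
  if (anyDuplicated(s[, c("entity", "year")]))
    abort_table("duplicate (entity, year) rows in %s series", what)
  s[, c("entity", "year", "value")]
}

#' Read a long-format CPI or PPP series
#'
#' Both series share the layout `entity` (currency or country code),
#' `year`, `value`. For CPI the value is the food consumer price index;
#' for PPP it is local currency units per international dollar.
#'
#' @param path CSV path.
#' @return Validated tibble.
#' @export
read_cpi_series <- function(path) {
  validate_series(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE), "CPI")
}

#' @rdname read_cpi_series
#' @export
read_ppp_series <- function(path) {
  validate_series(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE), "PPP")
}

#' Load an analysis configuration
#'
#' Reads a YAML configuration holding regions, the synthesis weighting tree,
#' the replacement-scenario list, the comparison basis, and the seed, and
#' fills package defaults for anything omitted. Weight levels must each sum
#' to 1.
#'
#' @param path YAML file path.
#' @param foods Optional `food_table`; when supplied every food id named in
#'   a scenario must resolve.
#' @return A list of class `swap_config` with elements `regions`, `basis`,
#'   `weights` (a [synthesis_weights()] object), `scenarios` (list of
#'   [replacement_scenario()] objects), `seed`.
#' @export
load_config <- function(path, foods = NULL) {
  raw <- yaml::read_yaml(path)
  build_config(raw, foods = foods)
}

build_config <- function(raw, foods = NULL) {
  raw <- raw %||% list()
  w <- raw$weights %||% list()
  weights <- synthesis_weights(
    top = unlist(w$top %||% NULL) %||% NULL,
    health = unlist(w$health %||% NULL) %||% NULL,
    environment = unlist(w$environment %||% NULL) %||% NULL
  )
  scenarios <- lapply(raw$scenarios %||% list(), function(s) {
    replacement_scenario(
      id = s$id,
      region = s$region %||% (raw$regions[[1]] %||% "HIC"),
      replace = s$replace,
      with = s$with,
      basis = s$basis %||% (raw$basis %||% "calorie"),
      sodium_addon_mg_per_100g = s$sodium_addon_mg_per_100g %||% 0,
      processing_emissions = isTRUE(s$processing_emissions),
      potassium_cap = s$potassium_cap %||% NULL
    )
  })
  if (!is.null(foods)) {
    for (s in scenarios) {
      unknown <- setdiff(unlist(s$with), foods$id)
      if (length(unknown) > 0)
        abort_table("scenario '%s' references unknown food id(s): %s",
                    s$id, paste(unknown, collapse = ", "))
    }
  }
  structure(list(
    regions = as.character(raw$regions %||% "HIC"),
    basis = raw$basis %||% "calorie",
    weights = weights,
    scenarios = scenarios,
    seed = as.integer(raw$seed %||% 1L)
  ), class = "swap_config")
}

#' Assemble an input bundle
#'
#' A bundle is the complete set of inputs one analysis run needs: foods,
#' regional diets, nutrient recommendations (plus the zinc reference table
#' and iron absorption model backing their special handlers), risk-factor
#' definitions and relative risks, mortality, and CPI/PPP series. All
#' referential-integrity checks run at construction.
#'
#' @param foods `food_table`.
#' @param diets `diet_table`.
#' @param recommendations Recommendation tibble.
#' @param rr_table Relative-risk tibble.
#' @param mortality Mortality tibble.
#' @param cpi,ppp Long-format series tibbles.
#' @param zinc_reference Phytate/zinc reference table.
#' @param iron_model Iron absorption model list.
#' @param risk_factors Risk-factor definition tibble.
#' @param weights [synthesis_weights()] object.
#' @return A list of class `swap_bundle`.
#' @export
swap_bundle <- function(foods, diets, recommendations = default_recommendations(),
                        rr_table = default_rr_table(),
                        mortality,
                        cpi, ppp,
                        zinc_reference = default_zinc_reference(),
                        iron_model = default_iron_model(),
                        risk_factors = risk_factor_definitions(),
                        weights = synthesis_weights()) {
  stopifnot(inherits(foods, "food_table"))
  diets <- diet_table(diets, foods = foods)
  structure(list(
    foods = foods,
    diets = diets,
    recommendations = validate_recommendations(recommendations),
    rr_table = validate_rr_table(rr_table, risk_factors),
    mortality = validate_mortality(mortality),
    cpi = validate_series(cpi, "CPI"),
    ppp = validate_series(ppp, "PPP"),
    zinc_reference = tibble::as_tibble(zinc_reference),
    iron_model = iron_model,
    risk_factors = tibble::as_tibble(risk_factors),
    weights = weights
  ), class = "swap_bundle")
}

#' Write / read a bundle directory
#'
#' Persists every bundle table as tidy CSV (plus a small YAML for the iron
#' model and weights) and reads it back with full validation. Write-then-read
#' reproduces all values to full double precision.
#'
#' @param bundle A `swap_bundle`.
#' @param dir Directory path (created if needed).
#' @return `dir` (write) or a `swap_bundle` (read).
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "swap_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_food_table(bundle$foods, p("foods.csv"))
  write_diet_table(bundle$diets, p("diets.csv"))
  write_recommendation_table(bundle$recommendations, p("recommendations.csv"))
  readr::write_csv(bundle$rr_table, p("relative_risks.csv"), progress = FALSE)
  readr::write_csv(bundle$mortality, p("mortality.csv"), progress = FALSE)
  readr::write_csv(bundle$cpi, p("cpi.csv"), progress = FALSE)
  readr::write_csv(bundle$ppp, p("ppp.csv"), progress = FALSE)
  readr::write_csv(bundle$zinc_reference, p("zinc_reference.csv"),
                   progress = FALSE)
  readr::write_csv(bundle$risk_factors, p("risk_factors.csv"),
                   progress = FALSE)
  # numbers serialized as full-precision strings: YAML float emission
  # truncates significant digits, which would break round-trip fidelity
  num <- function(x) {
    out <- lapply(unname(x), function(v) format(v, digits = 17))
    if (!is.null(names(x))) names(out) <- names(x)
    out
  }
  yaml::write_yaml(list(
    iron_model = list(
      target_absorbed_mg = num(bundle$iron_model$target_absorbed_mg),
      heme_absorption = num(bundle$iron_model$heme_absorption),
      nonheme_intercept = num(bundle$iron_model$nonheme_intercept),
      nonheme_coefficients = num(bundle$iron_model$nonheme_coefficients)
    ),
    weights = list(
      top = num(bundle$weights$top),
      health = num(bundle$weights$health),
      environment = num(bundle$weights$environment)
    )
  ), p("bundle.yaml"))
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  meta <- yaml::read_yaml(p("bundle.yaml"))
  denum <- function(x) {
    out <- vapply(x, function(v) as.numeric(v[[1]]), numeric(1))
    if (length(out) == 1 && is.null(names(x))) unname(out) else out
  }
  im <- meta$iron_model
  foods <- read_food_table(p("foods.csv"))
  rf <- readr::read_csv(p("risk_factors.csv"), show_col_types = FALSE,
                        progress = FALSE)
  swap_bundle(
    foods = foods,
    diets = read_diet_table(p("diets.csv"), foods = foods),
    recommendations = read_recommendation_table(p("recommendations.csv")),
    rr_table = read_rr_table(p("relative_risks.csv"), rf),
    mortality = read_mortality_table(p("mortality.csv")),
    cpi = read_cpi_series(p("cpi.csv")),
    ppp = read_ppp_series(p("ppp.csv")),
    zinc_reference = readr::read_csv(p("zinc_reference.csv"),
                                     show_col_types = FALSE, progress = FALSE),
    iron_model = list(
      target_absorbed_mg = denum(im$target_absorbed_mg),
      heme_absorption = denum(im$heme_absorption),
      nonheme_intercept = denum(im$nonheme_intercept),
      nonheme_coefficients = denum(im$nonheme_coefficients)
    ),
    risk_factors = rf,
    weights = synthesis_weights(
      top = denum(meta$weights$top),
      health = denum(meta$weights$health),
      environment = denum(meta$weights$environment)
    )
  )
}
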