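series_value <- function(series, entity, year, what) {
  row <- series[series$entity == entity & series$year == year, ]
  if (nrow(row) == 0)
    abort_table("%s value missing for entity '%s', year %s", what, entity,
                year)
  row$value[1]
}

#' Deflate a price to a base year with a CPI series
#'
#' `price * CPI(base_year) / CPI(year)`. Deflating and re-inflating with the
#' same series is the identity.
#'
#' @param price Observed price.
#' @param year Observation year.
#' @param cpi_series Long-format CPI tibble (`entity`, `year`, `value`).
#' @param entity CPI series entity (currency or country code).
#' @param base_year Target year (default 2020).
#' @return Price expressed at the base year's price level.
#' @export
deflate_to_base_year <- function(price, year, cpi_series, entity,
                                 base_year = 2020) {
  price * series_value(cpi_series, entity, base_year, "CPI") /
    series_value(cpi_series, entity, year, "CPI")
}

#' Convert a local-currency price to international dollars
#'
#' Divides by the PPP rate (local currency units per international dollar),
#' which controls for price-level differences across countries.
#'
#' @param price_local Price in local currency.
#' @param ppp_rate PPP conversion factor (> 0).
#' @return Price in international dollars.
#' @export
to_international_dollars <- function(price_local, ppp_rate) {
  if (any(!is.finite(ppp_rate) | ppp_rate <= 0))
    abort_table("PPP rate must be > 0")
  price_local / ppp_rate
}

#' Harmonize food prices to international dollars at a base year
#'
#' For each price observation: deflate to the base year with the CPI series
#' of its currency, then convert with the base-year PPP rate. When a food
#' has several observations, the mean of the harmonized values is used.
#' Full provenance (source year, currency, CPI factor, PPP rate) is kept.
#'
#' @param foods A `food_table` (each row carries one observation: `price`,
#'   `currency`, `year`), or a long price tibble with columns `food_id`,
#'   `price`, `currency`, `year`.
#' @param cpi_series,ppp_series Long-format series tibbles.
#' @param base_year Common price year (default 2020).
#' @return Tibble `food_id`, `price_intl_per_kg`, `n_observations`, and a
#'   `provenance` list-column of per-observation detail.
#' @export
harmonize_prices <- function(foods, cpi_series, ppp_series,
                             base_year = 2020) {
  obs <- if (inherits(foods, "food_table")) {
    tibble::tibble(food_id = foods$id, price = foods$price,
                   currency = foods$currency, year = foods$year)
  } else {
    tibble::as_tibble(foods)
  }
  harmonize_one <- function(i) {
    cpi_base <- series_value(cpi_series, obs$currency[i], base_year, "CPI")
    cpi_year <- series_value(cpi_series, obs$currency[i], obs$year[i], "CPI")
    ppp <- series_value(ppp_series, obs$currency[i], base_year, "PPP")
    deflated <- obs$price[i] * cpi_base / cpi_year
    tibble::tibble(
      food_id = obs$food_id[i],
      price_intl = to_international_dollars(deflated, ppp),
      source_year = obs$year[i], currency = obs$currency[i],
      cpi_factor = cpi_base / cpi_year, ppp_rate = ppp)
  }
  detail <- dplyr::bind_rows(lapply(seq_len(nrow(obs)), harmonize_one))
  out <- dplyr::summarise(
    dplyr::group_by(detail, .data$food_id),
    price_intl_per_kg = mean(.data$price_intl),
    n_observations = dplyr::n(), .groups = "drop")
  out$provenance <- lapply(out$food_id, function(id)
    detail[detail$food_id == id,
           c("price_intl", "source_year", "currency", "cpi_factor",
             "ppp_rate")])
  out
}

#' Cost of a food on a chosen basis
#'
#' Per serving (`per_kg * serving_g / 1000`), per 1000 kcal
#' (`per_kg / kcal_per_kg * 1000`), or per kg.
#'
#' @param food Single-row food table (provides serving size and energy).
#' @param price_intl_per_kg Harmonized price, int$/kg.
#' @param basis `"serving"`, `"calorie"` (per 1000 kcal), or `"weight"`.
#' @return Cost in international dollars on the basis.
#' @export
cost_per_basis <- function(food, price_intl_per_kg,
                           basis = c("serving", "calorie", "weight")) {
  basis <- match.arg(basis)
  switch(basis,
    weight = price_intl_per_kg,
    serving = price_intl_per_kg * food$serving_g / 1000,
    calorie = {
      if (food$energy_kcal <= 0)
        abort_table("food '%s' has zero energy density: calorie basis undefined",
                    food$id)
      kcal_per_kg <- food$energy_kcal * 10
      price_intl_per_kg / kcal_per_kg * 1000
    })
}

#' Daily cost of a diet
#'
#' `sum_f grams_f / 1000 * price_per_kg(f)` in international dollars per
#' person per day; linear in quantities.
#'
#' @param diet Single-region `diet_table`.
#' @param harmonized_prices Output of [harmonize_prices()] (or any tibble
#'   with `food_id`, `price_intl_per_kg`) covering every consumed food.
#' @return Scalar cost, int$/person/day.
#' @export
diet_cost <- function(diet, harmonized_prices) {
  if (nrow(diet) == 0) return(0)
  i <- match(diet$food_id, harmonized_prices$food_id)
  if (any(is.na(i)))
    abort_table("no harmonized price for food id(s): %s",
                paste(diet$food_id[is.na(i)], collapse = ", "))
  sum(diet$intake_g_day / 1000 * harmonized_prices$price_intl_per_kg[i])
}

#' Cost change of a replacement diet
#'
#' @param baseline_cost,scenario_cost Daily diet costs ([diet_cost()]).
#' @return Signed percentage change vs. baseline.
#' @export
replacement_cost_change <- function(baseline_cost, scenario_cost) {
  if (!is.finite(baseline_cost) || baseline_cost <= 0)
    abort_table("baseline diet cost must be > 0")
  100 * (scenario_cost - baseline_cost) / baseline_cost
}
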