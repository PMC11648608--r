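#' Risk-factor exposures of a diet
#'
#' Daily intakes of the six nutrient risk factors (PUFA g, fiber g,
#' potassium mg, cholesterol mg, sodium mg, heme iron mg). Raw exposures
#' are returned; the potassium cap is applied only inside risk computation
#' (see [apply_exposure_caps()]).
#'
#' @inheritParams nutrient_intake
#' @param risk_factors Risk-factor definition tibble.
#' @param sodium_addon_mg Optional extra sodium (mg/day) added to the
#'   exposure, used by the added-sodium sensitivity on unprocessed
#'   alternatives.
#' @return Named numeric vector over the six factor ids.
#' @export
exposure_from_diet <- function(diet, foods,
                               risk_factors = risk_factor_definitions(),
                               sodium_addon_mg = 0) {
  intakes <- nutrient_intake(diet, foods)
  exp <- intakes[risk_factors$factor]
  exp[is.na(exp)] <- 0
  if ("sodium_mg" %in% names(exp))
    exp[["sodium_mg"]] <- exp[["sodium_mg"]] + sodium_addon_mg
  exp
}

#' Apply exposure caps
#'
#' Caps exposures where the risk-factor definition carries one (potassium
#' at 3,500 mg/day by default): protective benefits saturate, so intake
#' beyond the cap produces no further risk reduction.
#'
#' @param exposure Named exposure vector.
#' @param risk_factors Risk-factor definition tibble (its `cap` column may
#'   be overridden to run cap sensitivities).
#' @return Capped exposure vector.
#' @export
apply_exposure_caps <- function(exposure,
                                risk_factors = risk_factor_definitions()) {
  for (i in seq_len(nrow(risk_factors))) {
    f <- risk_factors$factor[i]
    cap <- risk_factors$cap[i]
    if (!is.na(cap) && f %in% names(exposure))
      exposure[[f]] <- min(exposure[[f]], cap)
  }
  exposure
}

rr_entry <- function(rr_table, factor, endpoint) {
  row <- rr_table[rr_table$factor == factor & rr_table$endpoint == endpoint, ]
  if (nrow(row) == 0)
    abort_table("no relative risk for factor '%s' and endpoint '%s'",
                factor, endpoint)
  row
}

#' Relative risk of an exposure shift
#'
#' Log-linear dose-response: the per-increment relative risk compounds with
#' exposure, `RR_shift = RR_unit ^ (delta / increment)`. Deltas are taken
#' after any exposure caps.
#'
#' @param factor Risk-factor id.
#' @param endpoint `"CHD"`, `"stroke"`, or `"cancer"`.
#' @param delta_exposure Exposure change in the factor's intake units.
#' @param rr_table Relative-risk tibble.
#' @return RR multiplier (> 0).
#' @export
relative_risk_for_shift <- function(factor, endpoint, delta_exposure,
                                    rr_table = default_rr_table()) {
  row <- rr_entry(rr_table, factor, endpoint)
  if (row$increment == 0) abort_table("zero relative-risk increment")
  row$rr ^ (delta_exposure / row$increment)
}

# Product of per-factor RR shifts for one endpoint, exposure relative to a
# reference. Factors without an RR entry for this endpoint do not contribute.
combined_rr <- function(exposure, reference, rr_table, endpoint,
                        risk_factors = risk_factor_definitions()) {
  exposure <- apply_exposure_caps(exposure, risk_factors)
  reference <- apply_exposure_caps(reference, risk_factors)
  sub <- rr_table[rr_table$endpoint == endpoint, ]
  rr <- 1
  for (i in seq_len(nrow(sub))) {
    f <- sub$factor[i]
    delta <- (exposure[[f]] %||% 0) - (reference[[f]] %||% 0)
    rr <- rr * sub$rr[i] ^ (delta / sub$increment[i])
  }
  if (!is.finite(rr) || rr <= 0) abort_table("nonpositive combined RR")
  rr
}

#' Population impact fraction
#'
#' The proportion of cases of one endpoint avoided when population exposure
#' shifts from baseline to scenario:
#' `PIF = (RR_base - RR_scen) / RR_base`, with each RR the product of
#' per-factor log-linear shifts against a common reference. The reference
#' cancels in the ratio; the baseline exposure is used as reference for
#' numerical stability, so `RR_base = 1` exactly. Positive PIF means
#' deaths averted.
#'
#' @param baseline,scenario Named exposure vectors ([exposure_from_diet()]).
#' @param rr_table Relative-risk tibble.
#' @param endpoint Disease endpoint.
#' @param risk_factors Risk-factor definitions (caps applied inside).
#' @return Scalar PIF in (-Inf, 1].
#' @export
pif <- function(baseline, scenario, rr_table = default_rr_table(),
                endpoint = "CHD",
                risk_factors = risk_factor_definitions()) {
  rr_base <- combined_rr(baseline, baseline, rr_table, endpoint, risk_factors)
  rr_scen <- combined_rr(scenario, baseline, rr_table, endpoint, risk_factors)
  (rr_base - rr_scen) / rr_base
}

#' Attributable deaths averted by an exposure shift
#'
#' Applies endpoint-specific PIFs to cause-specific death counts:
#' `averted_c = PIF_c * deaths_c`. The all-cause percentage is the share of
#' total deaths averted among all-cause deaths; `mortality_change_pct` is
#' its negative (a favorable scenario shows a negative change, matching the
#' sign convention of the other assessment domains).
#'
#' @param pif_by_endpoint Named numeric, e.g. `c(CHD=, stroke=, cancer=)`.
#' @param mortality One-region row of a mortality table.
#' @return List: `by_cause` tibble (endpoint, pif, deaths, averted),
#'   `total_averted`, `pct_of_all_cause_averted`, `mortality_change_pct`.
#' @export
attributable_deaths <- function(pif_by_endpoint, mortality) {
  mortality <- validate_mortality(mortality)
  if (nrow(mortality) != 1)
    abort_table("attributable_deaths() expects a single-region mortality row")
  eps <- names(pif_by_endpoint)
  missing <- setdiff(eps, ENDPOINTS)
  if (length(missing) > 0)
    abort_table("unknown endpoint(s): %s", paste(missing, collapse = ", "))
  deaths <- setNames(as.numeric(
    mortality[1, paste0("deaths_", eps)]), eps)
  averted <- unlist(pif_by_endpoint) * deaths
  total <- sum(averted)
  pct <- 100 * total / mortality$deaths_all
  list(
    by_cause = tibble::tibble(endpoint = eps,
                              pif = as.numeric(pif_by_endpoint),
                              deaths = deaths, averted = as.numeric(averted)),
    total_averted = total,
    pct_of_all_cause_averted = pct,
    mortality_change_pct = -pct
  )
}

#' Per-serving overall disease-risk change of a food
#'
#' Exposure change of one serving of `food` relative to one serving of a
#' benchmark food (`mode = "swap"`) or relative to nothing (`mode = "add"`,
#' the food added on top of the current diet). Per-endpoint RR shifts are
#' combined into a single overall percentage change by weighting endpoints
#' with their shares of cause-specific deaths in the reference region:
#' `100 * sum_e w_e * (RR_e - 1)`.
#'
#' @param food,benchmark_food Single-row food tables ([lookup_food()] on a
#'   `food_table`); `benchmark_food` ignored in `"add"` mode.
#' @param rr_table Relative-risk tibble.
#' @param mortality Single-region mortality row providing endpoint weights.
#' @param mode `"swap"` or `"add"`.
#' @param risk_factors Risk-factor definitions.
#' @return List: `risk_change_pct` (negative = risk reduction), `mode`,
#'   `by_endpoint` tibble (endpoint, rr, weight).
#' @export
per_serving_risk_change <- function(food, benchmark_food = NULL,
                                    rr_table = default_rr_table(),
                                    mortality,
                                    mode = c("swap", "add"),
                                    risk_factors = risk_factor_definitions()) {
  mode <- match.arg(mode)
  mortality <- validate_mortality(mortality)
  if (nrow(mortality) != 1)
    abort_table("per_serving_risk_change() expects one mortality row")
  serving_exposure <- function(f) {
    setNames(vapply(risk_factors$factor, function(n)
      f[[n]] * f$serving_g / 100, numeric(1)), risk_factors$factor)
  }
  exp_food <- serving_exposure(food)
  exp_ref <- if (mode == "swap") {
    if (is.null(benchmark_food))
      abort_table("swap mode requires a benchmark food")
    serving_exposure(benchmark_food)
  } else {
    setNames(rep(0, nrow(risk_factors)), risk_factors$factor)
  }
  eps <- intersect(ENDPOINTS, unique(rr_table$endpoint))
  deaths <- setNames(as.numeric(mortality[1, paste0("deaths_", eps)]), eps)
  if (sum(deaths) <= 0) abort_table("endpoint death shares unavailable")
  w <- deaths / sum(deaths)
  rr <- vapply(eps, function(e)
    combined_rr(exp_food, exp_ref, rr_table, e, risk_factors), numeric(1))
  list(
    risk_change_pct = 100 * sum(w * (rr - 1)),
    mode = mode,
    by_endpoint = tibble::tibble(endpoint = eps, rr = as.numeric(rr),
                                 weight = as.numeric(w))
  )
}

#' Decompose a risk change into per-factor shares
#'
#' Each factor's share of the total change is its absolute summed
#' log-relative-risk shift across endpoints relative to the sum over all
#' factors; shares are nonnegative and sum to 100%.
#'
#' @param delta_exposures Named exposure-change vector (after caps, in the
#'   factors' intake units).
#' @param rr_table Relative-risk tibble.
#' @return Tibble `factor`, `dlog_rr`, `share_pct`.
#' @export
risk_change_decomposition <- function(delta_exposures,
                                      rr_table = default_rr_table()) {
  factors <- unique(rr_table$factor)
  dlog <- vapply(factors, function(f) {
    sub <- rr_table[rr_table$factor == f, ]
    sum(log(sub$rr) * (delta_exposures[[f]] %||% 0) / sub$increment)
  }, numeric(1))
  denom <- sum(abs(dlog))
  if (denom == 0) abort_table("all exposure deltas are zero")
  tibble::tibble(factor = factors, dlog_rr = as.numeric(dlog),
                 share_pct = as.numeric(100 * abs(dlog) / denom))
}
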