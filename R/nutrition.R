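#' Daily nutrient intake of a diet
#'
#' Pairs per-food-group consumption (g/person/day) with nutrient densities
#' (per 100 g): `intake(n) = sum_f grams_f / 100 * profile_f(n)`. Energy is
#' returned in kcal/day.
#'
#' @param diet A `diet_table` restricted to one region (an error otherwise).
#' @param foods A `food_table` covering every consumed food.
#' @return Named numeric vector over [nutrient_ids()].
#' @export
nutrient_intake <- function(diet, foods) {
  if (nrow(diet) > 0 && length(unique(diet$region)) > 1)
    abort_table("nutrient_intake() expects a single-region diet")
  nut <- nutrient_ids()
  if (nrow(diet) == 0) return(setNames(rep(0, length(nut)), nut))
  prof <- lookup_food(foods, diet$food_id)
  mat <- as.matrix(tibble::as_tibble(prof)[, nut])
  setNames(as.numeric(colSums(mat * diet$intake_g_day / 100)), nut)
}

#' Classify a nutrient source by per-serving density
#'
#' A food is a "high" source of a nutrient when one serving carries at least
#' 20% of the daily recommended intake, a "good" source at 10 to <20%, and
#' "none" below that.
#'
#' @param density Numeric fraction(s) of daily recommended intake per
#'   serving (>= 0).
#' @return Factor with levels `none`, `good`, `high`.
#' @export
classify_source <- function(density) {
  if (any(!is.finite(density) | density < 0))
    abort_table("nutrient density must be finite and >= 0")
  cls <- ifelse(density >= 0.20, "high",
                ifelse(density >= 0.10, "good", "none"))
  factor(cls, levels = c("none", "good", "high"))
}

#' Per-serving nutrient densities
#'
#' Fraction of the daily recommended intake contained in one serving, for
#' every (food, recommended nutrient) pair, with the good/high source
#' classification. Nutrients without recommendations are omitted.
#'
#' @param foods A `food_table`.
#' @param recommendations Recommendation tibble (daily values as given; no
#'   diet-dependent special handling, which only applies at diet level).
#' @return Tidy tibble `food_id`, `nutrient`, `per_serving`, `density`,
#'   `class`.
#' @export
nutrient_density <- function(foods, recommendations = default_recommendations()) {
  rec <- validate_recommendations(recommendations)
  out <- lapply(seq_len(nrow(rec)), function(i) {
    n <- rec$nutrient[i]
    per_serving <- foods[[n]] * foods$serving_g / 100
    tibble::tibble(
      food_id = foods$id, nutrient = n,
      per_serving = per_serving,
      density = per_serving / rec$daily_value[i]
    )
  })
  out <- dplyr::bind_rows(out)
  out$class <- classify_source(out$density)
  out
}

#' Phytate-adjusted zinc requirement
#'
#' Linearly interpolates the daily zinc requirement between tabulated
#' phytate intake levels, clamped at the table ends. The reference table
#' must be strictly increasing in phytate and nondecreasing in requirement.
#'
#' @param phytate_intake_mg Dietary phytate, mg/day.
#' @param reference_table Tibble with columns `phytate_mg`, `zinc_mg`.
#' @return Daily zinc requirement, mg.
#' @export
zinc_requirement <- function(phytate_intake_mg,
                             reference_table = default_zinc_reference()) {
  tab <- tibble::as_tibble(reference_table)
  if (nrow(tab) < 1) abort_table("zinc reference table is empty")
  if (is.unsorted(tab$phytate_mg, strictly = TRUE))
    abort_table("zinc reference table must be strictly increasing in phytate")
  if (is.unsorted(tab$zinc_mg))
    abort_table("zinc requirement must be nondecreasing in phytate")
  if (nrow(tab) == 1) return(rep(tab$zinc_mg, length(phytate_intake_mg)))
  approx(tab$phytate_mg, tab$zinc_mg, xout = phytate_intake_mg,
         rule = 2)$y
}

#' Absorption-adjusted iron requirement
#'
#' The requirement is the target absorbed iron divided by the diet's
#' absorption fraction, blending the constant heme absorption rate with a
#' nonheme rate that is log-linear in dietary mediators (see
#' [default_iron_model()]). Blend weights are the heme/nonheme shares of
#' total dietary iron; an all-nonheme diet uses the nonheme rate alone.
#'
#' @param intakes Named daily-intake vector (as from [nutrient_intake()]);
#'   mediators are read from it by nutrient id.
#' @param model Absorption model list (see [default_iron_model()]).
#' @return Daily iron requirement, mg.
#' @export
iron_requirement <- function(intakes, model = default_iron_model()) {
  a_heme <- model$heme_absorption
  if (!is.finite(a_heme) || a_heme <= 0 || a_heme > 1)
    abort_table("heme absorption fraction must be in (0, 1]")
  coefs <- model$nonheme_coefficients
  med <- intakes[names(coefs)]
  med[is.na(med)] <- 0
  a_nonheme <- exp(model$nonheme_intercept + sum(coefs * log1p(med)))
  a_nonheme <- min(a_nonheme, 1)
  if (!is.finite(a_nonheme) || a_nonheme <= 0)
    abort_table("nonheme absorption fraction must be in (0, 1]")
  iron <- intakes[["iron_mg"]] %||% 0
  heme <- min(intakes[["heme_iron_mg"]] %||% 0, iron)
  heme_share <- if (iron > 0) heme / iron else 0
  a_blend <- heme_share * a_heme + (1 - heme_share) * a_nonheme
  unname(model$target_absorbed_mg / a_blend)
}

#' Resolve diet-dependent recommendations
#'
#' Replaces the daily values of recommendations flagged with a special
#' handler: `zinc_phytate` via [zinc_requirement()] on the diet's phytate
#' intake, `iron_absorption` via [iron_requirement()] on the diet's
#' mediator intakes. Requirements are diet-dependent, so this runs once per
#' scenario, before the imbalance indicator.
#'
#' @param recommendations Recommendation tibble.
#' @param intakes Named daily-intake vector of the scenario diet.
#' @param zinc_reference,iron_model Handler parameter objects.
#' @return The recommendation tibble with handler daily values resolved.
#' @export
resolve_recommendations <- function(recommendations, intakes,
                                    zinc_reference = default_zinc_reference(),
                                    iron_model = default_iron_model()) {
  rec <- validate_recommendations(recommendations)
  zi <- rec$special_handler == "zinc_phytate"
  if (any(zi))
    rec$daily_value[zi] <- zinc_requirement(
      intakes[["phytate_mg"]] %||% 0, zinc_reference)
  ir <- rec$special_handler == "iron_absorption"
  if (any(ir))
    rec$daily_value[ir] <- iron_requirement(intakes, iron_model)
  rec
}

#' Nutritional imbalance indicator
#'
#' The mean magnitude of recommendation violations over all recommended
#' nutrients, in percent: nutrients with minimum limits contribute their
#' percentage shortfall when intake falls below the recommendation,
#' nutrients with maximum limits their percentage excess when intake
#' exceeds it, and compliant nutrients contribute zero; the sum is divided
#' by the number of recommended nutrients. A diet meeting every
#' recommendation scores 0. Deviations are uncapped. Calcium never enters
#' (it carries no recommendation).
#'
#' @param intakes Named daily-intake vector ([nutrient_intake()]).
#' @param recommendations Recommendation tibble with daily values already
#'   resolved for the diet (see [resolve_recommendations()]).
#' @return A list of class `imbalance_result`: `indicator` (%), `n_rec`,
#'   and `table` with per-nutrient `intake`, `daily_value`, `direction`,
#'   `deviation_pct` (signed intake vs. recommendation), `violation_pct`
#'   (the nonnegative term entering the indicator).
#' @export
imbalance_indicator <- function(intakes, recommendations) {
  rec <- validate_recommendations(recommendations)
  intake <- intakes[rec$nutrient]
  intake[is.na(intake)] <- 0
  deviation <- 100 * (intake - rec$daily_value) / rec$daily_value
  violation <- ifelse(rec$direction == "minimum",
                      pmax(0, -deviation), pmax(0, deviation))
  structure(list(
    indicator = sum(violation) / nrow(rec),
    n_rec = nrow(rec),
    table = tibble::tibble(
      nutrient = rec$nutrient, direction = rec$direction,
      daily_value = rec$daily_value, intake = as.numeric(intake),
      deviation_pct = as.numeric(deviation),
      violation_pct = as.numeric(violation))
  ), class = "imbalance_result")
}

#' @export
print.imbalance_result <- function(x, ...) {
  cat(sprintf("Nutritional imbalance indicator: %.2f%% (over %d recommended nutrients)\n",
              x$indicator, x$n_rec))
  viol <- x$table[x$table$violation_pct > 0, ]
  if (nrow(viol) > 0) {
    cat("Violated recommendations:\n")
    for (i in seq_len(nrow(viol)))
      cat(sprintf("  %-15s %s limit, deviation %+.1f%%\n", viol$nutrient[i],
                  viol$direction[i], viol$deviation_pct[i]))
  }
  invisible(x)
}

#' Diet-level imbalance with handler resolution
#'
#' Convenience wrapper: computes intakes, resolves zinc/iron requirements
#' for this diet, and evaluates the indicator.
#'
#' @inheritParams nutrient_intake
#' @inheritParams resolve_recommendations
#' @return An `imbalance_result`.
#' @export
diet_imbalance <- function(diet, foods,
                           recommendations = default_recommendations(),
                           zinc_reference = default_zinc_reference(),
                           iron_model = default_iron_model()) {
  intakes <- nutrient_intake(diet, foods)
  rec <- resolve_recommendations(recommendations, intakes,
                                 zinc_reference, iron_model)
  imbalance_indicator(intakes, rec)
}

#' Decompose an imbalance change into per-nutrient contributions
#'
#' Each nutrient's contribution to the indicator change is the change in
#' its own violation term divided by the number of recommended nutrients
#' (in percentage points); contributions sum exactly to the total change.
#' Shares express each contribution as a percent of the total change,
#' sign-aware: shares sum to 100%, and a nutrient moving against the
#' overall direction gets a negative share.
#'
#' @param baseline,scenario `imbalance_result` objects over the same
#'   recommendation set.
#' @return Tibble `nutrient`, `contribution_pp`, `share_pct`.
#' @export
imbalance_change_decomposition <- function(baseline, scenario) {
  stopifnot(inherits(baseline, "imbalance_result"),
            inherits(scenario, "imbalance_result"))
  if (!identical(baseline$table$nutrient, scenario$table$nutrient))
    abort_table("baseline and scenario cover different nutrient sets")
  contribution <- (scenario$table$violation_pct -
                     baseline$table$violation_pct) / baseline$n_rec
  total <- sum(contribution)
  share <- if (total == 0) rep(0, length(contribution)) else
    100 * contribution / total
  tibble::tibble(
    nutrient = baseline$table$nutrient,
    contribution_pp = contribution,
    share_pct = share
  )
}
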