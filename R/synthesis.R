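#' Synthesis weighting tree
#'
#' The weights used to fold six subdomain outcomes (nutrition, mortality,
#' GHG, land, water, cost) into one 0-100 score. The top level splits evenly
#' across health, environment, and cost; the health domain splits evenly
#' between the nutritional-imbalance and mortality analyses; the
#' environmental domain uses planetary-boundary weights that emphasize GHG
#' emissions (0.65) over land (0.17) and water use (0.18), reflecting the
#' larger contribution dietary change must make to stay within the climate
#' boundary. Every level must sum to 1 (tolerance 1e-9).
#'
#' @param top Named numeric `c(health=, environment=, cost=)`.
#' @param health Named numeric `c(nutrition=, mortality=)`.
#' @param environment Named numeric `c(ghg=, land=, water=)`.
#' @return A list of class `synthesis_weights`.
#' @export
#' @examples
#' synthesis_weights()                      # main scheme
#' weight_scheme("equal_env")               # equal environmental subweights
synthesis_weights <- function(top = NULL, health = NULL, environment = NULL) {
  top <- top %||% c(health = 1 / 3, environment = 1 / 3, cost = 1 / 3)
  health <- health %||% c(nutrition = 0.5, mortality = 0.5)
  environment <- environment %||% c(ghg = 0.65, land = 0.17, water = 0.18)
  check_level <- function(w, nm, what) {
    if (is.null(names(w)) || !setequal(names(w), nm))
      abort_table("%s weights must be named %s", what,
                  paste(nm, collapse = ", "))
    w <- w[nm]
    if (abs(sum(w) - 1) > 1e-9)
      abort_table("%s weights must sum to 1 (got %.12g)", what, sum(w))
    if (any(w < 0)) abort_table("%s weights must be >= 0", what)
    w
  }
  structure(list(
    top = check_level(top, c("health", "environment", "cost"), "top-level"),
    health = check_level(health, c("nutrition", "mortality"), "health"),
    environment = check_level(environment, c("ghg", "land", "water"),
                              "environment")
  ), class = "synthesis_weights")
}

#' Preset weighting schemes
#'
#' `"main"` is the planetary-boundary scheme of [synthesis_weights()];
#' `"equal_env"` keeps the domain structure but weighs GHG, land, and water
#' equally; `"equal_all"` gives each of the six subdomains weight 1/6.
#'
#' @param scheme One of `"main"`, `"equal_env"`, `"equal_all"`.
#' @return A `synthesis_weights` object.
#' @export
weight_scheme <- function(scheme = c("main", "equal_env", "equal_all")) {
  scheme <- match.arg(scheme)
  switch(scheme,
    main = synthesis_weights(),
    equal_env = synthesis_weights(
      environment = c(ghg = 1 / 3, land = 1 / 3, water = 1 / 3)),
    equal_all = synthesis_weights(
      top = c(health = 2 / 6, environment = 3 / 6, cost = 1 / 6),
      health = c(nutrition = 0.5, mortality = 0.5),
      environment = c(ghg = 1 / 3, land = 1 / 3, water = 1 / 3))
  )
}

# Flatten the tree to one weight per subdomain (sums to 1).
subdomain_weights <- function(weights) {
  stopifnot(inherits(weights, "synthesis_weights"))
  c(
    nutrition = unname(weights$top["health"] * weights$health["nutrition"]),
    mortality = unname(weights$top["health"] * weights$health["mortality"]),
    ghg = unname(weights$top["environment"] * weights$environment["ghg"]),
    land = unname(weights$top["environment"] * weights$environment["land"]),
    water = unname(weights$top["environment"] * weights$environment["water"]),
    cost = unname(weights$top["cost"])
  )
}

#' Min-max normalize percentage changes within one domain
#'
#' Linearly rescales a set of per-food changes so the most favorable change
#' (the largest reduction, i.e. the smallest signed value) maps to 1 and the
#' least favorable to 0: `score = 1 - (x - best) / (worst - best)`. The
#' mapping is invariant to adding a constant to all changes. When all foods
#' tie (zero spread) there is no information to discriminate and every food
#' scores 1, with a warning.
#'
#' @param changes Numeric vector of signed percentage changes (negative =
#'   improvement), one per food in the normalization pool.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
normalize_changes <- function(changes) {
  if (length(changes) < 1 || any(!is.finite(changes)))
    abort_table("normalize_changes() needs finite changes")
  best <- min(changes)
  worst <- max(changes)
  if (worst == best) {
    warning("degenerate spread in normalization pool: all foods score 1",
            call. = FALSE)
    return(rep(1, length(changes)))
  }
  1 - (changes - best) / (worst - best)
}

#' Weighted 0-100 summary score
#'
#' @param normalized Named numeric with entries `nutrition`, `mortality`,
#'   `ghg`, `land`, `water`, `cost`, each in \[0, 1\].
#' @param weights A [synthesis_weights()] object.
#' @return Scalar score in \[0, 100\].
#' @export
summary_score <- function(normalized, weights = synthesis_weights()) {
  w <- subdomain_weights(weights)
  missing <- setdiff(names(w), names(normalized))
  if (length(missing) > 0)
    abort_table("summary_score() missing subdomain score(s): %s",
                paste(missing, collapse = ", "))
  100 * sum(w * unlist(normalized)[names(w)])
}

#' Rank foods by synthesis score
#'
#' Descending by score; exact ties broken lexicographically by food id so
#' the ordering is deterministic.
#'
#' @param scores Tibble with columns `food_id`, `score`.
#' @return The tibble reordered with a `rank` column added.
#' @export
rank_foods <- function(scores) {
  if (nrow(scores) < 1) abort_table("rank_foods() needs at least one score")
  ord <- order(-scores$score, scores$food_id)
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

#' Synthesize domain changes into multicriteria scores
#'
#' Takes the tidy output of [run_scenarios()] (one row per scenario and
#' domain), min-max normalizes each domain within a pool of scenarios
#' sharing the same replaced category, basis, and region (the candidate
#' alternatives plus any in-pool animal comparators), applies the weighting
#' tree, and ranks.
#'
#' @param domain_changes Tibble with columns `scenario_id`, `food_id`,
#'   `replaced`, `basis`, `region`, `domain`, `value` where `domain` is one
#'   of `nutrition_pp`, `mortality_pct`, `ghg_pct`, `land_pct`, `water_pct`,
#'   `cost_pct`.
#' @param weights A [synthesis_weights()] object.
#' @return Tibble with normalized subdomain scores, the 0-100 `score`, and
#'   `rank`, one row per scenario, ranked within each pool.
#' @export
synthesize_scores <- function(domain_changes, weights = synthesis_weights()) {
  dom_map <- c(nutrition_pp = "nutrition", mortality_pct = "mortality",
               ghg_pct = "ghg", land_pct = "land", water_pct = "water",
               cost_pct = "cost")
  dc <- tibble::as_tibble(domain_changes)
  unknown <- setdiff(unique(dc$domain), names(dom_map))
  if (length(unknown) > 0)
    abort_table("unknown domain(s) in changes: %s",
                paste(unknown, collapse = ", "))
  dc$subdomain <- dom_map[dc$domain]

  pools <- split(dc, interaction(dc$replaced, dc$basis, dc$region,
                                 drop = TRUE))
  out <- lapply(pools, function(pool) {
    wide <- tidyr::pivot_wider(
      pool[, c("scenario_id", "food_id", "replaced", "basis", "region",
               "subdomain", "value")],
      names_from = "subdomain", values_from = "value")
    needed <- unname(dom_map)
    missing <- setdiff(needed, names(wide))
    if (length(missing) > 0)
      abort_table("pool '%s/%s' lacks domain(s): %s", wide$replaced[1],
                  wide$basis[1], paste(missing, collapse = ", "))
    for (d in needed)
      wide[[paste0("score_", d)]] <- normalize_changes(wide[[d]])
    wide$score <- vapply(seq_len(nrow(wide)), function(i) {
      summary_score(setNames(
        as.numeric(wide[i, paste0("score_", needed)]), needed), weights)
    }, numeric(1))
    rank_foods(wide)
  })
  dplyr::bind_rows(out)
}
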