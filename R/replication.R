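#' Locate user-supplied published-value replication inputs
#'
#' Reproducing the published food-level results end to end requires data
#' that is not shipped with the package: the study's deposited composition,
#' footprint, price, and intake tables plus region-level mortality
#' envelopes. Users who have these can stage them as a bundle directory
#' (see [write_bundle()] for the layout) plus a `reference.csv` of printed
#' values to check against (columns `scenario_id`, `quantity`, `value`,
#' `digits` -- 0 for printed integers, 1 for one-decimal values). The
#' integration tests pick the directory up automatically.
#'
#' @param dir Directory to look in.
#' @return `NULL` when the directory or its `reference.csv` is absent;
#'   otherwise a list with `bundle_dir` and `reference` (the parsed
#'   reference table).
#' @export
find_replication_data <- function(dir = "paper-data") {
  ref_path <- file.path(dir, "reference.csv")
  if (!dir.exists(dir) || !file.exists(ref_path)) return(NULL)
  list(
    bundle_dir = dir,
    reference = readr::read_csv(ref_path, show_col_types = FALSE,
                                progress = FALSE)
  )
}

#' Compare computed quantities against printed reference values
#'
#' Printed integers are accepted within +/- 1 unit, printed one-decimal
#' values within +/- 0.2: the slack a faithful reimplementation needs
#' against values that were rounded for print.
#'
#' @param computed Named numeric vector of computed quantities.
#' @param reference Tibble with columns `quantity`, `value`, `digits`
#'   (0 = printed integer, 1 = one printed decimal).
#' @return The reference tibble with `computed`, `tolerance`, and `pass`
#'   columns added; quantities missing from `computed` fail with `NA`.
#' @export
compare_to_reference <- function(computed, reference) {
  ref <- tibble::as_tibble(reference)
  ref$computed <- unname(computed[ref$quantity])
  ref$tolerance <- ifelse(ref$digits >= 1, 0.2, 1)
  ref$pass <- !is.na(ref$computed) &
    abs(ref$computed - ref$value) <= ref$tolerance
  ref
}
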