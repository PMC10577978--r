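#' Default drinking-water standards (MCLs) for the modelled metals
#'
#' EPA maximum contaminant levels (or analogous regulatory standards) in ppb
#' used for the exceedance parameterization: inorganic arsenic 10, cadmium 5,
#' chromium 100, copper 1300, lead 15, manganese 300, zinc 5000.
#'
#' @return A tibble with columns `metal` and `mcl` (ppb).
#' @export
default_mcls <- function() {
  tibble::tibble(
    metal = c("iAs", "Cd", "Cr", "Cu", "Pb", "Mn", "Zn"),
    mcl = c(10, 5, 100, 1300, 15, 300, 5000)
  )
}

#' The seven modelled well-water metals
#' @return Character vector of analyte codes.
#' @export
wellmix_metals <- function() c("iAs", "Cd", "Cr", "Cu", "Pb", "Mn", "Zn")

#' Aggregate well tests to census-tract exposure summaries
#'
#' For each tract and analyte computes the arithmetic mean concentration on
#' the ppb scale, the fraction of tests at or above the MCL, and the test
#' count. Tests without a tract ID cannot be assigned and are dropped with an
#' informative message. Intended to run on a complete (imputed) table, though
#' it accepts any table of filled values.
#'
#' @param wells A long well-test tibble with columns `test_id`, `tract_id`,
#'   `analyte`, `value` (ppb, complete).
#' @param mcl Tibble with columns `metal`, `mcl`; analytes without an entry
#'   (e.g. nitrate/nitrite) get `NA` exceedance fractions.
#' @return A tibble with one row per tract x analyte: `tract_id`, `analyte`,
#'   `mean_conc`, `exceedance_fraction`, `n_tests`.
#' @examples
#' wells <- tibble::tibble(
#'   test_id = rep(c("t1", "t2", "t3", "t4"), each = 1),
#'   tract_id = "a", analyte = "Pb", value = c(2, 4, 6, 8)
#' )
#' tract_summaries(wells, default_mcls())
#' @export
tract_summaries <- function(wells, mcl = default_mcls()) {
  stopifnot(all(c("tract_id", "analyte", "value") %in% names(wells)))
  if (nrow(wells) == 0) {
    stop_wellmix("no well tests to summarise", "input_error")
  }
  if (any(!is.finite(wells$value))) {
    stop_wellmix("tract_summaries requires complete concentrations; impute first",
                 "input_error")
  }
  n_dropped <- length(unique(wells$test_id[is.na(wells$tract_id) | wells$tract_id == ""]))
  if (n_dropped > 0) {
    inform(sprintf("dropping %d test(s) without a tract ID", n_dropped))
    wells <- dplyr::filter(wells, !is.na(.data$tract_id), .data$tract_id != "")
  }
  wells |>
    dplyr::left_join(mcl, by = c(analyte = "metal")) |>
    dplyr::group_by(.data$tract_id, .data$analyte) |>
    dplyr::summarise(
      mean_conc = mean(.data$value),
      exceedance_fraction = ifelse(all(is.na(.data$mcl)), NA_real_,
                                   mean(.data$value >= .data$mcl)),
      n_tests = dplyr::n(),
      .groups = "drop"
    )
}

#' Pivot tract summaries to the wide on-disk layout
#'
#' @param exposures Long output of [tract_summaries()].
#' @return One row per tract: `tract_id`, then `mean_<analyte>`,
#'   `exceedfrac_<analyte>`, `n_tests_<analyte>` per analyte, and
#'   `nitrate_nitrite_mean` if that analyte is present.
#' @export
widen_tract_exposures <- function(exposures) {
  wide <- exposures |>
    tidyr::pivot_wider(
      id_cols = "tract_id",
      names_from = "analyte",
      values_from = c("mean_conc", "exceedance_fraction", "n_tests")
    )
  names(wide) <- sub("^mean_conc_", "mean_", names(wide))
  names(wide) <- sub("^exceedance_fraction_", "exceedfrac_", names(wide))
  if ("mean_nitrate_nitrite" %in% names(wide)) {
    wide <- wide |>
      dplyr::rename(nitrate_nitrite_mean = "mean_nitrate_nitrite") |>
      dplyr::select(-dplyr::any_of(c("exceedfrac_nitrate_nitrite",
                                     "n_tests_nitrate_nitrite")))
  }
  wide
}

#' Three-level percentile coding of a birth-level exposure
#'
#' Codes each value as 0 (at or below the 50th percentile), 1 (above the 50th
#' and at or below the 90th) or 2 (above the 90th). Cutpoints are computed on
#' the supplied distribution itself — in the study design this is the
#' birth-level (person-weighted) distribution of tract means — using
#' linear-interpolation sample quantiles. Boundaries are right-closed: a value
#' exactly at a cutpoint falls in the lower category.
#'
#' @param birth_values Numeric vector, one entry per birth (tract mean
#'   concentration for one metal). Missing entries get `NA` categories.
#' @param probs The two percentile cutpoints (default 0.5 and 0.9).
#' @return A list with `category` (integer vector in 0:2, `NA` preserved) and
#'   `cutpoints` (named numeric length 2, ppb).
#' @examples
#' code_percentile_category(1:10)
#' @export
code_percentile_category <- function(birth_values, probs = c(0.5, 0.9)) {
  ok <- !is.na(birth_values)
  if (sum(ok) < 10) {
    stop_wellmix("need at least 10 non-missing exposures for percentile coding",
                 "input_error")
  }
  cut <- quantile(birth_values[ok], probs = probs, names = FALSE, type = 7)
  if (diff(cut) <= 0) {
    stop_wellmix(
      "degenerate exposure distribution (50th and 90th percentiles coincide); consider the exceedance coding instead",
      "degenerate_error")
  }
  category <- rep(NA_integer_, length(birth_values))
  category[ok] <- score_from_cutpoints(birth_values[ok], cut)
  list(category = category,
       cutpoints = setNames(cut, paste0("p", probs * 100)))
}

#' Binary MCL-exceedance coding of tract exposure
#'
#' Flags tracts in which at least `threshold` (default 25%) of well tests for
#' a metal were at or above the MCL. The boundary is inclusive: a tract with
#' exactly a 25% exceedance fraction is flagged.
#'
#' @param exposures Long tract-summary tibble from [tract_summaries()].
#' @param threshold Fraction in (0, 1).
#' @return `exposures` with an added integer `exceedance_flag` column.
#' @export
code_exceedance_flag <- function(exposures, threshold = 0.25) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop_wellmix("exceedance threshold must lie strictly between 0 and 1",
                 "input_error")
  }
  dplyr::mutate(
    exposures,
    exceedance_flag = as.integer(.data$exceedance_fraction >= threshold)
  )
}

#' Ordinal nitrate/nitrite co-pollutant covariate
#'
#' Applies the same 0/1/2 percentile coding machinery to the tract-level
#' average of nitrate and nitrite concentrations, the co-pollutant adjustment
#' covariate. If the distribution is degenerate or entirely missing the
#' covariate is omitted (all `NA`) with a warning rather than an error, since
#' adjustment sets should degrade gracefully.
#'
#' @param birth_values Per-birth tract nitrate/nitrite means (ppb).
#' @return A list with `category` and `cutpoints` as in
#'   [code_percentile_category()]; `cutpoints` is `NULL` when omitted.
#' @export
code_nitrate_covariate <- function(birth_values) {
  if (all(is.na(birth_values))) {
    warn("nitrate/nitrite data entirely missing; covariate omitted")
    return(list(category = rep(NA_integer_, length(birth_values)),
                cutpoints = NULL))
  }
  tryCatch(
    code_percentile_category(birth_values),
    wellmix_degenerate_error = function(e) {
      warn("nitrate/nitrite distribution degenerate; covariate omitted")
      list(category = rep(NA_integer_, length(birth_values)), cutpoints = NULL)
    },
    wellmix_input_error = function(e) {
      warn("too few nitrate/nitrite values; covariate omitted")
      list(category = rep(NA_integer_, length(birth_values)), cutpoints = NULL)
    }
  )
}
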