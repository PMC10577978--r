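race_levels <- function() {
  c("White non-Hispanic", "Black non-Hispanic", "Hispanic",
    "Asian/Pacific Islander", "American Indian", "Other/unknown")
}

education_levels <- function() c("<HS", "HS", ">HS")

season_levels <- function() c("winter", "spring", "summer", "fall")

#' Derive nested preterm-birth outcomes from gestational age
#'
#' Preterm birth is delivery before 37 completed weeks; very preterm before
#' 32; extremely preterm before 28. The indicators are nested by
#' construction: `extreme_ptb <= very_ptb <= ptb` for every record.
#'
#' @param ga_weeks Gestational age in completed weeks; must already satisfy
#'   the cohort inclusion range `20 <= ga < 44` (run
#'   [apply_inclusion_filters()] first).
#' @return A tibble with integer columns `ptb`, `very_ptb`, `extreme_ptb`.
#' @examples
#' derive_outcomes(c(27, 36, 37))
#' @export
derive_outcomes <- function(ga_weeks) {
  if (any(is.na(ga_weeks)) || any(ga_weeks < 20 | ga_weeks >= 44)) {
    stop_wellmix("gestational age outside [20, 44); apply inclusion filters first",
                 "input_error")
  }
  tibble::tibble(
    ptb = as.integer(ga_weeks < 37),
    very_ptb = as.integer(ga_weeks < 32),
    extreme_ptb = as.integer(ga_weeks < 28)
  )
}

# Season of conception from birth date and gestational age; conception date
# approximated as birth_date - 7 * ga_weeks days, mapped to
# winter (Dec-Feb), spring (Mar-May), summer (Jun-Aug), fall (Sep-Nov).
season_of_conception <- function(birth_date, ga_weeks) {
  conception <- as.Date(birth_date) - round(7 * ga_weeks)
  m <- as.integer(format(conception, "%m"))
  s <- dplyr::case_when(
    m %in% c(12, 1, 2) ~ "winter",
    m %in% 3:5 ~ "spring",
    m %in% 6:8 ~ "summer",
    TRUE ~ "fall"
  )
  factor(s, levels = season_levels())
}

#' Apply the cohort inclusion and exclusion rules
#'
#' Retains singleton, non-anomalous births with gestational age in
#' `[20, 44)` weeks whose census tract appears in the exposure table. Rules
#' are applied in a fixed order — geography, plurality/anomaly, gestational
#' age, tract coverage — and each record is tallied under the first rule that
#' removes it, so the tally sums to the number excluded.
#'
#' @param births Typed birth-record tibble (see [read_birth_records()]).
#' @param exposures Tract exposure table (long or wide) with a `tract_id`
#'   column; tracts absent from it cannot be assigned exposure.
#' @return A list with `cohort` (retained records plus derived `ptb`,
#'   `very_ptb`, `extreme_ptb` and `season` columns) and `tally`, a tibble of
#'   per-rule removal counts with attribute checks `n_input = n_final +
#'   sum(removed)`.
#' @export
apply_inclusion_filters <- function(births, exposures) {
  n_input <- nrow(births)
  covered <- unique(exposures$tract_id)

  bad_geo <- is.na(births$tract_id) | births$tract_id == ""
  removed_geo <- sum(bad_geo)
  kept <- births[!bad_geo, , drop = FALSE]

  multi_anom <- (!is.na(kept$plurality) & kept$plurality > 1) |
    (!is.na(kept$anomaly_flag) & kept$anomaly_flag == 1)
  removed_plur <- sum(multi_anom)
  kept <- kept[!multi_anom, , drop = FALSE]

  bad_ga <- is.na(kept$ga_weeks) | kept$ga_weeks < 20 | kept$ga_weeks >= 44
  removed_ga <- sum(bad_ga)
  kept <- kept[!bad_ga, , drop = FALSE]

  uncovered <- !(kept$tract_id %in% covered)
  removed_tract <- sum(uncovered)
  kept <- kept[!uncovered, , drop = FALSE]

  if (nrow(kept) == 0) warn("no births remain after inclusion filters")

  cohort <- dplyr::bind_cols(
    tibble::as_tibble(kept),
    derive_outcomes(kept$ga_weeks)
  )
  if ("birth_date" %in% names(kept)) {
    cohort$season <- season_of_conception(kept$birth_date, kept$ga_weeks)
  }

  tally <- tibble::tibble(
    rule = c("bad_geography", "multiple_or_anomalous", "ga_out_of_range",
             "tract_without_tests"),
    removed = c(removed_geo, removed_plur, removed_ga, removed_tract)
  )
  list(cohort = cohort, tally = tally, n_input = n_input,
       n_final = nrow(cohort))
}

#' Join tract exposure codings onto a cohort
#'
#' Adds, per metal, the per-birth tract mean concentration (`conc_<metal>`),
#' the three-level percentile category (`pctcat_<metal>`, coded on the
#' birth-level distribution) and the MCL-exceedance flag (`exceed_<metal>`),
#' plus the ordinal `nitrate_category` covariate when nitrate/nitrite means
#' are available.
#'
#' @param cohort Output `cohort` of [apply_inclusion_filters()].
#' @param exposures Long tract summary table from [tract_summaries()].
#' @param metals Metals to code (default the seven modelled metals).
#' @param threshold Exceedance threshold fraction (default 0.25).
#' @return A list with `cohort` (augmented tibble) and `cutpoints` (tibble of
#'   realized percentile cutpoints per metal, ppb).
#' @export
assign_exposures <- function(cohort, exposures, metals = wellmix_metals(),
                             threshold = 0.25) {
  flagged <- code_exceedance_flag(exposures, threshold)
  cuts <- list()
  for (m in metals) {
    em <- dplyr::filter(flagged, .data$analyte == m)
    idx <- match(cohort$tract_id, em$tract_id)
    cohort[[paste0("conc_", m)]] <- em$mean_conc[idx]
    cohort[[paste0("exceed_", m)]] <- em$exceedance_flag[idx]
    pc <- code_percentile_category(em$mean_conc[idx])
    cohort[[paste0("pctcat_", m)]] <- pc$category
    cuts[[m]] <- tibble::tibble(
      metal = m, p50 = pc$cutpoints[["p50"]], p90 = pc$cutpoints[["p90"]]
    )
  }
  nn <- dplyr::filter(exposures, .data$analyte == "nitrate_nitrite")
  if (nrow(nn) > 0) {
    nitrate_birth <- nn$mean_conc[match(cohort$tract_id, nn$tract_id)]
    cohort$nitrate_category <- code_nitrate_covariate(nitrate_birth)$category
  } else {
    cohort$nitrate_category <- NA_integer_
  }
  list(cohort = cohort, cutpoints = dplyr::bind_rows(cuts))
}

#' Build the adjusted-model design matrix
#'
#' Encodes the adjustment covariates the way the analysis specifies:
#' maternal age with a quadratic term; race/ethnicity as five disjoint
#' indicators against a White non-Hispanic reference; smoking binary;
#' education, tract poverty quartile and the nitrate/nitrite category as
#' single ordinal numeric columns; season of conception as three indicators
#' against a winter reference. Rows missing any required covariate are
#' dropped (complete-case) and counted.
#'
#' @param cohort Cohort tibble with coded covariate columns.
#' @param covariates Character vector naming the covariates to include, from
#'   `age`, `race_ethnicity`, `smoking`, `education`,
#'   `tract_poverty_quartile`, `season`, `nitrate_category`.
#' @return A list with `X` (numeric matrix including intercept), `rows`
#'   (integer indices of `cohort` rows retained) and `n_dropped`.
#' @export
build_design_matrix <- function(cohort,
                                covariates = c("age", "race_ethnicity",
                                               "smoking", "education",
                                               "tract_poverty_quartile",
                                               "season", "nitrate_category")) {
  if (nrow(cohort) == 0) stop_wellmix("empty cohort", "input_error")
  cols <- list("(Intercept)" = rep(1, nrow(cohort)))
  for (cv in covariates) {
    if (cv == "age") {
      if (all(is.na(cohort$age_years))) {
        stop_wellmix("covariate age_years entirely missing", "input_error")
      }
      cols[["age"]] <- cohort$age_years
      cols[["age_sq"]] <- cohort$age_years^2
    } else if (cv == "race_ethnicity") {
      re <- factor(cohort$race_ethnicity, levels = race_levels())
      if (all(is.na(re))) {
        stop_wellmix("covariate race_ethnicity entirely missing", "input_error")
      }
      for (lev in race_levels()[-1]) {
        nm <- paste0("race_", gsub("[^A-Za-z]+", "_", lev))
        v <- as.numeric(re == lev)
        v[is.na(re)] <- NA
        cols[[nm]] <- v
      }
    } else if (cv == "smoking") {
      if (all(is.na(cohort$smoking))) {
        stop_wellmix("covariate smoking entirely missing", "input_error")
      }
      cols[["smoking"]] <- as.numeric(cohort$smoking)
    } else if (cv == "education") {
      ed <- factor(cohort$education, levels = education_levels())
      if (all(is.na(ed))) {
        stop_wellmix("covariate education entirely missing", "input_error")
      }
      cols[["education_ord"]] <- as.numeric(ed) - 1
    } else if (cv == "tract_poverty_quartile") {
      if (all(is.na(cohort$tract_poverty_quartile))) {
        stop_wellmix("covariate tract_poverty_quartile entirely missing",
                     "input_error")
      }
      cols[["poverty_ord"]] <- as.numeric(cohort$tract_poverty_quartile) - 1
    } else if (cv == "season") {
      se <- factor(cohort$season, levels = season_levels())
      if (all(is.na(se))) {
        stop_wellmix("covariate season entirely missing", "input_error")
      }
      for (lev in season_levels()[-1]) {
        v <- as.numeric(se == lev)
        v[is.na(se)] <- NA
        cols[[paste0("season_", lev)]] <- v
      }
    } else if (cv == "nitrate_category") {
      if (all(is.na(cohort$nitrate_category))) {
        warn("nitrate_category entirely missing; omitted from design")
        next
      }
      cols[["nitrate_ord"]] <- as.numeric(cohort$nitrate_category)
    } else {
      # any other name: take the column as numeric as-is
      if (!cv %in% names(cohort)) {
        stop_wellmix(paste0("unknown covariate: ", cv), "input_error")
      }
      cols[[cv]] <- as.numeric(cohort[[cv]])
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  keep <- complete.cases(X)
  list(X = X[keep, , drop = FALSE], rows = which(keep),
       n_dropped = sum(!keep))
}
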