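BELOW_LOR_TOKEN <- "<LOR"

#' Read a well-test CSV into the long measurement table
#'
#' The on-disk layout has one row per well test: `test_id`, `county`,
#' `tract_id`, `date`, then per analyte a value column and an `<analyte>_lor`
#' column. A value cell holds a concentration in ppb, the literal token
#' `"<LOR"` for a below-limit-of-reporting result (with the LOR in the
#' companion column), or is empty when the test did not measure that
#' analyte. This mirrors how state-laboratory reports express censoring while
#' keeping a single file.
#'
#' @param path CSV path.
#' @param analytes Declared analyte set; the file must carry exactly these
#'   analyte columns (unknown analyte columns are a schema error).
#' @return Long tibble: `test_id`, `county`, `tract_id`, `date`, `analyte`,
#'   `status` (`observed` / `below_lor` / `not_measured`), `value`, `lor`.
#' @export
read_well_tests <- function(path, analytes = c(wellmix_metals(),
                                               "nitrate_nitrite")) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  base_cols <- c("test_id", "county", "tract_id", "date")
  missing_base <- setdiff(base_cols, names(raw))
  if (length(missing_base) > 0) {
    stop_wellmix(paste0("missing required columns: ",
                        paste(missing_base, collapse = ", ")), "schema_error")
  }
  other <- setdiff(names(raw), base_cols)
  value_cols <- other[!grepl("_lor$", other)]
  unknown <- setdiff(value_cols, analytes)
  if (length(unknown) > 0) {
    stop_wellmix(paste0("unknown analyte column(s): ",
                        paste(unknown, collapse = ", ")), "schema_error")
  }
  missing_an <- setdiff(analytes, value_cols)
  if (length(missing_an) > 0) {
    stop_wellmix(paste0("declared analyte(s) absent from file: ",
                        paste(missing_an, collapse = ", ")), "schema_error")
  }
  if (anyDuplicated(raw$test_id)) {
    stop_wellmix("duplicate test_id values", "validation_error")
  }
  if (any(raw$county == "")) {
    stop_wellmix("empty county values", "validation_error")
  }

  if (nrow(raw) == 0) {
    return(tibble::tibble(
      test_id = character(), county = character(), tract_id = character(),
      date = as.Date(character()), analyte = character(), status = character(),
      value = numeric(), lor = numeric()
    ))
  }

  out <- purrr::map_dfr(analytes, function(a) {
    v <- raw[[a]]
    lor_col <- paste0(a, "_lor")
    lor_raw <- if (lor_col %in% names(raw)) raw[[lor_col]] else
      rep("", nrow(raw))
    status <- dplyr::case_when(
      v == BELOW_LOR_TOKEN ~ "below_lor",
      v == "" ~ "not_measured",
      TRUE ~ "observed"
    )
    value <- suppressWarnings(as.numeric(ifelse(status == "observed", v, NA)))
    bad <- which(status == "observed" & is.na(value))
    if (length(bad) > 0) {
      stop_wellmix(sprintf("non-numeric concentration for %s in row %d", a,
                           bad[1]), "validation_error")
    }
    neg <- which(!is.na(value) & value <= 0)
    if (length(neg) > 0) {
      stop_wellmix(sprintf("non-positive concentration for %s in row %d: %s",
                           a, neg[1], format(value[neg[1]])),
                   "validation_error")
    }
    lor <- suppressWarnings(as.numeric(ifelse(status == "below_lor",
                                              lor_raw, NA)))
    bad_lor <- which(status == "below_lor" & (is.na(lor) | lor <= 0))
    if (length(bad_lor) > 0) {
      stop_wellmix(sprintf("below-LOR cell without a positive LOR for %s in row %d",
                           a, bad_lor[1]), "validation_error")
    }
    tibble::tibble(
      test_id = raw$test_id,
      county = raw$county,
      tract_id = dplyr::na_if(raw$tract_id, ""),
      date = as.Date(raw$date),
      analyte = a,
      status = status,
      value = value,
      lor = lor
    )
  })
  out
}

#' Write a long well-test table back to the wide CSV layout
#' @param wells Long well-test tibble (see [read_well_tests()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_well_tests <- function(wells, path) {
  analytes <- unique(wells$analyte)
  cell <- dplyr::case_when(
    wells$status == "below_lor" ~ BELOW_LOR_TOKEN,
    wells$status == "not_measured" ~ "",
    TRUE ~ format(wells$value, digits = 15, trim = TRUE, scientific = FALSE)
  )
  long <- tibble::tibble(
    test_id = wells$test_id, county = wells$county,
    tract_id = dplyr::coalesce(wells$tract_id, ""),
    date = as.character(wells$date),
    analyte = wells$analyte, cell = cell,
    lor = ifelse(is.na(wells$lor), "",
                 format(wells$lor, digits = 15, trim = TRUE,
                        scientific = FALSE))
  )
  wide_v <- tidyr::pivot_wider(
    long[c("test_id", "county", "tract_id", "date", "analyte", "cell")],
    names_from = "analyte", values_from = "cell")
  wide_l <- tidyr::pivot_wider(
    long[c("test_id", "analyte", "lor")],
    names_from = "analyte", values_from = "lor",
    names_glue = "{analyte}_lor")
  wide <- dplyr::left_join(wide_v, wide_l, by = "test_id")
  # interleave analyte and lor columns in declared order
  ordered <- c("test_id", "county", "tract_id", "date",
               as.vector(rbind(analytes, paste0(analytes, "_lor"))))
  readr::write_csv(wide[ordered], path, na = "")
  invisible(path)
}

#' Read a birth-record CSV
#'
#' Columns: `id`, `tract_id`, `ga_weeks`, `birth_date`, `plurality`,
#' `anomaly_flag`, `age_years`, `race_ethnicity`, `education`, `smoking`,
#' `tract_poverty_quartile`, `pred_well_user_fraction`. Empty cells are kept
#' as explicit missing values; a non-numeric gestational age or a
#' race/ethnicity label outside the six-category vocabulary is a validation
#' error.
#'
#' @param path CSV path.
#' @return Typed tibble, one row per birth.
#' @export
read_birth_records <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  required <- c("id", "tract_id", "ga_weeks", "birth_date", "plurality",
                "anomaly_flag", "age_years", "race_ethnicity", "education",
                "smoking", "tract_poverty_quartile")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop_wellmix(paste0("missing required columns: ",
                        paste(missing_cols, collapse = ", ")), "schema_error")
  }
  num <- function(x, what) {
    out <- suppressWarnings(as.numeric(dplyr::na_if(x, "")))
    bad <- which(!is.na(dplyr::na_if(x, "")) & is.na(out))
    if (length(bad) > 0) {
      stop_wellmix(sprintf("non-numeric %s in row %d: '%s'", what, bad[1],
                           x[bad[1]]), "validation_error")
    }
    out
  }
  race <- dplyr::na_if(raw$race_ethnicity, "")
  bad_race <- setdiff(unique(race[!is.na(race)]), race_levels())
  if (length(bad_race) > 0) {
    stop_wellmix(paste0("unknown race/ethnicity label(s): ",
                        paste(bad_race, collapse = ", "),
                        "; allowed: ", paste(race_levels(), collapse = ", ")),
                 "validation_error")
  }
  edu <- dplyr::na_if(raw$education, "")
  bad_edu <- setdiff(unique(edu[!is.na(edu)]), education_levels())
  if (length(bad_edu) > 0) {
    stop_wellmix(paste0("unknown education label(s): ",
                        paste(bad_edu, collapse = ", "),
                        "; allowed: ", paste(education_levels(), collapse = ", ")),
                 "validation_error")
  }
  tibble::tibble(
    id = raw$id,
    tract_id = dplyr::na_if(raw$tract_id, ""),
    ga_weeks = num(raw$ga_weeks, "gestational age"),
    birth_date = as.Date(dplyr::na_if(raw$birth_date, "")),
    plurality = as.integer(num(raw$plurality, "plurality")),
    anomaly_flag = as.integer(num(raw$anomaly_flag, "anomaly flag")),
    age_years = num(raw$age_years, "maternal age"),
    race_ethnicity = race,
    education = edu,
    smoking = as.integer(num(raw$smoking, "smoking")),
    tract_poverty_quartile = as.integer(num(raw$tract_poverty_quartile,
                                            "poverty quartile")),
    pred_well_user_fraction = if ("pred_well_user_fraction" %in% names(raw)) {
      num(raw$pred_well_user_fraction, "predicted well-user fraction")
    } else NA_real_
  )
}

#' Published 2x2 category counts for the single-metal crude odds ratios
#'
#' Case and non-case counts, by metal and exposure contrast, as printed in
#' the source study's single-metal results table. Crude odds ratios computed
#' from these counts by [odds_ratio_2x2()] reproduce the printed values and
#' serve as arithmetic worked examples.
#'
#' @return Tibble: `metal`, `parameterization`, `contrast`, `cases_exposed`,
#'   `noncases_exposed`, `cases_ref`, `noncases_ref`.
#' @export
published_category_counts <- function() {
  path <- system.file("extdata", "published_category_counts.csv",
                      package = "wellmix", mustWork = TRUE)
  readr::read_csv(path, col_types = "cccdddd", progress = FALSE)
}
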