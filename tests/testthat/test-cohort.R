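make_births <- function(n = 8, ...) {
  base <- tibble::tibble(
    id = sprintf("b%02d", seq_len(n)),
    tract_id = "tr1",
    ga_weeks = 39,
    birth_date = as.Date("2010-06-15"),
    plurality = 1L,
    anomaly_flag = 0L,
    age_years = 30,
    race_ethnicity = "White non-Hispanic",
    education = ">HS",
    smoking = 0L,
    tract_poverty_quartile = 2L,
    pred_well_user_fraction = NA_real_
  )
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

exposures_for <- function(tracts) {
  tibble::tibble(tract_id = tracts, analyte = "Pb", mean_conc = 1,
                 exceedance_fraction = 0, n_tests = 1L)
}

test_that("gestational-age boundaries follow the inclusion rule", {
  births <- make_births(4, ga_weeks = c(19, 20, 43, 44))
  res <- apply_inclusion_filters(births, exposures_for("tr1"))
  expect_equal(res$n_final, 2L)
  expect_equal(res$cohort$ga_weeks, c(20, 43))
  expect_equal(res$tally$removed[res$tally$rule == "ga_out_of_range"], 2L)
})

test_that("each record is tallied once, under the first matching rule", {
  births <- make_births(
    5,
    tract_id = c(NA, "tr1", "tr1", "tr1", "gone"),
    plurality = c(2L, 2L, 1L, 1L, 1L),   # row 1 bad geography AND twin
    ga_weeks = c(30, 30, 19, 39, 39)     # row 2 twin AND bad ga? no: ga 30 ok
  )
  res <- apply_inclusion_filters(births, exposures_for("tr1"))
  expect_equal(res$tally$removed,
               c(1L, 1L, 1L, 1L))  # geography, twin, ga, uncovered tract
  expect_equal(res$n_final, 1L)
  expect_equal(res$n_input, res$n_final + sum(res$tally$removed))
})

test_that("anomalous singletons are excluded with multiples", {
  births <- make_births(2, anomaly_flag = c(1L, 0L))
  res <- apply_inclusion_filters(births, exposures_for("tr1"))
  expect_equal(res$tally$removed[res$tally$rule == "multiple_or_anomalous"], 1L)
})

test_that("filtering is idempotent", {
  births <- make_births(6, ga_weeks = c(19, 25, 37, 41, 44, 30),
                        plurality = c(1L, 2L, 1L, 1L, 1L, 1L))
  first <- apply_inclusion_filters(births, exposures_for("tr1"))
  again <- apply_inclusion_filters(first$cohort[names(births)],
                                   exposures_for("tr1"))
  expect_equal(again$n_final, first$n_final)
  expect_equal(sum(again$tally$removed), 0L)
})

test_that("outcomes are nested and follow the completed-week thresholds", {
  out <- derive_outcomes(c(36, 27, 37, 31, 28, 20, 43))
  expect_equal(out$ptb,        c(1, 1, 0, 1, 1, 1, 0))
  expect_equal(out$very_ptb,   c(0, 1, 0, 1, 1, 1, 0))
  expect_equal(out$extreme_ptb, c(0, 1, 0, 0, 0, 1, 0))
  expect_true(all(out$extreme_ptb <= out$very_ptb))
  expect_true(all(out$very_ptb <= out$ptb))
  expect_error(derive_outcomes(c(19)), class = "wellmix_input_error")
  expect_error(derive_outcomes(c(44)), class = "wellmix_input_error")
})

test_that("season of conception uses the birth date minus gestation", {
  births <- make_births(2,
                        birth_date = as.Date(c("2010-09-15", "2010-03-01")),
                        ga_weeks = c(39, 40))
  res <- apply_inclusion_filters(births, exposures_for("tr1"))
  # 2010-09-15 - 273 days -> mid-December -> winter conception
  expect_equal(as.character(res$cohort$season), c("winter", "spring"))
})

test_that("the design matrix encodes covariates as specified", {
  coh <- make_births(
    6,
    age_years = c(30, 20, 40, 25, 35, 28),
    race_ethnicity = c("White non-Hispanic", "Black non-Hispanic", "Hispanic",
                       "Asian/Pacific Islander", "American Indian",
                       "Other/unknown"),
    education = c("<HS", "HS", ">HS", ">HS", NA, "HS"),
    smoking = c(0L, 1L, 0L, 0L, 1L, 0L),
    tract_poverty_quartile = c(1L, 2L, 3L, 4L, 1L, 2L)
  )
  coh$season <- factor(rep(c("winter", "spring", "summer"), 2),
                       levels = c("winter", "spring", "summer", "fall"))
  coh$nitrate_category <- c(0L, 1L, 2L, 0L, 1L, 2L)
  dm <- build_design_matrix(coh)
  # row 5 has missing education -> complete-case drop
  expect_equal(dm$n_dropped, 1L)
  expect_equal(dm$rows, c(1:4, 6L))
  expect_equal(unname(dm$X[1, c("age", "age_sq")]), c(30, 900))
  race_cols <- grep("^race_", colnames(dm$X), value = TRUE)
  expect_length(race_cols, 5)          # six categories, five indicators
  expect_equal(sum(dm$X[1, race_cols]), 0)  # reference row all zero
  expect_equal(unname(dm$X[, "education_ord"]), c(0, 1, 2, 2, 1))
  expect_equal(unname(dm$X[, "poverty_ord"]), c(0, 1, 2, 3, 1))
  expect_equal(unname(dm$X[, "nitrate_ord"]), c(0, 1, 2, 0, 2))
  season_cols <- grep("^season_", colnames(dm$X), value = TRUE)
  expect_length(season_cols, 3)
  expect_error(build_design_matrix(dplyr::mutate(coh, age_years = NA)),
               class = "wellmix_input_error")
})

test_that("exposure codings join per tract and report cutpoints", {
  tracts <- sprintf("tr%02d", 1:20)
  exposures <- withr::with_seed(101, tibble::tibble(
    tract_id = rep(tracts, 2),
    analyte = rep(c("Pb", "nitrate_nitrite"), each = 20),
    mean_conc = c(rlnorm(20, log(2), 1), rlnorm(20, log(200), 0.5)),
    exceedance_fraction = c(runif(20, 0, 0.5), rep(NA, 20)),
    n_tests = 3L
  ))
  births <- make_births(40, tract_id = rep(tracts, 2))
  filt <- apply_inclusion_filters(births, exposures)
  asg <- assign_exposures(filt$cohort, exposures, metals = "Pb")
  expect_true(all(c("conc_Pb", "exceed_Pb", "pctcat_Pb", "nitrate_category")
                  %in% names(asg$cohort)))
  expect_equal(asg$cutpoints$metal, "Pb")
  # every birth in the same tract shares the tract's values
  by_tract <- split(asg$cohort$conc_Pb, asg$cohort$tract_id)
  expect_true(all(vapply(by_tract, function(v) length(unique(v)) == 1,
                         logical(1))))
})
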