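test_that("latent concentrations follow the configured lognormal law", {
  # median of a lognormal is exp(location); check arsenic at location log(0.5)
  wp <- well_sim_params(n_tests = 50000, n_counties = 1, n_tracts = 10,
                        metals = c("iAs", "Pb"),
                        log_location = c(iAs = log(0.5)),
                        county_shift_sd = 0)
  sim <- simulate_well_tests(wp, seed = 201)
  lat <- sim$truth$latent
  med <- median(lat$latent_value[lat$analyte == "iAs"])
  expect_lt(abs(med / 0.5 - 1), 0.02)
})

test_that("marginal log-moments match the parameters with censoring off", {
  wp <- well_sim_params(n_tests = 50000, n_counties = 1, n_tracts = 10,
                        metals = c("Cr", "Mn"), county_shift_sd = 0,
                        lor = c(Cr = 0, Mn = 0),
                        p_not_measured = c(Cr = 0, Mn = 0))
  sim <- simulate_well_tests(wp, seed = 211)
  expect_true(all(sim$wells$status == "observed"))
  for (m in c("Cr", "Mn")) {
    lv <- log(sim$wells$value[sim$wells$analyte == m])
    expect_lt(abs(mean(lv) - wp$log_location[[m]]),
              3 * wp$log_scale[[m]] / sqrt(50000))
    expect_lt(abs(sd(lv) / wp$log_scale[[m]] - 1), 0.02)
  }
})

test_that("statuses are consistent with the latent truth", {
  wp <- well_sim_params(n_tests = 2000, n_counties = 4, n_tracts = 20)
  sim <- simulate_well_tests(wp, seed = 221)
  joined <- dplyr::left_join(sim$wells, sim$truth$latent,
                             by = c("test_id", "analyte"))
  measured <- joined[joined$status != "not_measured", ]
  lor <- wp$lor[measured$analyte]
  expect_identical(measured$status == "below_lor",
                   unname(measured$latent_value < lor))
  obs <- joined[joined$status == "observed", ]
  expect_identical(obs$value, obs$latent_value)
  # same seed, same table
  sim2 <- simulate_well_tests(wp, seed = 221)
  expect_identical(sim$wells, sim2$wells)
  # invalid correlation rejected
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(well_sim_params(metals = c("iAs", "Pb"),
                               log_correlation = bad),
               class = "wellmix_param_error")
})

test_that("with all effects off the cohort hits the baseline prevalence", {
  expos <- make_test_exposures(n_tracts = 100, seed = 231)
  params <- null_covariate_params(
    50000, c(Cd = 0, Pb = 0, Cr = 0, Zn = 0, iAs = 0, Cu = 0, Mn = 0))
  sim <- simulate_births(params, expos, seed = 232)
  prev <- mean(sim$births$ga_weeks < 37)
  se <- sqrt(0.094 * 0.906 / 50000)
  expect_lt(abs(prev - 0.094), 3 * se)
  # same seed reproduces the cohort
  sim2 <- simulate_births(params, expos, seed = 232)
  expect_identical(sim$births, sim2$births)
  expect_error(simulate_births(params, expos[0, ], seed = 1),
               class = "wellmix_input_error")
})

test_that("simulated gestational ages are consistent with the outcome", {
  expos <- make_test_exposures(n_tracts = 50, seed = 241)
  sim <- simulate_births(birth_sim_params(n_births = 5000), expos, seed = 242)
  ga <- sim$births$ga_weeks
  expect_true(all(ga >= 20 & ga < 44))
  # truth records the coefficient sum as psi
  expect_equal(sim$truth$psi,
               sum(unlist(sim$truth$metal_coefficients)))
})

test_that("fixture bundles are reproducible and self-consistent", {
  d1 <- tempfile()
  d2 <- tempfile()
  p1 <- make_fixture("tiny", d1)
  p2 <- make_fixture("tiny", d2)
  for (f in c("wells", "births", "config")) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
  truth <- jsonlite::read_json(p1$truth)
  expect_true(truth$synthetic)
  expect_equal(truth$psi, sum(unlist(truth$metal_coefficients)))
  wells <- read_well_tests(p1$wells)
  expect_lte(length(unique(wells$test_id)), 200)
  births <- read_birth_records(p1$births)
  expect_lte(nrow(births), 2000)
})
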