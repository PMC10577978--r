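#' Parameters for the well-test generator
#'
#' Defaults emulate the structure of a state-wide private-well testing
#' database: strongly right-skewed (lognormal) concentrations with
#' between-county location shifts, cross-analyte log-scale correlation,
#' per-analyte limits of reporting that leave a large share of trace-metal
#' results left-censored, and a not-measured probability for tests that did
#' not request a given analyte. Medians and spreads are anchored to the
#' published birth-level percentile cutpoints of the tract-mean
#' distributions (e.g. arsenic 50th/90th percentiles 0.220/2.838 ppb).
#'
#' @param n_tests Number of well tests.
#' @param n_counties,n_tracts Counts of counties and census tracts (tracts
#'   are nested within counties).
#' @param metals Analytes to simulate.
#' @param log_location,log_scale Named per-analyte lognormal parameters
#'   (log-ppb).
#' @param county_shift_sd SD of the per-county, per-analyte location shift
#'   (log-ppb).
#' @param log_correlation Either a single off-diagonal correlation or a full
#'   symmetric positive-definite matrix across analytes.
#' @param lor Named per-analyte limit of reporting (ppb); 0 disables
#'   censoring.
#' @param p_not_measured Named per-analyte probability a test did not
#'   measure the analyte.
#' @return A `well_sim_params` list.
#' @export
well_sim_params <- function(n_tests = 5000,
                            n_counties = 20,
                            n_tracts = 200,
                            metals = c(wellmix_metals(), "nitrate_nitrite"),
                            log_location = NULL,
                            log_scale = NULL,
                            county_shift_sd = 0.5,
                            log_correlation = 0.3,
                            lor = NULL,
                            p_not_measured = NULL) {
  defaults_loc <- c(iAs = log(0.220), Cd = log(0.007), Cr = log(0.579),
                    Cu = log(21.1), Pb = log(1.43), Mn = log(33.6),
                    Zn = log(126.8), nitrate_nitrite = log(250))
  defaults_scale <- c(iAs = 2.0, Cd = 2.3, Cr = 1.25, Cu = 1.5, Pb = 1.45,
                      Mn = 1.35, Zn = 2.0, nitrate_nitrite = 1.4)
  defaults_lor <- c(iAs = 0.25, Cd = 0.01, Cr = 0.5, Cu = 20, Pb = 1.5,
                    Mn = 30, Zn = 100, nitrate_nitrite = 100)
  defaults_pnm <- c(iAs = 0.10, Cd = 0.10, Cr = 0.10, Cu = 0.10, Pb = 0.10,
                    Mn = 0.10, Zn = 0.10, nitrate_nitrite = 0.20)
  pick <- function(user, def) {
    out <- def[metals]
    names(out) <- metals
    out[is.na(out)] <- 0
    if (!is.null(user)) out[names(user)] <- user
    out
  }
  loc <- pick(log_location, defaults_loc)
  scl <- pick(log_scale, defaults_scale)
  scl[scl <= 0] <- 1
  lorv <- pick(lor, defaults_lor)
  pnm <- pick(p_not_measured, defaults_pnm)
  if (any(pnm < 0 | pnm > 1)) {
    stop_wellmix("not-measured probabilities must lie in [0, 1]", "param_error")
  }
  A <- length(metals)
  if (is.matrix(log_correlation)) {
    R <- log_correlation
  } else {
    R <- matrix(log_correlation, A, A)
    diag(R) <- 1
  }
  if (!isTRUE(all.equal(R, t(R))) || any(eigen(R, symmetric = TRUE,
                                               only.values = TRUE)$values <= 1e-10)) {
    stop_wellmix("analyte log-correlation matrix must be symmetric positive-definite",
                 "param_error")
  }
  structure(
    list(n_tests = n_tests, n_counties = n_counties, n_tracts = n_tracts,
         metals = metals, log_location = loc, log_scale = scl,
         county_shift_sd = county_shift_sd, log_correlation = R,
         lor = lorv, p_not_measured = pnm),
    class = "well_sim_params"
  )
}

#' Simulate a well-test table with known latent truth
#'
#' Draws latent log concentrations from a multivariate normal (lognormal on
#' the ppb scale) with per-county location shifts, then applies the
#' observation process: a cell is dropped to not-measured with its stated
#' probability, otherwise reported below the limit of reporting when the
#' latent value falls under the LOR, otherwise observed. Statuses are
#' therefore consistent with the latent truth by construction.
#'
#' @param params A [well_sim_params()] object.
#' @param seed Integer seed.
#' @return A list with `wells` (long well-test tibble) and `truth` (a list
#'   holding the latent concentrations and the simulation parameters); the
#'   truth is for test assertions only and is never read by analysis stages.
#' @export
simulate_well_tests <- function(params = well_sim_params(), seed = 1) {
  stopifnot(inherits(params, "well_sim_params"))
  metals <- params$metals
  A <- length(metals)
  n <- params$n_tests
  Rchol <- chol(params$log_correlation)
  withr::with_seed(seed, {
    county <- sprintf("county%02d", sample.int(params$n_counties, n,
                                               replace = TRUE))
    # tracts nested in counties
    tract_county <- rep_len(seq_len(params$n_counties), params$n_tracts)
    tract_ids <- sprintf("tract%04d", seq_len(params$n_tracts))
    tract <- vapply(county, function(cc) {
      ci <- as.integer(sub("county", "", cc))
      cand <- tract_ids[tract_county == ci]
      cand[sample.int(length(cand), 1)]
    }, character(1))
    shifts <- matrix(rnorm(params$n_counties * A, 0, params$county_shift_sd),
                     params$n_counties, A, dimnames = list(NULL, metals))
    county_idx <- as.integer(sub("county", "", county))
    Zmat <- matrix(rnorm(n * A), n, A) %*% Rchol
    Lat <- sweep(Zmat, 2, params$log_scale, `*`)
    Lat <- sweep(Lat, 2, params$log_location, `+`)
    Lat <- Lat + shifts[county_idx, , drop = FALSE]
    conc <- exp(Lat)
    nm <- matrix(runif(n * A), n, A) < rep(params$p_not_measured,
                                           each = n)
    dates <- as.Date("2003-01-01") + sample.int(4745, n, replace = TRUE)
  })
  below <- sweep(conc, 2, params$lor, `<`)
  status <- matrix("observed", n, A)
  status[below] <- "below_lor"
  status[nm] <- "not_measured"

  wells <- tibble::tibble(
    test_id = rep(sprintf("test%06d", seq_len(n)), times = A),
    county = rep(county, times = A),
    tract_id = rep(unname(tract), times = A),
    date = rep(dates, times = A),
    analyte = rep(metals, each = n),
    status = as.vector(status),
    value = ifelse(as.vector(status) == "observed", as.vector(conc), NA_real_),
    lor = ifelse(as.vector(status) == "below_lor",
                 rep(params$lor, each = n), NA_real_)
  )
  truth <- list(
    latent = tibble::tibble(
      test_id = rep(sprintf("test%06d", seq_len(n)), times = A),
      analyte = rep(metals, each = n),
      latent_value = as.vector(conc)
    ),
    params = params,
    seed = seed
  )
  list(wells = wells, truth = truth)
}

#' Parameters for the birth-cohort generator
#'
#' Defaults emulate the study population: a 9.4% baseline preterm-birth
#' prevalence, the published race/ethnicity, education and smoking margins,
#' 8.9% missingness in education and smoking, and per-metal per-quartile
#' log-odds coefficients anchored to the published adjusted mixture
#' coefficients (their sum is the true mixture effect psi). Per-stratum
#' increments to psi are spread equally across the metal coefficients, so a
#' stratum's true mixture effect is `psi + increment`.
#'
#' @param n_births Number of births.
#' @param baseline_logodds Intercept of the outcome model; default
#'   `qlogis(0.094)`.
#' @param metal_coefficients Named per-metal per-quartile log-odds
#'   coefficients.
#' @param covariate_effects Named list of covariate effects on the log-odds
#'   scale (see Details in the source; all default to modest literature-scale
#'   values).
#' @param race_probs Named probabilities over the race/ethnicity levels.
#' @param modifier_increments Named per-stratum additive increments to psi
#'   (reference increment 0); names must be race levels.
#' @param p_smoking,p_education,p_missing_education,p_missing_smoking
#'   Covariate distribution knobs.
#' @param q Number of exposure quantiles used by the outcome model.
#' @param individual_noise_sd SD of optional individual-level log-exposure
#'   noise before quantization (default 0: births in a tract share the tract
#'   summary exactly).
#' @return A `birth_sim_params` list.
#' @export
birth_sim_params <- function(n_births = 10000,
                             baseline_logodds = qlogis(0.094),
                             metal_coefficients = c(
                               Cd = 0.015, Pb = 0.009, Cr = 0.004,
                               Zn = -0.009, iAs = -0.009, Cu = -0.005,
                               Mn = -0.002),
                             covariate_effects = list(
                               smoking = 0.35, age = -0.06, age_sq = 0.001,
                               education = -0.10, poverty = 0.05,
                               race = c("Black non-Hispanic" = 0.35,
                                        "Hispanic" = -0.10,
                                        "Asian/Pacific Islander" = -0.10,
                                        "American Indian" = 0.15,
                                        "Other/unknown" = 0)),
                             race_probs = c(
                               "White non-Hispanic" = 0.582,
                               "Black non-Hispanic" = 0.220,
                               "Hispanic" = 0.151,
                               "Asian/Pacific Islander" = 0.031,
                               "American Indian" = 0.015,
                               "Other/unknown" = 0.002),
                             modifier_increments = NULL,
                             p_smoking = 0.111,
                             p_education = c(0.204, 0.261, 0.535),
                             p_missing_education = 0.089,
                             p_missing_smoking = 0.089,
                             q = 4,
                             individual_noise_sd = 0) {
  race_probs <- race_probs / sum(race_probs)
  p_education <- p_education / sum(p_education)
  if (!is.null(modifier_increments) &&
      !all(names(modifier_increments) %in% names(race_probs))) {
    stop_wellmix("modifier increment names must be race/ethnicity levels",
                 "param_error")
  }
  structure(
    list(n_births = n_births, baseline_logodds = baseline_logodds,
         metal_coefficients = metal_coefficients,
         covariate_effects = covariate_effects,
         race_probs = race_probs,
         modifier_increments = modifier_increments,
         p_smoking = p_smoking, p_education = p_education,
         p_missing_education = p_missing_education,
         p_missing_smoking = p_missing_smoking,
         q = q, individual_noise_sd = individual_noise_sd,
         thresholds = c(extreme = 28, very = 32, ptb = 37)),
    class = "birth_sim_params"
  )
}

#' Simulate a birth cohort from tract exposures with known ground truth
#'
#' Assigns each birth to a tract (weights proportional to a mildly dispersed
#' lognormal draw, emulating unequal tract populations), joins the tract
#' exposure summary, quantizes each metal's birth-level exposure, draws
#' covariates from their stated distributions and draws the preterm-birth
#' indicator from the logistic outcome model. Gestational age is then
#' assigned uniformly within class: cases uniform on [20, 37) weeks,
#' non-cases uniform on [37, 44).
#'
#' @param params A [birth_sim_params()] object.
#' @param exposures Long tract exposure table from [tract_summaries()] (or
#'   any table with `tract_id`, `analyte`, `mean_conc`).
#' @param seed Integer seed.
#' @return A list with `births` (raw birth-record tibble matching the
#'   births.csv schema) and `truth` (true psi overall and per stratum, the
#'   per-metal coefficients, and the generator parameters).
#' @export
simulate_births <- function(params = birth_sim_params(), exposures, seed = 1) {
  stopifnot(inherits(params, "birth_sim_params"))
  if (is.null(exposures) || nrow(exposures) == 0) {
    stop_wellmix("empty exposure table", "input_error")
  }
  metals <- names(params$metal_coefficients)
  tracts <- unique(exposures$tract_id)
  n <- params$n_births
  ce <- params$covariate_effects
  race_levs <- names(params$race_probs)

  withr::with_seed(seed, {
    tract_w <- exp(rnorm(length(tracts), 0, 0.5))
    tract <- sample(tracts, n, replace = TRUE, prob = tract_w / sum(tract_w))

    conc <- matrix(NA_real_, n, length(metals),
                   dimnames = list(NULL, metals))
    for (m in metals) {
      em <- exposures[exposures$analyte == m, ]
      conc[, m] <- em$mean_conc[match(tract, em$tract_id)]
    }
    if (params$individual_noise_sd > 0) {
      conc <- conc * exp(matrix(rnorm(n * length(metals), 0,
                                      params$individual_noise_sd),
                                n, length(metals)))
    }
    S <- matrix(NA_real_, n, length(metals), dimnames = list(NULL, metals))
    for (m in metals) S[, m] <- quantize(conc[, m], q = params$q)$score

    race <- sample(race_levs, n, replace = TRUE, prob = params$race_probs)
    smoking <- rbinom(n, 1, params$p_smoking)
    education <- sample(education_levels(), n, replace = TRUE,
                        prob = params$p_education)
    age <- pmin(pmax(round(rnorm(n, 27, 6)), 13), 50)
    poverty <- sample(1:4, n, replace = TRUE)
    birth_date <- as.Date("2003-01-01") + sample.int(4745, n, replace = TRUE)

    # per-birth metal coefficients, shifted by the stratum increment
    beta_mat <- matrix(rep(params$metal_coefficients, each = n), n,
                       length(metals), dimnames = list(NULL, metals))
    if (!is.null(params$modifier_increments)) {
      for (lev in names(params$modifier_increments)) {
        idx <- race == lev
        beta_mat[idx, ] <- beta_mat[idx, , drop = FALSE] +
          params$modifier_increments[[lev]] / length(metals)
      }
    }
    eta <- params$baseline_logodds +
      rowSums(S * beta_mat) +
      ce$smoking * smoking +
      ce$age * (age - 27) + ce$age_sq * (age - 27)^2 +
      ce$education * (match(education, education_levels()) - 1) +
      ce$poverty * (poverty - 1)
    re_eff <- ce$race[race]
    re_eff[is.na(re_eff)] <- 0
    eta <- eta + re_eff

    ptb <- rbinom(n, 1, plogis(eta))
    ga <- ifelse(ptb == 1, runif(n, 20, 37), runif(n, 37, 44))
    ga <- floor(ga)

    education[runif(n) < params$p_missing_education] <- NA
    smoking_chr <- as.character(smoking)
    smoking_chr[runif(n) < params$p_missing_smoking] <- NA
  })

  births <- tibble::tibble(
    id = sprintf("birth%07d", seq_len(n)),
    tract_id = tract,
    ga_weeks = as.numeric(ga),
    birth_date = birth_date,
    plurality = 1L,
    anomaly_flag = 0L,
    age_years = as.numeric(age),
    race_ethnicity = race,
    education = education,
    smoking = suppressWarnings(as.integer(smoking_chr)),
    tract_poverty_quartile = poverty,
    pred_well_user_fraction = NA_real_
  )
  psi <- sum(params$metal_coefficients)
  psi_strata <- setNames(rep(psi, length(race_levs)), race_levs)
  if (!is.null(params$modifier_increments)) {
    for (lev in names(params$modifier_increments)) {
      psi_strata[lev] <- psi + params$modifier_increments[[lev]]
    }
  }
  truth <- list(
    psi = psi,
    psi_strata = as.list(psi_strata),
    metal_coefficients = as.list(params$metal_coefficients),
    seed = seed
  )
  list(births = births, truth = truth)
}

#' Write a self-consistent synthetic fixture bundle
#'
#' Generates wells, tract exposures (from the latent truth, so no imputation
#' is needed to build the bundle), births and a pipeline configuration, and
#' writes `wells.csv`, `births.csv`, `config.yaml` and `truth.json` to `dir`.
#' Seeds are fixed per size, so regenerating a bundle reproduces it
#' byte-for-byte.
#'
#' @param size `"tiny"` (200 tests, 2,000 births) or `"small"` (1,000 tests,
#'   10,000 births).
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
make_fixture <- function(size = c("tiny", "small"), dir = tempfile("fixture")) {
  size <- match.arg(size)
  dims <- switch(size,
    tiny = list(n_tests = 200, n_counties = 4, n_tracts = 12,
                n_births = 2000, seed = 101L),
    small = list(n_tests = 1000, n_counties = 8, n_tracts = 40,
                 n_births = 10000, seed = 202L)
  )
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wp <- well_sim_params(n_tests = dims$n_tests, n_counties = dims$n_counties,
                        n_tracts = dims$n_tracts)
  sim_w <- simulate_well_tests(wp, seed = dims$seed)
  complete <- sim_w$truth$latent |>
    dplyr::rename(value = "latent_value") |>
    dplyr::mutate(tract_id = sim_w$wells$tract_id[
      match(paste(.data$test_id, .data$analyte),
            paste(sim_w$wells$test_id, sim_w$wells$analyte))])
  exposures <- tract_summaries(complete, default_mcls())
  bp <- birth_sim_params(n_births = dims$n_births)
  sim_b <- simulate_births(bp, exposures, seed = dims$seed + 1L)

  # paths are stored relative to the config file so regenerated bundles are
  # byte-identical wherever they land; read_config() resolves them
  cfg <- wellmix_config(
    seeds = list(simulate = dims$seed, impute = dims$seed + 2L,
                 mixture = dims$seed + 3L),
    outcomes = "ptb",
    paths = list(wells = "wells.csv", births = "births.csv")
  )
  paths <- list(
    wells = file.path(dir, "wells.csv"),
    births = file.path(dir, "births.csv"),
    config = file.path(dir, "config.yaml"),
    truth = file.path(dir, "truth.json")
  )
  write_well_tests(sim_w$wells, paths$wells)
  readr::write_csv(sim_b$births, paths$births, na = "")
  write_config(cfg, paths$config)
  jsonlite::write_json(
    list(psi = sim_b$truth$psi,
         psi_strata = sim_b$truth$psi_strata,
         metal_coefficients = sim_b$truth$metal_coefficients,
         seeds = list(wells = dims$seed, births = dims$seed + 1L),
         synthetic = TRUE),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
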