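# Shared builders for synthetic inputs used across test files.

# Tract exposure table with correlated lognormal tract-mean concentrations,
# emulating the output of tract_summaries() without running the well stages.
make_test_exposures <- function(n_tracts = 400, seed = 42, rho = 0.3,
                                metals = wellmix_metals()) {
  loc <- c(iAs = log(0.220), Cd = log(0.007), Cr = log(0.579),
           Cu = log(21.1), Pb = log(1.43), Mn = log(33.6), Zn = log(126.8))
  scl <- c(iAs = 2.0, Cd = 2.3, Cr = 1.25, Cu = 1.5, Pb = 1.45, Mn = 1.35,
           Zn = 2.0)
  A <- length(metals)
  R <- matrix(rho, A, A); diag(R) <- 1
  withr::with_seed(seed, {
    Z <- matrix(rnorm(n_tracts * A), n_tracts, A) %*% chol(R)
  })
  L <- sweep(sweep(Z, 2, scl[metals], `*`), 2, loc[metals], `+`)
  tibble::tibble(
    tract_id = rep(sprintf("t%04d", seq_len(n_tracts)), times = A),
    analyte = rep(metals, each = n_tracts),
    mean_conc = exp(as.vector(L)),
    exceedance_fraction = NA_real_,
    n_tests = 1L
  )
}

# Birth cohort with conc_<metal> columns attached, ready for qgcomp fits.
make_test_cohort <- function(params, exposures, seed) {
  sim <- simulate_births(params, exposures, seed = seed)
  births <- dplyr::bind_cols(sim$births, derive_outcomes(sim$births$ga_weeks))
  for (m in names(params$metal_coefficients)) {
    em <- exposures[exposures$analyte == m, ]
    births[[paste0("conc_", m)]] <- em$mean_conc[match(births$tract_id,
                                                       em$tract_id)]
  }
  list(cohort = births, truth = sim$truth)
}

# Parameters with covariate effects and missingness switched off, for clean
# calibration checks where conditional and marginal effects coincide.
null_covariate_params <- function(n_births, metal_coefficients, ...) {
  birth_sim_params(
    n_births = n_births,
    metal_coefficients = metal_coefficients,
    covariate_effects = list(smoking = 0, age = 0, age_sq = 0, education = 0,
                             poverty = 0,
                             race = c("Black non-Hispanic" = 0,
                                      "Hispanic" = 0,
                                      "Asian/Pacific Islander" = 0,
                                      "American Indian" = 0,
                                      "Other/unknown" = 0)),
    p_missing_education = 0, p_missing_smoking = 0, ...)
}

# Small long-format well table built by hand for exposure / IO tests.
make_hand_wells <- function() {
  tibble::tibble(
    test_id = rep(sprintf("w%02d", 1:4), each = 2),
    county = rep(c("alpha", "alpha", "beta", "beta"), each = 2),
    tract_id = rep(c("tr1", "tr1", "tr2", "tr2"), each = 2),
    date = as.Date("2010-06-01") + rep(0:3, each = 2),
    analyte = rep(c("Pb", "iAs"), times = 4),
    status = c("observed", "observed",
               "observed", "below_lor",
               "observed", "observed",
               "not_measured", "observed"),
    value = c(2, 0.5, 4, NA, 20, 3.1, NA, 0.9),
    lor = c(NA, NA, NA, 1, NA, NA, NA, NA)
  )
}
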