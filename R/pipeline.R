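stage <- function(name, expr) {
  t0 <- Sys.time()
  inform(sprintf("[%s] starting", name))
  res <- tryCatch(force(expr), error = function(e) {
    stop_wellmix(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), "stage_error")
  })
  inform(sprintf("[%s] done in %.1fs", name,
                 as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> impute -> tract exposures -> cohort ->
#' single-metal models -> mixture models -> report. With identical
#' configuration and seeds the returned report bundle is identical, which is
#' the package's reproducibility contract. Stage progress and timings go to
#' stderr; timings are never part of the bundle.
#'
#' @param config A [wellmix_config()]; must carry either input `paths` or a
#'   `simulation` block.
#' @return A `wellmix_report` list: `exclusions`, `cutpoints`,
#'   `single_metal` (crude and adjusted OR tables for every requested
#'   outcome and both parameterizations), `mixture` (overall crude/adjusted
#'   fits, partial effects, stratified effects or a skip note), `diagnostics`
#'   (imputation trace summary), `exposures`, and `provenance` (config,
#'   seeds, package version).
#' @export
run_pipeline <- function(config = wellmix_config()) {
  validate_config(config)
  have_paths <- !is.null(config$paths)
  have_sim <- !is.null(config$simulation)
  if (!have_paths && !have_sim) {
    stop_wellmix("config must carry input paths or a simulation block",
                 "config_error")
  }

  dat <- stage("data", {
    if (have_paths && file.exists(config$paths$wells %||% "")) {
      list(
        wells = read_well_tests(config$paths$wells, config$analytes),
        births = read_birth_records(config$paths$births)
      )
    } else {
      sim <- config$simulation
      wp <- well_sim_params(
        n_tests = sim$n_tests %||% 5000,
        n_counties = sim$n_counties %||% 20,
        n_tracts = sim$n_tracts %||% 200,
        metals = config$analytes
      )
      sw <- simulate_well_tests(wp, seed = config$seeds$simulate)
      # births need exposures; built from the raw observed table for
      # assignment only (true tract summaries come later from imputed data)
      bp <- birth_sim_params(n_births = sim$n_births %||% 10000)
      latent <- sw$truth$latent |>
        dplyr::rename(value = "latent_value") |>
        dplyr::mutate(tract_id = sw$wells$tract_id[
          match(paste(.data$test_id, .data$analyte),
                paste(sw$wells$test_id, sw$wells$analyte))])
      expos <- tract_summaries(latent, default_mcls())
      sb <- simulate_births(bp, expos, seed = config$seeds$simulate + 1L)
      list(wells = sw$wells, births = sb$births)
    }
  })

  imp <- stage("impute", {
    impute_chain(dat$wells, analytes = config$analytes,
                 n_iterations = config$n_iterations,
                 seed = config$seeds$impute)
  })

  exposures <- stage("exposures", {
    mcl_tbl <- tibble::tibble(metal = names(config$mcl),
                              mcl = unlist(config$mcl))
    tract_summaries(imp$imputed, mcl_tbl)
  })

  cohort_res <- stage("cohort", {
    filt <- apply_inclusion_filters(dat$births, exposures)
    assigned <- assign_exposures(filt$cohort, exposures,
                                 metals = config$metals,
                                 threshold = config$exceedance_threshold)
    list(cohort = assigned$cohort, cutpoints = assigned$cutpoints,
         tally = filt$tally, n_input = filt$n_input,
         n_final = filt$n_final)
  })
  cohort <- cohort_res$cohort

  single <- stage("single_metal", {
    purrr::map_dfr(config$outcomes, function(oc) {
      dplyr::bind_rows(
        single_metal_models(cohort, outcome = oc, adjusted = FALSE,
                            metals = config$metals),
        single_metal_models(cohort, outcome = oc, adjusted = TRUE,
                            metals = config$metals,
                            covariates = config$covariates)
      )
    })
  })

  mixture <- stage("mixture", {
    res <- list()
    for (oc in config$outcomes) {
      res[[oc]] <- list(
        crude = qgcomp_fit(cohort, config$metals, covariates = NULL,
                           outcome = oc, q = config$q),
        adjusted = qgcomp_fit(cohort, config$metals,
                              covariates = config$covariates,
                              outcome = oc, q = config$q)
      )
    }
    primary <- config$outcomes[1]
    res$partial <- partial_effects(
      cohort, config$metals, covariates = config$covariates,
      outcome = primary, split_fraction = config$split_fraction,
      n_cycles = config$n_cycles, seed = config$seeds$mixture,
      q = config$q)
    res$strata <- tryCatch(
      qgcomp_emm(cohort, config$metals,
                 covariates = setdiff(config$covariates, "race_ethnicity"),
                 modifier = "race_ethnicity", outcome = primary,
                 q = config$q),
      error = function(e) {
        inform(paste0("stratified analysis skipped: ", conditionMessage(e)))
        paste0("skipped: ", conditionMessage(e))
      })
    res
  })

  report <- stage("report", {
    structure(
      list(
        exclusions = list(tally = cohort_res$tally,
                          n_input = cohort_res$n_input,
                          n_final = cohort_res$n_final),
        cutpoints = cohort_res$cutpoints,
        single_metal = single,
        mixture = mixture,
        diagnostics = list(
          trace = imp$diagnostics$trace,
          stability = trace_diagnostics(imp$diagnostics)
        ),
        exposures = exposures,
        provenance = list(
          config = unclass(config),
          seeds = config$seeds,
          package_version = as.character(utils::packageVersion("wellmix"))
        )
      ),
      class = "wellmix_report"
    )
  })
  report
}

#' @export
print.wellmix_report <- function(x, ...) {
  cat("wellmix pipeline report\n")
  cat(sprintf("  cohort: %d of %d births retained\n",
              x$exclusions$n_final, x$exclusions$n_input))
  cat(sprintf("  single-metal OR rows: %d\n", nrow(x$single_metal)))
  oc <- setdiff(names(x$mixture), c("partial", "strata"))[1]
  adj <- x$mixture[[oc]]$adjusted
  cat(sprintf("  adjusted mixture OR (%s): %.3f (%.3f, %.3f)\n", oc,
              adj$or, adj$ci_low, adj$ci_high))
  invisible(x)
}
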