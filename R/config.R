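#' Pipeline configuration
#'
#' Bundles every tunable of the analysis with its default: the modelled
#' metals; the analyte list used by the imputation model; the number of
#' exposure quantiles `q` (4, i.e. quartiles); the MCL-exceedance threshold
#' (0.25); the number of chained-equation iterations (30); the
#' partial-effects training share (0.30) and number of repeated split cycles
#' (12); named seeds per stage; the adjustment covariates; the outcomes; and
#' the MCL table. Every default is overridable, and the seeds are carried
#' into the report so any random quantity is reproducible.
#'
#' @param metals Modelled metals.
#' @param analytes Analytes entering the imputation model.
#' @param q Number of exposure quantiles (>= 2).
#' @param exceedance_threshold Fraction in (0, 1).
#' @param n_iterations Imputation iterations.
#' @param split_fraction Partial-effects training share in (0, 1).
#' @param n_cycles Partial-effects split cycles.
#' @param seeds Named list of integer seeds (`simulate`, `impute`,
#'   `mixture`).
#' @param covariates Adjustment covariate names.
#' @param outcomes Outcomes to model.
#' @param mcl Named list/vector of standards (ppb), one per modelled metal.
#' @param paths Optional named list with `wells` and `births` CSV paths.
#' @param simulation Optional named list passed to the synthetic generator
#'   (`n_tests`, `n_counties`, `n_tracts`, `n_births`).
#' @return A validated `wellmix_config` list.
#' @export
wellmix_config <- function(metals = wellmix_metals(),
                           analytes = c(wellmix_metals(), "nitrate_nitrite"),
                           q = 4,
                           exceedance_threshold = 0.25,
                           n_iterations = 30,
                           split_fraction = 0.30,
                           n_cycles = 12,
                           seeds = list(simulate = 1L, impute = 2L,
                                        mixture = 3L),
                           covariates = c("age", "race_ethnicity", "smoking",
                                          "education",
                                          "tract_poverty_quartile", "season",
                                          "nitrate_category"),
                           outcomes = c("ptb", "very_ptb", "extreme_ptb"),
                           mcl = NULL,
                           paths = NULL,
                           simulation = NULL) {
  if (is.null(mcl)) {
    mt <- default_mcls()
    mcl <- setNames(as.list(mt$mcl), mt$metal)
  }
  cfg <- structure(
    list(metals = metals, analytes = analytes, q = q,
         exceedance_threshold = exceedance_threshold,
         n_iterations = n_iterations, split_fraction = split_fraction,
         n_cycles = n_cycles, seeds = seeds, covariates = covariates,
         outcomes = outcomes, mcl = mcl, paths = paths,
         simulation = simulation),
    class = "wellmix_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$q < 2) stop_wellmix("q must be at least 2", "config_error")
  if (cfg$split_fraction <= 0 || cfg$split_fraction >= 1) {
    stop_wellmix("split_fraction must lie strictly between 0 and 1",
                 "config_error")
  }
  if (cfg$exceedance_threshold <= 0 || cfg$exceedance_threshold >= 1) {
    stop_wellmix("exceedance_threshold must lie strictly between 0 and 1",
                 "config_error")
  }
  missing_mcl <- setdiff(cfg$metals, names(cfg$mcl))
  if (length(missing_mcl) > 0) {
    stop_wellmix(paste0("no MCL configured for modelled metal(s): ",
                        paste(missing_mcl, collapse = ", ")), "config_error")
  }
  if (any(unlist(cfg$mcl) <= 0)) {
    stop_wellmix("all MCL standards must be positive", "config_error")
  }
  needed_seeds <- c("simulate", "impute", "mixture")
  if (!all(needed_seeds %in% names(cfg$seeds))) {
    stop_wellmix(paste0("seeds must name: ",
                        paste(needed_seeds, collapse = ", ")), "config_error")
  }
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return [read_config()] returns a `wellmix_config`; [write_config()]
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), names(formals(wellmix_config)))]
  args$metals <- unlist(args$metals)
  args$analytes <- unlist(args$analytes)
  args$covariates <- unlist(args$covariates)
  args$outcomes <- unlist(args$outcomes)
  cfg <- do.call(wellmix_config, args)
  # resolve input paths relative to the config file's own directory
  if (!is.null(cfg$paths)) {
    base <- dirname(normalizePath(path))
    cfg$paths <- lapply(cfg$paths, function(p) {
      if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
    })
  }
  cfg
}

#' @rdname read_config
#' @param cfg A `wellmix_config` object.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "wellmix_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
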