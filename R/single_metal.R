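#' Crude or adjusted single-metal odds-ratio tables
#'
#' For each metal fits two logistic models against the chosen preterm-birth
#' outcome: (a) the three-level percentile parameterization, entered as two
#' indicators against the at-or-below-median reference, and (b) the binary
#' MCL-exceedance parameterization. Odds ratios are exponentiated
#' coefficients with Wald 95% intervals. Reference rows carry OR 1.00, and
#' every contrast row reports the case and non-case counts of the crude-model
#' sample; adjusted models may use fewer rows (complete-case) and report
#' their own `n_model`.
#'
#' @param cohort Cohort tibble with `pctcat_<metal>` and `exceed_<metal>`
#'   columns (see [assign_exposures()]) and the outcome column.
#' @param outcome One of `"ptb"`, `"very_ptb"`, `"extreme_ptb"`.
#' @param adjusted Logical; adjust for the standard covariate set?
#' @param metals Metals to model (default all seven).
#' @param covariates Covariate list used when `adjusted = TRUE`.
#' @return An OR-table tibble: metal, parameterization, contrast, outcome,
#'   n_noncases, n_cases, or, ci_low, ci_high, adjusted, n_model, note.
#'   A metal whose exceedance flag is constant in the sample yields a warning
#'   row (`note`) instead of a model.
#' @export
single_metal_models <- function(cohort, outcome = "ptb", adjusted = FALSE,
                                metals = wellmix_metals(),
                                covariates = c("age", "race_ethnicity",
                                               "smoking", "education",
                                               "tract_poverty_quartile",
                                               "season", "nitrate_category")) {
  stopifnot(outcome %in% names(cohort))
  y_all <- cohort[[outcome]]
  rows <- list()

  fit_param <- function(exposure_cols, data) {
    # returns tidy tibble of exposure coefficients with Wald CIs
    if (adjusted) {
      dm <- build_design_matrix(data, covariates)
      X <- cbind(dm$X, as.matrix(data[dm$rows, exposure_cols, drop = FALSE]))
      y <- data[[outcome]][dm$rows]
    } else {
      X <- cbind("(Intercept)" = 1,
                 as.matrix(data[, exposure_cols, drop = FALSE]))
      y <- data[[outcome]]
    }
    keep <- complete.cases(X) & !is.na(y)
    Xk <- drop_constant_columns(X[keep, , drop = FALSE],
                                protect = c("(Intercept)", exposure_cols))
    Xk <- drop_aliased_columns(Xk, protect = c("(Intercept)", exposure_cols))
    fit <- fit_logistic(Xk, y[keep])
    se <- sqrt(diag(fit$vcov))
    list(
      est = unname(fit$beta[exposure_cols]),
      se = unname(se[exposure_cols]),
      n_model = sum(keep)
    )
  }

  for (m in metals) {
    pc <- cohort[[paste0("pctcat_", m)]]
    ex <- cohort[[paste0("exceed_", m)]]

    # --- percentile parameterization -------------------------------------
    dat <- cohort[!is.na(pc) & !is.na(y_all), , drop = FALSE]
    pcv <- dat[[paste0("pctcat_", m)]]
    dat$.pct1 <- as.numeric(pcv == 1)
    dat$.pct2 <- as.numeric(pcv == 2)
    counts <- function(flag) {
      c(noncases = sum(dat[[outcome]] == 0 & flag),
        cases = sum(dat[[outcome]] == 1 & flag))
    }
    c0 <- counts(pcv == 0); c1 <- counts(pcv == 1); c2 <- counts(pcv == 2)
    res <- tryCatch(fit_param(c(".pct1", ".pct2"), dat), error = identity)
    if (inherits(res, "error")) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        metal = m, parameterization = "percentile", contrast = "model_failed",
        outcome = outcome, n_noncases = NA_integer_, n_cases = NA_integer_,
        or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        adjusted = adjusted, n_model = NA_integer_,
        note = conditionMessage(res))
    } else {
      rows[[length(rows) + 1]] <- tibble::tibble(
        metal = m, parameterization = "percentile",
        contrast = c("<=p50 (ref)", ">p50 to <=p90", ">p90"),
        outcome = outcome,
        n_noncases = c(c0[["noncases"]], c1[["noncases"]], c2[["noncases"]]),
        n_cases = c(c0[["cases"]], c1[["cases"]], c2[["cases"]]),
        or = c(1, exp(res$est)),
        ci_low = c(NA, exp(res$est - 1.96 * res$se)),
        ci_high = c(NA, exp(res$est + 1.96 * res$se)),
        adjusted = adjusted, n_model = res$n_model, note = "")
    }

    # --- exceedance parameterization -------------------------------------
    dat <- cohort[!is.na(ex) & !is.na(y_all), , drop = FALSE]
    exv <- dat[[paste0("exceed_", m)]]
    if (length(unique(exv)) < 2) {
      warn(sprintf("exceedance flag constant for %s; model skipped", m))
      rows[[length(rows) + 1]] <- tibble::tibble(
        metal = m, parameterization = "exceedance", contrast = "skipped",
        outcome = outcome, n_noncases = NA_integer_, n_cases = NA_integer_,
        or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        adjusted = adjusted, n_model = NA_integer_,
        note = "constant exceedance flag")
      next
    }
    dat$.exc <- as.numeric(exv)
    cr <- c(noncases = sum(dat[[outcome]] == 0 & exv == 0),
            cases = sum(dat[[outcome]] == 1 & exv == 0))
    ce <- c(noncases = sum(dat[[outcome]] == 0 & exv == 1),
            cases = sum(dat[[outcome]] == 1 & exv == 1))
    res <- tryCatch(fit_param(".exc", dat), error = identity)
    if (inherits(res, "error")) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        metal = m, parameterization = "exceedance", contrast = "model_failed",
        outcome = outcome, n_noncases = NA_integer_, n_cases = NA_integer_,
        or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        adjusted = adjusted, n_model = NA_integer_,
        note = conditionMessage(res))
    } else {
      rows[[length(rows) + 1]] <- tibble::tibble(
        metal = m, parameterization = "exceedance",
        contrast = c("<25% tests >= MCL (ref)", ">=25% tests >= MCL"),
        outcome = outcome,
        n_noncases = c(cr[["noncases"]], ce[["noncases"]]),
        n_cases = c(cr[["cases"]], ce[["cases"]]),
        or = c(1, exp(res$est)),
        ci_low = c(NA, exp(res$est - 1.96 * res$se)),
        ci_high = c(NA, exp(res$est + 1.96 * res$se)),
        adjusted = adjusted, n_model = res$n_model, note = "")
    }
  }
  dplyr::bind_rows(rows)
}

#' Forest plot of a single-metal OR table
#' @param or_table Output of [single_metal_models()].
#' @return A ggplot object.
#' @export
plot_or_table <- function(or_table) {
  df <- dplyr::filter(or_table, !is.na(.data$or), .data$contrast != "skipped")
  df$label <- paste(df$metal, df$contrast)
  df$label <- factor(df$label, levels = rev(unique(df$label)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "OR (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
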