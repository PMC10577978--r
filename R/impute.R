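# Pool counties with fewer than `min_n` tests into an "other" level so the
# county indicator block cannot induce separation or rank problems.
pool_small_counties <- function(county, min_n = 5) {
  tab <- table(county)
  small <- names(tab)[tab < min_n]
  county[county %in% small] <- "other"
  factor(county)
}

#' Impute censored and unmeasured well-test concentrations
#'
#' Chained-equations imputation with a left-censored Gaussian (Tobit) model
#' on the natural-log concentration of each analyte given the current log
#' values of every other configured analyte plus county indicators. Cells
#' reported below the limit of reporting are censored at `log(LOR)`; cells
#' the test did not measure are censored at the log of the analyte's maximum
#' observed concentration. Each iteration cycles the analytes in the
#' configured order: fit the Tobit model, resample its parameters from
#' independent normals centred at the MLEs ([draw_parameters()]), then redraw
#' every incomplete cell from `Normal(x_i' beta*, sigma*^2)` truncated above
#' at its censor bound. Incomplete cells are initialised uniformly over the
#' analyte's observed log range. The complete table from the final iteration
#' is returned; observed cells are never touched.
#'
#' @param wells Long well-test tibble (`test_id`, `county`, `tract_id`,
#'   `date`, `analyte`, `status`, `value`, `lor`).
#' @param analytes Analytes to impute, cycled in this order; every one needs
#'   at least one observed value.
#' @param n_iterations Number of chained-equation iterations (default 30).
#' @param seed Integer seed governing initialisation, parameter resampling
#'   and truncated draws.
#' @return A list with `imputed` (the input tibble with `value` completed on
#'   the ppb scale and a logical `imputed` column) and `diagnostics`, an
#'   `imputation_diagnostics` object tracing the per-iteration mean and SD of
#'   imputed log values per analyte.
#' @export
impute_chain <- function(wells, analytes = wellmix_metals(),
                         n_iterations = 30, seed = 1) {
  stopifnot(all(c("test_id", "county", "analyte", "status", "value") %in%
                  names(wells)))
  sub <- dplyr::filter(wells, .data$analyte %in% analytes)
  wide_val <- tidyr::pivot_wider(sub[c("test_id", "analyte", "value")],
                                 names_from = "analyte",
                                 values_from = "value")
  wide_stat <- tidyr::pivot_wider(sub[c("test_id", "analyte", "status")],
                                  names_from = "analyte",
                                  values_from = "status")
  wide_lor <- tidyr::pivot_wider(sub[c("test_id", "analyte", "lor")],
                                 names_from = "analyte",
                                 values_from = "lor")
  missing_analytes <- setdiff(analytes, names(wide_val))
  if (length(missing_analytes) > 0) {
    stop_wellmix(paste0("analytes absent from table: ",
                        paste(missing_analytes, collapse = ", ")),
                 "input_error")
  }
  test_ids <- wide_val$test_id
  n <- length(test_ids)
  A <- length(analytes)
  V <- as.matrix(wide_val[analytes])          # ppb, NA where incomplete
  ST <- as.matrix(wide_stat[analytes])        # status strings
  LOR <- as.matrix(wide_lor[analytes])

  for (a in analytes) {
    if (!any(ST[, a] == "observed", na.rm = TRUE)) {
      stop_wellmix(paste0("analyte with zero observed values: ", a),
                   "input_error")
    }
  }

  county <- pool_small_counties(
    wells$county[match(test_ids, wells$test_id)])
  Cmat <- if (nlevels(county) > 1) {
    stats::model.matrix(~ county)[, -1, drop = FALSE]
  } else {
    matrix(nrow = n, ncol = 0)
  }

  obs <- ST == "observed"
  # censor bounds on the log scale
  B <- matrix(NA_real_, n, A, dimnames = list(NULL, analytes))
  for (j in seq_len(A)) {
    a <- analytes[j]
    max_obs <- max(V[obs[, j], j])
    B[ST[, j] == "below_lor", j] <- log(LOR[ST[, j] == "below_lor", j])
    B[ST[, j] == "not_measured", j] <- log(max_obs)
  }

  L <- log(V)   # log concentrations; NA where incomplete
  incomplete <- !obs
  if (!any(incomplete)) {
    out <- dplyr::mutate(wells, imputed = FALSE)
    trace <- tidyr::expand_grid(iteration = seq_len(n_iterations),
                                analyte = analytes) |>
      dplyr::mutate(mean = NA_real_, sd = NA_real_)
    diag <- structure(list(trace = trace, n_iterations = n_iterations,
                           seed = seed, analytes = analytes),
                      class = "imputation_diagnostics")
    return(list(imputed = out, diagnostics = diag))
  }

  trace_rows <- vector("list", n_iterations * A)
  withr::with_seed(seed, {
    # initialisation: uniform over the observed log range
    for (j in seq_len(A)) {
      idx <- which(incomplete[, j])
      if (length(idx) == 0) next
      rng <- range(L[obs[, j], j])
      L[idx, j] <- runif(length(idx), rng[1], rng[2])
    }
    for (it in seq_len(n_iterations)) {
      for (j in seq_len(A)) {
        idx <- which(incomplete[, j])
        others <- L[, -j, drop = FALSE]
        X <- cbind("(Intercept)" = 1, Cmat, others)
        fit <- fit_tobit(
          y = L[, j],
          cens = incomplete[, j],
          X = X,
          bound = B[, j]
        )
        par <- draw_parameters(fit)
        if (length(idx) > 0) {
          mu <- drop(X[idx, , drop = FALSE] %*% par$beta)
          L[idx, j] <- rtruncnorm_upper(length(idx), mu, par$sigma, B[idx, j])
        }
        trace_rows[[(it - 1) * A + j]] <- tibble::tibble(
          iteration = it, analyte = analytes[j],
          mean = if (length(idx)) mean(L[idx, j]) else NA_real_,
          sd = if (length(idx) > 1) sd(L[idx, j]) else NA_real_
        )
      }
    }
  })

  # map completed values back onto the long table
  filled <- tibble::tibble(
    test_id = rep(test_ids, times = A),
    analyte = rep(analytes, each = n),
    .value_new = exp(as.vector(L)),
    .imputed_new = as.vector(incomplete)
  )
  out <- wells |>
    dplyr::left_join(filled, by = c("test_id", "analyte")) |>
    dplyr::mutate(
      imputed = dplyr::coalesce(.data$.imputed_new, FALSE),
      value = dplyr::if_else(is.na(.data$.value_new), .data$value,
                             .data$.value_new)
    ) |>
    dplyr::select(-".value_new", -".imputed_new")

  diag <- structure(
    list(trace = dplyr::bind_rows(trace_rows), n_iterations = n_iterations,
         seed = seed, analytes = analytes),
    class = "imputation_diagnostics"
  )
  list(imputed = out, diagnostics = diag)
}

#' @export
print.imputation_diagnostics <- function(x, ...) {
  cat(sprintf("Imputation diagnostics: %d iterations over %d analytes (seed %s)\n",
              x$n_iterations, length(x$analytes), format(x$seed)))
  print(trace_diagnostics(x))
  invisible(x)
}

#' Stability summary of an imputation trace
#'
#' Regresses the trace of per-iteration imputed means on the iteration index
#' over the last 10 iterations (or all available, with a warning, when the
#' chain is shorter) and flags each analyte stable when the absolute slope is
#' below `tol` log-ppb per iteration. This is the numerical counterpart of
#' eyeballing trace plots for drift.
#'
#' @param diag An `imputation_diagnostics` object from [impute_chain()].
#' @param tol Absolute slope tolerance (default 0.01 log-ppb/iteration).
#' @return Tibble with `analyte`, `slope`, `stable`.
#' @export
trace_diagnostics <- function(diag, tol = 0.01) {
  stopifnot(inherits(diag, "imputation_diagnostics"))
  trace <- diag$trace
  last <- max(trace$iteration)
  if (last < 10) {
    warn(sprintf("only %d iterations available; stability assessed on all of them",
                 last))
    window <- seq_len(last)
  } else {
    window <- (last - 9):last
  }
  trace |>
    dplyr::filter(.data$iteration %in% window, !is.na(.data$mean)) |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(
      slope = if (dplyr::n() >= 2) {
        unname(coef(lm(mean ~ iteration,
                       data = data.frame(mean = .data$mean,
                                         iteration = .data$iteration)))[2])
      } else 0,
      .groups = "drop"
    ) |>
    dplyr::mutate(stable = abs(.data$slope) < tol)
}

#' Trace plot of imputation means
#' @param object An `imputation_diagnostics` object.
#' @param ... Unused.
#' @return A ggplot object with one panel per analyte.
#' @export
autoplot.imputation_diagnostics <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$mean)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "Iteration", y = "Mean imputed log concentration") +
    ggplot2::theme_minimal()
}
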