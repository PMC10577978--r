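#' Quantile-score an exposure
#'
#' Converts a continuous exposure into integer quantile scores
#' `0, ..., q - 1`. Cutpoints are the `1/q, ..., (q-1)/q` sample quantiles
#' (linear interpolation) of the supplied birth-level distribution; a value's
#' score is the number of cutpoints strictly below it, so ties at a cutpoint
#' fall to the lower score.
#'
#' @param values Numeric exposure vector (missing entries get `NA` scores).
#' @param q Number of quantile groups (default 4, i.e. quartiles).
#' @param cutpoints Optional pre-computed cutpoints (length `q - 1`); used by
#'   the sample-splitting machinery so that "one quartile" means the same
#'   contrast in training and validation splits.
#' @return A list with `score` (integer vector) and `cutpoints`.
#' @examples
#' quantize(1:8, q = 4)$score
#' @export
quantize <- function(values, q = 4, cutpoints = NULL) {
  stopifnot(q >= 2)
  ok <- !is.na(values)
  if (is.null(cutpoints)) {
    if (length(unique(values[ok])) < 2) {
      stop_wellmix("constant exposure cannot be quantized", "degenerate_error")
    }
    cutpoints <- quantile(values[ok], probs = seq_len(q - 1) / q,
                          names = FALSE, type = 7)
  }
  score <- rep(NA_integer_, length(values))
  score[ok] <- score_from_cutpoints(values[ok], cutpoints)
  list(score = as.integer(score), cutpoints = cutpoints)
}

# Resolve the data column holding a metal's exposure values: prefer the
# tract-mean concentration column conc_<metal>, else the bare name.
exposure_column <- function(data, metal) {
  cand <- paste0("conc_", metal)
  if (cand %in% names(data)) cand else metal
}

# Build the score matrix for a metal list, sharing supplied cutpoints.
score_matrix <- function(data, metals, q, cutpoints = NULL) {
  S <- matrix(NA_real_, nrow(data), length(metals),
              dimnames = list(NULL, metals))
  cuts <- list()
  for (m in metals) {
    qz <- quantize(data[[exposure_column(data, m)]], q = q,
                   cutpoints = cutpoints[[m]])
    S[, m] <- qz$score
    cuts[[m]] <- qz$cutpoints
  }
  list(S = S, cutpoints = cuts)
}

# Signed weights: w_j = beta_j / |sum of same-signed betas|, so positive
# weights sum to 1 and negative weights to -1 when that direction is present.
signed_weights <- function(beta) {
  w <- rep(0, length(beta))
  pos <- beta > 0
  neg <- beta < 0
  if (any(pos)) w[pos] <- beta[pos] / sum(beta[pos])
  if (any(neg)) w[neg] <- -beta[neg] / sum(beta[neg])
  setNames(w, names(beta))
}

#' Quantile-based g-computation for an exposure mixture
#'
#' Fits the joint model
#' \deqn{\mathrm{logit}\,P(Y=1) = \alpha + \sum_j \beta_j s_{ij} +
#'   \gamma^\top z_i}
#' where \eqn{s_{ij}} is the quantile score of metal \eqn{j} for birth
#' \eqn{i}, and summarises the mixture by
#' \eqn{\psi = \sum_j \beta_j}: the change in log-odds from simultaneously
#' raising every exposure by one quantile. The Wald interval uses
#' \eqn{\mathrm{Var}(\hat\psi) = \mathbf{1}^\top V \mathbf{1}} over the
#' exposure block of the coefficient covariance. Per-metal weights are
#' \eqn{\beta_j} normalised within its sign group, so positive weights sum to
#' 1 and negative weights to -1. This is the no-bootstrap (conditional) form:
#' \eqn{\psi} is a conditional log-OR per simultaneous quantile increase.
#'
#' @param data Cohort tibble. Exposure values for metal `m` are read from
#'   column `conc_<m>` if present, else from column `m`.
#' @param metals Character vector of mixture components.
#' @param covariates Covariate names passed to [build_design_matrix()]
#'   (`NULL` for a crude model).
#' @param outcome Name of the binary outcome column.
#' @param q Number of quantiles (default 4).
#' @param family `"binomial"` (logistic, the default) or `"gaussian"`
#'   (identity-link linear model, useful for closed-form checks).
#' @param cutpoints Optional named list of pre-computed cutpoints per metal.
#' @return A `qgcomp_result`: list with `psi`, `or`, `ci_low`, `ci_high`
#'   (OR scale), `se_psi`, `coefficients` (tibble of metal, coefficient,
#'   weight, direction), `cutpoints`, `fit`, `n`, `n_dropped`, `outcome`,
#'   `q`, `family`.
#' @export
qgcomp_fit <- function(data, metals, covariates = NULL, outcome = "ptb",
                       q = 4, family = c("binomial", "gaussian"),
                       cutpoints = NULL) {
  family <- match.arg(family)
  sm <- score_matrix(data, metals, q, cutpoints)
  if (!is.null(covariates) && length(covariates) > 0) {
    dm <- build_design_matrix(data, covariates)
    Z <- dm$X
    rows_z <- dm$rows
  } else {
    Z <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
    rows_z <- seq_len(nrow(data))
  }
  y_all <- data[[outcome]]
  keep <- intersect(rows_z, which(stats::complete.cases(sm$S) & !is.na(y_all)))
  X <- cbind(Z[match(keep, rows_z), , drop = FALSE],
             sm$S[keep, , drop = FALSE])
  X <- drop_constant_columns(X, protect = c("(Intercept)", metals))
  X <- drop_aliased_columns(X, protect = c("(Intercept)", metals))
  y <- y_all[keep]

  if (family == "binomial") {
    fit <- fit_logistic(X, y)
    beta_all <- fit$beta
    V <- fit$vcov
  } else {
    lmfit <- lm(y ~ X - 1)
    beta_all <- setNames(coef(lmfit), colnames(X))
    V <- stats::vcov(lmfit)
    dimnames(V) <- list(colnames(X), colnames(X))
    fit <- lmfit
  }
  bmix <- beta_all[metals]
  psi <- sum(bmix)
  ones <- rep(1, length(metals))
  var_psi <- drop(t(ones) %*% V[metals, metals, drop = FALSE] %*% ones)
  se_psi <- sqrt(var_psi)
  w <- signed_weights(bmix)
  structure(
    list(
      psi = psi,
      or = exp(psi),
      ci_low = exp(psi - 1.96 * se_psi),
      ci_high = exp(psi + 1.96 * se_psi),
      se_psi = se_psi,
      coefficients = tibble::tibble(
        metal = metals,
        coefficient = unname(bmix),
        weight = unname(w),
        direction = ifelse(bmix > 0, "positive", "negative")
      ),
      cutpoints = sm$cutpoints,
      fit = fit,
      n = length(y),
      n_dropped = nrow(data) - length(y),
      outcome = outcome,
      q = q,
      family = family
    ),
    class = "qgcomp_result"
  )
}

#' @export
print.qgcomp_result <- function(x, ...) {
  cat(sprintf(
    "Quantile-based g-computation (%s), outcome '%s', q = %d, n = %d\n",
    x$family, x$outcome, x$q, x$n))
  cat(sprintf("  psi = %.4f  OR per quantile increase = %.3f (95%% CI %.3f, %.3f)\n",
              x$psi, x$or, x$ci_low, x$ci_high))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.qgcomp_result <- function(x, ...) x$coefficients

#' @export
glance.qgcomp_result <- function(x, ...) {
  tibble::tibble(psi = x$psi, or = x$or, ci_low = x$ci_low,
                 ci_high = x$ci_high, se_psi = x$se_psi, n = x$n,
                 n_dropped = x$n_dropped, outcome = x$outcome, q = x$q)
}

#' Weight plot for a mixture fit
#'
#' Horizontal bar chart of signed per-metal weights, the conventional display
#' for quantile-based g-computation results.
#'
#' @param object A [qgcomp_fit()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qgcomp_result <- function(object, ...) {
  df <- dplyr::arrange(object$coefficients, .data$weight)
  df$metal <- factor(df$metal, levels = df$metal)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight, y = .data$metal,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Signed weight", y = NULL,
                  title = sprintf("Mixture OR per quantile increase: %.3f (%.3f, %.3f)",
                                  object$or, object$ci_low, object$ci_high)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Sample-splitting partial effects for a mixture
#'
#' Repeats, for `n_cycles` seeded cycles: randomly split the analysis sample
#' into a training share (`split_fraction`, default 30%) and a validation
#' share; fit the full mixture on the training split and partition the metals
#' by coefficient sign into a positive set and a negative set (an exactly
#' zero coefficient goes to the negative set); then, on the validation split,
#' estimate the positive-set mixture effect adjusting for the negative-set
#' scores as covariates, and vice versa. Quantile cutpoints are computed once
#' on the full sample and reused everywhere, so "one quantile" is the same
#' physical contrast in every fit.
#'
#' @inheritParams qgcomp_fit
#' @param split_fraction Training share in (0, 1), default 0.30.
#' @param n_cycles Number of repeated random splits, default 12.
#' @param seed Integer master seed; cycle seeds are derived by fixed
#'   increments, and a split that leaves a side without both cases and
#'   non-cases is redrawn (at most 5 times) with a logged note.
#' @return A `partial_effects_result`: list with `cycles` (one row per cycle:
#'   seed, positive/negative sets, validation-set psi/OR/CI per direction),
#'   `summary` (per-direction median OR and CI across cycles, and the modal
#'   sign partition), plus the shared `cutpoints`.
#' @export
partial_effects <- function(data, metals, covariates = NULL, outcome = "ptb",
                            split_fraction = 0.30, n_cycles = 12, seed = 1,
                            q = 4) {
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop_wellmix("split_fraction must lie strictly between 0 and 1",
                 "input_error")
  }
  shared <- score_matrix(data, metals, q)$cutpoints
  work <- data
  for (m in metals) {
    work[[paste0("score_", m)]] <-
      quantize(work[[exposure_column(work, m)]], q = q,
               cutpoints = shared[[m]])$score
  }
  n <- nrow(work)
  n_train <- round(split_fraction * n)
  y <- work[[outcome]]

  one_cycle <- function(cycle) {
    notes <- character()
    for (attempt in 0:5) {
      if (attempt == 5) {
        stop_wellmix("could not draw a split with cases in both sets after 5 redraws",
                     "split_error")
      }
      cycle_seed <- seed + cycle + 1000L * attempt
      idx <- withr::with_seed(cycle_seed, sample.int(n))
      train <- idx[seq_len(n_train)]
      valid <- idx[-seq_len(n_train)]
      ok <- function(i) {
        yy <- y[i]
        any(yy == 1, na.rm = TRUE) && any(yy == 0, na.rm = TRUE)
      }
      if (ok(train) && ok(valid)) break
      notes <- c(notes, sprintf("redrew split (attempt %d)", attempt + 1L))
    }
    train_fit <- qgcomp_fit(work[train, , drop = FALSE], metals, covariates,
                            outcome, q = q, cutpoints = shared)
    pos_set <- train_fit$coefficients$metal[train_fit$coefficients$coefficient > 0]
    neg_set <- setdiff(metals, pos_set)

    fit_side <- function(mix, other) {
      if (length(mix) == 0) return(NULL)
      covs <- c(covariates,
                if (length(other) > 0) paste0("score_", other))
      qgcomp_fit(work[valid, , drop = FALSE], mix, covs, outcome, q = q,
                 cutpoints = shared[mix])
    }
    pos_fit <- fit_side(pos_set, neg_set)
    neg_fit <- fit_side(neg_set, pos_set)
    gl <- function(f) {
      if (is.null(f)) {
        tibble::tibble(psi = NA_real_, or = NA_real_, ci_low = NA_real_,
                       ci_high = NA_real_)
      } else {
        tibble::tibble(psi = f$psi, or = f$or, ci_low = f$ci_low,
                       ci_high = f$ci_high)
      }
    }
    gp <- gl(pos_fit)
    gn <- gl(neg_fit)
    tibble::tibble(
      cycle = cycle,
      seed = seed + cycle,
      pos_set = list(pos_set),
      neg_set = list(neg_set),
      psi_pos = gp$psi, or_pos = gp$or,
      ci_low_pos = gp$ci_low, ci_high_pos = gp$ci_high,
      psi_neg = gn$psi, or_neg = gn$or,
      ci_low_neg = gn$ci_low, ci_high_neg = gn$ci_high,
      pos_weights = list(if (is.null(pos_fit)) NULL else pos_fit$coefficients),
      neg_weights = list(if (is.null(neg_fit)) NULL else neg_fit$coefficients),
      notes = paste(notes, collapse = "; ")
    )
  }
  cycles <- purrr::map_dfr(seq_len(n_cycles), one_cycle)

  partition_key <- purrr::map_chr(cycles$pos_set,
                                  ~ paste(sort(.x), collapse = "+"))
  modal <- names(sort(table(partition_key), decreasing = TRUE))[1]
  summary <- tibble::tibble(
    direction = c("positive", "negative"),
    median_or = c(stats::median(cycles$or_pos, na.rm = TRUE),
                  stats::median(cycles$or_neg, na.rm = TRUE)),
    median_ci_low = c(stats::median(cycles$ci_low_pos, na.rm = TRUE),
                      stats::median(cycles$ci_low_neg, na.rm = TRUE)),
    median_ci_high = c(stats::median(cycles$ci_high_pos, na.rm = TRUE),
                       stats::median(cycles$ci_high_neg, na.rm = TRUE))
  )
  structure(
    list(cycles = cycles, summary = summary, modal_positive_set = modal,
         prop_modal = mean(partition_key == modal), cutpoints = shared,
         n_cycles = n_cycles, seed = seed),
    class = "partial_effects_result"
  )
}

#' @export
print.partial_effects_result <- function(x, ...) {
  cat(sprintf("Partial-effects quantile g-computation: %d cycles, modal positive set {%s} in %.0f%% of cycles\n",
              x$n_cycles, x$modal_positive_set, 100 * x$prop_modal))
  print(x$summary)
  invisible(x)
}

#' Effect-measure modification of the mixture effect by a categorical stratum
#'
#' Fits a single shared logistic model containing the quantile scores, the
#' modifier's main-effect indicators, products of every score with every
#' non-reference modifier indicator, and the adjustment covariates (the
#' modifier itself is excluded from the covariate list). The stratum-specific
#' mixture effect is
#' \eqn{\psi_g = \sum_j (\beta_j + \eta_{jg})}, with \eqn{\eta \equiv 0} in
#' the reference stratum, and its variance is the corresponding quadratic
#' form in the coefficient covariance. Using one shared model borrows
#' covariate information across strata instead of refitting per stratum.
#'
#' @inheritParams qgcomp_fit
#' @param modifier Name of the categorical modifier column (e.g.
#'   `race_ethnicity`); its first factor level is the reference stratum.
#' @return A `qgcomp_emm` object: list with `strata` (tibble: level, n,
#'   n_cases, psi, or, ci_low, ci_high), `coefficients` (the full shared
#'   model), `fit`, `cutpoints`.
#' @export
qgcomp_emm <- function(data, metals, covariates = NULL,
                       modifier = "race_ethnicity", outcome = "ptb", q = 4) {
  covariates <- setdiff(covariates, modifier)
  mod_raw <- data[[modifier]]
  if (is.factor(mod_raw)) {
    g <- droplevels(mod_raw)
  } else if (identical(modifier, "race_ethnicity")) {
    g <- factor(mod_raw, levels = race_levels())
    g <- droplevels(g)
  } else {
    g <- factor(mod_raw)
  }
  levs <- levels(g)
  if (length(levs) < 2) {
    stop_wellmix("modifier needs at least two observed levels", "input_error")
  }

  sm <- score_matrix(data, metals, q)
  if (!is.null(covariates) && length(covariates) > 0) {
    dm <- build_design_matrix(data, covariates)
    Z <- dm$X
    rows_z <- dm$rows
  } else {
    Z <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
    rows_z <- seq_len(nrow(data))
  }
  y_all <- data[[outcome]]
  keep <- intersect(rows_z,
                    which(stats::complete.cases(sm$S) & !is.na(y_all) & !is.na(g)))
  y <- y_all[keep]
  gg <- g[keep]
  for (lev in levs) {
    yy <- y[gg == lev]
    if (!any(yy == 1)) {
      stop_wellmix(paste0("stratum without cases: ", lev), "stratum_error")
    }
    if (!any(yy == 0)) {
      stop_wellmix(paste0("stratum without non-cases: ", lev), "stratum_error")
    }
  }
  S <- sm$S[keep, , drop = FALSE]
  Zk <- Z[match(keep, rows_z), , drop = FALSE]
  blocks <- list(Zk, S)
  nm_int <- character()
  for (lev in levs[-1]) {
    ind <- as.numeric(gg == lev)
    tag <- gsub("[^A-Za-z0-9]+", "_", lev)
    main <- matrix(ind, ncol = 1, dimnames = list(NULL, paste0("mod_", tag)))
    inter <- S * ind
    colnames(inter) <- paste0(metals, ":mod_", tag)
    nm_int <- c(nm_int, colnames(inter))
    blocks <- c(blocks, list(main, inter))
  }
  X <- do.call(cbind, blocks)
  protect_emm <- c("(Intercept)", metals, nm_int,
                   paste0("mod_", gsub("[^A-Za-z0-9]+", "_", levs[-1])))
  X <- drop_constant_columns(X, protect = protect_emm)
  X <- drop_aliased_columns(X, protect = protect_emm)
  fit <- fit_logistic(X, y)
  V <- fit$vcov
  beta <- fit$beta

  strata <- purrr::map_dfr(levs, function(lev) {
    cvec <- setNames(rep(0, length(beta)), names(beta))
    cvec[metals] <- 1
    if (lev != levs[1]) {
      tag <- gsub("[^A-Za-z0-9]+", "_", lev)
      cvec[paste0(metals, ":mod_", tag)] <- 1
    }
    psi <- sum(beta * cvec)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tibble::tibble(
      level = lev,
      n = sum(gg == lev),
      n_cases = sum(y[gg == lev]),
      psi = psi,
      or = exp(psi),
      ci_low = exp(psi - 1.96 * se),
      ci_high = exp(psi + 1.96 * se)
    )
  })
  structure(
    list(
      strata = strata,
      coefficients = tibble::tibble(term = names(beta),
                                    estimate = unname(beta),
                                    std.error = sqrt(diag(V))),
      fit = fit,
      cutpoints = sm$cutpoints,
      reference = levs[1],
      modifier = modifier,
      outcome = outcome,
      q = q
    ),
    class = "qgcomp_emm"
  )
}

#' @export
print.qgcomp_emm <- function(x, ...) {
  cat(sprintf("Stratified mixture effects by %s (reference: %s), outcome '%s'\n",
              x$modifier, x$reference, x$outcome))
  print(x$strata)
  invisible(x)
}

#' @export
tidy.qgcomp_emm <- function(x, ...) x$strata

#' Forest plot of stratum-specific mixture odds ratios
#' @param object A [qgcomp_emm()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qgcomp_emm <- function(object, ...) {
  df <- object$strata
  df$level <- factor(df$level, levels = rev(df$level))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$level)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Mixture OR per quantile increase (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
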