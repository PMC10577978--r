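#' Maximum-likelihood logistic regression
#'
#' Newton--Raphson with step-halving from a zero start. Convergence is
#' declared when the largest score component falls below `1e-8` or the
#' log-likelihood improves by less than `1e-10`. The coefficient covariance is
#' the inverse observed information at the optimum, which is what the Wald
#' confidence intervals elsewhere in the package rest on.
#'
#' @param X Design matrix including the intercept column; full column rank.
#' @param y Binary response vector (0/1).
#' @param max_iter Maximum Newton iterations (default 100).
#' @return An object of class `logistic_fit` with `beta`, `vcov`, `loglik`,
#'   `n`, `iterations`, `converged`.
#' @details Perfect separation is reported as an error: it manifests as a
#'   coefficient path diverging while the score does not vanish, so no finite
#'   maximiser exists and Wald inference would be meaningless.
#' @examples
#' X <- cbind(1, rbinom(500, 1, 0.4))
#' y <- rbinom(500, 1, plogis(-1 + 0.7 * X[, 2]))
#' fit <- fit_logistic(X, y)
#' exp(fit$beta[2])
#' @export
fit_logistic <- function(X, y, max_iter = 100L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (!all(y %in% c(0, 1))) {
    stop_wellmix("outcome must be coded 0/1", "input_error")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop_wellmix("design matrix is rank deficient", "rank_error")
  }
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))

  loglik <- function(beta) {
    eta <- drop(X %*% beta)
    # log(1 + exp(eta)) computed overflow-free
    sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  }
  # Newton step solved as a weighted least-squares problem through the QR of
  # sqrt(w) X, which is much better conditioned than forming X'WX.
  newton_step <- function(mu) {
    w <- pmax(mu * (1 - mu), 1e-10)
    sw <- sqrt(w)
    qrx <- qr(X * sw)
    if (qrx$rank < p) {
      stop_wellmix("observed information is singular (possible separation)",
                   "separation_error")
    }
    step <- qr.coef(qrx, (y - mu) / sw)
    list(step = step, qrx = qrx)
  }
  beta <- rep(0, p)
  ll <- loglik(beta)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    score <- drop(crossprod(X, y - mu))
    step <- newton_step(mu)$step
    # step halving
    new_beta <- beta + step
    new_ll <- loglik(new_beta)
    halvings <- 0L
    while (!is.finite(new_ll) || new_ll < ll) {
      halvings <- halvings + 1L
      if (halvings > 30L) break
      step <- step / 2
      new_beta <- beta + step
      new_ll <- loglik(new_beta)
    }
    delta_ll <- new_ll - ll
    beta <- new_beta
    ll <- new_ll
    if (max(abs(score)) < 1e-8 || (delta_ll >= 0 && delta_ll < 1e-10)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  # complete separation: the coefficient path diverges while every fitted
  # probability collapses onto its outcome, so no finite MLE exists. A
  # sparse covariate cell (quasi-separation) leaves interior probabilities
  # elsewhere and still yields a usable fit with a wide interval.
  if (max(abs(beta)) > 15 && max(mu * (1 - mu)) < 1e-6) {
    stop_wellmix("perfect separation detected: no finite MLE exists",
                 "separation_error")
  }
  if (!converged) {
    stop_wellmix("logistic fit failed to converge", "convergence_error")
  }
  qrx <- newton_step(mu)$qrx
  Rm <- qr.R(qrx)
  piv <- qrx$pivot
  vcov <- chol2inv(Rm)
  vcov <- vcov[order(piv), order(piv), drop = FALSE]
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(
    list(
      beta = setNames(beta, colnames(X)),
      vcov = vcov,
      loglik = ll,
      n = n,
      iterations = iter,
      converged = converged
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit: n = %d, logLik = %.4f, %d iterations\n",
              x$n, x$loglik, x$iterations))
  print(round(cbind(estimate = x$beta, se = sqrt(diag(x$vcov))), 4))
  invisible(x)
}

#' @export
tidy.logistic_fit <- function(x, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  zq <- qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = unname(se),
    statistic = unname(x$beta / se),
    p.value = 2 * pnorm(-abs(unname(x$beta / se))),
    conf.low = unname(x$beta - zq * se),
    conf.high = unname(x$beta + zq * se)
  )
}

#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n = x$n, iterations = x$iterations,
                 converged = x$converged)
}

#' Odds ratio from a 2x2 table with a Wald confidence interval
#'
#' Computes `OR = (exposed_cases * ref_noncases) / (exposed_noncases *
#' ref_cases)` and the Wald interval
#' `exp(log OR +/- z * sqrt(sum of reciprocal cell counts))`. No continuity
#' correction is applied: a zero cell is an error rather than a silently
#' adjusted estimate.
#'
#' @param exposed_cases,exposed_noncases,ref_cases,ref_noncases Cell counts.
#' @param conf.level Confidence level (default 0.95).
#' @return A one-row tibble: `or`, `ci_low`, `ci_high`, `log_or`, `se_log_or`.
#' @examples
#' odds_ratio_2x2(466, 109433, 4819, 1214353)
#' @export
odds_ratio_2x2 <- function(exposed_cases, exposed_noncases,
                           ref_cases, ref_noncases, conf.level = 0.95) {
  cells <- c(exposed_cases = exposed_cases, exposed_noncases = exposed_noncases,
             ref_cases = ref_cases, ref_noncases = ref_noncases)
  if (any(cells < 0)) {
    stop_wellmix(paste0("negative count in cell: ",
                        paste(names(cells)[cells < 0], collapse = ", ")),
                 "validation_error")
  }
  if (any(cells == 0)) {
    stop_wellmix(paste0("zero count in cell: ",
                        paste(names(cells)[cells == 0], collapse = ", "),
                        "; no continuity correction is applied"),
                 "zero_cell_error")
  }
  log_or <- log(exposed_cases) + log(ref_noncases) -
    log(exposed_noncases) - log(ref_cases)
  se <- sqrt(sum(1 / cells))
  zq <- qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(
    or = exp(log_or),
    ci_low = exp(log_or - zq * se),
    ci_high = exp(log_or + zq * se),
    log_or = log_or,
    se_log_or = se
  )
}
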