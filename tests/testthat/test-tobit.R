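test_that("with no censoring the Tobit MLE is the Gaussian least-squares fit", {
  withr::with_seed(11, {
    x <- rnorm(200)
    y <- 1.5 - 0.8 * x + rnorm(200, sd = 0.6)
  })
  fit <- fit_tobit(y, rep(FALSE, 200), cbind("(Intercept)" = 1, x = x))
  ols <- lm(y ~ x)
  expect_lt(max(abs(fit$beta - coef(ols))), 1e-6)
  expect_lt(abs(fit$sigma - sqrt(mean(residuals(ols)^2))), 1e-6)
})

test_that("intercept-only censored fits match the grid-search oracle", {
  for (fx in tobit_oracle_fixtures()) {
    n <- length(fx$y) + fx$n_cens
    y <- c(fx$y, rep(NA, fx$n_cens))
    cens <- c(rep(FALSE, length(fx$y)), rep(TRUE, fx$n_cens))
    bound <- c(rep(NA, length(fx$y)), rep(fx$c, fx$n_cens))
    fit <- fit_tobit(y, cens, matrix(1, n, 1,
                                     dimnames = list(NULL, "(Intercept)")),
                     bound = bound)
    oracle <- grid_tobit_intercept(fx$y, rep(fx$c, fx$n_cens))
    expect_lt(abs(fit$beta[[1]] - oracle$beta0), 1e-3)
    expect_lt(abs(fit$sigma - oracle$sigma), 1e-3)
  }
})

test_that("Tobit estimates recover known parameters under 30% censoring", {
  withr::with_seed(21, {
    n <- 5000
    x1 <- rnorm(n)
    x2 <- rbinom(n, 1, 0.4)
    mu <- 0.5 + 0.7 * x1 - 0.4 * x2
    y <- mu + rnorm(n, sd = 0.9)
  })
  bound <- quantile(y, 0.30)  # censor the lowest ~30%
  cens <- y < bound
  yv <- ifelse(cens, NA, y)
  X <- cbind("(Intercept)" = 1, x1 = x1, x2 = x2)
  fit <- fit_tobit(yv, cens, X, bound = rep(bound, n))
  truth <- c(0.5, 0.7, -0.4)
  for (j in 1:3) {
    expect_lt(abs(fit$beta[[j]] - truth[j]), 3 * fit$se[[j]])
  }
  expect_lt(abs(fit$sigma - 0.9), 3 * fit$se_sigma)
})

test_that("Tobit agrees with an independent survival-model implementation", {
  withr::with_seed(31, {
    n <- 800
    x <- rnorm(n)
    y <- 0.3 + 0.6 * x + rnorm(n)
  })
  cens <- y < -0.2
  yv <- ifelse(cens, NA, y)
  fit <- fit_tobit(yv, cens, cbind(1, x), bound = rep(-0.2, n))
  sv <- survival::survreg(
    survival::Surv(ifelse(cens, -0.2, y), !cens, type = "left") ~ x,
    dist = "gaussian")
  expect_lt(max(abs(fit$beta - coef(sv))), 1e-5)
  expect_lt(abs(fit$sigma - sv$scale), 1e-5)
  expect_lt(max(abs(fit$se[1:2] - sqrt(diag(sv$var))[1:2])), 1e-3)
})

test_that("the optimizer never ends below its warm start", {
  withr::with_seed(41, {
    for (rep in 1:5) {
      n <- 200
      x <- rnorm(n)
      y <- 0.2 * x + rnorm(n)
      cens <- y < qnorm(runif(1, 0.1, 0.5))
      b <- min(y[!cens])
      yv <- ifelse(cens, NA, y)
      fit <- fit_tobit(yv, cens, cbind(1, x), bound = rep(b, n))
      expect_gte(fit$loglik, fit$loglik_start - 1e-8)
    }
  })
})

test_that("degenerate and invalid inputs are rejected", {
  expect_error(fit_tobit(rep(NA, 5), rep(TRUE, 5), matrix(1, 5, 1),
                         bound = rep(0, 5)),
               class = "wellmix_identifiability_error")
  X <- cbind(1, 1:6, 2 * (1:6))
  expect_error(fit_tobit(rnorm(6), rep(FALSE, 6), X),
               class = "wellmix_rank_error")
  expect_error(fit_tobit(c(1, NA, 2), c(FALSE, TRUE, FALSE),
                         matrix(1, 3, 1)),
               class = "wellmix_input_error")
})

test_that("parameter resampling has the documented distribution", {
  withr::with_seed(51, {
    y <- rnorm(400, 2, 1)
  })
  fit <- fit_tobit(y, rep(FALSE, 400),
                   matrix(1, 400, 1, dimnames = list(NULL, "b0")))
  # degenerate SEs return the MLE exactly
  fit0 <- fit
  fit0$se[] <- 0
  fit0$se_log_sigma <- 0
  d0 <- draw_parameters(fit0, seed = 1)
  expect_identical(d0$beta[["b0"]], fit$beta[["b0"]])
  expect_identical(d0$sigma, fit$sigma)
  # same seed, same draw
  expect_identical(draw_parameters(fit, seed = 7), draw_parameters(fit, seed = 7))
  # empirical SD of 10,000 draws within 3% of the SE
  draws <- withr::with_seed(8, replicate(10000, draw_parameters(fit)$beta[[1]]))
  expect_lt(abs(sd(draws) / fit$se[[1]] - 1), 0.03)
  # refuses non-converged fits
  bad <- fit
  bad$converged <- FALSE
  expect_error(draw_parameters(bad), class = "wellmix_convergence_error")
})
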