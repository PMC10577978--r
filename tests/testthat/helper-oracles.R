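# Independent grid-search maximizer of the censored-Gaussian likelihood for
# intercept-only problems: coarse pass at step 0.01 over beta0 in [-3, 3]
# and sigma in (0, 3], refined to step 1e-3 around the coarse optimum.
grid_tobit_intercept <- function(y_obs, c_cens) {
  ll <- function(b0, sigma) {
    sum(dnorm((y_obs - b0) / sigma, log = TRUE) - log(sigma)) +
      sum(pnorm((c_cens - b0) / sigma, log.p = TRUE))
  }
  search <- function(b_grid, s_grid) {
    best <- c(-Inf, NA, NA)
    for (s in s_grid) {
      vals <- vapply(b_grid, ll, numeric(1), sigma = s)
      i <- which.max(vals)
      if (vals[i] > best[1]) best <- c(vals[i], b_grid[i], s)
    }
    best
  }
  coarse <- search(seq(-3, 3, by = 0.01), seq(0.01, 3, by = 0.01))
  fine <- search(seq(coarse[2] - 0.02, coarse[2] + 0.02, by = 1e-3),
                 seq(max(coarse[3] - 0.02, 1e-3), coarse[3] + 0.02, by = 1e-3))
  list(beta0 = fine[2], sigma = fine[3], loglik = fine[1])
}

# Intercept-only censored fixtures shared by the unit and acceptance suites.
tobit_oracle_fixtures <- function() {
  list(
    list(y = c(0.8, 1.2, 0.3, 1.5, 0.7, 1.0), n_cens = 4, c = 0),
    list(y = c(-0.2, 0.9, 0.4, 1.8, 0.1), n_cens = 3, c = -0.5),
    list(y = c(2.1, 1.7, 0.6, 1.1, 0.9, 1.4, 0.2), n_cens = 2, c = 0.3)
  )
}
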