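test_that("quantile scores split evenly and break ties downward", {
  expect_equal(quantize(1:8, 4)$score, as.integer(c(0, 0, 1, 1, 2, 2, 3, 3)))
  qz <- quantize(1:8, 4)
  # a value exactly at the first cutpoint takes the lower score
  expect_equal(quantize(qz$cutpoints[1], 4, cutpoints = qz$cutpoints)$score, 0L)
  shares <- withr::with_seed(111, {
    s <- quantize(runif(100000), 4)$score
    as.numeric(table(s)) / 100000
  })
  expect_true(all(abs(shares - 0.25) < 0.01))
  expect_error(quantize(rep(1, 50), 4), class = "wellmix_degenerate_error")
})

test_that("psi is exactly the coefficient sum and weights normalise by sign", {
  expos <- make_test_exposures(n_tracts = 150, seed = 121)
  cb <- make_test_cohort(null_covariate_params(8000,
                                               c(Cd = 0.4, Pb = 0.2,
                                                 Zn = -0.3, iAs = -0.1)),
                         expos, seed = 122)
  res <- qgcomp_fit(cb$cohort, c("Cd", "Pb", "Zn", "iAs"), NULL, "ptb")
  expect_identical(res$psi, sum(res$coefficients$coefficient))
  w <- res$coefficients$weight
  b <- res$coefficients$coefficient
  expect_lt(abs(sum(w[b > 0]) - 1), 1e-12)
  expect_lt(abs(sum(w[b < 0]) + 1), 1e-12)
})

test_that("a single-metal mixture degenerates to that metal's coefficient", {
  expos <- make_test_exposures(n_tracts = 100, seed = 131)
  cb <- make_test_cohort(null_covariate_params(4000, c(Pb = 0.3)),
                         expos, seed = 132)
  res <- qgcomp_fit(cb$cohort, "Pb", NULL, "ptb")
  expect_identical(res$psi, res$coefficients$coefficient[1])
  expect_equal(res$coefficients$weight[1], 1.0)
})

test_that("psi equals the brute-force g-computation contrast", {
  expos <- make_test_exposures(n_tracts = 60, seed = 141)
  cb <- make_test_cohort(null_covariate_params(1500,
                                               c(Cd = 0.3, Pb = 0.15,
                                                 Zn = -0.2)),
                         expos, seed = 142)
  coh <- cb$cohort
  coh$z <- withr::with_seed(143, rnorm(nrow(coh)))
  metals <- c("Cd", "Pb", "Zn")

  for (fam in c("gaussian", "binomial")) {
    covs <- if (fam == "gaussian") "z" else NULL
    res <- qgcomp_fit(coh, metals, covs, "ptb", family = fam)
    # rebuild the design exactly as fitted and move every score up one
    S0 <- sapply(metals, function(m) {
      quantize(coh[[paste0("conc_", m)]], 4,
               cutpoints = res$cutpoints[[m]])$score
    })
    Z <- if (fam == "gaussian") cbind(1, coh$z) else matrix(1, nrow(coh), 1)
    beta <- if (fam == "gaussian") unname(coef(res$fit)) else unname(res$fit$beta)
    lp0 <- drop(cbind(Z, S0) %*% beta)       # linear predictor at observed scores
    lp1 <- drop(cbind(Z, S0 + 1) %*% beta)   # all exposures one quantile up
    # identity link: contrast of mean predictions; logit link (covariate-free):
    # contrast of log-odds — both equal psi
    expect_equal(mean(lp1) - mean(lp0), res$psi, tolerance = 1e-12)
  }
})

test_that("the 95% interval for psi is calibrated on synthetic cohorts", {
  # 300 seeded replicates at n = 50,000, no covariate effects: coverage of
  # the true psi should land in the binomial-plausible band around 95%.
  expos <- make_test_exposures(n_tracts = 400, seed = 151)
  truth <- sum(birth_sim_params()$metal_coefficients)
  cover <- vapply(1:300, function(i) {
    cb <- make_test_cohort(null_covariate_params(
      50000, birth_sim_params()$metal_coefficients), expos, seed = 151 + i)
    res <- qgcomp_fit(cb$cohort, wellmix_metals(), NULL, "ptb")
    res$ci_low <= exp(truth) && exp(truth) <= res$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)
})

test_that("partial effects are reproducible and handle one-sided partitions", {
  expos <- make_test_exposures(n_tracts = 200, seed = 161)
  metals <- c("Cd", "Pb", "Cr", "Zn")
  cb <- make_test_cohort(
    null_covariate_params(20000, c(Cd = log(1.3), Pb = log(1.3),
                                   Cr = log(1.3), Zn = log(1.3))),
    expos, seed = 162)
  pe1 <- partial_effects(cb$cohort, metals, NULL, "ptb", n_cycles = 3,
                         seed = 9)
  pe2 <- partial_effects(cb$cohort, metals, NULL, "ptb", n_cycles = 3,
                         seed = 9)
  expect_equal(pe1$cycles, pe2$cycles)
  # uniformly harmful mixture: negative set empty in every cycle
  expect_true(all(vapply(pe1$cycles$pos_set, length, integer(1)) == 4))
  expect_true(all(is.na(pe1$cycles$psi_neg)))
  # the positive-set validation fit is then the full mixture on that split
  n <- nrow(cb$cohort)
  idx <- withr::with_seed(9 + 1, sample.int(n))
  valid <- idx[-seq_len(round(0.3 * n))]
  full <- qgcomp_fit(cb$cohort[valid, ], metals, NULL, "ptb",
                     cutpoints = pe1$cutpoints)
  expect_equal(pe1$cycles$psi_pos[1], full$psi, tolerance = 1e-10)
})

test_that("result objects expose tidy, glance and autoplot interfaces", {
  expos <- make_test_exposures(n_tracts = 100, seed = 181)
  cb <- make_test_cohort(null_covariate_params(3000,
                                               c(Cd = 0.3, Zn = -0.2)),
                         expos, seed = 182)
  res <- qgcomp_fit(cb$cohort, c("Cd", "Zn"), NULL, "ptb")
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$metal, c("Cd", "Zn"))
  gl <- glance(res)
  expect_equal(gl$psi, res$psi)
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("stratified mixture effects satisfy the coding identities", {
  expos <- make_test_exposures(n_tracts = 200, seed = 171)
  params <- birth_sim_params(
    n_births = 30000,
    metal_coefficients = c(Cd = 0.03, Pb = 0.01, Zn = -0.02),
    race_probs = c("White non-Hispanic" = 0.6, "Black non-Hispanic" = 0.3,
                   "Hispanic" = 0.1, "Asian/Pacific Islander" = 0,
                   "American Indian" = 0, "Other/unknown" = 0),
    p_missing_education = 0, p_missing_smoking = 0)
  cb <- make_test_cohort(params, expos, seed = 172)
  metals <- c("Cd", "Pb", "Zn")
  emm <- qgcomp_emm(cb$cohort, metals, covariates = NULL,
                    modifier = "race_ethnicity", outcome = "ptb")
  # reference stratum psi is exactly the sum of the main-effect coefficients
  mains <- emm$coefficients$estimate[match(metals, emm$coefficients$term)]
  expect_identical(emm$strata$psi[emm$strata$level == emm$reference],
                   sum(mains))
  # no modification in truth: every stratum CI overlaps the overall estimate
  overall <- qgcomp_fit(cb$cohort, metals, NULL, "ptb")
  expect_true(all(emm$strata$ci_low <= overall$or &
                    overall$or <= emm$strata$ci_high))
  # a stratum without cases is refused by name
  no_case <- cb$cohort[cb$cohort$ptb == 0 |
                         cb$cohort$race_ethnicity != "Hispanic", ]
  expect_error(
    qgcomp_emm(no_case, metals, NULL, "race_ethnicity", "ptb"),
    "Hispanic", class = "wellmix_stratum_error")
})
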