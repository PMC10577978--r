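test_that("tract summaries compute means and exceedance fractions", {
  wells <- tibble::tibble(
    test_id = sprintf("t%d", 1:8),
    tract_id = rep(c("a", "b"), each = 4),
    analyte = "Pb",
    value = c(2, 4, 6, 8, 20, 5, 5, 5)
  )
  out <- tract_summaries(wells, default_mcls())
  a <- out[out$tract_id == "a", ]
  b <- out[out$tract_id == "b", ]
  expect_equal(a$mean_conc, 5.0)
  expect_equal(a$exceedance_fraction, 0)   # MCL for lead is 15 ppb
  expect_equal(b$exceedance_fraction, 0.25)
  expect_equal(b$n_tests, 4L)
})

test_that("a 12-test fixture matches its hand-computed summary", {
  # 12 arsenic tests across 3 tracts; MCL 10 ppb
  wells <- tibble::tibble(
    test_id = sprintf("t%02d", 1:12),
    tract_id = rep(c("x", "y", "z"), times = c(3, 4, 5)),
    analyte = "iAs",
    value = c(1, 2, 12,          # x: mean 5, 1/3 at/above 10
              10, 10, 1, 3,      # y: mean 6, 2/4 (boundary counts)
              0.5, 0.5, 0.5, 0.5, 0.5)  # z: mean 0.5, 0/5
  )
  out <- tract_summaries(wells, default_mcls())
  expect_equal(out$mean_conc, c(5, 6, 0.5))
  expect_equal(out$exceedance_fraction, c(1 / 3, 0.5, 0))
  expect_equal(out$n_tests, c(3L, 4L, 5L))
})

test_that("tract means are invariant to test ordering and tests without tracts are dropped", {
  wells <- make_hand_wells()
  complete <- dplyr::mutate(wells, value = dplyr::coalesce(value, 1))
  s1 <- suppressMessages(tract_summaries(complete))
  s2 <- suppressMessages(tract_summaries(complete[sample(nrow(complete)), ]))
  expect_equal(s1, s2)
  with_missing <- dplyr::mutate(complete,
                                tract_id = replace(tract_id, 1:2, NA))
  expect_message(tract_summaries(with_missing), "without a tract ID")
})

test_that("percentile coding uses right-closed interpolated cutpoints", {
  pc <- code_percentile_category(1:10)
  expect_equal(unname(pc$cutpoints), c(5.5, 9.1))
  expect_equal(pc$category[10], 2L)
  expect_equal(pc$category[5], 0L)
  # a value exactly at the 50th percentile stays in the lower category
  vals <- c(1:10, 5.5)
  pc2 <- code_percentile_category(vals)
  expect_equal(pc2$category[11], 0L)
  # value exactly at the 90th percentile maps to the middle category
  vals3 <- c(1:10, 9.1)
  pc3 <- code_percentile_category(vals3)
  expect_equal(pc3$category[11], 1L)
})

test_that("percentile coding rejects degenerate or tiny inputs", {
  expect_error(code_percentile_category(rep(2, 50)),
               class = "wellmix_degenerate_error")
  expect_error(code_percentile_category(1:5), class = "wellmix_input_error")
})

test_that("percentile categories split births roughly 50/40/10", {
  x <- withr::with_seed(81, rlnorm(20000, 0, 1.5))
  pc <- code_percentile_category(x)
  shares <- as.numeric(table(pc$category)) / 20000
  expect_equal(shares, c(0.5, 0.4, 0.1), tolerance = 0.02)
})

test_that("exceedance flag is inclusive at the threshold", {
  ex <- tibble::tibble(
    tract_id = c("a", "b", "c"),
    analyte = "Pb",
    mean_conc = 1,
    exceedance_fraction = c(0.25, 0, 0.249),
    n_tests = 4L
  )
  out <- code_exceedance_flag(ex, 0.25)
  expect_equal(out$exceedance_flag, c(1L, 0L, 0L))
  expect_error(code_exceedance_flag(ex, 1.2), class = "wellmix_input_error")
})

test_that("raising the MCL never raises an exceedance fraction", {
  wells <- withr::with_seed(91, tibble::tibble(
    test_id = sprintf("t%03d", 1:200),
    tract_id = sample(c("a", "b", "c", "d"), 200, replace = TRUE),
    analyte = "Mn",
    value = rlnorm(200, log(50), 1)
  ))
  mcls <- seq(50, 500, by = 50)
  fracs <- sapply(mcls, function(m) {
    out <- tract_summaries(wells, tibble::tibble(metal = "Mn", mcl = m))
    out$exceedance_fraction[order(out$tract_id)]
  })
  for (i in seq_len(nrow(fracs))) {
    expect_true(all(diff(fracs[i, ]) <= 0))
  }
})

test_that("tract exposures widen to the on-disk column layout", {
  long <- tibble::tibble(
    tract_id = rep(c("a", "b"), 3),
    analyte = rep(c("Pb", "iAs", "nitrate_nitrite"), each = 2),
    mean_conc = c(1, 2, 3, 4, 100, 200),
    exceedance_fraction = c(0.1, 0.2, 0, 0, NA, NA),
    n_tests = 5L
  )
  wide <- widen_tract_exposures(long)
  expect_equal(nrow(wide), 2)
  expect_true(all(c("mean_Pb", "exceedfrac_Pb", "n_tests_Pb", "mean_iAs",
                    "nitrate_nitrite_mean") %in% names(wide)))
  expect_equal(wide$mean_Pb, c(1, 2))
  expect_equal(wide$nitrate_nitrite_mean, c(100, 200))
})

test_that("the nitrate covariate degrades to omission instead of failing", {
  expect_warning(out <- code_nitrate_covariate(rep(3.3, 100)),
                 "degenerate")
  expect_true(all(is.na(out$category)))
  expect_warning(out2 <- code_nitrate_covariate(rep(NA_real_, 10)),
                 "entirely missing")
  expect_true(all(is.na(out2$category)))
  ok <- code_nitrate_covariate(as.numeric(1:100))
  expect_equal(sort(unique(ok$category)), 0:2)
  # value exactly at the 90th percentile -> middle category
  expect_equal(ok$category[which(1:100 == round(quantile(1:100, 0.9)))], 1L)
})
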