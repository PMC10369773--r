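test_that("rates follow the 1000 * numerator / denominator definition", {
  df <- one_conf_records(10, ever = "no")
  df$conf1_abortion_ever[1:3] <- "yes"
  df$conf1_certainty[1:3] <- c("certain", "certain", "less_certain")
  df$conf1_abortion_year[1:3] <- 2017
  expect_equal(base_rate(df, "confidante", 2017)$rate_per_1000, 200.0)
  expect_equal(adjust_1a(df, "confidante", 2017)$rate_per_1000, 300.0)
  # all less-certain: the certain-only rate is 0
  df2 <- one_conf_records(10, ever = c("yes", rep("no", 9)),
                          certainty = "less_certain", year = 2017)
  expect_equal(base_rate(df2, "confidante", 2017)$rate_per_1000, 0)
  expect_equal(adjust_1a(df2, "confidante", 2017)$rate_per_1000, 100.0)
})

test_that("adjustment 1b counts less-certain abortions only with method info", {
  df <- one_conf_records(10, ever = "no")
  df$conf1_abortion_ever[1:4] <- "yes"
  df$conf1_certainty[1:4] <- c("certain", "certain", "less_certain", "less_certain")
  df$conf1_abortion_year[1:4] <- 2017
  df$conf1_method_info[1:4] <- c(TRUE, TRUE, TRUE, FALSE)
  expect_equal(adjust_1b(df, "confidante", 2017)$rate_per_1000, 300.0)
  # no less-certain report has method info -> 1b equals the certain-only rate
  df$conf1_method_info[3] <- FALSE
  expect_equal(adjust_1b(df, "confidante", 2017)$rate_per_1000,
               base_rate(df, "confidante", 2017)$rate_per_1000)
  # all less-certain have method info -> 1b equals 1a
  df$conf1_method_info[3:4] <- TRUE
  expect_equal(adjust_1b(df, "confidante", 2017)$rate_per_1000,
               adjust_1a(df, "confidante", 2017)$rate_per_1000)
})

test_that("a survey without method information yields an explicit unavailability", {
  df <- one_conf_records(10, ever = c("yes", rep("no", 9)),
                         certainty = "less_certain", year = 2017)
  df$conf1_method_info <- NA
  est <- adjust_1b(df, "confidante", 2017)
  expect_false(est$available)
  expect_true(is.na(est$rate_per_1000))
  expect_match(est$note, "not collected")
})

test_that("the visibility correction is exact algebra on the base rate", {
  df <- one_conf_records(100, ever = "no")
  df$conf1_abortion_ever[1] <- "yes"
  df$conf1_certainty[1] <- "certain"
  df$conf1_abortion_year[1] <- 2017
  base <- base_rate(df, "confidante", 2017)
  expect_equal(base$rate_per_1000, 10.0)
  disc <- structure(list(p_any = 0.5, correction_factor = 2,
                         n_self_reporters = 8L),
                    class = "disclosure_estimate")
  adj <- adjust_2(base, disc)
  expect_identical(adj$rate_per_1000, base$rate_per_1000 * 2)
  expect_equal(adj$rate_per_1000, 20.0)
  disc1 <- structure(list(p_any = 1, correction_factor = 1,
                          n_self_reporters = 8L),
                     class = "disclosure_estimate")
  expect_equal(adjust_2(base, disc1)$rate_per_1000, base$rate_per_1000)
  expect_error(adjust_2(adjust_1a(df, "confidante", 2017), disc),
               "certain-only")
})

test_that("certain-only <= adj_1b <= adj_1a on random fixtures", {
  set.seed(2024)
  for (i in 1:20) {
    df <- random_fixture(n = 50)
    base <- base_rate(df, "confidante", 2017)$rate_per_1000
    a1b <- adjust_1b(df, "confidante", 2017)
    a1a <- adjust_1a(df, "confidante", 2017)$rate_per_1000
    if (isTRUE(a1b$available)) {
      expect_lte(base, a1b$rate_per_1000 + 1e-12)
      expect_lte(a1b$rate_per_1000, a1a + 1e-12)
    }
    expect_lte(base, a1a + 1e-12)
  }
})

test_that("rates are invariant under uniform rescaling of weights", {
  sim <- simulate_survey(simulation_params(n_respondents = 1500, seed = 17))
  rec <- sim$records
  scaled <- rec
  scaled$sample_weight <- scaled$sample_weight * 7.3
  for (pop in c("confidante", "respondent")) {
    expect_equal(base_rate(scaled, pop, 2017)$rate_per_1000,
                 base_rate(rec, pop, 2017)$rate_per_1000, tolerance = 1e-12)
  }
})

test_that("the respondent rate uses self-reports without a certainty filter", {
  df <- empty_records(50)
  df$self_abortion_ever[1:2] <- "yes"
  df$self_abortion_year[1:2] <- c(2017, 2016)
  est <- base_rate(df, "respondent", 2017)
  expect_equal(est$rate_per_1000, 20.0)
  expect_equal(est$denominator, 50)
})

test_that("an empty denominator is an error", {
  df <- empty_records(5)  # no confidante reports at all
  expect_error(base_rate(df, "confidante", 2017), "empty denominator")
})

test_that("the bootstrap is deterministic and degenerates to zero width", {
  df <- one_conf_records(40, ever = c("yes", "no"), certainty = "certain",
                         year = 2017)
  df$conf1_certainty[df$conf1_abortion_ever != "yes"] <- NA
  df$conf1_abortion_year[df$conf1_abortion_ever != "yes"] <- NA
  stat <- function(x) base_rate(x, "confidante", 2017)
  ci1 <- bootstrap_ci(stat, df, B = 200, seed = 5)
  ci2 <- bootstrap_ci(stat, df, B = 200, seed = 5)
  expect_identical(ci1$ci_low, ci2$ci_low)
  expect_identical(ci1$ci_high, ci2$ci_high)

  ident <- one_conf_records(30, ever = "yes", certainty = "certain", year = 2017)
  ci0 <- bootstrap_ci(stat, ident, B = 200, seed = 6)
  expect_equal(ci0$ci_low, ci0$ci_high)
  expect_equal(ci0$ci_low, 1000)

  expect_error(bootstrap_ci(stat, df, B = 50, seed = 1), "at least 200")
})

test_that("estimator failure in most resamples is reported, not hidden", {
  df <- empty_records(10)
  df$conf1_abortion_ever[1] <- "no"  # a single respondent carries all reports
  df$n_confidantes_reported[1] <- 1L
  stat <- function(x) base_rate(x, "confidante", 2017)
  expect_error(bootstrap_ci(stat, df, B = 200, seed = 2), "resamples")
})

test_that("set_bootstrap_ci fills the interval slots", {
  df <- one_conf_records(40, ever = c("yes", "no"), certainty = "certain",
                         year = 2017)
  df$conf1_certainty[df$conf1_abortion_ever != "yes"] <- NA
  df$conf1_abortion_year[df$conf1_abortion_ever != "yes"] <- NA
  est <- base_rate(df, "confidante", 2017)
  ci <- bootstrap_ci(function(x) base_rate(x, "confidante", 2017), df,
                     B = 200, seed = 3)
  est <- set_bootstrap_ci(est, ci)
  expect_lte(est$ci_low, est$rate_per_1000)
  expect_gte(est$ci_high, est$rate_per_1000)
  expect_match(est$ci_method, "bootstrap")
})
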