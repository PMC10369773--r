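test_that("a single-covariate uPR equals the direct prevalence ratio", {
  df <- empty_records(20)
  df$residence <- factor(rep(c("urban", "rural"), each = 10),
                         levels = fixture_levels$residence)
  df$n_confidantes_reported <- c(rep(c(1L, 0L), c(4, 6)),  # urban: 0.4
                                 rep(c(1L, 0L), c(8, 2)))  # rural: 0.8
  b <- barrier_upr(df, "residence")
  expect_equal(b$reference_category, "urban")
  expect_equal(b$table$upr[b$table$category == "rural"], 2.0, tolerance = 1e-10)
})

test_that("equal prevalence in all categories gives uPR 1", {
  df <- empty_records(40)
  df$education <- factor(rep(fixture_levels$education, each = 10),
                         levels = fixture_levels$education)
  df$n_confidantes_reported <- rep(rep(c(1L, 0L), c(6, 4)), 4)
  b <- barrier_upr(df, "education")
  expect_equal(b$table$upr, rep(1, 4), tolerance = 1e-10)
})

test_that("uPR oracle equivalence holds on random weighted fixtures", {
  set.seed(404)
  for (i in 1:25) {
    n <- sample(30:80, 1)
    df <- empty_records(n)
    df$residence <- factor(sample(c("urban", "rural"), n, replace = TRUE,
                                  prob = c(0.5, 0.5)),
                           levels = fixture_levels$residence)
    df$n_confidantes_reported <- rbinom(n, 1, 0.4 + 0.3 * (df$residence == "rural"))
    df$sample_weight <- runif(n, 0.5, 2)
    if (length(unique(df$residence)) < 2) next
    prev <- tapply(df$sample_weight * (df$n_confidantes_reported >= 1),
                   df$residence, sum) / tapply(df$sample_weight, df$residence, sum)
    if (any(prev == 0) || any(is.na(prev))) next
    b <- barrier_upr(df, "residence")
    expect_equal(b$table$upr[2], unname(prev["rural"] / prev["urban"]),
                 tolerance = 1e-10)
  }
})

test_that("a constant outcome yields a not-estimable result, not an error", {
  df <- empty_records(10)
  df$residence <- factor(rep(c("urban", "rural"), 5),
                         levels = fixture_levels$residence)
  df$n_confidantes_reported <- 1L
  b <- barrier_upr(df, "residence")
  expect_false(b$estimable)
})

test_that("uPRs are near 1 when confidante counts ignore covariates", {
  sim <- simulate_survey(simulation_params(n_respondents = 10000, seed = 88))
  for (cov in c("education", "residence")) {
    t <- barrier_upr(sim$records, cov)$table
    t <- t[!t$reference, , drop = FALSE]
    expect_true(all(abs(t$upr - 1) < 0.1), label = cov)
  }
  # and the 95% CIs cover the null at roughly nominal frequency
  covers <- sapply(1:30, function(s) {
    sim <- simulate_survey(simulation_params(n_respondents = 4000, seed = s))
    t <- barrier_upr(sim$records, "residence")$table
    t$ci_low[2] <= 1 & t$ci_high[2] >= 1
  })
  expect_gte(mean(covers), 0.85)
})

test_that("disclosure proportions follow their definitions exactly", {
  df <- empty_records(8)
  df$self_abortion_ever <- factor(rep("yes", 8), levels = fixture_levels$yn)
  df$self_abortion_year <- 2017
  df$conf1_abortion_ever <- factor(rep("no", 8), levels = fixture_levels$yn)
  df$conf1_disclosed <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  df$n_confidantes_reported <- 1L
  de <- disclosure_estimate(df)
  expect_equal(de$p_any, 0.5)
  expect_equal(de$correction_factor, 2.0)
  expect_identical(de$correction_factor * de$p_any, 1)

  df$conf1_disclosed <- rep(TRUE, 8)
  de2 <- disclosure_estimate(df)
  expect_equal(de2$p_any, 1)
  expect_equal(de2$correction_factor, 1)
})

test_that("no eligible self-reporters makes transmission adjustment unavailable", {
  df <- one_conf_records(10, ever = "no")
  df$self_abortion_ever <- factor(rep("no", 10), levels = fixture_levels$yn)
  expect_error(disclosure_estimate(df), "transmission adjustment 2 unavailable")
  # self-reporters exist but disclosed to nobody
  df$self_abortion_ever <- factor(rep("yes", 10), levels = fixture_levels$yn)
  df$conf1_disclosed <- FALSE
  expect_error(disclosure_estimate(df), "transmission adjustment 2 unavailable")
})

test_that("annualization scales partial-year counts by 12/months", {
  df <- one_conf_records(1000, ever = "no")
  hit <- 1:3
  df$conf1_abortion_ever[hit] <- "yes"
  df$conf1_certainty[hit] <- "certain"
  df$conf1_abortion_year[hit] <- 2018
  schema <- survey_schema(months_observed_partial = 4)
  tc <- telescoping_check(df, schema)
  expect_equal(tc$rate_annualized_partial$numerator, 9)
  expect_equal(tc$rate_annualized_partial$rate_per_1000, 9.0)
})

test_that("telescoping ratio is near 1 without telescoping and above 1 with it", {
  sim0 <- simulate_survey(simulation_params(n_respondents = 100000,
                                            disclosure_prob = 1,
                                            less_certain_prob = 0,
                                            telescope_prob = 0, seed = 99))
  tc0 <- telescoping_check(sim0$records)
  expect_lt(abs(tc0$ratio - 1), 0.12)

  sim3 <- simulate_survey(simulation_params(n_respondents = 20000,
                                            disclosure_prob = 1,
                                            less_certain_prob = 0,
                                            telescope_prob = 0.3, seed = 100))
  tc3 <- telescoping_check(sim3$records)
  expect_gt(tc3$ratio, 1.5)
})

test_that("telescoping_check is invariant to record order", {
  sim <- simulate_survey(simulation_params(n_respondents = 2000, seed = 13))
  rec <- sim$records
  shuffled <- rec[rev(seq_len(nrow(rec))), ]
  attr(shuffled, "schema") <- attr(rec, "schema")
  a <- telescoping_check(rec)
  b <- telescoping_check(shuffled)
  expect_equal(a$ratio, b$ratio)
  expect_equal(a$rate_full_year$rate_per_1000, b$rate_full_year$rate_per_1000)
})
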