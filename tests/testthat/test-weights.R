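test_that("identical pairs give 100% 'same' shares and a degeneracy flag", {
  df <- empty_records(4)
  df$education <- factor(c("primary", "primary", "secondary", "higher"),
                         levels = fixture_levels$education)
  df$conf1_education <- df$education
  df$conf1_abortion_ever <- factor(rep("no", 4), levels = fixture_levels$yn)
  df$n_confidantes_reported <- 1L
  ht <- homophily_table(to_pairs(df))
  sh <- ht$shares[ht$shares$characteristic == "education", ]
  expect_equal(sh$share_pct[sh$relation == "same"], 100)
  t <- ht$tests[ht$tests$characteristic == "education", ]
  expect_true(t$degenerate)
  expect_equal(t$chi_square, 0)
})

test_that("the chi-square matches a hand-computed Pearson statistic", {
  # crafted 2x2: respondent education never/primary vs confidante codes
  df <- empty_records(40)
  df$education <- factor(rep(c("never", "primary"), c(25, 15)),
                         levels = fixture_levels$education)
  df$conf1_education <- factor(rep(c("never", "primary", "never", "primary"),
                                   c(10, 15, 10, 5)),
                               levels = fixture_levels$education)
  df$conf1_abortion_ever <- factor(rep("no", 40), levels = fixture_levels$yn)
  df$n_confidantes_reported <- 1L
  ht <- homophily_table(to_pairs(df))
  t <- ht$tests[ht$tests$characteristic == "education", ]
  # independent oracle: Pearson chi-square on the 2xK distribution table
  tab <- rbind(respondent = c(25, 15), confidante = c(20, 20))
  oracle <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(t$chi_square, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(t$p_value, oracle$p.value, tolerance = 1e-12)
})

test_that("weighted chi-square uses weight-scaled counts at nominal size", {
  df <- empty_records(20)
  df$residence <- factor(rep(c("urban", "rural"), 10),
                         levels = fixture_levels$residence)
  df$conf1_residence <- factor(rep(c("urban", "rural"), c(14, 6)),
                               levels = fixture_levels$residence)
  df$conf1_abortion_ever <- factor(rep("no", 20), levels = fixture_levels$yn)
  df$n_confidantes_reported <- 1L
  df$sample_weight <- rep(c(2, 1), 10)
  ht <- homophily_table(to_pairs(df))
  t <- ht$tests[ht$tests$characteristic == "residence", ]
  w_urban_r <- 2 * 10 / 30 * 20       # respondent urban share, rescaled to n=20
  w_urban_c <- sum(rep(c(2, 1), 10)[1:14]) / 30 * 20
  tab <- rbind(c(w_urban_r, 20 - w_urban_r), c(w_urban_c, 20 - w_urban_c))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(t$chi_square, sum((tab - e)^2 / e), tolerance = 1e-12)
})

test_that("characteristics not collected are NA, none collected is not fatal", {
  df <- empty_records(3)
  df$education <- factor(rep("primary", 3), levels = fixture_levels$education)
  df$conf1_education <- df$education
  df$conf1_abortion_ever <- factor(rep("no", 3), levels = fixture_levels$yn)
  df$n_confidantes_reported <- 1L
  ht <- homophily_table(to_pairs(df))
  expect_true(is.na(ht$tests$p_value[ht$tests$characteristic == "residence"]))
  df2 <- empty_records(2)
  df2$conf1_abortion_ever <- factor(rep("no", 2), levels = fixture_levels$yn)
  df2$n_confidantes_reported <- 1L
  ht2 <- homophily_table(to_pairs(df2))
  expect_false(ht2$assessable)
})

test_that("one-binary-covariate saturated weights equal the margin odds ratio", {
  n_ref <- 100
  ref <- empty_records(n_ref)
  ref$residence <- factor(rep(c("urban", "rural"), c(60, 40)),
                          levels = fixture_levels$residence)
  conf <- empty_records(50)
  conf$conf1_residence <- factor(rep(c("urban", "rural"), c(20, 30)),
                                 levels = fixture_levels$residence)
  conf$conf1_abortion_ever <- factor(rep("no", 50), levels = fixture_levels$yn)
  conf$n_confidantes_reported <- 1L
  ws <- fit_poststrat_weights(to_pairs(conf), ref, "residence", saturated = TRUE)
  w <- ws$weights$weight
  urban <- as.character(conf$conf1_residence) == "urban"
  # density-ratio form: urban weight / rural weight = (0.6/0.4)/(0.4/0.6)
  expect_equal(unique(round(w[urban], 12)) / unique(round(w[!urban], 12)),
               (0.6 / 0.4) / (0.4 / 0.6), tolerance = 1e-9)
  expect_equal(mean(w), 1, tolerance = 1e-12)
})

test_that("matching margins give equal weights", {
  ref <- empty_records(40)
  ref$education <- factor(rep(c("never", "primary"), 20),
                          levels = fixture_levels$education)
  conf <- empty_records(10)
  conf$conf1_education <- factor(rep(c("never", "primary"), 5),
                                 levels = fixture_levels$education)
  conf$conf1_abortion_ever <- factor(rep("no", 10), levels = fixture_levels$yn)
  conf$n_confidantes_reported <- 1L
  ws <- fit_poststrat_weights(to_pairs(conf), ref, "education")
  expect_equal(ws$weights$weight, rep(1, 10), tolerance = 1e-9)
})

test_that("saturated weights reproduce reference margins on simulated data", {
  sim <- simulate_survey(simulation_params(n_respondents = 4000, homophily = 0,
                                           seed = 77))
  rec <- sim$records
  pairs <- to_pairs(rec)
  ws <- fit_poststrat_weights(pairs, rec, c("education", "residence"),
                              saturated = TRUE)
  w <- ws$weights$weight
  for (cov in c("education", "residence")) {
    ref_m <- prop.table(xtabs(rec$sample_weight ~ rec[[cov]]))
    conf_m <- tapply(w, pairs[[paste0("c_", cov)]], sum) / sum(w)
    expect_equal(as.numeric(conf_m), as.numeric(ref_m), tolerance = 1e-9,
                 label = cov)
  }
  d <- ws$diagnostics
  expect_lte(d$effective_sample_size, d$n_pairs)
  expect_true(all(w > 0))
})

test_that("weighting with homophily = 0 restores a skewed education margin", {
  margins <- default_margins()
  sim <- simulate_survey(simulation_params(n_respondents = 6000, homophily = 0,
                                           covariate_margins = margins,
                                           seed = 78))
  rec <- sim$records
  pairs <- to_pairs(rec)
  ws <- fit_poststrat_weights(pairs, rec, "education", saturated = TRUE)
  w <- ws$weights$weight
  ref_m <- prop.table(xtabs(rec$sample_weight ~ rec$education))
  conf_m <- tapply(w, pairs$c_education, sum) / sum(w)
  expect_true(all(abs(as.numeric(conf_m) - as.numeric(ref_m)) < 0.01))
})

test_that("an empty stratification cell is an error naming the cell", {
  ref <- empty_records(20)
  ref$education <- factor(rep(c("never", "primary"), 10),
                          levels = fixture_levels$education)
  conf <- empty_records(10)
  conf$conf1_education <- factor(rep("never", 10),
                                 levels = fixture_levels$education)
  conf$conf1_abortion_ever <- factor(rep("no", 10), levels = fixture_levels$yn)
  conf$n_confidantes_reported <- 1L
  expect_error(fit_poststrat_weights(to_pairs(conf), ref, "education"),
               "primary")
})

test_that("post-stratification weighting never creates events from nothing", {
  # weighted rate is 0 iff the unweighted numerator is 0
  df <- one_conf_records(30, ever = "no")
  df$conf1_education <- factor(rep(c("never", "primary", "secondary"), 10),
                               levels = fixture_levels$education)
  ref <- empty_records(30)
  ref$education <- factor(rep(c("never", "primary", "secondary"), c(20, 5, 5)),
                          levels = fixture_levels$education)
  ws <- fit_poststrat_weights(to_pairs(df), ref, "education", saturated = TRUE)
  est <- base_rate(df, "confidante", 2017, weights = ws)
  expect_equal(est$rate_per_1000, 0)
})
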