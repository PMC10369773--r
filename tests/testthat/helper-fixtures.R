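# Build canonical survey records in code (no stored fixtures).

fixture_levels <- list(
  age_group = c("15-19", "20-29", "30-39", "40-49"),
  education = c("never", "primary", "secondary", "higher"),
  residence = c("urban", "rural"),
  marital_status = c("married/cohabiting", "not married/cohabiting"),
  fp_use = c("no", "yes"),
  parity = c("0", "1-2", "3-5", "6+"),
  yn = c("no", "yes"),
  certainty = c("certain", "less_certain")
)

# All-canonical-column survey of n respondents, everything missing/default.
empty_records <- function(n) {
  f <- function(lv) factor(rep(NA_character_, n), levels = lv)
  df <- data.frame(
    respondent_id = as.character(seq_len(n)),
    sample_weight = rep(1, n),
    age_years = rep(NA_real_, n),
    age_group = f(fixture_levels$age_group),
    education = f(fixture_levels$education),
    residence = f(fixture_levels$residence),
    marital_status = f(fixture_levels$marital_status),
    fp_use = f(fixture_levels$fp_use),
    parity = f(fixture_levels$parity),
    self_abortion_ever = f(fixture_levels$yn),
    self_abortion_year = rep(NA_real_, n),
    self_abortion_month = rep(NA_real_, n),
    n_confidantes_reported = rep(0L, n),
    stringsAsFactors = FALSE)
  for (k in 1:2) {
    p <- paste0("conf", k, "_")
    df[[paste0(p, "age_years")]] <- rep(NA_real_, n)
    df[[paste0(p, "age_group")]] <- f(fixture_levels$age_group)
    df[[paste0(p, "education")]] <- f(fixture_levels$education)
    df[[paste0(p, "residence")]] <- f(fixture_levels$residence)
    df[[paste0(p, "marital_status")]] <- f(fixture_levels$marital_status)
    df[[paste0(p, "parity")]] <- f(fixture_levels$parity)
    df[[paste0(p, "abortion_ever")]] <- f(fixture_levels$yn)
    df[[paste0(p, "certainty")]] <- f(fixture_levels$certainty)
    df[[paste0(p, "abortion_year")]] <- rep(NA_real_, n)
    df[[paste0(p, "abortion_month")]] <- rep(NA_real_, n)
    df[[paste0(p, "method_info")]] <- rep(NA, n)
    df[[paste0(p, "disclosed")]] <- rep(NA, n)
  }
  structure(df, class = c("confidante_survey", "data.frame"))
}

# n respondents, one confidante each; confidante abortion report configured
# by parallel vectors (recycled): abortion_ever, certainty, year, method_info.
one_conf_records <- function(n, ever = "no", certainty = NA, year = NA,
                             method_info = NA) {
  df <- empty_records(n)
  df$n_confidantes_reported <- 1L
  df$conf1_abortion_ever <- factor(rep_len(ever, n), levels = fixture_levels$yn)
  df$conf1_certainty <- factor(rep_len(as.character(certainty), n),
                               levels = fixture_levels$certainty)
  df$conf1_abortion_year <- rep_len(as.numeric(year), n)
  df$conf1_method_info <- rep_len(method_info, n)
  df
}

# Small random survey for property tests: two respondent groups, random
# confidante reports in a reference year. Used with a fixed outer seed.
random_fixture <- function(n = 60, year = 2017) {
  df <- empty_records(n)
  df$education <- factor(sample(c("never", "primary"), n, replace = TRUE),
                         levels = fixture_levels$education)
  n_conf <- sample(0:2, n, replace = TRUE)
  df$n_confidantes_reported <- n_conf
  for (k in 1:2) {
    has <- n_conf >= k
    ever <- has & stats::runif(n) < 0.4
    cert <- ifelse(stats::runif(n) < 0.7, "certain", "less_certain")
    p <- paste0("conf", k, "_")
    df[[paste0(p, "abortion_ever")]][has] <-
      factor(ifelse(ever[has], "yes", "no"), levels = fixture_levels$yn)
    df[[paste0(p, "certainty")]][ever] <- cert[ever]
    df[[paste0(p, "abortion_year")]][ever] <-
      ifelse(stats::runif(sum(ever)) < 0.8, year, year - 1)
    df[[paste0(p, "method_info")]][ever] <- stats::runif(sum(ever)) < 0.5
  }
  df
}

write_fixture_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
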