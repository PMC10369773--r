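#' Barrier-effect diagnostic: who reports any confidantes?
#'
#' Barrier effects arise when the respondents who report zero confidantes
#' differ systematically from those who report at least one, so that whole
#' population segments are missing from the surrogate (confidante) sample.
#' This fits a log-link Poisson regression of the binary outcome "reported
#' any confidantes" on one respondent characteristic and reports unadjusted
#' prevalence ratios (uPRs) per category with 95% confidence intervals from
#' a robust (sandwich) variance estimator. Reference categories are the
#' customary ones: youngest age band, never attended school, urban,
#' married/cohabiting, no family-planning use, no children.
#'
#' @param records A `confidante_survey` data frame.
#' @param covariate One of the canonical respondent covariates
#'   (`age_group`, `education`, `residence`, `marital_status`, `fp_use`,
#'   `parity`).
#' @param weighted Use respondent sampling weights (default).
#' @return A `barrier_result`: covariate name, reference category, and a
#'   table of per-category uPRs with CIs and counts. If the outcome is
#'   constant the result is flagged not estimable rather than erroring.
#' @export
barrier_upr <- function(records, covariate, weighted = TRUE) {
  if (!covariate %in% canonical_covariates()) {
    stop("unknown covariate: ", covariate, call. = FALSE)
  }
  x <- records[[covariate]]
  keep <- !is.na(x)
  x <- droplevels(factor(x[keep]))
  y <- as.integer(records$n_confidantes_reported[keep] >= 1)
  w <- if (weighted) records$sample_weight[keep] else rep(1, sum(keep))
  full_levels <- canonical_levels()[[covariate]]
  dropped <- setdiff(full_levels, levels(x))
  if (length(dropped)) {
    warning("category(ies) with zero respondents dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (nlevels(x) < 2) {
    stop("covariate has fewer than 2 non-empty categories", call. = FALSE)
  }
  res <- structure(list(covariate = covariate,
                        reference_category = levels(x)[1],
                        estimable = TRUE, table = NULL,
                        n = length(y)),
                   class = "barrier_result")
  if (length(unique(y)) < 2) {
    res$estimable <- FALSE
    res$note <- "outcome constant: every respondent reported the same status"
    return(res)
  }
  dat <- data.frame(y = y, x = x, w = w)
  fit <- stats::glm(y ~ x, family = stats::poisson(), data = dat, weights = w,
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  vc <- sandwich::vcovHC(fit, type = "HC0")
  ct <- lmtest::coeftest(fit, vcov. = vc)
  b <- stats::coef(fit)[-1]
  se <- ct[-1, "Std. Error"]
  z <- stats::qnorm(0.975)
  cats <- levels(x)
  tab <- data.frame(
    category = cats,
    upr = c(1, exp(b)),
    ci_low = c(NA, exp(b - z * se)),
    ci_high = c(NA, exp(b + z * se)),
    n = as.integer(table(x)[cats]),
    reference = cats == levels(x)[1],
    row.names = NULL, stringsAsFactors = FALSE)
  res$table <- tab
  res
}

#' @export
print.barrier_result <- function(x, ...) {
  cat("Barrier-effect uPRs (any vs no confidantes) for", x$covariate, "\n")
  if (!x$estimable) {
    cat("  not estimable:", x$note, "\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    if (r$reference) {
      cat(sprintf("  %-22s 1 (reference), n = %d\n", r$category, r$n))
    } else {
      cat(sprintf("  %-22s %.2f (%.2f-%.2f), n = %d\n", r$category, r$upr,
                  r$ci_low, r$ci_high, r$n))
    }
  }
  invisible(x)
}

#' Abortion visibility among self-reporting respondents
#'
#' Estimates the proportion of respondents who self-reported an abortion and
#' had informed at least one of their reported confidantes (`p_any`),
#' together with per-position disclosure proportions, and the transmission
#' bias correction factor `1 / p_any` used by [adjust_2()].
#'
#' Eligible respondents are those with a self-reported abortion and at least
#' one reported confidante; respondents whose disclosure indicators are all
#' missing are excluded (complete case; the count is reported). Proportions
#' are computed with respondent sampling weights by default; set
#' `weighted = FALSE` to disable (the choice is recorded in the result).
#'
#' @param records A `confidante_survey` data frame.
#' @param weighted Use respondent sampling weights (default).
#' @return A `disclosure_estimate`: `p_any`, `p_conf1`, `p_conf2`,
#'   `n_self_reporters`, `n_excluded`, `correction_factor`, `weighted`.
#' @export
disclosure_estimate <- function(records, weighted = TRUE) {
  self <- !is.na(records$self_abortion_ever) & records$self_abortion_ever == "yes"
  rep1 <- block_reported(records, 1)
  rep2 <- block_reported(records, 2)
  elig <- self & (rep1 | rep2)
  if (!any(elig)) {
    stop("transmission adjustment 2 unavailable: no respondents self-reported ",
         "an abortion and reported a confidante", call. = FALSE)
  }
  d1 <- records$conf1_disclosed
  d2 <- records$conf2_disclosed
  known1 <- rep1 & !is.na(d1)
  known2 <- rep2 & !is.na(d2)
  usable <- elig & (known1 | known2)
  n_excluded <- sum(elig) - sum(usable)
  if (!any(usable)) {
    stop("transmission adjustment 2 unavailable: disclosure indicators ",
         "missing for every eligible respondent", call. = FALSE)
  }
  w <- if (weighted) records$sample_weight else rep(1, nrow(records))
  any_disc <- (known1 & d1 %in% TRUE) | (known2 & d2 %in% TRUE)
  p_any <- sum(w[usable & any_disc]) / sum(w[usable])
  prop_pos <- function(known, d) {
    i <- elig & known
    if (!any(i)) return(NA_real_)
    sum(w[i & d %in% TRUE]) / sum(w[i])
  }
  p1 <- prop_pos(known1, d1)
  p2 <- prop_pos(known2, d2)
  if (p_any <= 0) {
    stop("transmission adjustment 2 unavailable: no eligible respondent ",
         "disclosed to any confidante", call. = FALSE)
  }
  structure(list(p_any = p_any, p_conf1 = p1, p_conf2 = p2,
                 n_self_reporters = sum(usable), n_excluded = n_excluded,
                 correction_factor = 1 / p_any, weighted = weighted),
            class = "disclosure_estimate")
}

#' @export
print.disclosure_estimate <- function(x, ...) {
  cat("Abortion visibility among self-reporting respondents",
      if (x$weighted) "(weighted)\n" else "(unweighted)\n")
  cat(sprintf("  disclosed to any confidante: %.1f%% (n = %d%s)\n",
              100 * x$p_any, x$n_self_reporters,
              if (x$n_excluded > 0)
                sprintf(", %d excluded with missing indicators", x$n_excluded)
              else ""))
  cat(sprintf("  confidante 1: %.1f%%   confidante 2: %s\n",
              100 * x$p_conf1,
              if (is.na(x$p_conf2)) "NA" else sprintf("%.1f%%", 100 * x$p_conf2)))
  cat(sprintf("  correction factor (1/p_any): %.3f\n", x$correction_factor))
  invisible(x)
}

#' Telescoping diagnostic: full reference year vs annualized partial year
#'
#' Backward telescoping -- misdating past abortions into the recent
#' reporting window -- inflates rates for the most recent (partially
#' observed) year. This compares the rate for the full reference year with
#' the annualized rate for the partial fieldwork year (partial-year count
#' scaled by `12 / months observed`, same denominator rule) and reports
#' their ratio; a ratio materially above 1 indicates telescoping into the
#' fieldwork year.
#'
#' @param records A `confidante_survey` data frame.
#' @param schema A [survey_schema()] giving the reference year, partial year
#'   and months observed; defaults to the schema attached to `records`.
#' @param weights Optional `weight_set` (confidante rates).
#' @param population `"confidante"` (default) or `"respondent"`.
#' @param adjustment Numerator rule for both rates (default certain-only).
#' @return A `telescoping_result`: the two `incidence_estimate`s and their
#'   ratio (annualized partial / full reference year).
#' @export
telescoping_check <- function(records, schema = NULL, weights = NULL,
                              population = "confidante",
                              adjustment = "certain_only") {
  schema <- schema %||% attr(records, "schema")
  if (is.null(schema) || !inherits(schema, "survey_schema")) {
    stop("schema error: a survey_schema is required", call. = FALSE)
  }
  m <- schema$months_observed_partial
  if (is.null(m) || is.na(m) || m < 1) {
    stop("schema error: months_observed_partial must be at least 1", call. = FALSE)
  }
  full <- incidence_rate(records, population, schema$reference_year,
                         adjustment, weights)
  part <- incidence_rate(records, population, schema$partial_year,
                         adjustment, weights, annualize = 12 / m)
  ratio <- if (full$rate_per_1000 > 0) part$rate_per_1000 / full$rate_per_1000
           else NA_real_
  structure(list(rate_full_year = full, rate_annualized_partial = part,
                 ratio = ratio),
            class = "telescoping_result")
}

#' @export
print.telescoping_result <- function(x, ...) {
  cat("Telescoping diagnostic\n")
  cat(sprintf("  full %d rate:            %.1f per 1000\n",
              x$rate_full_year$year, x$rate_full_year$rate_per_1000))
  cat(sprintf("  annualized %d rate:      %.1f per 1000\n",
              x$rate_annualized_partial$year,
              x$rate_annualized_partial$rate_per_1000))
  cat(sprintf("  ratio (annualized/full):   %s\n",
              if (is.na(x$ratio)) "NA (full-year rate is 0)"
              else sprintf("%.2f", x$ratio)))
  invisible(x)
}
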