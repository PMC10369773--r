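#' One-year incidence rates with transmission-bias adjustments
#'
#' The rate is `1000 * numerator / denominator`, where the numerator is the
#' weighted count of abortions dated to `year` and the denominator is the
#' weighted number of respondents or confidante reports in the analytic
#' sample. `base_rate()` counts only abortions the respondent was "certain"
#' about (the certain-only rate); `adjust_1a()` additionally counts all
#' "less certain" abortions; `adjust_1b()` counts less-certain abortions
#' only when the respondent could report the abortion method; `adjust_2()`
#' inflates the certain-only rate by the visibility correction factor
#' `1 / p_any` estimated from self-reporting respondents (see
#' [disclosure_estimate()]).
#'
#' For `population = "confidante"` the denominator pools confidante reports
#' in positions 1 and 2, and units are weighted by the respondent design
#' weight times the post-stratification weight when a `weight_set` is
#' supplied (weights compose multiplicatively). For
#' `population = "respondent"` units are respondents under their design
#' weights, the numerator counts self-reported abortions dated to `year`,
#' and the certainty filter does not apply.
#'
#' @param records A `confidante_survey` data frame.
#' @param population `"confidante"` or `"respondent"`.
#' @param year Calendar year of the rate. Defaults to the reference year of
#'   the schema attached to `records`, if any.
#' @param weights Optional `weight_set` from [fit_poststrat_weights()]
#'   (confidante rates only).
#' @return An `incidence_estimate`: rate per 1000 women 15-49, weighted
#'   numerator and denominator, year, population, adjustment label, CI slots
#'   (filled by [bootstrap_ci()]), and the weighting applied.
#' @export
base_rate <- function(records, population = c("confidante", "respondent"),
                      year = NULL, weights = NULL) {
  incidence_rate(records, match.arg(population), year, "certain_only", weights)
}

#' @rdname base_rate
#' @export
adjust_1a <- function(records, population = c("confidante", "respondent"),
                      year = NULL, weights = NULL) {
  incidence_rate(records, match.arg(population), year, "adj_1a", weights)
}

#' @rdname base_rate
#' @export
adjust_1b <- function(records, population = c("confidante", "respondent"),
                      year = NULL, weights = NULL) {
  incidence_rate(records, match.arg(population), year, "adj_1b", weights)
}

#' @keywords internal
incidence_rate <- function(records, population, year, adjustment,
                           weights = NULL, annualize = 1) {
  if (is.null(year)) {
    sch <- attr(records, "schema")
    if (is.null(sch)) stop("year must be given when records carry no schema",
                           call. = FALSE)
    year <- sch$reference_year
  }
  if (population == "respondent") {
    w <- records$sample_weight
    den <- sum(w)
    if (den <= 0) stop("empty denominator: no respondents", call. = FALSE)
    hit <- !is.na(records$self_abortion_ever) &
      records$self_abortion_ever == "yes" &
      !is.na(records$self_abortion_year) & records$self_abortion_year == year
    num <- sum(w[hit]) * annualize
    return(new_incidence_estimate(1000 * num / den, num, den, year,
                                  population, adjustment, "design"))
  }

  ps <- function(k) {
    if (is.null(weights)) return(rep(1, nrow(records)))
    key <- paste(weights$weights$respondent_id, weights$weights$position)
    idx <- match(paste(records$respondent_id, k), key)
    weights$weights$weight[idx]
  }
  num <- 0; den <- 0
  mi_cols_all_na <- TRUE
  for (k in 1:2) {
    rep_k <- block_reported(records, k)
    if (!any(rep_k)) next
    wk <- records$sample_weight * ps(k)
    if (anyNA(wk[rep_k])) {
      stop("weight set does not cover ", sum(is.na(wk[rep_k])),
           " reported pair(s); refusing to estimate", call. = FALSE)
    }
    den <- den + sum(wk[rep_k])
    ae <- records[[paste0("conf", k, "_abortion_ever")]]
    ct <- records[[paste0("conf", k, "_certainty")]]
    yr <- records[[paste0("conf", k, "_abortion_year")]]
    mi <- records[[paste0("conf", k, "_method_info")]]
    if (!all(is.na(mi))) mi_cols_all_na <- FALSE
    ev <- rep_k & !is.na(ae) & ae == "yes" & !is.na(yr) & yr == year
    hit <- switch(adjustment,
      certain_only = ev & !is.na(ct) & ct == "certain",
      adj_1a = ev,
      adj_1b = ev & !is.na(ct) & (ct == "certain" |
                 (ct == "less_certain" & !is.na(mi) & mi)))
    num <- num + sum(wk[hit])
  }
  if (den <= 0) stop("empty denominator: no confidante reports", call. = FALSE)
  if (adjustment == "adj_1b" && mi_cols_all_na) {
    return(new_incidence_estimate(NA_real_, NA_real_, den, year, population,
      adjustment, if (is.null(weights)) "design" else "design_x_poststrat",
      available = FALSE,
      note = "method information not collected in this survey"))
  }
  num <- num * annualize
  new_incidence_estimate(1000 * num / den, num, den, year, population,
    adjustment, if (is.null(weights)) "design" else "design_x_poststrat")
}

#' @keywords internal
new_incidence_estimate <- function(rate, num, den, year, population,
                                   adjustment, weights_applied,
                                   available = TRUE, note = NULL) {
  structure(list(rate_per_1000 = rate, numerator = num, denominator = den,
                 year = year, population = population, adjustment = adjustment,
                 ci_low = NA_real_, ci_high = NA_real_, ci_method = "none",
                 weights_applied = weights_applied, available = available,
                 note = note),
            class = "incidence_estimate")
}

#' Apply the visibility (transmission-bias) correction
#'
#' Inflates a certain-only incidence estimate by the correction factor
#' `1 / p_any`, the inverse of the proportion of self-reporting respondents
#' who informed any of their reported confidantes. Under symmetric
#' disclosure this restores the abortions that were never visible to the
#' reporting respondents.
#'
#' @param base A certain-only `incidence_estimate` from [base_rate()].
#' @param disclosure A [disclosure_estimate()].
#' @return An `incidence_estimate` with adjustment label `adj_2`; the
#'   numerator is scaled by the correction factor so that
#'   `rate = 1000 * numerator / denominator` still holds.
#' @export
adjust_2 <- function(base, disclosure) {
  stopifnot(inherits(base, "incidence_estimate"),
            inherits(disclosure, "disclosure_estimate"))
  if (base$adjustment != "certain_only") {
    stop("adjust_2 applies to the certain-only base rate, got adjustment '",
         base$adjustment, "'", call. = FALSE)
  }
  if (!is.finite(disclosure$p_any) || disclosure$p_any <= 0) {
    stop("transmission adjustment 2 unavailable: disclosure proportion is ",
         "zero or undefined", call. = FALSE)
  }
  cf <- disclosure$correction_factor
  out <- new_incidence_estimate(base$rate_per_1000 * cf, base$numerator * cf,
                                base$denominator, base$year, base$population,
                                "adj_2", base$weights_applied)
  out$note <- sprintf("certain-only rate x correction factor %.4f (1/p_any, p_any = %.4f)",
                      cf, disclosure$p_any)
  out
}

#' @export
print.incidence_estimate <- function(x, ...) {
  if (!x$available) {
    cat(sprintf("Incidence estimate (%s, %s, %d): not available in this survey\n",
                x$population, x$adjustment, x$year))
    if (!is.null(x$note)) cat("  ", x$note, "\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("%s abortion incidence, %d [%s]: %.1f per 1000",
              x$population, x$year, x$adjustment, x$rate_per_1000))
  if (x$ci_method != "none") {
    cat(sprintf(" (95%% CI %.1f-%.1f, %s)", x$ci_low, x$ci_high, x$ci_method))
  }
  cat("\n")
  cat(sprintf("  numerator %.2f / denominator %.2f, weights: %s\n",
              x$numerator, x$denominator, x$weights_applied))
  if (!is.null(x$note)) cat("  ", x$note, "\n", sep = "")
  invisible(x)
}

#' Percentile bootstrap confidence interval, resampling respondents
#'
#' Respondent-level (cluster) bootstrap: confidante reports are clustered
#' within respondents, so whole respondent records are resampled with
#' replacement and the full estimator -- including any weight fitting or
#' disclosure-based correction inside `statistic` -- is recomputed on each
#' resample.
#'
#' @param statistic Function taking a resampled `confidante_survey` data
#'   frame and returning a numeric scalar or an `incidence_estimate`.
#' @param records The respondent records to resample.
#' @param B Number of bootstrap resamples (at least 200).
#' @param seed Integer seed; the interval is deterministic given the seed.
#' @param level Confidence level (default 0.95).
#' @return A `bootstrap_ci` list: `ci_low`, `ci_high`, `level`, `B`,
#'   `n_failed` (resamples where the estimator was unavailable). If the
#'   estimator fails in more than 20% of resamples, an error reports the
#'   failure rate instead.
#' @export
bootstrap_ci <- function(statistic, records, B = 1000, seed = NULL,
                         level = 0.95) {
  if (B < 200) stop("B must be at least 200", call. = FALSE)
  n <- nrow(records)
  schema <- attr(records, "schema")
  with_local_seed(seed, {
    vals <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      res <- records[idx, , drop = FALSE]
      attr(res, "schema") <- schema
      v <- tryCatch(statistic(res), error = function(e) NA_real_)
      if (inherits(v, "incidence_estimate")) {
        v <- if (isTRUE(v$available)) v$rate_per_1000 else NA_real_
      }
      vals[b] <- v
    }
    n_failed <- sum(is.na(vals))
    if (n_failed > 0.2 * B) {
      stop(sprintf("estimator unavailable in %d of %d resamples (%.0f%%)",
                   n_failed, B, 100 * n_failed / B), call. = FALSE)
    }
    qs <- stats::quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2),
                          na.rm = TRUE, names = FALSE)
    structure(list(ci_low = qs[1], ci_high = qs[2], level = level, B = B,
                   n_failed = n_failed),
              class = "bootstrap_ci")
  })
}

#' Attach a bootstrap interval to an estimate
#'
#' @param estimate An `incidence_estimate`.
#' @param ci A `bootstrap_ci`.
#' @return The estimate with `ci_low`, `ci_high` and `ci_method` filled.
#' @export
set_bootstrap_ci <- function(estimate, ci) {
  stopifnot(inherits(estimate, "incidence_estimate"),
            inherits(ci, "bootstrap_ci"))
  estimate$ci_low <- ci$ci_low
  estimate$ci_high <- ci$ci_high
  estimate$ci_method <- sprintf("bootstrap_percentile_B%d", ci$B)
  estimate
}

#' Tidy table of incidence estimates
#'
#' @param estimates A list of `incidence_estimate` objects.
#' @return Data frame with one row per estimate (population, adjustment,
#'   year, rate, CI, weighting, availability).
#' @export
estimates_table <- function(estimates) {
  if (inherits(estimates, "incidence_estimate")) estimates <- list(estimates)
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(population = e$population, adjustment = e$adjustment,
               year = e$year, rate_per_1000 = e$rate_per_1000,
               ci_low = e$ci_low, ci_high = e$ci_high, ci_method = e$ci_method,
               numerator = e$numerator, denominator = e$denominator,
               weights_applied = e$weights_applied, available = e$available,
               stringsAsFactors = FALSE)
  }))
}
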