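#' @keywords internal
bias_names <- function() {
  c("study_design", "transmission", "social_desirability_recall",
    "selection", "barrier_effects", "popularity")
}

#' @keywords internal
status_labels <- function() {
  c(not_assessed = "Not assessed",
    assessed_low = "Assessed, low risk of bias",
    assessed_moderate = "Assessed, moderate risk of bias",
    assessed_high = "Assessed, high risk of bias",
    assessed_unclear = "Assessed, unclear risk of bias")
}

#' Thresholds for the rule-based bias status mapping
#'
#' @param selection_alpha Significance level: any homophily p-value below it
#'   marks selection bias as high risk.
#' @param telescope_moderate,telescope_high Telescoping ratio cutoffs for
#'   moderate and high recall-bias risk.
#' @param implausibility_floor Certain-only confidante rate (per 1000) below
#'   which the study-design assumption is suspect.
#' @return A named list of thresholds.
#' @export
assessment_thresholds <- function(selection_alpha = 0.05,
                                  telescope_moderate = 1.25,
                                  telescope_high = 1.5,
                                  implausibility_floor = 5) {
  list(selection_alpha = selection_alpha,
       telescope_moderate = telescope_moderate,
       telescope_high = telescope_high,
       implausibility_floor = implausibility_floor)
}

#' Assemble the six-bias risk-of-bias assessment
#'
#' Maps the diagnostic results onto the standardized six-bias checklist
#' (study design, transmission, social desirability/recall, selection,
#' barrier effects, popularity) with a deterministic, threshold-based rule:
#' selection is high risk if any homophily chi-square p-value is below
#' `selection_alpha`; barrier effects are high risk if any uPR confidence
#' interval excludes 1; recall is moderate/high risk when the telescoping
#' ratio exceeds its cutoffs; transmission is high risk whenever the
#' disclosure proportion `p_any` is below 1; study design is low risk unless
#' the certain-only rate falls below the implausibility floor. Popularity
#' bias has no published assessment method and is always `not_assessed`.
#' A missing diagnostic marks the corresponding bias `not_assessed` with a
#' warning, never an error.
#'
#' @param diagnostics Named list with any of `homophily`
#'   (a [homophily_table()]), `barrier` (a `barrier_result` or list of
#'   them), `telescoping` (a [telescoping_check()] result), `disclosure`
#'   (a [disclosure_estimate()]).
#' @param estimates Optional list of `incidence_estimate`s; the certain-only
#'   confidante rate among them feeds the study-design rule.
#' @param thresholds See [assessment_thresholds()].
#' @return A `bias_assessment` data frame with columns `bias`, `status`,
#'   `adjustment_mode`, `evidence` (exactly six rows).
#' @export
build_assessment <- function(diagnostics = list(), estimates = NULL,
                             thresholds = assessment_thresholds()) {
  row <- function(bias, status, adjustment, evidence) {
    data.frame(bias = bias, status = status, adjustment_mode = adjustment,
               evidence = evidence, stringsAsFactors = FALSE)
  }
  missing_diag <- function(bias, what) {
    warning("no ", what, " diagnostic supplied; ", bias, " marked not_assessed",
            call. = FALSE)
    row(bias, "not_assessed", "none", "")
  }
  out <- list()

  # study design: implausibly low certain-only rate is the red flag
  cert <- NULL
  if (!is.null(estimates)) {
    if (inherits(estimates, "incidence_estimate")) estimates <- list(estimates)
    for (e in estimates) {
      if (e$adjustment == "certain_only" && e$population == "confidante" &&
          isTRUE(e$available)) cert <- e
    }
  }
  out$study_design <- if (is.null(cert)) {
    missing_diag("study_design", "certain-only confidante estimate")
  } else if (cert$rate_per_1000 < thresholds$implausibility_floor) {
    row("study_design", "assessed_high", "none",
        sprintf("certain-only rate %.1f per 1000 below implausibility floor %.1f",
                cert$rate_per_1000, thresholds$implausibility_floor))
  } else {
    row("study_design", "assessed_low", "none",
        sprintf("certain-only rate %.1f per 1000 at or above floor %.1f",
                cert$rate_per_1000, thresholds$implausibility_floor))
  }

  disc <- diagnostics$disclosure
  out$transmission <- if (is.null(disc)) {
    missing_diag("transmission", "disclosure")
  } else if (disc$p_any < 1) {
    row("transmission", "assessed_high",
        "visibility correction factor (1/p_any) applied to certain-only rate",
        sprintf("p_any = %.3f < 1 (n = %d self-reporters)", disc$p_any,
                disc$n_self_reporters))
  } else {
    row("transmission", "assessed_low", "none",
        sprintf("p_any = 1 (n = %d self-reporters)", disc$n_self_reporters))
  }

  tel <- diagnostics$telescoping
  out$social_desirability_recall <- if (is.null(tel) || is.na(tel$ratio)) {
    missing_diag("social_desirability_recall", "telescoping")
  } else if (tel$ratio > thresholds$telescope_high) {
    row("social_desirability_recall", "assessed_high",
        "reference-year (full-year) reports used for annual rates",
        sprintf("annualized/full-year ratio %.2f > %.2f", tel$ratio,
                thresholds$telescope_high))
  } else if (tel$ratio > thresholds$telescope_moderate) {
    row("social_desirability_recall", "assessed_moderate",
        "reference-year (full-year) reports used for annual rates",
        sprintf("annualized/full-year ratio %.2f > %.2f", tel$ratio,
                thresholds$telescope_moderate))
  } else {
    row("social_desirability_recall", "assessed_low", "none",
        sprintf("annualized/full-year ratio %.2f within %.2f", tel$ratio,
                thresholds$telescope_moderate))
  }

  hom <- diagnostics$homophily
  out$selection <- if (is.null(hom) || !isTRUE(hom$assessable)) {
    missing_diag("selection", "homophily")
  } else {
    pv <- hom$tests$p_value
    sig <- !is.na(pv) & pv < thresholds$selection_alpha
    if (any(sig)) {
      row("selection", "assessed_high",
          "post-stratification weights (logistic membership model)",
          sprintf("homophily rejected for: %s",
                  paste(hom$tests$characteristic[sig], collapse = ", ")))
    } else {
      row("selection", "assessed_low", "none",
          sprintf("no homophily test significant at %.2f",
                  thresholds$selection_alpha))
    }
  }

  bar <- diagnostics$barrier
  if (inherits(bar, "barrier_result")) bar <- list(bar)
  out$barrier_effects <- if (is.null(bar) || !length(bar)) {
    missing_diag("barrier_effects", "barrier uPR")
  } else {
    excl <- vapply(bar, function(b) {
      if (!isTRUE(b$estimable) || is.null(b$table)) return(FALSE)
      t <- b$table[!b$table$reference, , drop = FALSE]
      any(t$ci_low > 1 | t$ci_high < 1, na.rm = TRUE)
    }, logical(1))
    covs <- vapply(bar, function(b) b$covariate, character(1))
    if (any(excl)) {
      row("barrier_effects", "assessed_high",
          "none (missing confidantes are not imputed)",
          sprintf("uPR CI excludes 1 for: %s", paste(covs[excl], collapse = ", ")))
    } else {
      row("barrier_effects", "assessed_low", "none",
          sprintf("no uPR CI excludes 1 (covariates: %s)",
                  paste(covs, collapse = ", ")))
    }
  }

  # no published method quantifies popularity bias; never auto-upgraded
  out$popularity <- row("popularity", "not_assessed", "none", "")

  res <- do.call(rbind, out[bias_names()])
  rownames(res) <- NULL
  class(res) <- c("bias_assessment", "data.frame")
  res
}

#' Render the bias assessment and estimates as a document
#'
#' @param assessment A `bias_assessment` from [build_assessment()].
#' @param estimates Optional list of `incidence_estimate`s (or the data
#'   frame from [estimates_table()]) appended as an estimates table.
#' @param format One of `"markdown"`, `"json"`, `"delimited"`. JSON output
#'   round-trips losslessly through [parse_report()].
#' @return A single character string (the document).
#' @export
render_report <- function(assessment, estimates = NULL,
                          format = c("markdown", "json", "delimited")) {
  if (length(format) == 1 && !format %in% c("markdown", "json", "delimited")) {
    stop("unknown format '", format,
         "'; supported formats: markdown, json, delimited", call. = FALSE)
  }
  format <- match.arg(format)
  stopifnot(inherits(assessment, "bias_assessment"))
  est <- if (is.null(estimates)) NULL
         else if (is.data.frame(estimates)) estimates
         else estimates_table(estimates)
  labs <- status_labels()
  chk <- as.data.frame(assessment)
  chk$status_label <- unname(labs[chk$status])

  if (format == "json") {
    payload <- list(checklist = chk)
    if (!is.null(est)) payload$estimates <- est
    return(as.character(jsonlite::toJSON(payload, dataframe = "rows",
                                         auto_unbox = TRUE, digits = NA,
                                         na = "null", pretty = TRUE)))
  }
  if (format == "delimited") {
    con <- textConnection("doc", "w", local = TRUE)
    utils::write.table(chk, con, sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(est)) {
      writeLines("", con)
      utils::write.table(est, con, sep = "\t", row.names = FALSE, quote = FALSE)
    }
    close(con)
    return(paste0(paste(doc, collapse = "\n"), "\n"))
  }
  # markdown
  lines <- c("# Confidante-method bias assessment", "",
             "| Bias | Assessment status | Mode of adjustment | Evidence |",
             "|------|-------------------|--------------------|----------|")
  for (i in seq_len(nrow(chk))) {
    lines <- c(lines, sprintf("| %s | %s | %s | %s |", chk$bias[i],
                              chk$status_label[i], chk$adjustment_mode[i],
                              chk$evidence[i]))
  }
  if (!is.null(est)) {
    lines <- c(lines, "", "## Incidence estimates", "",
               "| Population | Adjustment | Year | Rate per 1000 | 95% CI |",
               "|------------|-----------|------|---------------|--------|")
    for (i in seq_len(nrow(est))) {
      ci <- if (is.na(est$ci_low[i])) "-" else
        sprintf("%.1f-%.1f", est$ci_low[i], est$ci_high[i])
      rate <- if (is.na(est$rate_per_1000[i])) "not available" else
        sprintf("%.1f", est$rate_per_1000[i])
      lines <- c(lines, sprintf("| %s | %s | %d | %s | %s |",
                                est$population[i], est$adjustment[i],
                                est$year[i], rate, ci))
    }
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse a JSON bias-assessment document
#'
#' Inverse of `render_report(..., format = "json")`: re-rendering the parsed
#' result reproduces the document exactly.
#'
#' @param json A JSON document string.
#' @return List with `assessment` (a `bias_assessment`) and `estimates`
#'   (data frame or `NULL`).
#' @export
parse_report <- function(json) {
  payload <- jsonlite::fromJSON(json)
  chk <- payload$checklist
  assessment <- chk[c("bias", "status", "adjustment_mode", "evidence")]
  class(assessment) <- c("bias_assessment", "data.frame")
  list(assessment = assessment, estimates = payload$estimates)
}
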