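#' Read and validate a confidante survey file
#'
#' Reads a delimited wide-format survey table (one row per respondent, up to
#' two confidante report blocks under `conf1_`/`conf2_` column prefixes),
#' harmonizes columns and category codes under `schema`, and validates the
#' data model. Respondents reporting three or more confidantes are kept with
#' the confidante list truncated to the first and second positions; the
#' originally reported count is preserved in `n_confidantes_reported`.
#'
#' Rows violating hard invariants (age outside 15-49, age group inconsistent
#' with age in years, non-positive sampling weight, a reported confidante
#' abortion without a certainty level) are rejected with row-indexed
#' diagnostics rather than silently dropped; repairable inconsistencies
#' (e.g. an abortion date present without a "yes" report) are cleared and
#' logged. Diagnostics are attached as `attr(x, "diagnostics")`.
#'
#' Missingness is kept explicit throughout: nothing is imputed at ingest, and
#' downstream estimators document their complete-case behavior.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema A [survey_schema()] describing column names, category codes
#'   and the survey's calendar window.
#' @return A `confidante_survey` data frame of validated respondent records
#'   with attributes `diagnostics` (a data frame with columns `row`, `field`,
#'   `value`, `problem`, `action`) and `schema`.
#' @export
read_survey <- function(path, schema = survey_schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.delim(path, sep = schema$delimiter, stringsAsFactors = FALSE,
                      check.names = FALSE, na.strings = c("", "NA")),
    error = function(e) stop("empty or unreadable survey file: ", path,
                             " (", conditionMessage(e), ")", call. = FALSE)
  )
  if (nrow(raw) == 0) stop("survey file has no data rows: ", path, call. = FALSE)

  cmap <- schema$column_map
  explicit <- schema$explicit
  missing_cols <- vapply(explicit, function(f) {
    src <- cmap[[f]]
    length(src) == 1 && !is.na(src) && !(src %in% names(raw))
  }, logical(1))
  if (any(missing_cols)) {
    stop("schema error: mapped column(s) not in file: ",
         paste(unlist(cmap[explicit[missing_cols]]), collapse = ", "),
         call. = FALSE)
  }

  n <- nrow(raw)
  pull <- function(field) {
    src <- cmap[[field]]
    if (is.null(src) || length(src) == 0 || is.na(src) || !(src %in% names(raw)))
      rep(NA, n)
    else raw[[src]]
  }

  diag <- list()
  note <- function(rows, field, values, problem, action) {
    if (length(rows)) {
      diag[[length(diag) + 1L]] <<- data.frame(
        row = rows, field = field, value = as.character(values),
        problem = problem, action = action, stringsAsFactors = FALSE)
    }
  }

  lv <- canonical_levels()
  map_category <- function(x, field) {
    x <- as.character(x)
    base <- base_field(field)
    km <- schema$category_map[[base]]
    if (!is.null(km)) {
      hit <- x %in% names(km)
      x[hit] <- unname(km[x[hit]])
    }
    bad <- !is.na(x) & !(x %in% lv[[base]])
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf(
        "validation error: unparseable category code for %s at row %d: '%s'",
        field, i, x[i]), call. = FALSE)
    }
    factor(x, levels = lv[[base]])
  }
  as_bool <- function(x) {
    if (is.logical(x)) return(x)
    x <- tolower(as.character(x))
    out <- rep(NA, length(x))
    out[x %in% c("true", "1", "yes", "t")] <- TRUE
    out[x %in% c("false", "0", "no", "f")] <- FALSE
    out
  }
  num <- function(x) suppressWarnings(as.numeric(x))

  rec <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    respondent_id = as.character(pull("respondent_id")))
  if (all(is.na(rec$respondent_id))) rec$respondent_id <- as.character(seq_len(n))
  rec$sample_weight <- num(pull("sample_weight"))
  if (all(is.na(rec$sample_weight))) {
    rec$sample_weight <- rep(1.0, n)
  } else if (anyNA(rec$sample_weight)) {
    i <- which(is.na(rec$sample_weight))
    note(i, "sample_weight", NA, "missing sampling weight", "defaulted to 1.0")
    rec$sample_weight[i] <- 1.0
  }
  rec$age_years <- num(pull("age_years"))
  for (f in c("age_group", "education", "residence", "marital_status",
              "fp_use", "parity", "self_abortion_ever")) {
    rec[[f]] <- map_category(pull(f), f)
  }
  rec$self_abortion_year <- num(pull("self_abortion_year"))
  rec$self_abortion_month <- num(pull("self_abortion_month"))

  for (k in 1:2) {
    p <- paste0("conf", k, "_")
    for (f in c("age_group", "education", "residence", "marital_status",
                "parity", "abortion_ever", "certainty")) {
      rec[[paste0(p, f)]] <- map_category(pull(paste0(p, f)), paste0(p, f))
    }
    rec[[paste0(p, "age_years")]] <- num(pull(paste0(p, "age_years")))
    i <- which(is.na(rec[[paste0(p, "age_group")]]) &
                 !is.na(rec[[paste0(p, "age_years")]]))
    if (length(i)) {
      rec[[paste0(p, "age_group")]][i] <- age_to_group(rec[[paste0(p, "age_years")]][i])
    }
    rec[[paste0(p, "abortion_year")]] <- num(pull(paste0(p, "abortion_year")))
    rec[[paste0(p, "abortion_month")]] <- num(pull(paste0(p, "abortion_month")))
    rec[[paste0(p, "method_info")]] <- as_bool(pull(paste0(p, "method_info")))
    rec[[paste0(p, "disclosed")]] <- as_bool(pull(paste0(p, "disclosed")))
  }

  block_cols <- function(prefix, frame) {
    nm <- grep(paste0("^", prefix), names(frame), value = TRUE)
    if (!length(nm)) return(rep(FALSE, n))
    sub <- frame[nm]
    Reduce(`|`, lapply(sub, function(x) !is.na(x)))
  }
  conf1_rep <- block_cols("conf1_", rec)
  conf2_rep <- block_cols("conf2_", rec)
  # blocks past position 2 are counted, then dropped (analytic truncation)
  extra_prefixes <- unique(regmatches(explicit,
    regexpr("^conf[3-9]_", explicit)))
  extra_reported <- rep(0L, n)
  for (p in extra_prefixes) {
    flds <- explicit[startsWith(explicit, p)]
    src <- unlist(cmap[flds])
    src <- src[src %in% names(raw)]
    if (length(src)) {
      extra_reported <- extra_reported +
        as.integer(Reduce(`|`, lapply(raw[src], function(x) !is.na(x))))
    }
  }
  n_rep <- num(pull("n_confidantes_reported"))
  derived <- as.integer(conf1_rep) + as.integer(conf2_rep) + extra_reported
  rec$n_confidantes_reported <- ifelse(is.na(n_rep), derived, n_rep)

  # ---- soft repairs --------------------------------------------------------
  not_self <- is.na(rec$self_abortion_ever) | rec$self_abortion_ever != "yes"
  i <- which(not_self & (!is.na(rec$self_abortion_year) |
                         !is.na(rec$self_abortion_month)))
  note(i, "self_abortion_year", rec$self_abortion_year[i],
       "abortion date without self-reported abortion", "cleared")
  rec$self_abortion_year[i] <- NA_real_
  rec$self_abortion_month[i] <- NA_real_
  for (k in 1:2) {
    dcol <- paste0("conf", k, "_disclosed")
    i <- which(not_self & !is.na(rec[[dcol]]))
    note(i, dcol, rec[[dcol]][i],
         "disclosure indicator without self-reported abortion", "cleared")
    rec[[dcol]][i] <- NA
  }
  i <- which(is.na(rec$age_group) & !is.na(rec$age_years))
  if (length(i)) {
    rec$age_group[i] <- age_to_group(rec$age_years[i])
    note(i, "age_group", NA, "age group absent", "derived from age_years")
  }

  # ---- hard invariants -----------------------------------------------------
  reject <- rep(FALSE, n)
  flag <- function(cond, field, problem) {
    i <- which(cond & !reject)
    note(i, field, rec[[field]][i], problem, "rejected")
    reject[i] <<- TRUE
  }
  flag(!is.na(rec$age_years) & (rec$age_years < 15 | rec$age_years > 49),
       "age_years", "age outside 15-49")
  flag(!is.na(rec$age_years) & !is.na(rec$age_group) &
         as.character(age_to_group(rec$age_years)) != as.character(rec$age_group),
       "age_group", "age group inconsistent with age in years")
  flag(rec$sample_weight <= 0, "sample_weight", "non-positive sampling weight")
  for (k in 1:2) {
    ae <- rec[[paste0("conf", k, "_abortion_ever")]]
    ct <- rec[[paste0("conf", k, "_certainty")]]
    flag(!is.na(ae) & ae == "yes" & is.na(ct),
         paste0("conf", k, "_certainty"),
         "reported confidante abortion without certainty level")
  }

  diagnostics <- if (length(diag)) do.call(rbind, diag) else
    data.frame(row = integer(0), field = character(0), value = character(0),
               problem = character(0), action = character(0))
  out <- rec[!reject, , drop = FALSE]
  rownames(out) <- NULL
  if (any(reject)) {
    message(sum(reject), " row(s) rejected by validation; see attr(x, 'diagnostics')")
  }
  structure(out, diagnostics = diagnostics, schema = schema,
            class = c("confidante_survey", "data.frame"))
}

#' Write a confidante survey in the canonical wide format
#'
#' Inverse of [read_survey()] for canonical fields: writing and re-reading
#' under the same schema round-trips every canonical field.
#'
#' @param records A `confidante_survey` data frame.
#' @param path Output path.
#' @param schema A [survey_schema()]; only the delimiter is used.
#' @return `path`, invisibly.
#' @export
write_survey <- function(records, path, schema = survey_schema()) {
  out <- as.data.frame(records)
  out <- out[intersect(canonical_fields(), names(out))]
  for (f in names(out)) if (is.factor(out[[f]])) out[[f]] <- as.character(out[[f]])
  utils::write.table(out, path, sep = schema$delimiter, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Reshape a survey to one row per respondent-confidante pair
#'
#' Produces the long pair table used for homophily comparison and
#' post-stratification weighting: one row per reported confidante, carrying
#' the respondent's covariates (prefix `r_`), the confidante's covariates
#' (prefix `c_`), derived relation categories, the confidante abortion report
#' fields, the position (1 or 2), and the respondent's sampling weight.
#' Respondents with zero reported confidantes contribute no rows.
#'
#' Relations are derived from the harmonized ordered categories: e.g.
#' `age_relation` is `"R_younger"`, `"same"` or `"R_older"` comparing the
#' respondent's and confidante's age bands; `marital_relation` has the four
#' joint categories (`both`, `neither`, `R_yes_CF_no`, `R_no_CF_yes`).
#'
#' @param records A `confidante_survey` data frame.
#' @return A `confidante_pairs` data frame.
#' @export
to_pairs <- function(records) {
  lv <- canonical_levels()
  covs <- c("age_group", "education", "residence", "marital_status", "parity")
  one <- function(k) {
    p <- paste0("conf", k, "_")
    rep_cols <- grep(paste0("^", p), names(records), value = TRUE)
    reported <- if (length(rep_cols)) {
      Reduce(`|`, lapply(records[rep_cols], function(x) !is.na(x)))
    } else rep(FALSE, nrow(records))
    idx <- which(reported)
    if (!length(idx)) return(NULL)
    r <- records[idx, , drop = FALSE]
    out <- data.frame(respondent_id = r$respondent_id, position = k,
                      sample_weight = r$sample_weight,
                      stringsAsFactors = FALSE)
    for (f in c(covs, "fp_use")) out[[paste0("r_", f)]] <- r[[f]]
    for (f in covs) out[[paste0("c_", f)]] <- r[[paste0(p, f)]]
    rel3 <- function(rf, cf, lo, hi) {
      a <- as.integer(r[[rf]]); b <- as.integer(r[[paste0(p, cf)]])
      ifelse(is.na(a) | is.na(b), NA_character_,
             ifelse(a < b, lo, ifelse(a > b, hi, "same")))
    }
    # exact-age comparison where confidante age was collected, else age bands
    band_rel <- rel3("age_group", "age_group", "R_younger", "R_older")
    ra <- r$age_years; ca <- r[[paste0(p, "age_years")]]
    exact <- !is.na(ra) & !is.na(ca)
    out$age_relation <- ifelse(exact,
      ifelse(ra < ca, "R_younger", ifelse(ra > ca, "R_older", "same")),
      band_rel)
    out$education_relation <- rel3("education", "education", "R_less", "R_more")
    out$parity_relation <- rel3("parity", "parity", "R_fewer", "R_more")
    rres <- as.character(r$residence); cres <- as.character(r[[paste0(p, "residence")]])
    out$residence_relation <- ifelse(is.na(rres) | is.na(cres), NA_character_,
                                     ifelse(rres == cres, "same", "different"))
    rm_ <- as.character(r$marital_status) == "married/cohabiting"
    cm_ <- as.character(r[[paste0(p, "marital_status")]]) == "married/cohabiting"
    out$marital_relation <- ifelse(is.na(rm_) | is.na(cm_), NA_character_,
      ifelse(rm_ & cm_, "both", ifelse(!rm_ & !cm_, "neither",
        ifelse(rm_, "R_yes_CF_no", "R_no_CF_yes"))))
    for (f in c("abortion_ever", "certainty")) out[[f]] <- r[[paste0(p, f)]]
    out$abortion_year <- r[[paste0(p, "abortion_year")]]
    out$abortion_month <- r[[paste0(p, "abortion_month")]]
    out$method_info <- r[[paste0(p, "method_info")]]
    out$disclosed <- r[[paste0(p, "disclosed")]]
    out
  }
  pieces <- Filter(Negate(is.null), list(one(1), one(2)))
  out <- if (length(pieces)) do.call(rbind, pieces) else {
    tmpl <- one_empty_pairs()
    tmpl
  }
  rownames(out) <- NULL
  structure(out, class = c("confidante_pairs", "data.frame"))
}

#' @keywords internal
one_empty_pairs <- function() {
  covs <- c("age_group", "education", "residence", "marital_status", "parity")
  out <- data.frame(respondent_id = character(0), position = integer(0),
                    sample_weight = numeric(0), stringsAsFactors = FALSE)
  for (f in c(covs, "fp_use")) out[[paste0("r_", f)]] <- factor(character(0))
  for (f in covs) out[[paste0("c_", f)]] <- factor(character(0))
  for (f in c("age_relation", "education_relation", "parity_relation",
              "residence_relation", "marital_relation"))
    out[[f]] <- character(0)
  out$abortion_ever <- factor(character(0))
  out$certainty <- factor(character(0))
  out$abortion_year <- numeric(0)
  out$abortion_month <- numeric(0)
  out$method_info <- logical(0)
  out$disclosed <- logical(0)
  out
}

#' Proportion of respondents reporting zero confidantes
#'
#' A headline barrier-effect summary: the share of the respondent sample that
#' contributes nothing to the confidante (surrogate) sample.
#'
#' @param records A `confidante_survey` data frame.
#' @param weighted Use sampling weights (default) or raw counts.
#' @return Proportion in `[0, 1]`.
#' @export
prop_zero_confidantes <- function(records, weighted = TRUE) {
  w <- if (weighted) records$sample_weight else rep(1, nrow(records))
  zero <- records$n_confidantes_reported == 0
  sum(w[zero]) / sum(w)
}
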