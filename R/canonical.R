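# Canonical field definitions shared across the package.
#
# A survey is stored wide: one row per respondent, confidante blocks under
# conf1_/conf2_ prefixes. Category levels are the harmonized ones used for
# cross-context comparison; source-specific codes are mapped onto these via
# the schema's category_map.

#' @keywords internal
canonical_levels <- function() {
  list(
    age_group      = c("15-19", "20-29", "30-39", "40-49"),
    education      = c("never", "primary", "secondary", "higher"),
    residence      = c("urban", "rural"),
    marital_status = c("married/cohabiting", "not married/cohabiting"),
    fp_use         = c("no", "yes"),
    parity         = c("0", "1-2", "3-5", "6+"),
    self_abortion_ever = c("no", "yes"),
    abortion_ever  = c("no", "yes"),
    certainty      = c("certain", "less_certain")
  )
}

# Respondent covariates used for homophily, barrier and weighting analyses.
#' @keywords internal
canonical_covariates <- function() {
  c("age_group", "education", "residence", "marital_status", "fp_use", "parity")
}

# Confidante-block field suffixes (canonical names are conf<k>_<suffix>).
#' @keywords internal
confidante_suffixes <- function() {
  c("age_years", "age_group", "education", "residence", "marital_status", "parity",
    "abortion_ever", "certainty", "abortion_year", "abortion_month",
    "method_info", "disclosed")
}

#' @keywords internal
respondent_fields <- function() {
  c("respondent_id", "sample_weight", "age_years", "age_group", "education",
    "residence", "marital_status", "fp_use", "parity",
    "self_abortion_ever", "self_abortion_year", "self_abortion_month",
    "n_confidantes_reported")
}

#' @keywords internal
canonical_fields <- function(n_conf = 2L) {
  conf <- unlist(lapply(seq_len(n_conf), function(k) {
    paste0("conf", k, "_", confidante_suffixes())
  }))
  c(respondent_fields(), conf)
}

# Map an age in years onto the canonical age band.
#' @keywords internal
age_to_group <- function(age) {
  cut(age, breaks = c(14, 19, 29, 39, 49), labels = canonical_levels()$age_group,
      right = TRUE)
}

# Base field name for category mapping: conf1_education -> education.
#' @keywords internal
base_field <- function(field) {
  sub("^conf[0-9]+_", "", field)
}

# Run code with a deterministic RNG stream without disturbing the caller's.
#' @keywords internal
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# A confidante block counts as reported if any of its fields is non-missing.
#' @keywords internal
block_reported <- function(records, k) {
  nm <- grep(paste0("^conf", k, "_"), names(records), value = TRUE)
  if (!length(nm)) return(rep(FALSE, nrow(records)))
  Reduce(`|`, lapply(records[nm], function(x) !is.na(x)))
}
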