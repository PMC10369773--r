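#' Survey schema: column and category mapping for a confidante survey
#'
#' Confidante-method instruments differ across contexts in column naming,
#' category coding, which confidante characteristics were collected, and the
#' calendar window of fieldwork. A `survey_schema` captures those per-survey
#' facts so that [read_survey()] can produce one harmonized representation.
#'
#' @param column_map Named character vector or list mapping canonical field
#'   names to source column names. Canonical fields not named here default to
#'   their own name; map a field to `NA` to declare it absent from the survey.
#'   Confidante fields use `conf1_`/`conf2_` prefixes (e.g.
#'   `conf1_abortion_ever`). Blocks beyond the second (prefix `conf3_` and up)
#'   may be mapped so that the originally reported confidante count is
#'   preserved, but they never enter estimation.
#' @param category_map Named list: for a categorical field (base name, e.g.
#'   `"education"`, applying to the respondent and both confidante columns),
#'   a named character vector from source codes to canonical categories.
#' @param delimiter Field delimiter of the source file (`","` default).
#' @param reference_year Calendar year with a full year of reporting (the
#'   default reference year for annual rates).
#' @param partial_year Calendar year observed only partially at fieldwork.
#' @param months_observed_partial Number of months (1-12) of `partial_year`
#'   covered by fieldwork; used to annualize partial-year counts.
#' @param survey_end_date Survey end date (`Date` or `"YYYY-MM-DD"` string),
#'   recorded for provenance.
#'
#' @return An object of class `survey_schema`.
#' @seealso [read_survey()], [write_schema()]
#' @export
survey_schema <- function(column_map = NULL, category_map = NULL,
                          delimiter = ",",
                          reference_year = 2017L, partial_year = 2018L,
                          months_observed_partial = 4L,
                          survey_end_date = NULL) {
  months_observed_partial <- as.integer(months_observed_partial)
  if (is.na(months_observed_partial) || months_observed_partial < 1L ||
      months_observed_partial > 12L) {
    stop("schema error: months_observed_partial must be an integer in 1..12",
         call. = FALSE)
  }
  full_map <- stats::setNames(as.list(canonical_fields()), canonical_fields())
  if (!is.null(column_map)) {
    column_map <- as.list(column_map)
    if (is.null(names(column_map)) || any(names(column_map) == "")) {
      stop("schema error: column_map must be fully named", call. = FALSE)
    }
    known <- names(column_map) %in% canonical_fields() |
      grepl("^conf[3-9]_", names(column_map))
    if (!all(known)) {
      stop("schema error: unknown canonical field(s): ",
           paste(names(column_map)[!known], collapse = ", "), call. = FALSE)
    }
    for (f in names(column_map)) full_map[[f]] <- column_map[[f]]
  }
  if (!is.null(category_map)) {
    bad <- setdiff(names(category_map), names(canonical_levels()))
    if (length(bad)) {
      stop("schema error: category_map for non-categorical field(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(column_map = full_map,
         explicit = if (is.null(column_map)) character(0) else names(column_map),
         category_map = category_map %||% list(),
         delimiter = delimiter,
         reference_year = as.integer(reference_year),
         partial_year = as.integer(partial_year),
         months_observed_partial = months_observed_partial,
         survey_end_date = if (is.null(survey_end_date)) NULL
                           else as.character(survey_end_date)),
    class = "survey_schema"
  )
}

#' @export
print.survey_schema <- function(x, ...) {
  absent <- names(x$column_map)[vapply(x$column_map,
    function(v) length(v) == 0 || is.na(v), logical(1))]
  remapped <- names(x$column_map)[mapply(function(f, v) {
    length(v) == 1 && !is.na(v) && !identical(f, v)
  }, names(x$column_map), x$column_map)]
  cat("<survey_schema>\n")
  cat("  reference year:", x$reference_year,
      " partial year:", x$partial_year,
      sprintf("(%d months observed)\n", x$months_observed_partial))
  cat("  remapped columns:", if (length(remapped)) length(remapped) else "none", "\n")
  cat("  declared absent:", if (length(absent))
        paste(absent, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Read or write a survey schema as YAML
#'
#' @param path File path.
#' @return `read_schema()` returns a [survey_schema()]; `write_schema()`
#'   returns `path` invisibly.
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  cmap <- raw$column_map
  if (!is.null(cmap)) {
    cmap <- lapply(cmap, function(v) if (is.null(v)) NA_character_ else v)
  }
  kmap <- raw$category_map
  if (!is.null(kmap)) kmap <- lapply(kmap, function(m) unlist(m))
  survey_schema(column_map = cmap, category_map = kmap,
                delimiter = raw$delimiter %||% ",",
                reference_year = raw$reference_year %||% 2017L,
                partial_year = raw$partial_year %||% 2018L,
                months_observed_partial = raw$months_observed_partial %||% 4L,
                survey_end_date = raw$survey_end_date)
}

#' @rdname read_schema
#' @param schema A [survey_schema()].
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "survey_schema"))
  out <- unclass(schema)
  # only the explicitly mapped entries are survey facts; defaults regenerate
  out$column_map <- lapply(out$column_map[out$explicit],
    function(v) if (length(v) == 0 || is.na(v)) NULL else v)
  out$explicit <- NULL
  out$category_map <- lapply(out$category_map, as.list)
  yaml::write_yaml(out, path)
  invisible(path)
}
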