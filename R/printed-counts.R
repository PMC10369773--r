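#' Published zero-confidante counts from six confidante-method applications
#'
#' Respondent counts by confidante reporting status (zero vs one or more) as
#' published for six national/sub-national applications of the confidante
#' method (Cote d'Ivoire, Ethiopia, Java/Indonesia, Nigeria, Rajasthan/India,
#' Uganda), together with the percentage of respondents reporting zero
#' confidantes as printed in the source tables. These counts let the
#' barrier-effect headline summaries be recomputed without access to the
#' restricted microdata.
#'
#' @return Data frame with columns `context`, `n_zero`, `n_one_plus`,
#'   `printed_pct_zero`.
#' @seealso [zero_confidante_shares()]
#' @export
context_confidante_counts <- function() {
  path <- system.file("extdata", "context_zero_confidante_counts.csv",
                      package = "confidante", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Recompute zero-confidante percentages from published counts
#'
#' @param counts A data frame as returned by [context_confidante_counts()].
#' @return The input with an added `recomputed_pct_zero` column
#'   (`100 * n_zero / (n_zero + n_one_plus)`, unrounded).
#' @export
zero_confidante_shares <- function(counts = context_confidante_counts()) {
  counts$recomputed_pct_zero <-
    100 * counts$n_zero / (counts$n_zero + counts$n_one_plus)
  counts
}
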