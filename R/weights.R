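# Characteristics compared between respondents and confidantes, with the
# derived relation column and its display levels.
#' @keywords internal
homophily_characteristics <- function() {
  list(
    age_group = list(rel = "age_relation",
                     levels = c("R_younger", "same", "R_older")),
    education = list(rel = "education_relation",
                     levels = c("R_less", "same", "R_more")),
    residence = list(rel = "residence_relation",
                     levels = c("same", "different")),
    marital_status = list(rel = "marital_relation",
                          levels = c("both", "neither", "R_yes_CF_no", "R_no_CF_yes")),
    parity = list(rel = "parity_relation",
                  levels = c("R_fewer", "same", "R_more"))
  )
}

#' Respondent-confidante homophily comparison
#'
#' Compares the distributions of sociodemographic characteristics between
#' respondents and their confidantes, pair-wise, to diagnose selection bias.
#' For each available characteristic it reports the weighted distribution of
#' respondent-confidante relation categories (e.g. R younger / same age /
#' R older) and a Pearson chi-square test of independence between the
#' respondent and confidante category distributions, computed on
#' weight-scaled counts rescaled to the nominal number of complete pairs.
#' Characteristics not collected by the survey are reported as `NA`;
#' a characteristic where every pair falls in the "same" relation (e.g. a
#' sample generated under perfect homophily) is flagged as degenerate, with
#' a zero statistic, rather than failing.
#'
#' @param pairs A pair table from [to_pairs()].
#' @param weights Optional per-pair weights; defaults to the respondent
#'   sampling weights carried by the pair table.
#' @return A `homophily_table`: list with `shares` (characteristic, relation,
#'   weighted percentage), `tests` (chi-square statistic, df, p-value,
#'   number of complete pairs, degeneracy flag) and `assessable`.
#' @export
homophily_table <- function(pairs, weights = NULL) {
  if (nrow(pairs) == 0) stop("pair table is empty", call. = FALSE)
  w_all <- weights %||% pairs$sample_weight %||% rep(1, nrow(pairs))
  chars <- homophily_characteristics()
  shares <- list(); tests <- list()
  any_avail <- FALSE
  for (nm in names(chars)) {
    spec <- chars[[nm]]
    rcol <- pairs[[paste0("r_", nm)]]
    ccol <- pairs[[paste0("c_", nm)]]
    rel <- pairs[[spec$rel]]
    cc <- !is.na(rcol) & !is.na(ccol)
    if (!any(cc)) {
      tests[[nm]] <- data.frame(characteristic = nm, chi_square = NA_real_,
                                df = NA_integer_, p_value = NA_real_,
                                n_pairs = 0L, degenerate = NA)
      next
    }
    any_avail <- TRUE
    w <- w_all[cc]
    sh <- vapply(spec$levels, function(l) sum(w[rel[cc] == l]) / sum(w), numeric(1))
    shares[[nm]] <- data.frame(characteristic = nm, relation = spec$levels,
                               share_pct = 100 * sh, row.names = NULL)
    # 2 x K table: respondent vs confidante category distributions,
    # weighted counts rescaled so each row sums to the number of pairs
    n_cc <- sum(cc)
    rw <- tapply(w, droplevels(factor(rcol[cc])), sum)
    levs <- union(levels(droplevels(factor(rcol[cc]))),
                  levels(droplevels(factor(ccol[cc]))))
    rowcount <- function(x) {
      cnt <- vapply(levs, function(l) sum(w[as.character(x) == l]), numeric(1))
      cnt / sum(cnt) * n_cc
    }
    tab <- rbind(respondent = rowcount(rcol[cc]), confidante = rowcount(ccol[cc]))
    keep <- colSums(tab) > 0
    tab <- tab[, keep, drop = FALSE]
    degenerate <- all(rel[cc] == "same")
    if (ncol(tab) < 2) {
      stat <- 0; dfree <- 0L; pval <- 1
      degenerate <- TRUE
    } else {
      expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      stat <- sum((tab - expd)^2 / expd)
      dfree <- as.integer(ncol(tab) - 1L)
      pval <- stats::pchisq(stat, dfree, lower.tail = FALSE)
    }
    tests[[nm]] <- data.frame(characteristic = nm, chi_square = stat,
                              df = dfree, p_value = pval, n_pairs = n_cc,
                              degenerate = degenerate)
  }
  structure(list(
    shares = if (length(shares)) do.call(rbind, c(shares, make.row.names = FALSE))
             else NULL,
    tests = do.call(rbind, c(tests, make.row.names = FALSE)),
    assessable = any_avail,
    weighted = !is.null(weights) || !is.null(pairs$sample_weight)
  ), class = "homophily_table")
}

#' @export
print.homophily_table <- function(x, digits = 1, ...) {
  cat("Respondent-confidante homophily comparison",
      if (x$weighted) "(weighted)" else "(unweighted)", "\n")
  if (!x$assessable) {
    cat("  no characteristic assessable in this survey\n")
    return(invisible(x))
  }
  for (nm in unique(x$tests$characteristic)) {
    t <- x$tests[x$tests$characteristic == nm, ]
    if (is.na(t$p_value)) {
      cat(sprintf("  %-15s NA (not collected)\n", nm))
      next
    }
    cat(sprintf("  %-15s chi2 = %.2f, df = %d, p = %.3g, n = %d%s\n", nm,
                t$chi_square, t$df, t$p_value, t$n_pairs,
                if (isTRUE(t$degenerate)) " [degenerate: all pairs identical]" else ""))
    s <- x$shares[x$shares$characteristic == nm, ]
    for (i in seq_len(nrow(s))) {
      cat(sprintf("      %-12s %5.*f%%\n", s$relation[i], digits, s$share_pct[i]))
    }
  }
  invisible(x)
}

#' Post-stratification weights for the confidante sample
#'
#' Aligns the confidante sample's covariate distribution to the population
#' represented by the (design-weighted) respondent sample, the standard
#' remedy when the homophily assumption fails. A logistic membership model
#' (reference respondents, weighted by their sampling weights, versus
#' confidante pairs) is fit on the stacked data; each pair's weight is its
#' fitted odds of reference membership (a density-ratio weight), normalized
#' to mean one. With `saturated = TRUE` the model is fit on the full
#' stratification cells (the interaction of all covariates), in which case
#' the weighted confidante covariate margins reproduce the weighted
#' reference margins exactly.
#'
#' Pairs or reference rows with missing values in any weighting covariate
#' are dropped (complete-case; the count is reported in the diagnostics).
#' Weights are never extrapolated: a stratification cell populated on only
#' one side is an error naming the cell.
#'
#' @param pairs A pair table from [to_pairs()].
#' @param reference The respondent records (a `confidante_survey`), carrying
#'   `sample_weight`.
#' @param covariates Canonical covariate names to balance on (must be
#'   collected for confidantes, i.e. any of `age_group`, `education`,
#'   `residence`, `marital_status`, `parity`).
#' @param saturated Fit on the full interaction cells (exact margin
#'   matching) instead of a main-effects logistic model.
#' @return A `weight_set`: list with `weights` (data frame keyed by
#'   `respondent_id` + `position`), `normalization`, `model_spec`, and
#'   `diagnostics` (convergence flag, max/min weight, effective sample
#'   size, counts).
#' @export
fit_poststrat_weights <- function(pairs, reference, covariates,
                                  saturated = FALSE) {
  ok <- c("age_group", "education", "residence", "marital_status", "parity")
  bad <- setdiff(covariates, ok)
  if (length(bad)) {
    stop("covariate(s) not available for confidantes: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  miss_p <- setdiff(paste0("c_", covariates), names(pairs))
  miss_r <- setdiff(covariates, names(reference))
  if (length(miss_p) || length(miss_r)) {
    stop("covariate column(s) missing: ",
         paste(c(miss_p, miss_r), collapse = ", "), call. = FALSE)
  }

  ref <- data.frame(y = 1, w = reference$sample_weight)
  for (f in covariates) ref[[f]] <- factor(as.character(reference[[f]]))
  cf <- data.frame(y = rep(0, nrow(pairs)), w = rep(1, nrow(pairs)))
  for (f in covariates) cf[[f]] <- factor(as.character(pairs[[paste0("c_", f)]]))
  cc_ref <- stats::complete.cases(ref)
  cc_cf <- stats::complete.cases(cf)
  n_dropped <- sum(!cc_ref) + sum(!cc_cf)
  ref <- ref[cc_ref, , drop = FALSE]
  cfk <- cf[cc_cf, , drop = FALSE]
  if (nrow(cfk) == 0 || nrow(ref) == 0) {
    stop("no complete cases to fit post-stratification weights", call. = FALSE)
  }

  # refuse to extrapolate: every fitted cell must be populated on both sides
  cell_of <- function(d) {
    if (saturated || length(covariates) == 1) {
      interaction(d[covariates], drop = FALSE, sep = " x ")
    } else NULL
  }
  if (saturated || length(covariates) == 1) {
    rc <- table(cell_of(ref)); kc <- table(cell_of(cfk))
    levs <- union(names(rc[rc > 0]), names(kc[kc > 0]))
    one_sided <- levs[!(levs %in% names(rc[rc > 0])) | !(levs %in% names(kc[kc > 0]))]
    if (length(one_sided)) {
      stop("stratification cell(s) empty on one side: ",
           paste(one_sided, collapse = "; "), call. = FALSE)
    }
  } else {
    for (f in covariates) {
      rl <- names(which(table(ref[[f]]) > 0))
      kl <- names(which(table(cfk[[f]]) > 0))
      only <- c(setdiff(rl, kl), setdiff(kl, rl))
      if (length(only)) {
        stop("covariate cell(s) empty on one side: ",
             paste(paste0(f, "=", only), collapse = "; "), call. = FALSE)
      }
    }
  }

  stacked <- rbind(ref, cfk)
  for (f in covariates) stacked[[f]] <- droplevels(factor(stacked[[f]]))
  form <- if (saturated) {
    stats::as.formula(paste("y ~", paste(covariates, collapse = " * ")))
  } else {
    stats::as.formula(paste("y ~", paste(covariates, collapse = " + ")))
  }
  fit <- stats::glm(form, family = stats::quasibinomial(), data = stacked,
                    weights = stacked$w,
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) {
    stop("post-stratification membership model did not converge (covariates: ",
         paste(covariates, collapse = ", "),
         if (saturated) ", saturated)" else ")", call. = FALSE)
  }
  p <- stats::fitted(fit)[stacked$y == 0]
  w_raw <- p / (1 - p)
  w <- rep(NA_real_, nrow(cf))
  w[cc_cf] <- w_raw / mean(w_raw)
  wt <- data.frame(respondent_id = pairs$respondent_id,
                   position = pairs$position, weight = w,
                   stringsAsFactors = FALSE)
  wk <- w[!is.na(w)]
  structure(list(
    weights = wt,
    normalization = "mean_one",
    model_spec = list(covariates = covariates, saturated = saturated,
                      formula = deparse(form)),
    diagnostics = list(converged = fit$converged,
                       max_weight = max(wk), min_weight = min(wk),
                       effective_sample_size = sum(wk)^2 / sum(wk^2),
                       n_pairs = length(wk), n_dropped = n_dropped)
  ), class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  d <- x$diagnostics
  cat("Post-stratification weight set (", d$n_pairs, " pairs)\n", sep = "")
  cat("  model: ", x$model_spec$formula,
      if (x$model_spec$saturated) " [saturated]" else "", "\n", sep = "")
  cat(sprintf("  weights: min %.3f / max %.3f, ESS %.1f, normalization %s\n",
              d$min_weight, d$max_weight, d$effective_sample_size,
              x$normalization))
  if (d$n_dropped > 0) cat("  ", d$n_dropped, " row(s) dropped (incomplete covariates)\n")
  invisible(x)
}

#' Export a weight set as delimited text
#'
#' @param ws A `weight_set`.
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @return `path`, invisibly.
#' @export
write_weight_set <- function(ws, path, delimiter = ",") {
  stopifnot(inherits(ws, "weight_set"))
  utils::write.table(ws$weights, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
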