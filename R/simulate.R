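#' Parameters for the synthetic confidante survey generator
#'
#' Defines the generative model for a synthetic confidante survey with known
#' truth. The generator emulates the measurement process of a confidante
#' instrument: respondents with sociodemographic covariates and a sampling
#' design weight, 0-2 reported confidantes whose covariates follow a
#' homophily rule, true abortion events with calendar dates over the window
#' from the year before the reference year through the partially observed
#' fieldwork year, woman-level disclosure determining which confidante events
#' are visible to the respondent, certain/less-certain knowledge states, and
#' optional backward telescoping of reference-year events into the fieldwork
#' year.
#'
#' Disclosure is modeled as an all-or-none trait of each woman: with
#' probability `disclosure_prob` she shares her abortion experience with her
#' confidante circle (so a respondent who discloses does so to every reported
#' confidante, and a confidante's abortion is visible to the respondent if
#' and only if the confidante is a discloser). Under this symmetric rule the
#' visibility of confidante abortions equals the proportion of self-reporting
#' respondents who informed any confidante, which is the identifying
#' assumption of the visibility (transmission-bias) correction.
#'
#' @param n_respondents Number of respondents.
#' @param covariate_margins Named list of per-covariate category probability
#'   vectors (names must match the canonical levels).
#' @param true_rate_per_1000 True annual abortion incidence per 1000 women
#'   15-49 (applies to respondents and confidantes alike).
#' @param rate_gradients Optional named list of per-covariate multiplicative
#'   risk modifiers (named numeric per category); `NULL` for a homogeneous
#'   rate. A gradient on `fp_use` affects respondents only (confidante
#'   contraceptive use is not collected).
#' @param confidante_count_probs Probability vector over reporting 0, 1, 2
#'   confidantes; or a list `list(covariate =, probs =)` with one probability
#'   vector per category of a respondent covariate (the barrier-effect knob).
#' @param homophily Probability, per covariate, that a confidante copies the
#'   respondent's category; otherwise her category is drawn from the margins.
#' @param disclosure_prob Probability a woman with an abortion discloses it
#'   to her confidante circle (see Details).
#' @param less_certain_prob Probability a known (disclosed) confidante
#'   abortion is reported as "less certain" rather than "certain".
#' @param method_info_prob Probability the respondent can report the abortion
#'   method for a reported confidante abortion; set to `NA` to emulate a
#'   survey that did not collect method information.
#' @param telescope_prob Probability a reference-year event is misdated into
#'   the fieldwork (partial) year when reported.
#' @param reference_year,partial_year,months_observed_partial Calendar window
#'   of the emulated survey (full reporting year, fieldwork year, and months
#'   of the fieldwork year observed).
#' @param seed Integer seed; output is byte-identical given the same
#'   parameters and seed.
#' @return A validated `simulation_params` object.
#' @export
simulation_params <- function(n_respondents = 5000,
                              covariate_margins = default_margins(),
                              true_rate_per_1000 = 40,
                              rate_gradients = NULL,
                              confidante_count_probs = c("0" = 0.35, "1" = 0.35, "2" = 0.30),
                              homophily = 0.7,
                              disclosure_prob = 0.5,
                              less_certain_prob = 0.05,
                              method_info_prob = 0.5,
                              telescope_prob = 0,
                              reference_year = 2017L,
                              partial_year = 2018L,
                              months_observed_partial = 4L,
                              seed = 1L) {
  perr <- function(...) stop("parameter error: ", ..., call. = FALSE)
  chk_prob <- function(x, nm) {
    if (length(x) != 1 || is.na(x) || x < 0 || x > 1) perr(nm, " must be in [0, 1]")
  }
  chk_vec <- function(p, nm) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1)) perr(nm, " has entries outside [0, 1]")
    if (abs(sum(p) - 1) > 1e-9) perr(nm, " must sum to 1 (within 1e-9)")
  }
  if (n_respondents < 1) perr("n_respondents must be positive")
  if (true_rate_per_1000 <= 0) perr("true_rate_per_1000 must be positive")
  lv <- canonical_levels()
  for (cov in canonical_covariates()) {
    m <- covariate_margins[[cov]]
    if (is.null(m)) perr("covariate_margins missing ", cov)
    if (!setequal(names(m), lv[[cov]])) perr("covariate_margins$", cov,
                                             " names must be ",
                                             paste(lv[[cov]], collapse = ", "))
    chk_vec(m, paste0("covariate_margins$", cov))
  }
  if (is.list(confidante_count_probs)) {
    cov <- confidante_count_probs$covariate
    if (!(cov %in% canonical_covariates())) perr("confidante_count_probs$covariate unknown")
    for (cat in lv[[cov]]) {
      p <- confidante_count_probs$probs[[cat]]
      if (is.null(p) || length(p) != 3) perr("confidante_count_probs$probs$", cat,
                                             " must have 3 entries (0, 1, 2)")
      chk_vec(p, paste0("confidante_count_probs$probs$", cat))
    }
  } else {
    if (length(confidante_count_probs) != 3) perr("confidante_count_probs must have 3 entries")
    chk_vec(confidante_count_probs, "confidante_count_probs")
  }
  chk_prob(homophily, "homophily")
  chk_prob(disclosure_prob, "disclosure_prob")
  chk_prob(less_certain_prob, "less_certain_prob")
  if (!is.na(method_info_prob)) chk_prob(method_info_prob, "method_info_prob")
  chk_prob(telescope_prob, "telescope_prob")
  if (!is.null(rate_gradients)) {
    bad <- setdiff(names(rate_gradients), canonical_covariates())
    if (length(bad)) perr("rate_gradients for unknown covariate(s): ",
                          paste(bad, collapse = ", "))
    if (any(unlist(rate_gradients) < 0)) perr("rate_gradients must be non-negative")
  }
  months_observed_partial <- as.integer(months_observed_partial)
  if (months_observed_partial < 1L || months_observed_partial > 12L) {
    perr("months_observed_partial must be in 1..12")
  }
  structure(list(
    n_respondents = as.integer(n_respondents),
    covariate_margins = covariate_margins,
    true_rate_per_1000 = true_rate_per_1000,
    rate_gradients = rate_gradients,
    confidante_count_probs = confidante_count_probs,
    homophily = homophily,
    disclosure_prob = disclosure_prob,
    less_certain_prob = less_certain_prob,
    method_info_prob = method_info_prob,
    telescope_prob = telescope_prob,
    reference_year = as.integer(reference_year),
    partial_year = as.integer(partial_year),
    months_observed_partial = months_observed_partial,
    seed = as.integer(seed)
  ), class = "simulation_params")
}

# Margins loosely matching the age/education/residence profiles of women
# 15-49 in the surveyed contexts; see the methods vignette.
#' @export
#' @rdname simulation_params
default_margins <- function() {
  list(
    age_group = c("15-19" = 0.20, "20-29" = 0.34, "30-39" = 0.27, "40-49" = 0.19),
    education = c(never = 0.25, primary = 0.30, secondary = 0.33, higher = 0.12),
    residence = c(urban = 0.45, rural = 0.55),
    marital_status = c("married/cohabiting" = 0.64, "not married/cohabiting" = 0.36),
    fp_use = c(no = 0.65, yes = 0.35),
    parity = c("0" = 0.25, "1-2" = 0.33, "3-5" = 0.29, "6+" = 0.13)
  )
}

#' Read or write simulator parameters as YAML
#'
#' @param path File path.
#' @return `read_simulation_params()` returns a validated
#'   [simulation_params()] object; `write_simulation_params()` returns
#'   `path` invisibly.
#' @export
read_simulation_params <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$covariate_margins)) {
    raw$covariate_margins <- lapply(raw$covariate_margins, unlist)
  }
  if (!is.null(raw$rate_gradients)) {
    raw$rate_gradients <- lapply(raw$rate_gradients, unlist)
  }
  if (!is.null(raw$confidante_count_probs)) {
    ccp <- raw$confidante_count_probs
    raw$confidante_count_probs <- if (is.list(ccp) && !is.null(ccp$covariate)) {
      list(covariate = ccp$covariate, probs = lapply(ccp$probs, unlist))
    } else unlist(ccp)
  }
  do.call(simulation_params, raw)
}

#' @rdname read_simulation_params
#' @param params A [simulation_params()] object.
#' @export
write_simulation_params <- function(params, path) {
  stopifnot(inherits(params, "simulation_params"))
  out <- unclass(params)
  out$covariate_margins <- lapply(out$covariate_margins, as.list)
  if (!is.null(out$rate_gradients)) {
    out$rate_gradients <- lapply(out$rate_gradients, as.list)
  }
  ccp <- out$confidante_count_probs
  out$confidante_count_probs <- if (is.list(ccp)) {
    list(covariate = ccp$covariate, probs = lapply(ccp$probs, as.list))
  } else as.list(ccp)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Simulate a confidante survey with known truth
#'
#' Draws a synthetic survey under a [simulation_params()] model and returns
#' both the observable records (exactly the canonical format [read_survey()]
#' produces) and the latent truth needed for parameter-recovery tests.
#'
#' @param params A [simulation_params()] object.
#' @return A list with components `records` (a `confidante_survey` data
#'   frame, with the matching [survey_schema()] attached as its `schema`
#'   attribute), `truth` (a `simulation_truth` list: the true rate and
#'   disclosure probability plus per-record latent tables of true events,
#'   discloser traits and visibility), and `schema`.
#' @export
simulate_survey <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  with_local_seed(params$seed, {
    n <- params$n_respondents
    lv <- canonical_levels()
    m <- params$months_observed_partial
    years <- seq(params$reference_year - 1L, params$partial_year)
    rate <- params$true_rate_per_1000 / 1000

    draw_cat <- function(field) {
      p <- params$covariate_margins[[field]]
      factor(sample(names(p), n, replace = TRUE, prob = p), levels = lv[[field]])
    }
    resp <- data.frame(respondent_id = sprintf("r%06d", seq_len(n)),
                       sample_weight = rep(1.0, n), stringsAsFactors = FALSE)
    for (f in canonical_covariates()) resp[[f]] <- draw_cat(f)
    band_lo <- c(15, 20, 30, 40)[as.integer(resp$age_group)]
    band_hi <- c(19, 29, 39, 49)[as.integer(resp$age_group)]
    resp$age_years <- band_lo + floor(stats::runif(n) * (band_hi - band_lo + 1))
    resp <- resp[c("respondent_id", "sample_weight", "age_years",
                   canonical_covariates())]

    grad_mult <- function(covdf) {
      g <- params$rate_gradients
      if (is.null(g)) return(rep(1, nrow(covdf)))
      out <- rep(1, nrow(covdf))
      for (cov in names(g)) {
        if (!cov %in% names(covdf)) next
        out <- out * unname(g[[cov]][as.character(covdf[[cov]])])
      }
      out
    }

    # Per-year event draws over the simulated window; the partial year's
    # probability is scaled by the observed fraction of the year and its
    # months drawn within the observed window.
    sim_events <- function(rate_i) {
      nn <- length(rate_i)
      evy <- matrix(FALSE, nn, length(years),
                    dimnames = list(NULL, as.character(years)))
      evm <- matrix(NA_integer_, nn, length(years))
      for (j in seq_along(years)) {
        p <- if (years[j] == params$partial_year) rate_i * m / 12 else rate_i
        hit <- stats::runif(nn) < p
        evy[, j] <- hit
        mx <- if (years[j] == params$partial_year) m else 12L
        evm[hit, j] <- sample.int(mx, sum(hit), replace = TRUE)
      }
      # most recent event year: highest column index with an event
      last_true <- max.col(evy[, rev(seq_along(years)), drop = FALSE] + 0,
                           ties.method = "first")
      recent_j <- length(years) + 1L - last_true
      recent_j[!rowSums(evy)] <- NA_integer_
      list(any = !is.na(recent_j),
           year = ifelse(is.na(recent_j), NA_integer_, years[recent_j]),
           month = evm[cbind(seq_len(nn), recent_j)],
           by_year = evy)
    }

    telescope <- function(year, month) {
      move <- !is.na(year) & year == params$reference_year &
        stats::runif(length(year)) < params$telescope_prob
      year[move] <- params$partial_year
      month[move] <- sample.int(m, sum(move), replace = TRUE)
      list(year = year, month = month)
    }

    self_ev <- sim_events(rate * grad_mult(resp))
    self_discloser <- stats::runif(n) < params$disclosure_prob
    self_rep <- telescope(self_ev$year, self_ev$month)

    resp$self_abortion_ever <- factor(ifelse(self_ev$any, "yes", "no"),
                                      levels = lv$self_abortion_ever)
    resp$self_abortion_year <- ifelse(self_ev$any, self_rep$year, NA_real_)
    resp$self_abortion_month <- ifelse(self_ev$any, self_rep$month, NA_real_)

    ccp <- params$confidante_count_probs
    if (is.list(ccp)) {
      cats <- as.character(resp[[ccp$covariate]])
      n_conf <- vapply(cats, function(cat) {
        sample(0:2, 1L, prob = ccp$probs[[cat]])
      }, numeric(1))
    } else {
      n_conf <- sample(0:2, n, replace = TRUE, prob = ccp)
    }
    resp$n_confidantes_reported <- as.integer(n_conf)

    conf_truth <- list()
    conf_covs <- c("age_group", "education", "residence", "marital_status", "parity")
    for (k in 1:2) {
      exists_k <- n_conf >= k
      ne <- sum(exists_k)
      p <- paste0("conf", k, "_")
      cc <- data.frame(row.names = NULL)[seq_len(ne), , drop = FALSE]
      for (f in conf_covs) {
        copied <- stats::runif(ne) < params$homophily
        drawn <- sample(names(params$covariate_margins[[f]]), ne, replace = TRUE,
                        prob = params$covariate_margins[[f]])
        val <- ifelse(copied, as.character(resp[[f]][exists_k]), drawn)
        cc[[f]] <- factor(val, levels = lv[[f]])
      }
      ev <- sim_events(rate * grad_mult(cc))
      discloser <- stats::runif(ne) < params$disclosure_prob
      visible <- ev$any & discloser
      less_cert <- visible & (stats::runif(ne) < params$less_certain_prob)
      rep_date <- telescope(ev$year, ev$month)

      for (f in conf_covs) {
        col <- rep(factor(NA, levels = lv[[f]]), n)
        col[exists_k] <- cc[[f]]
        resp[[paste0(p, f)]] <- col
      }
      # exact confidante ages are not elicited by the emulated instruments
      resp[[paste0(p, "age_years")]] <- rep(NA_real_, n)
      ae <- rep(factor(NA, levels = lv$abortion_ever), n)
      ae[exists_k] <- factor(ifelse(visible, "yes", "no"), levels = lv$abortion_ever)
      resp[[paste0(p, "abortion_ever")]] <- ae
      ct <- rep(factor(NA, levels = lv$certainty), n)
      ct[exists_k][visible] <- factor(ifelse(less_cert[visible], "less_certain",
                                             "certain"), levels = lv$certainty)
      resp[[paste0(p, "certainty")]] <- ct
      yy <- rep(NA_real_, n); mm <- rep(NA_real_, n)
      yy[exists_k][visible] <- rep_date$year[visible]
      mm[exists_k][visible] <- rep_date$month[visible]
      resp[[paste0(p, "abortion_year")]] <- yy
      resp[[paste0(p, "abortion_month")]] <- mm
      mi <- rep(NA, n)
      if (!is.na(params$method_info_prob)) {
        mi[exists_k][visible] <- stats::runif(sum(visible)) < params$method_info_prob
      }
      resp[[paste0(p, "method_info")]] <- mi
      dc <- rep(NA, n)
      dc[exists_k & self_ev$any] <- self_discloser[exists_k & self_ev$any]
      resp[[paste0(p, "disclosed")]] <- dc

      conf_truth[[k]] <- data.frame(
        respondent_id = resp$respondent_id[exists_k], position = k,
        true_any_event = ev$any, true_recent_year = ev$year,
        true_recent_month = ev$month, discloser = discloser,
        visible = visible, stringsAsFactors = FALSE)
    }

    schema <- survey_schema(reference_year = params$reference_year,
                            partial_year = params$partial_year,
                            months_observed_partial = m)
    records <- structure(resp[canonical_fields()],
                         schema = schema,
                         class = c("confidante_survey", "data.frame"))
    truth <- structure(list(
      true_rate_per_1000 = params$true_rate_per_1000,
      true_disclosure_prob = params$disclosure_prob,
      respondents = data.frame(
        respondent_id = resp$respondent_id,
        discloser = self_discloser,
        true_any_event = self_ev$any,
        true_recent_year = self_ev$year,
        true_recent_month = self_ev$month,
        stringsAsFactors = FALSE),
      confidantes = do.call(rbind, conf_truth),
      self_events_by_year = self_ev$by_year
    ), class = "simulation_truth")
    list(records = records, truth = truth, schema = schema)
  })
}
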