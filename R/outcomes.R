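#' Derive the progressive CKD endpoint from longitudinal eGFR
#'
#' Progressive chronic kidney disease is a confirmed decline in eGFR of 40%
#' or more from baseline: the event occurs at the first measurement at or
#' below `0.6 * baseline` for which some later measurement, at least
#' `min_confirm_gap` years afterwards, is also at or below the threshold.
#' An unconfirmed drop does not count; without a confirmed drop the
#' participant is censored at the last available measurement. The event is
#' timed at the first qualifying measurement, not at its confirmation.
#'
#' @param labs Long tibble `participant_id`, `time_years`, `egfr` (times
#'   strictly increasing within participant).
#' @param baseline Data frame `participant_id`, `egfr` (baseline values,
#'   e.g. the cohort table), or a named vector.
#' @param min_confirm_gap Minimum confirmation gap in years (default 0.25,
#'   i.e. 3 months).
#' @param decline Fractional decline defining the endpoint (default 0.4).
#' @return Tibble `participant_id`, `time`, `event` (1 event, 0 censored).
#' @export
derive_progressive_ckd <- function(labs, baseline, min_confirm_gap = 0.25,
                                   decline = 0.4) {
  if (is.data.frame(baseline)) {
    baseline <- setNames(baseline$egfr, baseline$participant_id)
  }
  if (any(baseline <= 0, na.rm = TRUE)) abort("Baseline eGFR must be positive.")
  labs |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(df, key) {
      t <- df$time_years
      if (is.unsorted(t, strictly = TRUE)) {
        abort(paste0("Unsorted measurement times for participant ",
                     key$participant_id, "."))
      }
      b <- baseline[[key$participant_id]]
      if (is.null(b) || is.na(b)) abort(paste0("No baseline eGFR for ",
                                               key$participant_id, "."))
      low <- df$egfr <= (1 - decline) * b
      for (i in which(low)) {
        if (any(low & t >= t[i] + min_confirm_gap)) {
          return(tibble::tibble(time = t[i], event = 1L))
        }
      }
      tibble::tibble(time = t[length(t)], event = 0L)
    }) |>
    dplyr::ungroup()
}

#' Incidence rate per 1000 person-years with exact Poisson interval
#'
#' `rate = 1000 * events / person_years`, with the exact (Garwood)
#' chi-square interval: lower `qchisq(alpha/2, 2k) / 2`, upper
#' `qchisq(1 - alpha/2, 2k + 2) / 2`, each divided by the person-years and
#' scaled to 1000. With zero events the lower bound is 0 by convention.
#'
#' @param events Non-negative event count.
#' @param person_years Positive person-years of follow-up.
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble `events`, `person_years`, `rate`, `conf_low`, `conf_high`
#'   (all rates per 1000 person-years).
#' @export
incidence_rate <- function(events, person_years, conf_level = 0.95) {
  if (person_years <= 0) abort("`person_years` must be positive.")
  if (events < 0 || events != round(events)) abort("`events` must be a count.")
  alpha <- 1 - conf_level
  lower <- if (events == 0) 0 else qchisq(alpha / 2, 2 * events) / 2
  upper <- qchisq(1 - alpha / 2, 2 * events + 2) / 2
  tibble::tibble(events = as.integer(events), person_years = person_years,
                 rate = 1000 * events / person_years,
                 conf_low = 1000 * lower / person_years,
                 conf_high = 1000 * upper / person_years)
}

#' Kaplan-Meier survival estimate as a tidy step function
#'
#' Product-limit estimator (via `survival::survfit`), returned as a tibble
#' of event-time steps, optionally stratified by group.
#'
#' @param times Follow-up times (>= 0).
#' @param events Event indicators (1 event, 0 censored).
#' @param groups Optional group labels for stratified curves.
#' @return Tibble `time`, `n_risk`, `n_event`, `survival` (and `group`).
#' @export
km_estimate <- function(times, events, groups = NULL) {
  if (any(times < 0)) abort("Times must be non-negative.")
  if (!length(times)) abort("Empty input.")
  if (is.null(groups)) {
    fit <- survival::survfit(survival::Surv(times, events) ~ 1)
    tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                   n_event = fit$n.event, survival = fit$surv)
  } else {
    g <- factor(groups)
    fit <- survival::survfit(survival::Surv(times, events) ~ g)
    tibble::tibble(
      group = rep(sub("^g=", "", names(fit$strata)), fit$strata),
      time = fit$time, n_risk = fit$n.risk,
      n_event = fit$n.event, survival = fit$surv)
  }
}

#' Logrank test across groups
#'
#' Standard observed-minus-expected logrank statistic with hypergeometric
#' variance (via `survival::survdiff`), chi-square with `groups - 1`
#' degrees of freedom.
#'
#' @inheritParams km_estimate
#' @param groups Group labels (>= 2 non-empty groups).
#' @return Tibble `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(times, events, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) abort("Need at least 2 groups.")
  if (any(table(g) == 0)) abort("A group has zero subjects.")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- nlevels(g) - 1
  tibble::tibble(statistic = sd$chisq, df = df,
                 p_value = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional hazards fit with Efron ties and PH diagnostics
#'
#' Fits a Cox proportional hazards model (Efron tie handling) of the event
#' table on subgroup membership plus covariates, and attaches per-covariate
#' and global proportional-hazards tests based on scaled Schoenfeld
#' residuals. Subgroup enters as indicators against the reference (MOD by
#' default); categorical covariates such as ethnicity are coded with their
#' largest level as reference.
#'
#' @param data Data frame with `time`, `event`, a subgroup column, and the
#'   covariates.
#' @param covariates Character vector of covariate columns (possibly empty).
#' @param subgroup Name of the subgroup column (set `NULL` to omit).
#' @param reference Reference subgroup level.
#' @return An object of class `cox_fit`; `tidy()` gives the hazard-ratio
#'   table, `glance()` the model summary.
#' @export
cox_fit <- function(data, covariates = character(), subgroup = "subgroup",
                    reference = "MOD") {
  df <- tibble::as_tibble(data)
  if (sum(df$event) < 1) abort("Need at least one event.")
  terms <- covariates
  if (!is.null(subgroup)) {
    if (!reference %in% df[[subgroup]]) {
      abort(paste0("Reference level '", reference, "' absent from '",
                   subgroup, "'."))
    }
    df$.subgroup <- stats::relevel(factor(df[[subgroup]]), ref = reference)
    terms <- c(".subgroup", terms)
  }
  for (v in covariates) {
    if (is.character(df[[v]]) || is.factor(df[[v]])) {
      f <- factor(df[[v]])
      df[[v]] <- stats::relevel(f, ref = names(which.max(table(f))))
    }
  }
  fm <- stats::reformulate(terms, response = "survival::Surv(time, event)")
  fit <- survival::coxph(fm, data = df, ties = "efron")
  if (any(is.na(coef(fit)))) abort("Rank-deficient design in Cox model.")
  zph <- tryCatch(survival::cox.zph(fit), error = function(e) NULL)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  tab <- tibble::tibble(
    term = gsub("^\\.subgroup", "subgroup", names(est)),
    log_hr = unname(est), hr = exp(unname(est)), std_error = unname(se),
    conf_low = exp(unname(est - 1.96 * se)),
    conf_high = exp(unname(est + 1.96 * se)),
    p_value = 2 * pnorm(-abs(est / se))
  )
  structure(list(table = tab, fit = fit, zph = zph,
                 loglik = fit$loglik[2], n = fit$n, n_event = fit$nevent,
                 reference = reference),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> n =", x$n, ", events =", x$n_event,
      ", partial log-likelihood =", signif(x$loglik, 6), "\n")
  print(x$table)
  invisible(x)
}

#' Proportional-hazards test on scaled Schoenfeld residuals
#'
#' Grambsch-Therneau test of correlation between scaled Schoenfeld
#' residuals and event time (via `survival::cox.zph`), per covariate and
#' globally.
#'
#' @param fit A `cox_fit` object.
#' @param transform Time transform passed to `cox.zph` (default `"km"`).
#' @return Tibble `term`, `chisq`, `df`, `p_value` (last row = GLOBAL).
#' @export
schoenfeld_ph_test <- function(fit, transform = "km") {
  stopifnot(inherits(fit, "cox_fit"))
  if (fit$n_event < 3) abort("Need at least 3 events for the PH test.")
  zph <- survival::cox.zph(fit$fit, transform = transform)
  tab <- zph$table
  tibble::tibble(term = gsub("^\\.subgroup", "subgroup", rownames(tab)),
                 chisq = tab[, "chisq"], df = tab[, "df"],
                 p_value = tab[, "p"])
}
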