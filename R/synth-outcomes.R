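#' Specify the hazard structure of a simulated time-to-event outcome
#'
#' Event times follow a (default exponential, optionally Weibull) hazard
#' `h(t | x) = baseline_rate * shape * t^(shape - 1) * exp(lp)` with linear
#' predictor built from the subgroup hazard ratios and the age/sex log
#' hazard ratios. Follow-up is cut at an administrative censoring time —
#' fixed, or drawn uniformly per participant from a range to emulate
#' staggered recruitment (the default range `c(5.9, 8.7)` years gives a
#' median follow-up near 7.3 years) — and, optionally, at an independent
#' exponential random-censoring time.
#'
#' @param outcome Outcome name (e.g. `"heart_failure"`, `"progressive_CKD"`,
#'   `"MACE"`, `"all_cause_mortality"`).
#' @param baseline_rate Baseline events per person-year for the reference
#'   subgroup at centred covariates; must be positive.
#' @param hr_subgroup Named vector of hazard ratios versus the reference
#'   subgroup (unnamed subgroups get 1).
#' @param reference Reference subgroup label.
#' @param log_hr_age,log_hr_sex_female Covariate log hazard ratios (age is
#'   centred at the cohort mean; sex indicator is 1 for female).
#' @param admin_censor_years Scalar (fixed) or length-2 range (uniform).
#' @param random_censor_rate Rate of independent exponential censoring
#'   (0 disables it).
#' @param shape Weibull shape; 1 (default) gives constant baseline hazard.
#' @return An object of class `hazard_spec`.
#' @export
hazard_spec <- function(outcome, baseline_rate, hr_subgroup = c(),
                        reference = "MOD", log_hr_age = 0,
                        log_hr_sex_female = 0,
                        admin_censor_years = c(5.9, 8.7),
                        random_censor_rate = 0, shape = 1) {
  if (baseline_rate <= 0) abort("`baseline_rate` must be positive.")
  if (any(admin_censor_years < 0) || !length(admin_censor_years) %in% 1:2) {
    abort("`admin_censor_years` must be a non-negative scalar or range.")
  }
  if (shape <= 0) abort("`shape` must be positive.")
  structure(list(outcome = outcome, baseline_rate = baseline_rate,
                 hr_subgroup = hr_subgroup, reference = reference,
                 log_hr_age = log_hr_age,
                 log_hr_sex_female = log_hr_sex_female,
                 admin_censor_years = admin_censor_years,
                 random_censor_rate = random_censor_rate, shape = shape),
            class = "hazard_spec")
}

#' Simulate a time-to-event table for a cohort
#'
#' @param cohort Cohort tibble with `participant_id`, `subgroup_true`,
#'   `index_age`, `sex` (and any further covariates carried through).
#' @param spec A [hazard_spec()].
#' @param seed Integer seed.
#' @return Tibble `participant_id`, `outcome`, `time` (years), `event`
#'   (1 event / 0 censored) plus the cohort covariate columns.
#' @export
simulate_outcomes <- function(cohort, spec, seed = NULL) {
  stopifnot(inherits(spec, "hazard_spec"))
  n <- nrow(cohort)
  hr <- rep(1, n)
  if (length(spec$hr_subgroup)) {
    m <- match(cohort$subgroup_true, names(spec$hr_subgroup))
    hr <- ifelse(is.na(m), 1, spec$hr_subgroup[ifelse(is.na(m), 1L, m)])
  }
  lp <- log(hr) +
    spec$log_hr_age * (cohort$index_age - mean(cohort$index_age)) +
    spec$log_hr_sex_female * as.numeric(cohort$sex == "F")
  with_sim_seed(seed, {
    u <- runif(n)
    t_event <- (-log(u) / (spec$baseline_rate * exp(lp)))^(1 / spec$shape)
    t_admin <- if (length(spec$admin_censor_years) == 2L) {
      runif(n, spec$admin_censor_years[1], spec$admin_censor_years[2])
    } else rep(spec$admin_censor_years, n)
    t_cens <- if (spec$random_censor_rate > 0) {
      pmin(t_admin, rexp(n, spec$random_censor_rate))
    } else t_admin
    tibble::tibble(
      participant_id = cohort$participant_id,
      outcome = spec$outcome,
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens)
    ) |>
      dplyr::left_join(dplyr::select(cohort, -dplyr::any_of(c("outcome", "time", "event"))),
                       by = "participant_id")
  })
}

#' Simulate longitudinal eGFR series with planted progressors
#'
#' Each participant follows `egfr(t) = baseline * (1 - annual_decline)^t`
#' measured with multiplicative lognormal noise at scheduled visits and
#' floored at 5 ml/min/1.73m^2. A planted fraction of "progressors" draws a
#' steep decline so that the trajectory crosses the 40%-decline threshold
#' within follow-up (with later visits confirming it); the rest draw a
#' shallow decline that stays above the threshold in expectation.
#'
#' @param cohort Cohort tibble with `participant_id` and baseline `egfr`.
#' @param visit_times Numeric vector of visit times in years (>= 2 visits).
#' @param progressor Either a fraction in `[0, 1]` or a logical vector per
#'   participant.
#' @param progressor_decline,stable_decline Ranges of the annual fractional
#'   decline for the two groups.
#' @param noise_sd Log-scale SD of measurement noise.
#' @param seed Integer seed.
#' @return Long tibble `participant_id`, `time_years`, `egfr`, sorted by
#'   participant and time, with the planted plan attached as
#'   `attr(, "plan")` (`participant_id`, `progressor`, `annual_decline`).
#' @export
simulate_egfr_series <- function(cohort, visit_times = seq(0.5, 8, by = 0.5),
                                 progressor = 0.1,
                                 progressor_decline = c(0.10, 0.18),
                                 stable_decline = c(0, 0.02),
                                 noise_sd = 0.04, seed = NULL) {
  if (length(visit_times) < 2L) abort("`visit_times` needs at least 2 visits.")
  if (is.unsorted(visit_times, strictly = TRUE)) {
    abort("`visit_times` must be strictly increasing.")
  }
  n <- nrow(cohort)
  with_sim_seed(seed, {
    flag <- if (is.logical(progressor)) progressor else runif(n) < progressor
    decline <- ifelse(flag,
                      runif(n, progressor_decline[1], progressor_decline[2]),
                      runif(n, stable_decline[1], stable_decline[2]))
    labs <- tidyr::expand_grid(participant_id = cohort$participant_id,
                               time_years = visit_times) |>
      dplyr::left_join(tibble::tibble(participant_id = cohort$participant_id,
                                      baseline = cohort$egfr,
                                      decline = decline),
                       by = "participant_id") |>
      dplyr::mutate(
        egfr = pmax(.data$baseline * (1 - .data$decline)^.data$time_years *
                      exp(rnorm(dplyr::n(), 0, noise_sd)), 5),
        baseline = NULL, decline = NULL)
    attr(labs, "plan") <- tibble::tibble(participant_id = cohort$participant_id,
                                         progressor = flag,
                                         annual_decline = decline)
    labs
  })
}
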