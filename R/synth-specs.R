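#' Calibrate a lognormal distribution from a median and IQR
#'
#' Clinical tables typically summarise skewed variables as `median (Q1-Q3)`.
#' For a lognormal variable the median fixes the log-scale location and the
#' IQR fixes the log-scale spread, so both parameters can be recovered in
#' closed form: `mu = log(median)` and
#' `sigma = (log(q3) - log(q1)) / (2 * qnorm(0.75))`.
#'
#' The fitted distribution reproduces the median and the log-scale IQR width
#' (the ratio `q3 / q1`) exactly. When the reported quartiles are not
#' symmetric around the median on the log scale — which a lognormal cannot
#' represent — the individual quartiles are matched only approximately.
#'
#' @param median,q1,q3 Positive quantiles with `q1 < median < q3`.
#' @return A named numeric vector with elements `mu` and `sigma`
#'   (parameters of the log-scale normal distribution).
#' @examples
#' lognormal_from_median_iqr(96.9, 77.5, 131.7)
#' @export
lognormal_from_median_iqr <- function(median, q1, q3) {
  if (!all(is.finite(c(median, q1, q3))) || any(c(median, q1, q3) <= 0)) {
    abort("`median`, `q1` and `q3` must all be positive and finite.")
  }
  if (!(q1 < median && median < q3)) {
    abort("Quantiles must be strictly increasing: q1 < median < q3.")
  }
  c(mu = log(median), sigma = (log(q3) - log(q1)) / (2 * qnorm(0.75)))
}

#' Define a subgroup of a synthetic cohort
#'
#' A subgroup specification holds a mixture weight (or fixed count), a male
#' fraction, ethnicity fractions, and one marginal distribution per clinical
#' variable: `gaussian(mean, sd)` for variables a clinical table reports as
#' mean +/- SD, `lognormal(median, q1, q3)` for variables reported as
#' median (IQR). Variables are drawn independently within subgroup.
#'
#' @param name Subgroup label.
#' @param n Fixed participant count (used when simulating with fixed sizes).
#' @param weight Mixture proportion in `[0, 1]` (used for multinomial sizes).
#' @param male_fraction Fraction of male participants in `[0, 1]`.
#' @param ethnicity Named numeric vector of ethnicity fractions (summing
#'   to 1) or `NULL`.
#' @param gaussian Named list of `c(mean, sd)` pairs.
#' @param lognormal Named list of `c(median, q1, q3)` triples, converted with
#'   [lognormal_from_median_iqr()].
#' @return An object of class `subgroup_spec`.
#' @export
subgroup_spec <- function(name, n, weight, male_fraction,
                          ethnicity = NULL,
                          gaussian = list(), lognormal = list()) {
  stopifnot(is.character(name), length(name) == 1L,
            n >= 0, weight >= 0, weight <= 1,
            male_fraction >= 0, male_fraction <= 1)
  for (v in names(gaussian)) {
    p <- gaussian[[v]]
    if (length(p) != 2L || !is.finite(p[2]) || p[2] < 0) {
      abort(paste0("Gaussian spec for '", v, "' must be c(mean, sd) with sd >= 0."))
    }
  }
  vars <- dplyr::bind_rows(unname(c(
    purrr::imap(gaussian, function(p, v) {
      tibble::tibble(variable = v, family = "gaussian",
                     mean = p[[1]], sd = p[[2]],
                     median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                     mu = NA_real_, sigma = NA_real_)
    }),
    purrr::imap(lognormal, function(p, v) {
      par <- lognormal_from_median_iqr(p[[1]], p[[2]], p[[3]])
      tibble::tibble(variable = v, family = "lognormal",
                     mean = NA_real_, sd = NA_real_,
                     median = p[[1]], q1 = p[[2]], q3 = p[[3]],
                     mu = par[["mu"]], sigma = par[["sigma"]])
    })
  )))
  if (!is.null(ethnicity)) {
    if (is.null(names(ethnicity)) || abs(sum(ethnicity) - 1) > 1e-6) {
      abort("`ethnicity` must be a named vector of fractions summing to 1.")
    }
  }
  structure(
    list(name = name, n = as.integer(n), weight = weight,
         male_fraction = male_fraction, ethnicity = ethnicity,
         variables = vars),
    class = "subgroup_spec"
  )
}

#' @export
print.subgroup_spec <- function(x, ...) {
  cat("<subgroup_spec> ", x$name, ": n = ", x$n,
      ", weight = ", signif(x$weight, 3),
      ", male fraction = ", signif(x$male_fraction, 3), "\n", sep = "")
  print(x$variables, n = Inf)
  invisible(x)
}

#' Default subgroup specifications for the recent-onset cohort
#'
#' Returns the three-subgroup mixture used throughout the package as the
#' reference synthetic cohort: mild obesity-related diabetes (MOD, n = 307),
#' severe insulin-resistant diabetes with relative insulin insufficiency
#' (SIRD-RII, n = 130) and mild age-related diabetes with insulin
#' insufficiency (MARD-II, n = 250). Per-subgroup marginals are parameterised
#' from published baseline characteristics: symmetric variables as
#' mean +/- SD Gaussians, skewed variables (HOMA2-B, HOMA2-IR, fasting
#' C-peptide, triacylglycerol, TG/HDL ratio, urine ACR, C-reactive protein)
#' as lognormals calibrated from median (IQR).
#'
#' @return A list of three [subgroup_spec()] objects named
#'   `MOD`, `SIRD-RII`, `MARD-II`.
#' @export
table1_specs <- function() {
  list(
    "MOD" = subgroup_spec(
      "MOD", n = 307, weight = 307 / 687, male_fraction = 144 / 307,
      ethnicity = c(Chinese = 123, Malay = 104, Indian = 80) / 307,
      gaussian = list(
        index_age = c(55, 9.6), onset_age = c(52, 9.4), bmi = c(30.1, 5.0),
        hba1c = c(6.9, 0.7), fpg = c(6.5, 1.4),
        sbp = c(137, 16.8), dbp = c(80.2, 9.3), egfr = c(92, 19.2),
        hdl = c(1.3, 0.4), ldl = c(2.8, 0.8)),
      lognormal = list(
        c_peptide = c(931, 771, 1185), homa2b = c(96.9, 77.5, 131.7),
        homa2ir = c(2.2, 1.8, 2.9), tg_hdl = c(1.1, 0.8, 1.8),
        tg = c(1.4, 1.1, 1.9), acr = c(1.5, 0.5, 4.1), crp = c(2.7, 1.1, 5.8))),
    "SIRD-RII" = subgroup_spec(
      "SIRD-RII", n = 130, weight = 130 / 687, male_fraction = 74 / 130,
      ethnicity = c(Chinese = 62, Malay = 37, Indian = 31) / 130,
      gaussian = list(
        index_age = c(43, 11.5), onset_age = c(40, 10.9), bmi = c(31.6, 5.9),
        hba1c = c(9.2, 1.2), fpg = c(10.7, 2.6),
        sbp = c(136, 14.9), dbp = c(82.0, 9.2), egfr = c(109, 19.7),
        hdl = c(1.2, 0.3), ldl = c(3.3, 0.9)),
      lognormal = list(
        c_peptide = c(920, 709, 1305), homa2b = c(43.7, 32.4, 61.9),
        homa2ir = c(2.7, 1.9, 3.8), tg_hdl = c(1.6, 1.1, 2.3),
        tg = c(1.8, 1.3, 2.4), acr = c(2.7, 0.7, 8.4), crp = c(3.8, 2.0, 7.9))),
    "MARD-II" = subgroup_spec(
      "MARD-II", n = 250, weight = 250 / 687, male_fraction = 131 / 250,
      ethnicity = c(Chinese = 157, Malay = 49, Indian = 44) / 250,
      gaussian = list(
        index_age = c(59, 9.9), onset_age = c(56, 9.9), bmi = c(24.9, 3.4),
        hba1c = c(7.1, 0.9), fpg = c(7.4, 1.7),
        sbp = c(139.3, 18.0), dbp = c(78.3, 9.5), egfr = c(92, 21.0),
        hdl = c(1.4, 0.4), ldl = c(2.8, 0.8)),
      lognormal = list(
        c_peptide = c(523, 386, 644), homa2b = c(53.3, 40.0, 66.0),
        homa2ir = c(1.3, 0.9, 1.6), tg_hdl = c(0.9, 0.6, 1.4),
        tg = c(1.2, 0.9, 1.6), acr = c(1.1, 0.1, 4.6), crp = c(1.5, 0.5, 3.5)))
  )
}

#' The five clinical classifiers used for subtyping
#'
#' Diabetes onset age, BMI, HbA1c, HOMA2-B and HOMA2-IR; the two HOMA
#' indices are log-transformed before standardisation.
#' @return Character vector of classifier column names.
#' @export
classifier_vars <- function() c("onset_age", "bmi", "hba1c", "homa2b", "homa2ir")

#' @rdname classifier_vars
#' @export
log_classifiers <- function() c("homa2b", "homa2ir")
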