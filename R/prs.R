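#' Compute weighted polygenic risk scores
#'
#' `score_i = sum_v weight_v * dosage_iv`, with dosages oriented to the risk
#' allele. If the dosage file's counted allele is the panel's other allele
#' for some variants (given via `counted_allele`), those dosages are flipped
#' to `2 - dosage` before weighting. Missing dosages are mean-imputed per
#' variant by default (`missing = "mean"`); `missing = "strict"` errors on
#' any absent variant or missing value.
#'
#' @param dosages Tibble/data frame with `participant_id` and one numeric
#'   column per variant, values in `[0, 2]`.
#' @param panel Panel tibble (see [read_prs_panel()]).
#' @param counted_allele Optional named character vector giving, per variant
#'   id, the allele the dosage column counts; defaults to the risk allele.
#' @param missing `"mean"` (impute per-variant mean, logged) or `"strict"`.
#' @return Tibble `participant_id`, `score`.
#' @export
compute_prs <- function(dosages, panel, counted_allele = NULL,
                        missing = c("mean", "strict")) {
  missing <- match.arg(missing)
  panel <- validate_prs_panel(panel)
  absent <- setdiff(panel$variant_id, names(dosages))
  if (length(absent)) {
    if (missing == "strict") {
      abort(paste0("Panel variant(s) absent from dosage matrix: ",
                   paste(absent, collapse = ", ")))
    }
    inform(paste0(length(absent), " panel variant(s) absent; contributing ",
                  "their population mean (2 * freq * weight) to every score."))
  }
  present <- intersect(panel$variant_id, names(dosages))
  m <- as.matrix(tibble::as_tibble(dosages)[present])
  if (any(m < 0 | m > 2, na.rm = TRUE)) abort("Dosages must lie in [0, 2].")
  if (!is.null(counted_allele)) {
    pan <- panel[match(present, panel$variant_id), ]
    flip <- counted_allele[present] == pan$other_allele
    flip[is.na(flip)] <- FALSE
    m[, flip] <- 2 - m[, flip]
  }
  if (anyNA(m)) {
    if (missing == "strict") abort("Missing dosages under strict policy.")
    nmiss <- sum(is.na(m))
    mu <- colMeans(m, na.rm = TRUE)
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- mu[j]
    inform(paste0("Mean-imputed ", nmiss, " missing dosage value(s)."))
  }
  w <- panel$weight[match(present, panel$variant_id)]
  score <- as.vector(m %*% w)
  if (length(absent)) {
    pan_a <- panel[match(absent, panel$variant_id), ]
    score <- score + sum(pan_a$weight * 2 * pan_a$freq)
  }
  tibble::tibble(participant_id = dosages$participant_id, score = score)
}

#' Test association of a polygenic score with subgroup membership
#'
#' Ordinary least squares with the score as the dependent variable and
#' subgroup membership (indicator coding against a reference subgroup,
#' MOD by default), sex and the supplied principal-component columns as
#' covariates. Reports coefficients with Wald 95% CIs and two-sided
#' p-values.
#'
#' @param scores Tibble from [compute_prs()] (or any data frame with
#'   `participant_id`, `score`).
#' @param data Data frame with `participant_id`, a subgroup label column,
#'   `sex`, and the covariate columns.
#' @param subgroup Name of the subgroup label column.
#' @param reference Reference subgroup label.
#' @param covariates Character vector of additional covariate columns
#'   (default `sex` + `PC1:PC3` where present).
#' @param conf_level Confidence level for the Wald intervals.
#' @return An object of class `prs_fit`; use [tidy()] for the coefficient
#'   table.
#' @export
associate_prs <- function(scores, data, subgroup = "subgroup",
                          reference = "MOD",
                          covariates = intersect(c("sex", "PC1", "PC2", "PC3"),
                                                 names(data)),
                          conf_level = 0.95) {
  df <- dplyr::inner_join(tibble::as_tibble(scores), tibble::as_tibble(data),
                          by = "participant_id")
  if (!subgroup %in% names(df)) abort(paste0("Column '", subgroup, "' not found."))
  if (!reference %in% df[[subgroup]]) {
    abort(paste0("Reference subgroup '", reference, "' absent from data."))
  }
  df$.subgroup <- stats::relevel(factor(df[[subgroup]]), ref = reference)
  fm <- stats::reformulate(c(".subgroup", covariates), response = "score")
  fit <- lm(fm, data = df)
  if (any(is.na(coef(fit)))) {
    abort(paste0("Rank-deficient design; collinear term(s): ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tab <- tibble::tibble(
    term = gsub("^\\.subgroup", "subgroup", names(est)),
    estimate = unname(est), std_error = unname(se),
    conf_low = unname(est - z * se), conf_high = unname(est + z * se),
    p_value = 2 * pnorm(-abs(est / se))
  )
  structure(list(table = tab, fit = fit, reference = reference,
                 n = nrow(df), conf_level = conf_level),
            class = "prs_fit")
}

#' @export
print.prs_fit <- function(x, ...) {
  cat("<prs_fit> n =", x$n, ", reference subgroup:", x$reference, "\n")
  print(x$table)
  invisible(x)
}

#' Flag participants in the top percentiles of a score
#'
#' Flags the top `floor(top_fraction * n)` scores; ties at the threshold
#' value are kept (so with heavy ties more than the nominal fraction may be
#' flagged, and with all-equal scores everyone is, with a warning).
#'
#' @param scores Numeric vector.
#' @param top_fraction Fraction to flag (default 0.05, the top five
#'   percentiles).
#' @return Logical vector, `TRUE` for flagged participants.
#' @export
top_percentile_flag <- function(scores, top_fraction = 0.05) {
  if (!length(scores)) abort("`scores` is empty.")
  k <- max(1L, floor(top_fraction * length(scores)))
  thr <- sort(scores, decreasing = TRUE)[k]
  flag <- scores >= thr
  if (all(flag) && length(scores) > k) {
    warn("All scores tie at the threshold; every participant flagged.")
  }
  flag
}
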