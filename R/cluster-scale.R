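#' Standardise classifier columns to mean 0, SD 1
#'
#' Applies the declared log transforms (by default to HOMA2-B and HOMA2-IR),
#' then centres and scales each classifier. When `params` is `NULL` the
#' location/scale are fitted from the data; when given (e.g. the discovery
#' cohort's parameters) they are applied unchanged, which is how an external
#' cohort is projected onto a reference cohort's scale.
#'
#' @param data Data frame containing the classifier columns.
#' @param classifiers Character vector of classifier columns.
#' @param log_vars Subset of `classifiers` to log-transform first.
#' @param params Optional `scaling_params` tibble from a previous fit.
#' @param sd Denominator convention when fitting: `"sample"` (n - 1, the
#'   default) or `"population"` (n).
#' @return List with `x` (standardised numeric matrix, one column per
#'   classifier) and `params` (a `scaling_params` tibble:
#'   `variable`, `log_transform`, `center`, `scale`).
#' @export
standardize <- function(data, classifiers = classifier_vars(),
                        log_vars = log_classifiers(), params = NULL,
                        sd = c("sample", "population")) {
  sd <- match.arg(sd)
  missing <- setdiff(classifiers, names(data))
  if (length(missing)) {
    abort(paste0("Missing classifier column(s): ", paste(missing, collapse = ", ")))
  }
  x <- as.matrix(dplyr::select(tibble::as_tibble(data), dplyr::all_of(classifiers)))
  if (nrow(x) < 2L && is.null(params)) abort("Need at least 2 rows to fit scaling.")
  if (anyNA(x)) abort("Classifier columns contain missing values.")
  if (is.null(params)) {
    log_flags <- classifiers %in% log_vars
  } else {
    params <- params[match(classifiers, params$variable), ]
    if (anyNA(params$variable)) abort("`params` does not cover all classifiers.")
    log_flags <- params$log_transform
  }
  for (j in which(log_flags)) {
    if (any(x[, j] <= 0)) {
      abort(paste0("Non-positive values in log-transformed classifier '",
                   classifiers[j], "'."))
    }
    x[, j] <- log(x[, j])
  }
  if (is.null(params)) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    if (sd == "population") scale <- scale * sqrt((nrow(x) - 1) / nrow(x))
    zero <- which(scale == 0 | !is.finite(scale))
    if (length(zero)) {
      abort(paste0("Zero-variance classifier column(s): ",
                   paste(classifiers[zero], collapse = ", ")))
    }
    params <- tibble::tibble(variable = classifiers, log_transform = log_flags,
                             center = unname(center), scale = unname(scale))
  }
  z <- sweep(sweep(x, 2, params$center), 2, params$scale, "/")
  colnames(z) <- classifiers
  list(x = z, params = params)
}

#' Invert a standardisation back to the analysis scale
#'
#' @param x Standardised matrix from [standardize()].
#' @param params The matching `scaling_params` tibble.
#' @return Matrix on the original (pre-log, pre-scaling) scale.
#' @export
unstandardize <- function(x, params) {
  x <- as.matrix(x)
  out <- sweep(sweep(x, 2, params$scale, "*"), 2, params$center, "+")
  for (j in which(params$log_transform)) out[, j] <- exp(out[, j])
  colnames(out) <- params$variable
  out
}

#' Replace classifiers by their residuals on a covariate
#'
#' Regresses each classifier column on an intercept plus a single covariate
#' (ordinary least squares) and returns the residuals, e.g. to remove the
#' sex effect from the classifiers before clustering. Residuals are
#' orthogonal to the covariate by construction.
#'
#' @param data Data frame or numeric matrix of classifier columns.
#' @param covariate Numeric or two-level vector, one value per row;
#'   must not be constant.
#' @return Tibble of residualised columns (same names).
#' @export
residualize_on_covariate <- function(data, covariate) {
  x <- as.matrix(tibble::as_tibble(data))
  if (!is.numeric(covariate)) covariate <- as.numeric(factor(covariate))
  if (length(covariate) != nrow(x)) abort("`covariate` length must match rows.")
  if (stats::sd(covariate) == 0) abort("`covariate` is constant.")
  design <- cbind(1, covariate)
  resid <- x - design %*% solve(crossprod(design), crossprod(design, x))
  tibble::as_tibble(resid)
}
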