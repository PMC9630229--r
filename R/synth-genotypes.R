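#' Read a polygenic-score weight panel
#'
#' Panels are tab-separated files with columns `variant_id`, `risk_allele`,
#' `other_allele`, `weight` (per-allele effect on type 2 diabetes risk) and
#' `freq` (risk-allele frequency, used only for simulation). Three synthetic
#' example panels ship with the package: a 35-variant beta-cell dysfunction
#' panel, a 20-variant insulin-resistance panel and a 9-variant type 1
#' diabetes panel (`system.file("extdata", ..., package = "dmsubtype")`).
#' Their identifiers, frequencies and weights are invented but of realistic
#' magnitude; the pipeline treats a panel purely as data.
#'
#' @param path Path to a panel TSV.
#' @param label Optional panel label stored as an attribute.
#' @return A tibble with one row per variant.
#' @export
read_prs_panel <- function(path, label = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("variant_id", "risk_allele", "other_allele", "weight", "freq")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("Panel file is missing columns: ", paste(missing, collapse = ", ")))
  }
  validate_prs_panel(tibble::as_tibble(df), label)
}

validate_prs_panel <- function(panel, label = NULL) {
  if (anyDuplicated(panel$variant_id)) abort("Panel has duplicate variant ids.")
  if (!all(is.finite(panel$weight))) abort("Panel weights must be finite.")
  if ("freq" %in% names(panel) &&
      any(panel$freq <= 0 | panel$freq >= 1, na.rm = TRUE)) {
    abort("Panel allele frequencies must lie strictly in (0, 1).")
  }
  attr(panel, "label") <- label %||% attr(panel, "label")
  panel
}

#' Built-in synthetic example panels
#'
#' @param which One of `"beta_cell"` (35 variants), `"insulin_resistance"`
#'   (20) or `"t1d"` (9).
#' @return A panel tibble (see [read_prs_panel()]).
#' @export
example_prs_panel <- function(which = c("beta_cell", "insulin_resistance", "t1d")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("panel_", which, ".tsv"),
                      package = "dmsubtype", mustWork = TRUE)
  read_prs_panel(path, label = which)
}

#' Simulate risk-allele dosages with optional planted score shifts
#'
#' Dosages are drawn as `Binomial(2, f_v)` per variant with `f_v` the panel's
#' risk-allele frequency. A planted mean polygenic-score shift `delta` for a
#' subgroup is realised by perturbing frequencies in that subgroup by the
#' minimum-norm solution `f_v + delta * w_v / (2 * sum(w^2))`, which moves the
#' expected score `sum_v w_v * 2 f_v` by exactly `delta`.
#'
#' @param n Number of participants (ignored when `subgroups` is given).
#' @param panel Panel tibble with `variant_id`, `weight`, `freq`.
#' @param subgroups Optional character vector of per-participant subgroup
#'   labels.
#' @param score_shift Optional named numeric vector of planted mean score
#'   shifts per subgroup (unnamed subgroups get 0).
#' @param seed Integer seed.
#' @return Tibble: `participant_id` plus one dosage column per variant,
#'   values in `{0, 1, 2}` oriented to the risk allele.
#' @export
simulate_genotypes <- function(n = NULL, panel, subgroups = NULL,
                               score_shift = NULL, seed = NULL) {
  panel <- validate_prs_panel(panel)
  if (is.null(subgroups)) {
    if (is.null(n)) abort("Provide `n` or `subgroups`.")
    subgroups <- rep("all", n)
  }
  n <- length(subgroups)
  w <- panel$weight
  shift_freq <- function(delta) {
    if (delta == 0) return(panel$freq)
    f <- panel$freq + delta * w / (2 * sum(w^2))
    if (any(f <= 0 | f >= 1)) {
      abort("Planted score shift pushes an allele frequency outside (0, 1).")
    }
    f
  }
  with_sim_seed(seed, {
    dose <- matrix(NA_integer_, n, nrow(panel),
                   dimnames = list(NULL, panel$variant_id))
    for (g in unique(subgroups)) {
      idx <- which(subgroups == g)
      f <- shift_freq(if (!is.null(score_shift) && g %in% names(score_shift))
        score_shift[[g]] else 0)
      dose[idx, ] <- rbinom(length(idx) * nrow(panel), 2L,
                            rep(f, each = length(idx)))
    }
    dplyr::bind_cols(tibble::tibble(participant_id = sprintf("P%04d", seq_len(n))),
                     tibble::as_tibble(dose))
  })
}

#' Simulate Gaussian placeholder principal components
#'
#' Genotype-derived principal components enter downstream association models
#' as plain numeric covariates; for synthetic cohorts they are standard
#' normal placeholders, independent of subgroup.
#'
#' @param n Number of participants.
#' @param k Number of components.
#' @param seed Integer seed.
#' @return Tibble with columns `PC1` ... `PCk`.
#' @export
simulate_principal_components <- function(n, k = 3, seed = NULL) {
  with_sim_seed(seed, {
    m <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("PC", seq_len(k))))
    tibble::as_tibble(m)
  })
}
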