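#' Simulate a clinical cohort from subgroup specifications
#'
#' Draws a per-participant clinical table from a mixture of
#' [subgroup_spec()] components. Subgroup sizes are either fixed at each
#' spec's `n` (the default, which reproduces published subgroup proportions
#' exactly at the design stage) or drawn multinomially from the weights.
#' Within a subgroup every variable is drawn independently from its declared
#' marginal; sex and ethnicity are drawn from the spec fractions.
#'
#' @param specs List of [subgroup_spec()] objects (default [table1_specs()]).
#' @param n Total cohort size; required when `fixed_sizes = FALSE`, and used
#'   to rescale fixed counts proportionally when it differs from their sum.
#' @param seed Integer seed; the draw is deterministic given `seed`.
#' @param fixed_sizes Use each spec's `n` (`TRUE`) or multinomial weights.
#' @return A tibble with one row per participant: `participant_id`,
#'   `subgroup_true`, every variable in the specs, `sex` (`"M"`/`"F"`) and
#'   `ethnicity`.
#' @examples
#' cohort <- simulate_clinical_cohort(seed = 1)
#' dplyr::count(cohort, subgroup_true)
#' @export
simulate_clinical_cohort <- function(specs = table1_specs(), n = NULL,
                                     seed = NULL, fixed_sizes = TRUE) {
  if (length(specs) == 0L) abort("`specs` must contain at least one subgroup_spec.")
  ok <- vapply(specs, inherits, logical(1), "subgroup_spec")
  if (!all(ok)) abort("All elements of `specs` must be subgroup_spec objects.")
  w <- vapply(specs, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-6) abort("Subgroup weights must sum to 1.")

  draw <- function() {
    if (fixed_sizes) {
      sizes <- vapply(specs, `[[`, integer(1), "n")
      if (!is.null(n) && n != sum(sizes)) {
        sizes <- round(n * sizes / sum(sizes))
        sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
      }
    } else {
      if (is.null(n)) abort("`n` is required when `fixed_sizes = FALSE`.")
      sizes <- as.integer(rmultinom(1, n, w))
    }
    rows <- purrr::map2(specs, sizes, simulate_subgroup_rows)
    out <- dplyr::bind_rows(rows)
    out$participant_id <- sprintf("P%04d", seq_len(nrow(out)))
    dplyr::relocate(out, "participant_id", "subgroup_true")
  }
  with_sim_seed(seed, draw())
}

simulate_subgroup_rows <- function(spec, size) {
  if (size == 0L) return(tibble::tibble())
  vals <- purrr::pmap(spec$variables, function(variable, family, mean, sd,
                                               median, q1, q3, mu, sigma) {
    if (family == "gaussian") rnorm(size, mean, sd) else rlnorm(size, mu, sigma)
  })
  names(vals) <- spec$variables$variable
  out <- tibble::as_tibble(vals)
  out$subgroup_true <- spec$name
  out$sex <- ifelse(runif(size) < spec$male_fraction, "M", "F")
  out$ethnicity <- if (is.null(spec$ethnicity)) NA_character_ else
    sample(names(spec$ethnicity), size, replace = TRUE, prob = spec$ethnicity)
  out
}

# Run `expr` under a temporary RNG state when a seed is supplied, so
# simulation calls are reproducible without clobbering the caller's stream.
with_sim_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}
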