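#' Remove species with low signal-to-noise ratio
#'
#' Drops species whose signal-to-noise ratio is strictly below `threshold`
#' (a species at exactly the threshold is retained). The number removed is
#' reported.
#'
#' @param lipids A [lipid_matrix()].
#' @param threshold Minimum retained SNR (default 3).
#' @return A filtered `lipid_matrix`.
#' @export
filter_snr <- function(lipids, threshold = 3) {
  stopifnot(inherits(lipids, "lipid_matrix"))
  keep <- lipids$species$snr >= threshold
  inform(paste0("filter_snr: removed ", sum(!keep), " of ", length(keep),
                " species with SNR < ", threshold, "."))
  lipid_matrix(lipids$conc[keep, , drop = FALSE],
               lipids$species[keep, ], lipids$samples)
}

#' Correct batch effects by per-batch median centering on the log scale
#'
#' For each species, log-concentrations are centred on their within-batch
#' median and re-centred on the species' global median, then exponentiated.
#' This removes additive batch offsets on the log scale while preserving
#' positivity and the global level of each species. A batch with a single
#' sample is centred on that value, with a warning.
#'
#' @param lipids A [lipid_matrix()] with batch labels in the sample sheet.
#' @return A corrected `lipid_matrix`.
#' @export
batch_correct <- function(lipids) {
  stopifnot(inherits(lipids, "lipid_matrix"))
  logc <- log(lipids$conc)
  batches <- lipids$samples$batch
  global_med <- apply(logc, 1, median)
  for (b in unique(batches)) {
    cols <- which(batches == b)
    if (length(cols) < 2) {
      warn(paste0("Batch '", b, "' has a single sample; centred on its own value."))
    }
    med_b <- apply(logc[, cols, drop = FALSE], 1, median)
    logc[, cols] <- logc[, cols] - med_b + global_med
  }
  lipid_matrix(exp(logc), lipids$species, lipids$samples)
}

#' Discovery-stage Kruskal-Wallis screen across subgroups
#'
#' Applies the Kruskal-Wallis rank test (tie-corrected, chi-square
#' approximation) to every species across the subgroups and flags species
#' passing the Bonferroni threshold `family_alpha / m`, where `m` is the
#' number of species tested (the post-filter count). A species whose values
#' are identical in all groups is assigned H = 0, p = 1.
#'
#' @param lipids A [lipid_matrix()] with subgroup labels in the sample sheet.
#' @param family_alpha Family-wise alpha (default 0.05).
#' @return Tibble, one row per species: `species_id`, `class`, `statistic`
#'   (Kruskal-Wallis H), `df`, `p_discovery`, `pass_discovery`, plus
#'   attributes `m` and `threshold`.
#' @export
kw_screen <- function(lipids, family_alpha = 0.05) {
  stopifnot(inherits(lipids, "lipid_matrix"))
  groups <- factor(lipids$samples$subgroup)
  if (nlevels(groups) < 2) abort("Need at least 2 subgroups.")
  if (any(table(groups) < 2)) abort("Each subgroup needs at least 2 samples.")
  m <- nrow(lipids$conc)
  threshold <- family_alpha / m
  res <- purrr::map_dfr(seq_len(m), function(i) {
    y <- lipids$conc[i, ]
    if (length(unique(y)) == 1L) {
      tibble::tibble(statistic = 0, df = nlevels(groups) - 1L, p_discovery = 1)
    } else {
      kt <- kruskal.test(y, groups)
      tibble::tibble(statistic = unname(kt$statistic),
                     df = unname(kt$parameter), p_discovery = kt$p.value)
    }
  })
  out <- dplyr::bind_cols(lipids$species[c("species_id", "class")], res) |>
    dplyr::mutate(pass_discovery = .data$p_discovery < threshold)
  attr(out, "m") <- m
  attr(out, "threshold") <- threshold
  out
}

#' Replicate discovery hits in an independent validation lipidome
#'
#' Only species that passed the discovery Bonferroni filter are tested in
#' the validation cohort (Kruskal-Wallis across the same subgroups), and a
#' nominal `p < alpha` is considered replicated. A candidate absent from the
#' validation matrix is flagged non-replicable.
#'
#' @param results Discovery results from [kw_screen()].
#' @param validation A validation [lipid_matrix()].
#' @param alpha Nominal replication level (default 0.05).
#' @return `results` with `p_validation` and `pass_validation` columns
#'   (`pass_validation` is `FALSE` wherever `pass_discovery` is).
#' @export
replicate_screen <- function(results, validation, alpha = 0.05) {
  stopifnot(inherits(validation, "lipid_matrix"))
  groups <- factor(validation$samples$subgroup)
  results$p_validation <- NA_real_
  results$pass_validation <- FALSE
  cand <- which(results$pass_discovery)
  miss <- setdiff(results$species_id[cand], validation$species$species_id)
  if (length(miss)) {
    inform(paste0(length(miss), " candidate(s) absent from validation; ",
                  "flagged non-replicable."))
  }
  for (i in cand) {
    r <- match(results$species_id[i], validation$species$species_id)
    if (is.na(r)) next
    y <- validation$conc[r, ]
    p <- if (length(unique(y)) == 1L) 1 else kruskal.test(y, groups)$p.value
    results$p_validation[i] <- p
    results$pass_validation[i] <- p < alpha
  }
  results
}

#' Pairwise subgroup contrasts of log lipid concentrations
#'
#' Per species, ordinary least squares of the log-transformed concentration
#' on subgroup indicators against a reference subgroup; coefficients are
#' log-scale mean differences (log fold differences) versus the reference.
#'
#' @param lipids A [lipid_matrix()].
#' @param reference Reference subgroup (default `"MOD"`).
#' @param species Optional subset of species ids (default all).
#' @return Tibble: `species_id`, `subgroup`, `estimate`, `std_error`,
#'   `conf_low`, `conf_high`, `p_value`.
#' @export
pairwise_contrast <- function(lipids, reference = "MOD", species = NULL) {
  stopifnot(inherits(lipids, "lipid_matrix"))
  g <- lipids$samples$subgroup
  if (!reference %in% g) abort(paste0("Reference subgroup '", reference, "' absent."))
  f <- stats::relevel(factor(g), ref = reference)
  ids <- species %||% lipids$species$species_id
  purrr::map_dfr(ids, function(id) {
    r <- match(id, lipids$species$species_id)
    if (is.na(r)) abort(paste0("Unknown species '", id, "'."))
    fit <- lm(log(lipids$conc[r, ]) ~ f)
    if (any(is.na(coef(fit)))) abort("Rank-deficient contrast design.")
    est <- coef(fit)[-1]
    se <- sqrt(diag(vcov(fit)))[-1]
    tibble::tibble(species_id = id,
                   subgroup = sub("^f", "", names(est)),
                   estimate = unname(est), std_error = unname(se),
                   conf_low = unname(est - 1.96 * se),
                   conf_high = unname(est + 1.96 * se),
                   p_value = 2 * pnorm(-abs(est / se)))
  })
}

#' Row-standardised subgroup means for significant species
#'
#' For species passing both the discovery and validation stages, computes
#' per-subgroup means of the log concentration, centred and scaled across
#' subgroups within each species — the matrix behind the subgroup heatmap.
#' A species with identical group means yields a zero row.
#'
#' @param results Results from [replicate_screen()] (needs
#'   `pass_validation`), or from [kw_screen()] when `stage = "discovery"`.
#' @param lipids The matching [lipid_matrix()].
#' @param stage Which pass flag gates inclusion.
#' @return Numeric matrix, rows = passing species, columns = subgroups.
#' @export
heatmap_matrix <- function(results, lipids,
                           stage = c("validation", "discovery")) {
  stage <- match.arg(stage)
  flag <- if (stage == "validation") results$pass_validation else results$pass_discovery
  ids <- results$species_id[flag]
  if (!length(ids)) abort("No species pass the requested stage.")
  g <- factor(lipids$samples$subgroup)
  rows <- match(ids, lipids$species$species_id)
  means <- t(apply(log(lipids$conc[rows, , drop = FALSE]), 1, function(y) {
    tapply(y, g, mean)
  }))
  z <- t(apply(means, 1, function(r) {
    s <- stats::sd(r)
    if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  dimnames(z) <- list(ids, levels(g))
  z
}
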