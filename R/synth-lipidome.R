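#' Construct a lipid concentration container
#'
#' Couples a species-by-sample concentration matrix with a species sheet
#' (id, lipid class, per-species signal-to-noise ratio) and a sample sheet
#' (sample id, subgroup, batch), validating their consistency.
#'
#' @param conc Numeric matrix, species in rows, samples in columns, strictly
#'   positive, with row/column names.
#' @param species Tibble with `species_id`, `class`, `snr`.
#' @param samples Tibble with `sample_id`, `subgroup`, `batch`.
#' @return An object of class `lipid_matrix`.
#' @export
lipid_matrix <- function(conc, species, samples) {
  if (!is.matrix(conc) || !is.numeric(conc)) abort("`conc` must be a numeric matrix.")
  if (any(conc <= 0)) abort("Concentrations must be strictly positive.")
  if (!identical(rownames(conc), species$species_id)) {
    abort("Row names of `conc` must equal `species$species_id` in order.")
  }
  if (!identical(colnames(conc), samples$sample_id)) {
    abort("Column names of `conc` must equal `samples$sample_id` in order.")
  }
  bad <- setdiff(unique(species$class), lipid_class_vocabulary())
  if (length(bad)) {
    abort(paste0("Unknown lipid class(es): ", paste(bad, collapse = ", ")))
  }
  structure(list(conc = conc, species = tibble::as_tibble(species),
                 samples = tibble::as_tibble(samples)),
            class = "lipid_matrix")
}

#' @export
print.lipid_matrix <- function(x, ...) {
  cat("<lipid_matrix> ", nrow(x$conc), " species x ", ncol(x$conc), " samples; ",
      dplyr::n_distinct(x$samples$batch), " batch(es), subgroups: ",
      paste(sort(unique(x$samples$subgroup)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname lipid_matrix
#' @export
lipid_class_vocabulary <- function() {
  c("PE", "PC", "PI", "SM", "Cer", "LPC", "LPI", "Hex1Cer")
}

#' Plan planted subgroup effects for a synthetic lipidome
#'
#' Builds an effect plan in which the first `n_sig` species carry opposite
#' shifts in two subgroups (one raised, one lowered), emulating the
#' characteristic pattern in which the severe insulin-resistant subgroup has
#' elevated sphingolipid/glycerophospholipid levels and the age-related
#' subgroup has reduced ones.
#'
#' @param n_sig Number of species with planted effects.
#' @param shift_sd Mean shift in units of the within-group log-scale SD.
#' @param up,down Subgroup labels receiving `+shift_sd` and `-shift_sd`.
#' @return Tibble `species_id`, `subgroup`, `shift_sd` (an effect plan).
#' @export
lipid_effect_plan <- function(n_sig, shift_sd = 1.5,
                              up = "SIRD-RII", down = "MARD-II") {
  if (n_sig == 0) return(tibble::tibble(species_id = character(),
                                        subgroup = character(),
                                        shift_sd = numeric()))
  ids <- sprintf("lipid_%03d", seq_len(n_sig))
  tibble::tibble(species_id = rep(ids, each = 2L),
                 subgroup = rep(c(up, down), n_sig),
                 shift_sd = rep(c(shift_sd, -shift_sd), n_sig))
}

#' Simulate a lipidome with planted subgroup effects and batch offsets
#'
#' Log-concentrations are Gaussian per species: a species-specific baseline
#' (drawn once), a within-group SD (drawn once per species), optional planted
#' subgroup mean shifts expressed in within-group SD units, and optional
#' additive per-batch offsets on the log scale. Species are annotated with
#' lipid classes from [lipid_class_vocabulary()] and a per-species
#' signal-to-noise ratio.
#'
#' @param n_per_group Named integer vector of samples per subgroup.
#' @param n_species Total species count (default 315).
#' @param effect_plan Tibble `species_id`, `subgroup`, `shift_sd`
#'   (see [lipid_effect_plan()]); `NULL` for a null lipidome.
#' @param batch_offsets Named numeric vector of log-scale offsets per batch;
#'   samples are assigned to batches round-robin. `NULL` for one batch.
#' @param snr Per-species signal-to-noise values, recycled; default draws
#'   uniformly from `[5, 100]` (all species retained by the default filter).
#' @param base_log_mean,base_log_sd Distribution of species baselines.
#' @param within_sd_range Range of the within-group log-scale SD per species.
#' @param seed Integer seed.
#' @return A [lipid_matrix()].
#' @export
simulate_lipidome <- function(n_per_group, n_species = 315,
                              effect_plan = NULL, batch_offsets = NULL,
                              snr = NULL, base_log_mean = 2, base_log_sd = 1,
                              within_sd_range = c(0.3, 0.7), seed = NULL) {
  if (is.null(names(n_per_group))) abort("`n_per_group` must be named by subgroup.")
  if (!is.null(effect_plan) && nrow(effect_plan)) {
    if (anyDuplicated(effect_plan[c("species_id", "subgroup")])) {
      abort("Overlapping effect assignments: one species/subgroup pair listed twice.")
    }
    if (dplyr::n_distinct(effect_plan$species_id) > n_species) {
      abort("More planted species than `n_species`.")
    }
  }
  with_sim_seed(seed, {
    ids <- sprintf("lipid_%03d", seq_len(n_species))
    classes <- sample(lipid_class_vocabulary(), n_species, replace = TRUE,
                      prob = c(.18, .30, .10, .14, .10, .10, .04, .04))
    snr <- if (is.null(snr)) runif(n_species, 5, 100) else rep_len(snr, n_species)
    species <- tibble::tibble(species_id = ids, class = classes, snr = snr)

    groups <- rep(names(n_per_group), n_per_group)
    n <- length(groups)
    samples <- tibble::tibble(
      sample_id = sprintf("S%04d", seq_len(n)),
      subgroup = groups,
      batch = if (is.null(batch_offsets)) "batch1" else
        rep_len(names(batch_offsets), n))

    base <- rnorm(n_species, base_log_mean, base_log_sd)
    wsd <- runif(n_species, within_sd_range[1], within_sd_range[2])
    logc <- matrix(rnorm(n_species * n, 0, 1), n_species, n) * wsd + base
    if (!is.null(effect_plan) && nrow(effect_plan)) {
      for (i in seq_len(nrow(effect_plan))) {
        r <- match(effect_plan$species_id[i], ids)
        if (is.na(r)) abort(paste0("Unknown species in effect plan: ",
                                   effect_plan$species_id[i]))
        cols <- which(groups == effect_plan$subgroup[i])
        logc[r, cols] <- logc[r, cols] + effect_plan$shift_sd[i] * wsd[r]
      }
    }
    if (!is.null(batch_offsets)) {
      logc <- logc + rep(batch_offsets[samples$batch], each = n_species)
    }
    conc <- exp(logc)
    dimnames(conc) <- list(ids, samples$sample_id)
    lipid_matrix(conc, species, samples)
  })
}
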