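# Shared fixture builders. Everything is generated in code at test time.

# Well-separated spherical Gaussian blobs on p dimensions.
make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(j) {
      matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
        matrix(centers[j, ], n_per, ncol(centers), byrow = TRUE)
    }))
    list(x = x, labels = rep(seq_len(nrow(centers)), each = n_per))
  })
}

# A miniature single-subgroup spec for fast cohort draws.
tiny_spec <- function(name = "MOD", n = 10, bmi_sd = 0) {
  subgroup_spec(name, n = n, weight = 1, male_fraction = 0.5,
                gaussian = list(onset_age = c(52, bmi_sd), bmi = c(30, bmi_sd),
                                hba1c = c(7, bmi_sd), index_age = c(55, bmi_sd),
                                egfr = c(92, bmi_sd)),
                lognormal = list(homa2b = c(96.9, 77.5, 131.7),
                                 homa2ir = c(2.2, 1.8, 2.9)))
}

# Three well-separated "clinical" subgroups so label recovery is near-perfect.
separated_specs <- function() {
  gvars <- function(onset, bmi, hba1c) {
    list(onset_age = c(onset, 1.5), bmi = c(bmi, 1), hba1c = c(hba1c, 0.2),
         index_age = c(onset + 3, 1.5), egfr = c(95, 5))
  }
  list(
    "MOD" = subgroup_spec("MOD", n = 60, weight = 60 / 150, male_fraction = 0.5,
                          gaussian = gvars(52, 31, 6.9),
                          lognormal = list(homa2b = c(97, 90, 105),
                                           homa2ir = c(2.2, 2.1, 2.4))),
    "SIRD-RII" = subgroup_spec("SIRD-RII", n = 40, weight = 40 / 150,
                               male_fraction = 0.5,
                               gaussian = gvars(40, 32, 9.2),
                               lognormal = list(homa2b = c(44, 41, 47),
                                                homa2ir = c(2.7, 2.5, 2.9))),
    "MARD-II" = subgroup_spec("MARD-II", n = 50, weight = 50 / 150,
                              male_fraction = 0.5,
                              gaussian = gvars(62, 25, 7.1),
                              lognormal = list(homa2b = c(53, 50, 56),
                                               homa2ir = c(1.3, 1.2, 1.4))))
}

# Small lipid_matrix built by hand.
toy_lipids <- function(conc, groups, classes = NULL, snr = NULL, batches = NULL) {
  n_sp <- nrow(conc)
  ids <- sprintf("lipid_%03d", seq_len(n_sp))
  dimnames(conc) <- list(ids, sprintf("S%04d", seq_len(ncol(conc))))
  lipid_matrix(conc,
               tibble::tibble(species_id = ids,
                              class = classes %||% rep("PC", n_sp),
                              snr = snr %||% rep(10, n_sp)),
               tibble::tibble(sample_id = colnames(conc), subgroup = groups,
                              batch = batches %||% rep("b1", ncol(conc))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
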