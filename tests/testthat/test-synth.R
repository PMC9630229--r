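test_that("lognormal calibration from median/IQR recovers the stated quantiles", {
  # published HOMA2-B cell for the obesity-related subgroup
  par <- lognormal_from_median_iqr(96.9, 77.5, 131.7)
  expect_equal(unname(par["mu"]), log(96.9), tolerance = 1e-12)
  expect_equal(unname(par["sigma"]), (log(131.7) - log(77.5)) / (2 * qnorm(0.75)),
               tolerance = 1e-12)
  expect_equal(unname(par["sigma"]), 0.3930, tolerance = 1e-3)

  # identity case
  par0 <- lognormal_from_median_iqr(1, exp(-qnorm(0.75)), exp(qnorm(0.75)))
  expect_equal(unname(par0), c(0, 1), tolerance = 1e-12)

  # quantile-function oracle: the fit reproduces the median and the log-IQR
  # width exactly (individual quartiles only coincide when they are
  # log-symmetric, which a two-parameter lognormal requires)
  par2 <- lognormal_from_median_iqr(2.2, 1.8, 2.9)
  q <- qlnorm(c(.25, .5, .75), par2["mu"], par2["sigma"])
  expect_equal(q[2], 2.2, tolerance = 1e-9)
  expect_equal(q[3] / q[1], 2.9 / 1.8, tolerance = 1e-9)
  # a log-symmetric triple is reproduced in full
  par3 <- lognormal_from_median_iqr(2, 1, 4)
  expect_equal(qlnorm(c(.25, .5, .75), par3["mu"], par3["sigma"]),
               c(1, 2, 4), tolerance = 1e-9)

  expect_error(lognormal_from_median_iqr(2, 3, 4), "increasing")
  expect_error(lognormal_from_median_iqr(-1, 0.5, 2), "positive")
})

test_that("cohort simulation honours fixed subgroup sizes and seeds", {
  cohort <- simulate_clinical_cohort(seed = 42)
  counts <- table(cohort$subgroup_true)
  expect_equal(unname(counts[c("MOD", "SIRD-RII", "MARD-II")]),
               c(307, 130, 250), ignore_attr = TRUE)
  expect_identical(cohort, simulate_clinical_cohort(seed = 42))
  expect_false(identical(cohort, simulate_clinical_cohort(seed = 43)))
  expect_error(simulate_clinical_cohort(list()), "at least one")
})

test_that("degenerate zero-sd spec yields identical rows at the location", {
  cohort <- simulate_clinical_cohort(list(tiny_spec(bmi_sd = 0)), seed = 1)
  expect_equal(nrow(cohort), 10)
  expect_true(all(cohort$bmi == 30))
  expect_true(all(cohort$hba1c == 7))
})

test_that("simulated marginals match their specs at large n", {
  spec <- table1_specs()[["MOD"]]
  spec$weight <- 1
  spec$n <- 100000L
  cohort <- simulate_clinical_cohort(list(spec), seed = 5)
  expect_equal(mean(cohort$bmi), 30.1, tolerance = 0.05 / 30.1)
  # median and log-IQR width calibrated within 1% relative error
  q <- quantile(cohort$homa2b, c(.25, .5, .75))
  expect_equal(unname(q[2]), 96.9, tolerance = 0.01)
  expect_equal(unname(q[3] / q[1]), 131.7 / 77.5, tolerance = 0.01)
  q2 <- quantile(cohort$homa2ir, c(.25, .5, .75))
  expect_equal(unname(q2[2]), 2.2, tolerance = 0.01)
  expect_equal(unname(q2[3] / q2[1]), 2.9 / 1.8, tolerance = 0.01)
})

test_that("genotype simulation is reproducible and plants score shifts", {
  panel <- example_prs_panel("beta_cell")
  g1 <- simulate_genotypes(4, panel, seed = 9)
  expect_identical(g1, simulate_genotypes(4, panel, seed = 9))
  expect_true(all(as.matrix(g1[-1]) %in% 0:2))

  labels <- rep(c("MOD", "MARD-II"), each = 10000)
  geno <- simulate_genotypes(subgroups = labels,
                             panel = panel,
                             score_shift = c("MARD-II" = 1.39), seed = 10)
  s <- compute_prs(geno, panel)$score
  delta <- mean(s[labels == "MARD-II"]) - mean(s[labels == "MOD"])
  expect_equal(delta, 1.39, tolerance = 0.05)

  g0 <- simulate_genotypes(subgroups = labels, panel = panel, seed = 11)
  s0 <- compute_prs(g0, panel)$score
  d0 <- mean(s0[labels == "MARD-II"]) - mean(s0[labels == "MOD"])
  expect_lt(abs(d0), 0.05)

  expect_error(simulate_genotypes(subgroups = labels, panel = panel,
                                  score_shift = c("MARD-II" = 50), seed = 1),
               "outside")
})

test_that("null lipidome produces (almost) no Bonferroni hits", {
  lip <- simulate_lipidome(c(A = 30, B = 30, C = 30), n_species = 315, seed = 3)
  res <- kw_screen(lip)
  expect_lte(sum(res$pass_discovery), 1)  # expectation is 315 * alpha/315 = 0.05
  expect_equal(attr(res, "threshold"), 0.05 / 315)
})

test_that("planted batch offsets are removed by median centering", {
  lip <- simulate_lipidome(c(A = 20, B = 20), n_species = 40,
                           batch_offsets = c(b1 = 0, b2 = 1), seed = 4)
  raw_med <- apply(log(lip$conc), 1, function(y) {
    tapply(y, lip$samples$batch, median)
  })
  expect_gt(mean(raw_med["b2", ] - raw_med["b1", ]), 0.8)
  corr <- batch_correct(lip)
  med <- apply(log(corr$conc), 1, function(y) {
    tapply(y, corr$samples$batch, median)
  })
  expect_equal(unname(med["b1", ]), unname(med["b2", ]), tolerance = 1e-10)
  expect_true(all(corr$conc > 0))
})

test_that("lipidome simulation rejects conflicting effect plans", {
  plan <- tibble::tibble(species_id = c("lipid_001", "lipid_001"),
                         subgroup = c("A", "A"), shift_sd = c(1, 2))
  expect_error(simulate_lipidome(c(A = 5, B = 5), n_species = 10,
                                 effect_plan = plan, seed = 1), "Overlapping")
})

test_that("null outcome simulation recovers hazard ratio 1", {
  cohort <- simulate_clinical_cohort(seed = 8)
  spec <- hazard_spec("null_outcome", baseline_rate = 0.03)
  ev <- simulate_outcomes(cohort, spec, seed = 8)
  ev$subgroup <- ev$subgroup_true
  fit <- cox_fit(ev)
  hrs <- tidy(fit)$hr
  expect_true(all(abs(log(hrs)) < 0.5))
  expect_true(all(tidy(fit)$p_value > 0.001))
})

test_that("administrative censoring at 0 censors every record at 0", {
  cohort <- simulate_clinical_cohort(list(tiny_spec()), seed = 2)
  spec <- hazard_spec("x", 0.1, admin_censor_years = 0)
  ev <- simulate_outcomes(cohort, spec, seed = 2)
  expect_true(all(ev$time == 0))
  expect_true(all(ev$event == 0))
})

test_that("egfr trajectories cross the 40% threshold when planted", {
  cohort <- simulate_clinical_cohort(list(tiny_spec()), seed = 3)
  # no decline, no noise: nobody progresses
  labs0 <- simulate_egfr_series(cohort, progressor = rep(FALSE, 10),
                                stable_decline = c(0, 0), noise_sd = 0, seed = 4)
  out0 <- derive_progressive_ckd(labs0, cohort)
  expect_true(all(out0$event == 0))
  expect_true(all(out0$time == 8))

  # 12%/year decline crosses 0.6 * baseline between year 4 and 5
  labs1 <- simulate_egfr_series(cohort, progressor = rep(TRUE, 10),
                                progressor_decline = c(0.12, 0.12),
                                noise_sd = 0, seed = 5)
  out1 <- derive_progressive_ckd(labs1, cohort)
  expect_true(all(out1$event == 1))
  # 0.88^t <= 0.6 from t >= 3.996; first scheduled visit at/after that is 4.0
  expect_true(all(out1$time == 4.0))

  # planted progressor fraction is recovered
  specs <- table1_specs()
  big <- simulate_clinical_cohort(specs, seed = 6)
  labs <- simulate_egfr_series(big, progressor = 0.1, seed = 7)
  out <- derive_progressive_ckd(labs, big)
  expect_equal(mean(out$event), 0.1, tolerance = 0.35)
})
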