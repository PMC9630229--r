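test_that("progressive CKD rule walk-throughs behave at the boundaries", {
  flat <- tibble::tibble(participant_id = "A", time_years = 1:5,
                         egfr = rep(90, 5))
  out <- derive_progressive_ckd(flat, c(A = 90))
  expect_equal(out$time, 5)
  expect_equal(out$event, 0L)

  # qualifying drop without confirmation is censored
  dip <- tibble::tibble(participant_id = "A", time_years = c(1, 1.5, 2),
                        egfr = c(50, 80, 85))
  out2 <- derive_progressive_ckd(dip, c(A = 100))
  expect_equal(out2$event, 0L)

  # confirmation must respect the 3-month gap; event timed at first crossing
  walk <- tibble::tibble(participant_id = "A",
                         time_years = c(1, 1.2, 1.6),
                         egfr = c(58, 55, 54))
  out3 <- derive_progressive_ckd(walk, c(A = 100))
  expect_equal(out3$time, 1)
  expect_equal(out3$event, 1L)
  # with only the 0.2-year follow-up available there is no confirmation
  out4 <- derive_progressive_ckd(walk[1:2, ], c(A = 100))
  expect_equal(out4$event, 0L)

  expect_error(derive_progressive_ckd(
    tibble::tibble(participant_id = "A", time_years = c(2, 1), egfr = c(50, 50)),
    c(A = 100)), "Unsorted")
})

test_that("adding a later confirming measurement never removes an event", {
  withr::with_seed(6, {
    for (rep in 1:25) {
      t <- sort(runif(6, 0, 8))
      e <- runif(6, 40, 110)
      labs <- tibble::tibble(participant_id = "A", time_years = t, egfr = e)
      before <- derive_progressive_ckd(labs, c(A = 100))
      extra <- tibble::tibble(participant_id = "A", time_years = max(t) + 1,
                              egfr = 30)
      after <- derive_progressive_ckd(dplyr::bind_rows(labs, extra), c(A = 100))
      expect_gte(after$event, before$event)
      if (before$event == 1) expect_equal(after$time, before$time)
    }
  })
})

test_that("incidence rates match the exact Poisson interval", {
  r0 <- incidence_rate(0, 100)
  expect_equal(r0$rate, 0)
  expect_equal(r0$conf_low, 0)
  expect_equal(r0$conf_high, 1000 * qchisq(0.975, 2) / 2 / 100, tolerance = 1e-10)
  expect_equal(r0$conf_high, 36.89, tolerance = 1e-3)

  expect_equal(incidence_rate(10, 1000)$rate, 10)

  # 13 events in 896.6 person-years reproduces 14.5 (7.7, 24.8)
  r <- incidence_rate(13, 896.6)
  expect_equal(r$rate, 14.5, tolerance = 0.01)
  expect_equal(r$conf_low, 7.7, tolerance = 0.01)
  expect_equal(r$conf_high, 24.8, tolerance = 0.01)
  expect_error(incidence_rate(3, 0), "positive")
})

test_that("exact Poisson interval achieves nominal coverage", {
  true_rate <- 12   # events per 1000 person-years
  withr::with_seed(7, {
    py <- runif(2000, 200, 1500)
    k <- rpois(2000, true_rate * py / 1000)
  })
  covered <- vapply(seq_along(k), function(i) {
    ci <- incidence_rate(k[i], py[i])
    ci$conf_low <= true_rate && true_rate <= ci$conf_high
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("Kaplan-Meier matches the product-limit computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  # no events: flat at 1
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$survival == 1))
  # moving a censoring time further beyond the last event changes nothing
  km_a <- km_estimate(c(1, 2, 4), c(1, 1, 0))
  km_b <- km_estimate(c(1, 2, 9), c(1, 1, 0))
  expect_equal(km_a$survival, km_b$survival, tolerance = 1e-12)
  # KM with no censoring equals the empirical survival function
  withr::with_seed(8, t <- rexp(40))
  km2 <- km_estimate(t, rep(1, 40))
  expect_equal(km2$survival, 1 - ecdf(t)(km2$time), tolerance = 1e-10)
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("logrank matches the hand O-E/V computation and the Cox score test", {
  # worked two-group example, no ties
  t <- c(1, 2, 3, 4, 5, 6)
  e <- c(1, 1, 1, 1, 1, 0)
  g <- c("a", "b", "a", "b", "a", "b")
  lr <- logrank_test(t, e, g)
  # hand computation of O - E and hypergeometric variance per event time
  oe <- 0; v <- 0
  for (ti in t[e == 1]) {
    at_risk <- t >= ti
    n <- sum(at_risk); n1 <- sum(at_risk & g == "a")
    d <- sum(t == ti & e == 1)
    oe <- oe + sum(t == ti & e == 1 & g == "a") - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(lr$statistic, oe^2 / v, tolerance = 1e-10)
  expect_equal(lr$p_value, pchisq(oe^2 / v, 1, lower.tail = FALSE),
               tolerance = 1e-10)

  # label permutation of identical duplicated data gives statistic 0
  t2 <- rep(c(1, 2, 3), 2); e2 <- rep(1, 6); g2 <- rep(c("a", "b"), each = 3)
  expect_lt(logrank_test(rep(c(1, 2, 3), 2), rep(1, 6),
                         c("a", "b", "a", "b", "a", "b"))$statistic, 1e-10)

  # two-group logrank equals the Cox score test at beta = 0
  withr::with_seed(9, {
    tt <- rexp(60); ee <- rbinom(60, 1, 0.7); gg <- rep(c("a", "b"), 30)
  })
  lr2 <- logrank_test(tt, ee, gg)
  sc <- survival::coxph(survival::Surv(tt, ee) ~ gg)$score
  expect_equal(lr2$statistic, sc, tolerance = 0.02)

  expect_error(logrank_test(t, e, rep("a", 6)), "2 groups")
})

test_that("Cox estimate equals the brute-force partial likelihood maximiser", {
  d <- tibble::tibble(time = c(1, 2, 3, 4, 5, 6, 7, 8),
                      event = c(1, 0, 1, 1, 0, 1, 1, 1),
                      x = c(1, 1, 0, 1, 0, 0, 1, 0))
  fit <- cox_fit(d, covariates = "x", subgroup = NULL)
  # grid-search oracle over the exact partial likelihood (no ties present)
  pl <- function(beta) {
    sum(sapply(which(d$event == 1), function(i) {
      risk <- d$time >= d$time[i]
      beta * d$x[i] - log(sum(exp(beta * d$x[risk])))
    }))
  }
  grid <- seq(-5, 5, by = 1e-4)
  beta_hat <- grid[which.max(vapply(grid, pl, numeric(1)))]
  expect_equal(tidy(fit)$log_hr, beta_hat, tolerance = 1e-4)
})

test_that("Cox fits are invariant to time rescaling and covariate centering", {
  withr::with_seed(10, {
    d <- tibble::tibble(time = rexp(100), event = rbinom(100, 1, 0.8),
                        x = rnorm(100))
  })
  f1 <- cox_fit(d, covariates = "x", subgroup = NULL)
  f2 <- cox_fit(dplyr::mutate(d, time = 3.7 * time), covariates = "x",
                subgroup = NULL)
  f3 <- cox_fit(dplyr::mutate(d, x = x - 10), covariates = "x",
                subgroup = NULL)
  expect_equal(tidy(f2)$log_hr, tidy(f1)$log_hr, tolerance = 1e-8)
  expect_equal(tidy(f3)$log_hr, tidy(f1)$log_hr, tolerance = 1e-6)
})

test_that("Schoenfeld PH test detects a planted time-varying effect", {
  withr::with_seed(11, {
    n <- 2000
    x <- rbinom(n, 1, 0.5)
    # effect reverses over time: early hazard up, late hazard down for x = 1
    u <- runif(n)
    t0 <- -log(u) / (0.5 * exp(2 * x))
    t <- ifelse(t0 < 0.5, t0, 0.5 + (t0 - 0.5) * exp(3.5 * x))
    cens <- runif(n, 0, 6)
    d <- tibble::tibble(time = pmin(t, cens), event = as.integer(t <= cens),
                        x = x)
  })
  fit <- cox_fit(d, covariates = "x", subgroup = NULL)
  ph <- schoenfeld_ph_test(fit)
  expect_lt(ph$p_value[ph$term == "x"], 0.01)
})

test_that("Schoenfeld PH test is calibrated under proportional hazards", {
  withr::with_seed(12, {
    ps <- replicate(20, {
      n <- 150
      x <- rnorm(n)
      t <- rexp(n, 0.3 * exp(0.5 * x))
      cens <- runif(n, 0, 8)
      d <- tibble::tibble(time = pmin(t, cens), event = as.integer(t <= cens),
                          x = x)
      schoenfeld_ph_test(cox_fit(d, covariates = "x", subgroup = NULL))$p_value[1]
    })
  })
  expect_gt(mean(ps > 0.05), 0.7)   # nominal 95%, generous Monte-Carlo margin
  expect_gt(min(ps), 1e-4)
})
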