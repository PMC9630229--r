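test_that("standardisation fits mean 0 / SD 1 and honours conventions", {
  d <- tibble::tibble(a = c(2, 4, 6), b = c(1, 2, 4))
  pop <- standardize(d, classifiers = c("a", "b"), log_vars = character(),
                     sd = "population")
  expect_equal(pop$x[, "a"], c(-1.2247, 0, 1.2247), tolerance = 1e-4,
               ignore_attr = TRUE)
  fit <- standardize(d, classifiers = c("a", "b"), log_vars = character())
  expect_equal(colMeans(fit$x), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(fit$x, 2, sd), c(a = 1, b = 1), tolerance = 1e-12)

  # idempotence: applying the fitted params to already-standardised data
  again <- standardize(tibble::as_tibble(fit$x), classifiers = c("a", "b"),
                       params = transform(fit$params, center = 0, scale = 1))
  expect_equal(again$x, fit$x, tolerance = 1e-12)

  # round trip through the inverse
  back <- unstandardize(fit$x, fit$params)
  expect_equal(unname(back[, "a"]), d$a, tolerance = 1e-10)

  expect_error(standardize(tibble::tibble(a = c(1, 1, 1)), "a", character()),
               "Zero-variance.*a")
  expect_error(standardize(tibble::tibble(a = c(-1, 2, 3)), "a", "a"),
               "Non-positive")
})

test_that("k-means analytic edge cases hold", {
  b <- make_blobs(10, rbind(c(0, 0), c(8, 8)), seed = 2)
  m1 <- kmeans_fit(b$x, 1, restarts = 2, seed = 1)
  expect_equal(m1$centroids[1, ], colMeans(b$x), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(m1$wss, sum(sweep(b$x, 2, colMeans(b$x))^2), tolerance = 1e-10)
  mn <- kmeans_fit(b$x, nrow(b$x), restarts = 2, seed = 1)
  expect_equal(mn$wss, 0, tolerance = 1e-12)
})

test_that("k-means matches the exhaustive best-WSS bipartition on small data", {
  b <- make_blobs(5, rbind(c(0, 0), c(10, 10)), seed = 3)
  m <- kmeans_fit(b$x, 2, restarts = 10, seed = 4)
  # brute-force oracle: enumerate all non-trivial bipartitions of 10 points
  n <- nrow(b$x)
  best <- Inf; best_part <- NULL
  for (code in 1:(2^(n - 1) - 1)) {
    part <- as.integer(intToBits(code))[1:n] + 1L
    w <- sum(sapply(1:2, function(j) {
      xs <- b$x[part == j, , drop = FALSE]
      sum(sweep(xs, 2, colMeans(xs))^2)
    }))
    if (w < best) { best <- w; best_part <- part }
  }
  expect_equal(m$wss, best, tolerance = 1e-8)
  expect_equal(concordance(m$assignments, best_part)$agreement, 1)
})

test_that("every point is assigned to its nearest centroid and WSS is consistent", {
  b <- make_blobs(20, rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0)), seed = 5)
  m <- kmeans_fit(b$x, 3, restarts = 5, seed = 6)
  d <- outer(rowSums(b$x^2), rowSums(m$centroids^2), "+") -
    2 * b$x %*% t(m$centroids)
  expect_equal(m$assignments, max.col(-d))
  expect_equal(m$wss, sum(d[cbind(seq_len(nrow(b$x)), m$assignments)]),
               tolerance = 1e-8)
})

test_that("best-of-restarts WSS is non-increasing in the restart count", {
  b <- make_blobs(15, rbind(c(0, 0), c(3, 0), c(0, 3), c(3, 3)), seed = 7)
  wss <- sapply(c(1, 5, 25), function(r) kmeans_fit(b$x, 4, restarts = r,
                                                    seed = 11)$wss)
  expect_true(all(diff(wss) <= 1e-10))
})

test_that("residualisation removes the covariate and matches normal equations", {
  withr::with_seed(8, {
    x <- tibble::tibble(u = rnorm(5), v = rnorm(5))
    z <- c(0, 1, 0, 1, 1)
  })
  r <- residualize_on_covariate(x, z)
  expect_lt(abs(sum(r$u * z)), 1e-8)
  expect_lt(abs(sum(r$v * z)), 1e-8)
  # normal-equations oracle
  fit <- lm(u ~ z, data = cbind(x, z = z))
  expect_equal(r$u, unname(residuals(fit)), tolerance = 1e-10)
  # column proportional to covariate vanishes; orthogonal column is centred
  r2 <- residualize_on_covariate(tibble::tibble(w = 2 * z), z)
  expect_true(all(abs(r2$w) < 1e-10))
  expect_error(residualize_on_covariate(x, rep(1, 5)), "constant")
})

test_that("concordance aligns labels and reproduces the hand-computed kappa", {
  a <- rep(c("x", "y", "z"), times = c(5, 6, 7))
  expect_equal(concordance(a, a)$kappa, 1)
  # permuted relabeling is a perfect match after alignment
  b <- c(z = "q", x = "r", y = "s")[a]
  expect_equal(concordance(a, b)$agreement, 1)
  # 2x2 confusion [[20,5],[10,15]]: po = 0.7, pe = 0.5, kappa = 0.4
  la <- rep(1:2, times = c(25, 25))
  lb <- c(rep(1, 20), rep(2, 5), rep(1, 10), rep(2, 15))
  cc <- concordance(la, lb)
  expect_equal(cc$agreement, 0.7)
  expect_equal(cc$kappa, 0.4)
  expect_error(concordance(1:3, 1:4), "length")
})

test_that("subgroup naming follows the centroid rules and recovers planted labels", {
  cohort <- simulate_clinical_cohort(separated_specs(), seed = 9)
  model <- cluster_cohort(cohort, k = 3, restarts = 10, seed = 10)
  labels <- subgroup_labels(model)
  expect_setequal(model$subgroup_names, c("MOD", "SIRD-RII", "MARD-II"))
  expect_gt(mean(labels == cohort$subgroup_true), 0.95)

  # identical centroids cannot be named
  degenerate <- structure(list(k = 3,
                               centroids = matrix(0, 3, 2,
                                                  dimnames = list(NULL, c("hba1c", "onset_age"))),
                               assignments = rep(1:3, 5), size = c(5L, 5L, 5L),
                               wss = 0, iterations = 1,
                               classifiers = c("hba1c", "onset_age"),
                               subgroup_names = NULL, scaling = NULL),
                          class = "cluster_model")
  expect_warning(name_subgroups(degenerate), "indistinguishable")
})

test_that("reference assignment matches brute force and k-means fixed point", {
  withr::with_seed(12, {
    cen <- matrix(rnorm(12), 3, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
    newd <- tibble::as_tibble(matrix(rnorm(20), 5, 4,
                                     dimnames = list(NULL, c("a", "b", "c", "d"))))
  })
  lab <- assign_by_reference(newd, cen, scale = FALSE)
  oracle <- apply(as.matrix(newd), 1, function(r) {
    which.min(colSums((t(cen) - r)^2))
  })
  expect_equal(lab, oracle, ignore_attr = TRUE)

  # a row exactly at a centroid belongs to that centroid
  at <- assign_by_reference(tibble::as_tibble(cen), cen, scale = FALSE)
  expect_equal(at, 1:3, ignore_attr = TRUE)

  # applying the model's own raw-scale centroids over the five classifiers
  # reproduces the k-means assignments exactly
  cohort <- simulate_clinical_cohort(seed = 13)
  model <- cluster_cohort(cohort, restarts = 10, seed = 14)
  cen_raw <- unstandardize(model$centroids, model$scaling)
  back <- assign_by_reference(cohort, cen_raw, scaling = model$scaling)
  expect_equal(back, model$assignments, ignore_attr = TRUE)

  # affine rescaling absorbed by the scaling parameters leaves labels unchanged
  shifted <- dplyr::mutate(cohort, bmi = bmi * 3 + 100)
  sc2 <- model$scaling
  sc2$center[sc2$variable == "bmi"] <- sc2$center[sc2$variable == "bmi"] * 3 + 100
  sc2$scale[sc2$variable == "bmi"] <- sc2$scale[sc2$variable == "bmi"] * 3
  cen2 <- cen_raw; cen2[, "bmi"] <- cen2[, "bmi"] * 3 + 100
  expect_equal(assign_by_reference(shifted, cen2, scaling = sc2), back,
               ignore_attr = TRUE)

  expect_error(assign_by_reference(dplyr::select(cohort, -bmi), cen_raw,
                                   scaling = model$scaling), "missing.*bmi")
})
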