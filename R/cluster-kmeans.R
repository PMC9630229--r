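#' Fit k-means by Lloyd's algorithm with k-means++ starts
#'
#' Runs Lloyd's iterations from `restarts` independent k-means++
#' initialisations and keeps the solution with the lowest total
#' within-cluster sum of squares (WSS). Clusters are renumbered canonically
#' by descending size (ties broken by first occurrence), so labels are
#' deterministic up to the data, not the initialisation order. An empty
#' cluster arising during iteration is re-seeded at the point farthest from
#' its assigned centroid.
#'
#' @param x Numeric matrix (rows = observations), typically the standardised
#'   classifier matrix from [standardize()].
#' @param k Number of clusters, `1 <= k <= nrow(x)`.
#' @param restarts Number of independent initialisations (>= 1).
#' @param max_iter Maximum Lloyd iterations per restart.
#' @param tol Convergence tolerance on the decrease of WSS.
#' @param seed Integer seed.
#' @return An object of class `cluster_model`: `k`, `centroids` (k x p, on
#'   the scale of `x`), `assignments`, `wss` (total within-cluster SS),
#'   `size`, and slots `scaling`/`subgroup_names` filled by the pipeline
#'   wrappers.
#' @export
kmeans_fit <- function(x, k, restarts = 25, max_iter = 100, tol = 1e-10,
                       seed = NULL) {
  x <- as.matrix(x)
  if (anyNA(x)) abort("`x` contains missing values.")
  if (k < 1 || k > nrow(x)) abort("`k` must be between 1 and nrow(x).")
  if (restarts < 1) abort("`restarts` must be >= 1.")
  fit <- with_sim_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      cand <- lloyd_once(x, k, max_iter, tol)
      if (is.null(best) || cand$wss < best$wss - 1e-12) best <- cand
    }
    best
  })
  ord <- order(-tabulate(fit$cluster, k), match(seq_len(k), unique(fit$cluster)))
  relabel <- match(seq_len(k), ord)
  centroids <- fit$centers[ord, , drop = FALSE]
  dimnames(centroids) <- list(paste0("cluster", seq_len(k)), colnames(x))
  structure(list(k = k, centroids = centroids,
                 assignments = relabel[fit$cluster],
                 wss = fit$wss, size = tabulate(relabel[fit$cluster], k),
                 iterations = fit$iter, classifiers = colnames(x),
                 scaling = NULL, subgroup_names = NULL),
            class = "cluster_model")
}

# Squared Euclidean distances from each row of x to each row of centers.
dist_to_centers <- function(x, centers) {
  d <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
  pmax(d, 0)
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- dist_to_centers(x, centers[1, , drop = FALSE])[, 1]
    for (j in 2:k) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- x[sample.int(n, 1, prob = probs), ]
      d2 <- pmin(d2, dist_to_centers(x, centers[j, , drop = FALSE])[, 1])
    }
  }
  centers
}

lloyd_once <- function(x, k, max_iter, tol) {
  centers <- kmeanspp_init(x, k)
  cluster <- max.col(-dist_to_centers(x, centers))
  wss <- Inf
  for (iter in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      idx <- which(cluster == j)
      if (length(idx) == 0L) {
        # empty cluster: re-seed at the point farthest from its centroid
        far <- which.max(rowSums((x - centers[cluster, , drop = FALSE])^2))
        centers[j, ] <- x[far, ]
        cluster[far] <- j
      } else {
        centers[j, ] <- colMeans(x[idx, , drop = FALSE])
      }
    }
    d <- dist_to_centers(x, centers)
    cluster <- max.col(-d)
    new_wss <- sum(d[cbind(seq_len(nrow(x)), cluster)])
    if (wss - new_wss < tol) { wss <- new_wss; break }
    wss <- new_wss
  }
  # final centroid update so assignments sit at their own means
  for (j in seq_len(k)) {
    idx <- which(cluster == j)
    if (length(idx)) centers[j, ] <- colMeans(x[idx, , drop = FALSE])
  }
  d <- dist_to_centers(x, centers)
  cluster <- max.col(-d)
  list(centers = centers, cluster = cluster,
       wss = sum(d[cbind(seq_len(nrow(x)), cluster)]), iter = iter)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> k = ", x$k, ", n = ", length(x$assignments),
      ", total WSS = ", signif(x$wss, 6), "\n", sep = "")
  cat("Cluster sizes:", paste(x$size, collapse = ", "), "\n")
  if (!is.null(x$subgroup_names)) {
    cat("Subgroup names:", paste(x$subgroup_names, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Map the three clusters to clinical phenotype names
#'
#' For a three-cluster solution on the five classifiers: the cluster with
#' the highest standardised HbA1c centroid is the severe insulin-resistant
#' subgroup with relative insulin insufficiency (SIRD-RII); of the
#' remaining two, the one with the higher onset-age centroid is the mild
#' age-related subgroup (MARD-II); the last is the mild obesity-related
#' subgroup (MOD). With `k != 3` or indistinguishable centroids, generic
#' `cluster1..k` names are returned with a warning.
#'
#' @param model A `cluster_model` fitted on standardised classifiers whose
#'   columns include `hba1c` and `onset_age`.
#' @return The model with `subgroup_names` filled (one name per cluster).
#' @export
name_subgroups <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  generic <- paste0("cluster", seq_len(model$k))
  cen <- model$centroids
  if (model$k != 3 || !all(c("hba1c", "onset_age") %in% colnames(cen))) {
    warn("Phenotype naming needs k = 3 on the five classifiers; using generic names.")
    model$subgroup_names <- generic
    return(model)
  }
  if (max(stats::dist(cen)) < 1e-8) {
    warn("Centroids are indistinguishable; using generic names.")
    model$subgroup_names <- generic
    return(model)
  }
  names <- character(3)
  sird <- which.max(cen[, "hba1c"])
  names[sird] <- "SIRD-RII"
  rest <- setdiff(1:3, sird)
  mard <- rest[which.max(cen[rest, "onset_age"])]
  names[mard] <- "MARD-II"
  names[setdiff(rest, mard)] <- "MOD"
  model$subgroup_names <- names
  model
}

#' Standardise, cluster and name subgroups in one call
#'
#' The de novo subtyping pipeline: log-transform and standardise the five
#' classifiers, fit k-means, and (for `k = 3`) name the clusters by their
#' phenotype. The fitted scaling parameters are stored on the model so
#' external cohorts can be assigned by reference.
#'
#' @inheritParams standardize
#' @inheritParams kmeans_fit
#' @param k Number of clusters (default 3).
#' @return A `cluster_model` with `scaling` and `subgroup_names` set.
#' @examples
#' cohort <- simulate_clinical_cohort(seed = 1)
#' model <- cluster_cohort(cohort, k = 3, restarts = 10, seed = 1)
#' model$subgroup_names
#' @export
cluster_cohort <- function(data, classifiers = classifier_vars(),
                           log_vars = log_classifiers(), k = 3,
                           restarts = 25, seed = NULL, ...) {
  std <- standardize(data, classifiers, log_vars)
  model <- kmeans_fit(std$x, k, restarts = restarts, seed = seed, ...)
  model$scaling <- std$params
  if (k == 3 && all(c("hba1c", "onset_age") %in% classifiers)) {
    model <- name_subgroups(model)
  } else {
    model$subgroup_names <- paste0("cluster", seq_len(k))
  }
  model
}

#' Extract per-row subgroup labels from a fitted model
#'
#' @param model A `cluster_model`.
#' @return Character vector of phenotype (or generic) labels per row.
#' @export
subgroup_labels <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  names <- model$subgroup_names %||% paste0("cluster", seq_len(model$k))
  names[model$assignments]
}

#' Assign new data to reference centroids by minimal Euclidean distance
#'
#' Implements centroid-reference ("ANDIS-style") assignment: cluster centres
#' from a reference cohort, given as per-cluster means of a chosen variable
#' set on the raw scale, are applied to a new cohort, each row labelled by
#' its nearest centroid. By default both centroids and rows are standardised
#' with the reference cohort's scaling parameters first (otherwise variables
#' measured in large units dominate the distance); `scale = FALSE` gives the
#' strict raw-scale variant. Ties go to the lowest cluster index.
#'
#' @param new_data Data frame containing the centroid variables.
#' @param centroids_raw k x p matrix of per-cluster variable means on the
#'   raw scale, columns named by variable.
#' @param scaling `scaling_params` tibble covering the centroid variables
#'   (required unless `scale = FALSE`).
#' @param scale Standardise before computing distances (default `TRUE`).
#' @return Integer vector of cluster indices (1..k).
#' @export
assign_by_reference <- function(new_data, centroids_raw, scaling = NULL,
                                scale = TRUE) {
  vars <- colnames(centroids_raw)
  missing <- setdiff(vars, names(new_data))
  if (length(missing)) {
    abort(paste0("`new_data` is missing variable(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (scale) {
    if (is.null(scaling)) abort("`scaling` is required when `scale = TRUE`.")
    rows <- standardize(new_data, vars, params = scaling)$x
    cen <- standardize(tibble::as_tibble(centroids_raw), vars, params = scaling)$x
  } else {
    rows <- as.matrix(dplyr::select(tibble::as_tibble(new_data), dplyr::all_of(vars)))
    cen <- centroids_raw
  }
  d <- dist_to_centers(rows, cen)
  apply(d, 1, which.min)
}

#' Raw-scale centroids of a fitted model
#'
#' Per-cluster means of the (optionally different) variable set on the raw
#' scale, as used to build reference coordinates for external assignment.
#'
#' @param data The data the model was fitted on (or any data with labels).
#' @param labels Cluster labels per row (integer or character).
#' @param vars Variables to average.
#' @return Matrix with one row per label level, columns = `vars`.
#' @export
raw_centroids <- function(data, labels, vars) {
  df <- tibble::as_tibble(data)[vars]
  out <- rowsum(as.matrix(df), labels) / as.vector(table(labels))
  out[order(rownames(out)), , drop = FALSE]
}
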