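#' Bootstrap Jaccard stability of a k-means partition
#'
#' For each of `B` nonparametric bootstraps the rows are resampled with
#' replacement and k-means is re-fitted with the same k. Each original
#' cluster is then matched greedily to the bootstrap cluster maximising the
#' Jaccard index, with membership counted over distinct original rows
#' (both sets restricted to rows present in the bootstrap sample). A
#' bootstrap replicate in which an original cluster has no resampled member
#' carries no information about that cluster and is excluded from its mean.
#' A mean Jaccard near 1 indicates a stable cluster; dissolved clusters
#' drift towards 0.5 and below.
#'
#' @param x The matrix the model was fitted on.
#' @param model A `cluster_model` from [kmeans_fit()] / [cluster_cohort()].
#' @param B Number of bootstrap resamples (>= 1).
#' @param restarts Restarts for each bootstrap re-fit.
#' @param seed Integer seed.
#' @return An object of class `stability_report`: `mean_jaccard` (length-k),
#'   `per_bootstrap` (B x k matrix), `B`.
#' @export
jaccard_stability <- function(x, model, B = 500, restarts = 10, seed = NULL) {
  stopifnot(inherits(model, "cluster_model"), B >= 1)
  x <- as.matrix(x)
  n <- nrow(x)
  k <- model$k
  orig <- lapply(seq_len(k), function(j) which(model$assignments == j))
  per <- with_sim_seed(seed, {
    out <- matrix(NA_real_, B, k)
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      fit <- kmeans_fit(x[idx, , drop = FALSE], k, restarts = restarts)
      u <- unique(idx)
      cl_u <- fit$assignments[match(u, idx)]
      boot_sets <- lapply(seq_len(k), function(j) u[cl_u == j])
      for (j in seq_len(k)) {
        A <- intersect(orig[[j]], u)
        out[b, j] <- if (length(A) == 0L) NA_real_ else {
          max(vapply(boot_sets, function(C) {
            jaccard_index(A, C)
          }, numeric(1)))
        }
      }
    }
    out
  })
  structure(list(mean_jaccard = colMeans(per, na.rm = TRUE),
                 per_bootstrap = per, B = B),
            class = "stability_report")
}

#' Jaccard index of two sets
#'
#' `|A intersect B| / |A union B|`; 1 for two empty sets by convention.
#' @param a,b Vectors treated as sets.
#' @return A value in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report> B =", x$B, "bootstraps\n")
  cat("Mean Jaccard per cluster:",
      paste(sprintf("%.3f", x$mean_jaccard), collapse = ", "), "\n")
  invisible(x)
}

#' Agreement and Cohen's kappa between two labelings
#'
#' Aligns the two labelings by the permutation of the smaller label set that
#' maximises agreement (exact search over permutations, equivalent to
#' Hungarian assignment on the confusion matrix for k <= 8), then reports
#' the agreement fraction and Cohen's kappa
#' `(po - pe) / (1 - pe)` on the aligned labels.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Tibble with `agreement`, `kappa` and the aligned confusion matrix
#'   as an attribute `confusion`.
#' @export
concordance <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) abort("Label vectors differ in length.")
  a <- factor(labels_a)
  b <- factor(labels_b)
  la <- levels(a); lb <- levels(b)
  if (length(lb) > length(la)) { tmp <- a; a <- b; b <- tmp; tmp <- la; la <- lb; lb <- tmp }
  if (length(lb) > 8) abort("Exact label alignment supports at most 8 classes.")
  conf <- table(a, b)
  # map each level of b onto a distinct level of a, maximising the diagonal
  perms <- perms_of(seq_along(la), length(lb))
  best <- perms[[which.max(vapply(perms, function(p) {
    sum(conf[cbind(p, seq_along(lb))])
  }, numeric(1)))]]
  b_aligned <- factor(la[best[as.integer(b)]], levels = la)
  conf2 <- table(factor(a, levels = la), b_aligned)
  n <- length(a)
  po <- sum(diag(conf2)) / n
  pe <- sum(rowSums(conf2) * colSums(conf2)) / n^2
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  out <- tibble::tibble(agreement = po, kappa = kappa)
  attr(out, "confusion") <- conf2
  out
}

# All injections of 1..m into `from` (permutations of `from` taken m at a time).
perms_of <- function(from, m) {
  if (m == 0) return(list(integer(0)))
  out <- list()
  for (i in seq_along(from)) {
    for (rest in perms_of(from[-i], m - 1)) {
      out[[length(out) + 1L]] <- c(from[i], rest)
    }
  }
  out
}
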