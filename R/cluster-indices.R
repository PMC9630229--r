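#' Internal cluster-validity indices
#'
#' Twelve internal validity indices with known closed forms, used as the
#' "electorate" for majority voting on the number of clusters:
#' Calinski-Harabasz, average silhouette width, Davies-Bouldin, Dunn,
#' C-index, Ball-Hall difference, Hartigan rule, Krzanowski-Lai,
#' McClain-Rao, point-biserial, Ratkowsky-Lance and Xie-Beni. Each index
#' carries its own optimality direction; three (Ball-Hall, Hartigan,
#' Krzanowski-Lai) compare adjacent values of k rather than scoring each k
#' in isolation.
#'
#' @return Character vector of the default index names.
#' @export
validity_indices <- function() {
  c("calinski_harabasz", "silhouette", "davies_bouldin", "dunn", "c_index",
    "ball_hall", "hartigan", "krzanowski_lai", "mcclain_rao",
    "point_biserial", "ratkowsky_lance", "xie_beni")
}

index_silhouette <- function(D, cluster) {
  k <- max(cluster)
  n <- length(cluster)
  if (k < 2) return(NA_real_)
  sizes <- tabulate(cluster, k)
  # mean distance of each point to each cluster
  md <- sapply(seq_len(k), function(j) rowSums(D[, cluster == j, drop = FALSE]))
  md <- sweep(md, 2, sizes, "/")
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- cluster[i]
    if (sizes[ci] <= 1) { s[i] <- 0; next }
    a <- md[i, ci] * sizes[ci] / (sizes[ci] - 1)  # exclude self
    b <- min(md[i, -ci])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

index_dunn <- function(D, cluster) {
  k <- max(cluster)
  diam <- max(sapply(seq_len(k), function(j) {
    idx <- cluster == j
    if (sum(idx) < 2) 0 else max(D[idx, idx])
  }))
  sep <- min(sapply(seq_len(k - 1), function(i) {
    min(sapply((i + 1):k, function(j) min(D[cluster == i, cluster == j])))
  }))
  if (diam == 0) return(NA_real_)
  sep / diam
}

index_davies_bouldin <- function(x, cluster, centers) {
  k <- nrow(centers)
  s <- sapply(seq_len(k), function(j) {
    idx <- cluster == j
    mean(sqrt(rowSums((x[idx, , drop = FALSE] -
                         matrix(centers[j, ], sum(idx), ncol(x), byrow = TRUE))^2)))
  })
  M <- as.matrix(stats::dist(centers))
  r <- sapply(seq_len(k), function(i) {
    max(((s[i] + s[-i]) / M[i, -i]))
  })
  mean(r)
}

index_xie_beni <- function(x, cluster, centers, wgss) {
  sep <- min(stats::dist(centers))^2
  if (sep == 0) return(NA_real_)
  wgss / (nrow(x) * sep)
}

index_ratkowsky_lance <- function(x, cluster, k) {
  tssj <- colSums(sweep(x, 2, colMeans(x))^2)
  centers <- rowsum(x, cluster) / as.vector(table(cluster))
  sizes <- as.vector(table(cluster))
  bgssj <- colSums(sizes * sweep(centers, 2, colMeans(x))^2)
  mean(sqrt(bgssj / tssj)) / sqrt(k)
}

#' Choose the number of clusters by majority voting over validity indices
#'
#' For each candidate k, fits k-means ([kmeans_fit()]) and evaluates every
#' configured validity index. Each index casts one vote for the k it deems
#' optimal under its own direction (adjacent-difference indices use fits at
#' k - 1 and k + 1 as needed); an index whose score is undefined for every
#' candidate abstains. The winning k is the modal vote, ties broken to the
#' smallest k.
#'
#' @param x Standardised numeric matrix.
#' @param k_range Candidate numbers of clusters (default `2:8`).
#' @param indices Subset of [validity_indices()].
#' @param restarts Restarts per k-means fit.
#' @param seed Integer seed.
#' @return An object of class `k_vote`: `scores` (tibble index x k),
#'   `preferred` (per-index vote, `NA` = abstained), `votes` (count per k)
#'   and `best_k`.
#' @export
select_k_majority_vote <- function(x, k_range = 2:8,
                                   indices = validity_indices(),
                                   restarts = 10, seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > n - 1) {
    abort("`k_range` must lie within [2, nrow(x) - 1].")
  }
  indices <- match.arg(indices, validity_indices(), several.ok = TRUE)
  D <- as.matrix(stats::dist(x))
  tss <- sum(sweep(x, 2, colMeans(x))^2)
  dvec <- sort(D[lower.tri(D)])
  csum <- cumsum(dvec)
  csum_desc <- cumsum(rev(dvec))

  k_fit <- sort(unique(c(k_range, k_range - 1L, k_range + 1L)))
  k_fit <- k_fit[k_fit >= 1 & k_fit <= n]
  fits <- with_sim_seed(seed, {
    setNames(lapply(k_fit, function(k) {
      if (k == 1) {
        list(centroids = matrix(colMeans(x), 1, ncol(x)),
             assignments = rep(1L, n), wss = tss)
      } else kmeans_fit(x, k, restarts = restarts)
    }), as.character(k_fit))
  })
  wgss <- vapply(fits, `[[`, numeric(1), "wss")

  score_one <- function(index, k) {
    f <- fits[[as.character(k)]]
    cl <- f$assignments
    cen <- f$centroids
    same <- outer(cl, cl, "==")
    lower <- lower.tri(D)
    nw <- as.numeric(sum(same & lower)); nb <- as.numeric(sum(!same & lower))
    sw <- sum(D[same & lower]); sb <- sum(D[!same & lower])
    w <- f$wss
    switch(index,
      calinski_harabasz = ((tss - w) / (k - 1)) / (w / (n - k)),
      silhouette = index_silhouette(D, cl),
      davies_bouldin = index_davies_bouldin(x, cl, cen),
      dunn = index_dunn(D, cl),
      c_index = {
        smin <- csum[nw]; smax <- csum_desc[nw]
        if (smax == smin) NA_real_ else (sw - smin) / (smax - smin)
      },
      mcclain_rao = if (nw == 0 || sb == 0) NA_real_ else (sw / nw) / (sb / nb),
      point_biserial = {
        sdv <- stats::sd(D[lower])
        if (sdv == 0) NA_real_ else
          ((sb / nb) - (sw / nw)) * sqrt(nw * nb / (nw + nb)^2) / sdv
      },
      ratkowsky_lance = index_ratkowsky_lance(x, cl, k),
      xie_beni = index_xie_beni(x, cl, cen, w),
      ball_hall = w / k,
      hartigan = {
        nxt <- wgss[[as.character(k + 1)]] %||% NA_real_
        if (is.na(nxt)) NA_real_ else (w / nxt - 1) * (n - k - 1)
      },
      krzanowski_lai = {
        p <- ncol(x)
        diff_at <- function(kk) {
          wp <- wgss[[as.character(kk - 1)]] %||% NA_real_
          wk <- wgss[[as.character(kk)]] %||% NA_real_
          (kk - 1)^(2 / p) * wp - kk^(2 / p) * wk
        }
        d1 <- diff_at(k); d2 <- diff_at(k + 1)
        if (anyNA(c(d1, d2)) || d2 == 0) NA_real_ else abs(d1 / d2)
      })
  }

  scores <- tidyr::expand_grid(index = indices, k = k_range) |>
    dplyr::mutate(score = purrr::map2_dbl(.data$index, .data$k,
                                          ~ tryCatch(score_one(.x, .y),
                                                     error = function(e) NA_real_)))
  direction <- c(calinski_harabasz = "max", silhouette = "max",
                 davies_bouldin = "min", dunn = "max", c_index = "min",
                 ball_hall = "elbow", hartigan = "rule", krzanowski_lai = "max",
                 mcclain_rao = "min", point_biserial = "max",
                 ratkowsky_lance = "max", xie_beni = "min")
  preferred <- scores |>
    dplyr::group_by(.data$index) |>
    dplyr::summarise(k_preferred = {
      s <- .data$score; kk <- .data$k
      dir <- direction[[.data$index[1]]]
      if (all(is.na(s))) NA_integer_
      else if (dir == "max") kk[which.max(s)]
      else if (dir == "min") kk[which.min(s)]
      else if (dir == "elbow") {
        # difference-based index: largest drop between successive candidate
        # k (evaluated within the searched range only)
        if (sum(!is.na(s)) < 2) NA_integer_ else kk[which.max(-diff(s)) + 1L]
      } else { # Hartigan: smallest k whose statistic drops to <= 10; when
               # it never gets there, the within-range elbow votes
        ok <- which(!is.na(s) & s <= 10)
        if (length(ok)) kk[min(ok)]
        else if (sum(!is.na(s)) >= 2) {
          drop <- -diff(s)
          if (all(is.na(drop))) NA_integer_ else kk[which.max(drop) + 1L]
        } else NA_integer_
      }
    }, .groups = "drop")
  votes <- preferred |>
    dplyr::filter(!is.na(.data$k_preferred)) |>
    dplyr::count(k = .data$k_preferred, name = "votes")
  best_k <- if (nrow(votes)) {
    min(votes$k[votes$votes == max(votes$votes)])
  } else NA_integer_
  structure(list(scores = scores, preferred = preferred, votes = votes,
                 best_k = best_k, k_range = k_range),
            class = "k_vote")
}

#' @export
print.k_vote <- function(x, ...) {
  cat("<k_vote> winning k =", x$best_k, "\n")
  print(x$votes)
  invisible(x)
}
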