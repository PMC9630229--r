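#' Tidy a fitted cluster model
#'
#' One row per cluster with its phenotype name, size and standardised
#' centroid coordinates.
#'
#' @param x A `cluster_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cluster_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(cluster = seq_len(x$k),
                   subgroup = x$subgroup_names %||%
                     paste0("cluster", seq_len(x$k)),
                   size = x$size),
    tibble::as_tibble(x$centroids))
}

#' @rdname tidy.cluster_model
#' @export
glance.cluster_model <- function(x, ...) {
  tibble::tibble(k = x$k, n = length(x$assignments), tot_withinss = x$wss,
                 iterations = x$iterations)
}

#' Tidy methods for association and survival fits
#'
#' `tidy()` returns the coefficient table; `glance()` one-row model
#' summaries.
#'
#' @param x A `prs_fit`, `cox_fit`, `k_vote` or `stability_report` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.prs_fit <- function(x, ...) x$table

#' @rdname tidy.prs_fit
#' @export
glance.prs_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(n = x$n, r_squared = s$r.squared, sigma = s$sigma,
                 reference = x$reference)
}

#' @rdname tidy.prs_fit
#' @export
tidy.cox_fit <- function(x, ...) x$table

#' @rdname tidy.prs_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_event = x$n_event, loglik = x$loglik,
                 reference = x$reference)
}

#' @rdname tidy.prs_fit
#' @export
tidy.k_vote <- function(x, ...) x$preferred

#' @rdname tidy.prs_fit
#' @export
glance.k_vote <- function(x, ...) {
  tibble::tibble(best_k = x$best_k,
                 votes = if (nrow(x$votes)) max(x$votes$votes) else 0L,
                 electorate = nrow(x$preferred),
                 abstentions = sum(is.na(x$preferred$k_preferred)))
}

#' @rdname tidy.prs_fit
#' @export
tidy.stability_report <- function(x, ...) {
  tibble::tibble(cluster = seq_along(x$mean_jaccard),
                 mean_jaccard = x$mean_jaccard)
}

#' @rdname tidy.prs_fit
#' @export
glance.stability_report <- function(x, ...) {
  tibble::tibble(B = x$B, min_jaccard = min(x$mean_jaccard))
}
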